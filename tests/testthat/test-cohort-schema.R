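test_that("encoding min-max scales, one-hot encodes and flags missing labs", {
  em <- encode(toy_cohort())
  expect_equal(unname(em$data[, "age"]), c(0, 0.5, 1))
  drug_block <- em$data[, c("drug.t0", "drug.A", "drug.B")]
  expect_equal(unname(drug_block),
               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  # missing lab: sentinel 0 in the value column, indicator 1
  expect_equal(unname(em$data[2, "ldl"]), 0)
  expect_equal(unname(em$data[, "ldl.missing"]), c(0, 1, 0))
  expect_true(all(em$data >= 0 & em$data <= 1))
})

test_that("encoded width matches the hand-counted toy schema", {
  em <- encode(toy_cohort())
  # age(1) + drug(3 one-hot) + sbp_pre(1) + sbp_post(1) + ldl(1 + indicator)
  expect_identical(ncol(em$data), 8L)
  expect_identical(nrow(em$colmap), 8L)
})

test_that("a constant continuous column encodes to all zeros", {
  sc <- cohort_schema(list(
    variable_spec("x", "continuous", range = c(5, 5 + 1e-12)),
    variable_spec("drug", "categorical", categories = c("t0", "A"),
                  role = "treatment"),
    variable_spec("pre", "continuous", range = c(0, 10), role = "pre_lab"),
    variable_spec("post", "continuous", range = c(0, 10),
                  role = "post_lab")))
  # degenerate range handled through dates too: a single distinct date
  ct <- cohort_table(data.frame(x = rep(5, 3), drug = c("t0", "A", "A"),
                                pre = 1:3, post = 3:1), sc)
  em <- encode(ct)
  expect_true(all(em$data[, "x"] == 0) || all(abs(em$data[, "x"]) < 1e-10))
})

test_that("decode inverts encode exactly (categorical/date) and to 1e-9 (continuous)", {
  fx <- small_fixture(n = 200, seed = 7)
  em <- encode(fx$cohort)
  back <- decode(em)
  orig <- fx$cohort$data
  for (nm in names(orig)) {
    v0 <- orig[[nm]]; v1 <- back$data[[nm]]
    expect_identical(is.na(v0), is.na(v1), info = nm)
    ok <- !is.na(v0)
    if (is.numeric(v0)) {
      rel <- abs(v1[ok] - v0[ok]) / pmax(abs(v0[ok]), 1)
      expect_lt(max(rel, 0), 1e-9)
    } else {
      expect_identical(v1[ok], if (inherits(v0, "Date")) v0[ok] else v0[ok],
                       info = nm)
    }
  }
})

test_that("decode resolves soft one-hot blocks by argmax and indicators by threshold", {
  em <- encode(toy_cohort())
  m <- em$data
  m[1, c("drug.t0", "drug.A", "drug.B")] <- c(0.2, 0.7, 0.1)
  m[3, "ldl.missing"] <- 0.6
  m[3, "ldl"] <- 0.3
  back <- decode(encoded_matrix(m, em))
  expect_identical(back$data$drug[1], "A")
  expect_true(is.na(back$data$ldl[3]))
})

test_that("encoding rejects out-of-range values and unknown categories by name", {
  df <- toy_cohort()$data
  bad <- df; bad$age[2] <- 95
  expect_error(cohort_table(bad, toy_schema()), "age")
  bad <- df; bad$drug[1] <- "Z"
  expect_error(cohort_table(bad, toy_schema()), "drug")
})

test_that("partition separates covariates/treatment/outcome and excludes flagged variables", {
  fx <- small_fixture(n = 300, arms = 11, seed = 2)
  em <- encode(fx$cohort)
  part <- partition(em)
  expect_length(part$treatment_cols, 11L)
  cm <- em$colmap
  cov_vars <- unique(cm$variable[cm$col %in% part$covariate_cols])
  expect_false(any(c("drugs", "prior_drugs", "zip_cd", "sbp_post") %in%
                     cov_vars))
  expect_true("sbp_pre" %in% cov_vars)
  expect_length(intersect(part$covariate_cols, part$treatment_cols), 0L)
  # outcome is post minus pre on the original scale
  em2 <- encode(toy_cohort())
  expect_equal(outcome_delta(em2), c(-12, -10, 5))
})

test_that("encoded entries stay in [0,1] for random fixtures (property)", {
  for (s in 1:5) {
    em <- encode(small_fixture(n = 150, arms = 3, seed = s,
                               missingness_rate = 0.5)$cohort)
    expect_true(all(em$data >= 0 & em$data <= 1))
    # every one-hot block of a valid record sums to exactly 1
    for (v in unique(em$colmap$variable)) {
      oh <- em$colmap$col[em$colmap$variable == v &
                            em$colmap$role == "onehot"]
      if (length(oh))
        expect_true(all(rowSums(em$data[, oh, drop = FALSE]) == 1))
    }
  }
})

test_that("cohort CSV + schema YAML roundtrip is the identity", {
  fx <- small_fixture(n = 120, seed = 3)
  csv <- tempfile(fileext = ".csv"); yml <- tempfile(fileext = ".yaml")
  write_cohort(fx$cohort, csv, schema_path = yml)
  back <- read_cohort(csv, yml)
  expect_equal(back$data, fx$cohort$data)
  # empty cell in a lab column comes back as a missing marker
  expect_true(anyNA(back$data$lab1))
})

test_that("reading a CSV without the treatment column names the problem", {
  fx <- small_fixture(n = 120, seed = 3)
  csv <- tempfile(fileext = ".csv")
  df <- fx$cohort$data; df$drugs <- NULL
  utils::write.csv(df, csv, row.names = FALSE, na = "")
  expect_error(read_cohort(csv, fx$schema), "drugs")
})
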