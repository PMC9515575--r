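#' Declare a patient variable
#'
#' A variable spec describes one column of a patient cohort: its type, its
#' admissible values, which Table-1-style family it belongs to, whether missing
#' values are allowed (lab measurements), and whether it plays a designated
#' role (the treatment, or the pre/post lab pair that defines the outcome).
#'
#' @param name Column name (identifier).
#' @param kind One of `"continuous"`, `"categorical"`, `"date"`, `"binary"`.
#' @param family Variable family label, `"F1"`..`"F8"`.
#' @param categories Character vector of levels (categorical only, >= 2).
#' @param range Length-2 numeric `(min, max)` for continuous, or a pair of
#'   dates (anything `as.Date` accepts) for date variables.
#' @param missingness_allowed If `TRUE` the encoded matrix carries a paired
#'   binary missing-value indicator column for this variable.
#' @param role `"none"`, `"treatment"`, `"pre_lab"` or `"post_lab"`. Exactly
#'   one variable per schema may hold each non-`"none"` role.
#' @param covariate If `FALSE` the variable is excluded from the covariate
#'   domain (e.g. zip code, prior drugs). The treatment and the post-treatment
#'   lab are always excluded regardless of this flag.
#' @param reference For the treatment variable, the no-treatment level
#'   (defaults to the first category).
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind, family = "F4", categories = NULL,
                          range = NULL, missingness_allowed = FALSE,
                          role = "none", covariate = TRUE, reference = NULL) {
  kind <- match.arg(kind, c("continuous", "categorical", "date", "binary"))
  role <- match.arg(role, c("none", "treatment", "pre_lab", "post_lab"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2L)
      stop("categorical variable '", name, "' needs >= 2 categories")
    categories <- as.character(categories)
    if (anyDuplicated(categories))
      stop("duplicate categories in '", name, "'")
  } else if (kind %in% c("continuous", "date")) {
    if (is.null(range) || length(range) != 2L)
      stop("variable '", name, "' needs a (min, max) range")
    if (kind == "date") range <- as.Date(range)
    if (!(range[1] < range[2]))
      stop("variable '", name, "': range min must be < max")
  }
  if (role == "treatment") {
    if (kind != "categorical")
      stop("the treatment variable must be categorical")
    if (is.null(reference)) reference <- categories[1]
    if (!reference %in% categories)
      stop("treatment reference level '", reference,
           "' is not among the categories")
  }
  if (role %in% c("pre_lab", "post_lab") && kind != "continuous")
    stop("pre/post lab variables must be continuous")
  structure(list(name = name, kind = kind, family = family,
                 categories = categories, range = range,
                 missingness_allowed = isTRUE(missingness_allowed),
                 role = role, covariate = isTRUE(covariate),
                 reference = reference),
            class = "variable_spec")
}

#' Assemble a cohort schema
#'
#' Validates that the collection of [variable_spec()]s forms a usable patient
#' data model: unique names, exactly one treatment variable (whose categories
#' include the no-treatment reference), and exactly one pre-lab and one
#' post-lab variable, which together define the outcome (post minus pre on the
#' original measurement scale).
#'
#' @param specs A list of [variable_spec()] objects.
#' @return An object of class `cohort_schema`.
#' @export
cohort_schema <- function(specs) {
  if (inherits(specs, "variable_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 3L,
            all(vapply(specs, inherits, TRUE, "variable_spec")))
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate variable names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  roles <- vapply(specs, `[[`, "", "role")
  for (r in c("treatment", "pre_lab", "post_lab")) {
    k <- sum(roles == r)
    if (k != 1L) stop("schema must designate exactly one '", r,
                      "' variable (found ", k, ")")
  }
  names(specs) <- nms
  structure(list(specs = specs,
                 treatment = nms[roles == "treatment"],
                 pre_lab = nms[roles == "pre_lab"],
                 post_lab = nms[roles == "post_lab"]),
            class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("cohort_schema:", length(x$specs), "variables; treatment =",
      x$treatment, "; outcome =", x$post_lab, "-", x$pre_lab, "\n")
  invisible(x)
}

schema_spec <- function(schema, name) schema$specs[[name]]

#' Bind patient records to a schema
#'
#' Validates a data frame of patient records against a [cohort_schema()]:
#' every non-missing value must lie in its spec's range or category set,
#' missing values (`NA`) are only allowed where the spec permits them, and
#' each patient carries exactly one treatment level.
#'
#' @param data A data frame, one row per patient, with the schema's columns.
#' @param schema A [cohort_schema()].
#' @return An object of class `cohort_table` (a validated data frame plus
#'   schema).
#' @export
cohort_table <- function(data, schema) {
  stopifnot(is.data.frame(data), inherits(schema, "cohort_schema"))
  nms <- names(schema$specs)
  missing_cols <- setdiff(nms, names(data))
  extra_cols <- setdiff(names(data), nms)
  if (length(missing_cols) || length(extra_cols))
    stop("columns do not match schema",
         if (length(missing_cols)) paste0("; missing: ",
                                          paste(missing_cols, collapse = ", ")),
         if (length(extra_cols)) paste0("; unexpected: ",
                                        paste(extra_cols, collapse = ", ")))
  data <- data[nms]
  for (sp in schema$specs) {
    v <- data[[sp$name]]
    if (anyNA(v) && !sp$missingness_allowed)
      stop("variable '", sp$name, "' has missing values but the schema ",
           "does not allow them")
    ok <- !is.na(v)
    switch(sp$kind,
      continuous = {
        if (!is.numeric(v)) stop("'", sp$name, "' must be numeric")
        bad <- ok & (v < sp$range[1] | v > sp$range[2])
        if (any(bad))
          stop("value out of declared range in variable '", sp$name, "': ",
               v[bad][1], " not in [", sp$range[1], ", ", sp$range[2], "]")
      },
      date = {
        v <- as.Date(v)
        data[[sp$name]] <- v
        bad <- ok & (v < sp$range[1] | v > sp$range[2])
        if (any(bad))
          stop("date out of declared range in variable '", sp$name, "'")
      },
      categorical = {
        v <- as.character(v)
        data[[sp$name]] <- v
        bad <- ok & !(v %in% sp$categories)
        if (any(bad))
          stop("unknown category in variable '", sp$name, "': '",
               v[bad][1], "'")
      },
      binary = {
        v <- as.numeric(v)
        data[[sp$name]] <- v
        bad <- ok & !(v %in% c(0, 1))
        if (any(bad))
          stop("binary variable '", sp$name, "' must be 0/1")
      })
  }
  structure(list(data = data, schema = schema), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$data), "patients x", ncol(x$data),
      "variables\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$data)

# ---- encoding ---------------------------------------------------------------

date_offsets <- function(v, epoch) as.numeric(v) - as.numeric(epoch)

#' Encode a cohort into the unit-interval numeric feature space
#'
#' Continuous variables are min-max scaled to `[0,1]` using their declared
#' range; dates are converted to integer day offsets from the earliest date
#' observed in the column and then min-max scaled; categorical variables are
#' one-hot encoded; binary variables pass through as 0/1. Every variable that
#' allows missingness gets a paired binary missing-value indicator column;
#' missing entries are imputed with the sentinel 0 after scaling and flagged
#' by indicator = 1. A constant (degenerate-range) column encodes as all 0.
#'
#' @param cohort A [cohort_table()].
#' @return An object of class `encoded_matrix`: list with `data` (N x d matrix
#'   in `[0,1]`), `colmap` (data frame mapping encoded columns to source
#'   variable, role and level), `transforms` (per-variable scaling metadata
#'   needed by [decode()]), and the `schema`.
#' @export
encode <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$data
  n <- nrow(df)
  cols <- list(); map <- list(); transforms <- list()
  for (sp in cohort$schema$specs) {
    v <- df[[sp$name]]
    miss <- is.na(v)
    switch(sp$kind,
      continuous = {
        lo <- sp$range[1]; hi <- sp$range[2]
        span <- hi - lo
        x <- if (span > 0) (as.numeric(v) - lo) / span else rep(0, n)
        x[miss] <- 0
        cols[[length(cols) + 1L]] <- x
        map[[length(map) + 1L]] <- c(sp$name, "value", NA)
        transforms[[sp$name]] <- list(kind = "continuous", min = lo, max = hi)
      },
      date = {
        obs <- v[!miss]
        if (length(obs)) {
          epoch <- min(obs)
          span <- as.numeric(max(obs)) - as.numeric(epoch)
          off <- date_offsets(v, epoch)
          x <- if (span > 0) off / span else rep(0, n)
        } else {
          epoch <- NA; span <- 0
          x <- rep(0, n)
        }
        x[miss] <- 0
        cols[[length(cols) + 1L]] <- x
        map[[length(map) + 1L]] <- c(sp$name, "value", NA)
        transforms[[sp$name]] <- list(kind = "date", epoch = epoch,
                                      span = span)
      },
      categorical = {
        for (lev in sp$categories) {
          x <- as.numeric(!miss & v == lev)
          cols[[length(cols) + 1L]] <- x
          map[[length(map) + 1L]] <- c(sp$name, "onehot", lev)
        }
        transforms[[sp$name]] <- list(kind = "categorical",
                                      categories = sp$categories)
      },
      binary = {
        x <- as.numeric(v); x[miss] <- 0
        cols[[length(cols) + 1L]] <- x
        map[[length(map) + 1L]] <- c(sp$name, "value", NA)
        transforms[[sp$name]] <- list(kind = "binary")
      })
    if (sp$missingness_allowed) {
      cols[[length(cols) + 1L]] <- as.numeric(miss)
      map[[length(map) + 1L]] <- c(sp$name, "indicator", NA)
    }
  }
  m <- do.call(cbind, cols)
  cm <- do.call(rbind, map)
  colmap <- data.frame(col = seq_len(ncol(m)), variable = cm[, 1],
                       role = cm[, 2], level = cm[, 3],
                       stringsAsFactors = FALSE)
  colnames(m) <- ifelse(colmap$role == "onehot",
                        paste0(colmap$variable, ".", colmap$level),
                        ifelse(colmap$role == "indicator",
                               paste0(colmap$variable, ".missing"),
                               colmap$variable))
  stopifnot(all(m >= 0 & m <= 1))
  structure(list(data = m, colmap = colmap, transforms = transforms,
                 schema = cohort$schema),
            class = "encoded_matrix")
}

#' @export
dim.encoded_matrix <- function(x) dim(x$data)

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("encoded_matrix:", nrow(x$data), "patients x", ncol(x$data),
      "features in [0,1]\n")
  invisible(x)
}

#' Decode an encoded matrix back to a cohort table
#'
#' Inverse of [encode()]. Continuous values are rescaled to their original
#' range; date offsets are rounded back to whole days; each one-hot block is
#' resolved to its argmax category (lowest index wins ties); a missing-value
#' indicator `>= 0.5` makes the value missing; binary columns threshold at
#' 0.5. One-hot blocks need not sum to 1 (raw generator output is accepted).
#'
#' @param em An `encoded_matrix`.
#' @return A [cohort_table()]; `decode(encode(x))` reproduces `x` exactly for
#'   categorical/binary/date variables and to 1e-9 relative error for
#'   continuous ones.
#' @export
decode <- function(em) {
  stopifnot(inherits(em, "encoded_matrix"))
  m <- em$data
  if (ncol(m) != nrow(em$colmap))
    stop("colmap inconsistent with matrix width: ", ncol(m), " columns vs ",
         nrow(em$colmap), " colmap rows")
  n <- nrow(m)
  out <- list()
  for (sp in em$schema$specs) {
    rows_cm <- em$colmap[em$colmap$variable == sp$name, ]
    tr <- em$transforms[[sp$name]]
    vcol <- rows_cm$col[rows_cm$role %in% c("value")]
    icol <- rows_cm$col[rows_cm$role == "indicator"]
    miss <- if (length(icol)) m[, icol] >= 0.5 else rep(FALSE, n)
    v <- switch(sp$kind,
      continuous = m[, vcol] * (tr$max - tr$min) + tr$min,
      date = {
        if (is.na(tr$epoch)[1]) as.Date(rep(NA, n))
        else as.Date(round(m[, vcol] * tr$span), origin = tr$epoch)
      },
      categorical = {
        oc <- rows_cm[rows_cm$role == "onehot", ]
        block <- m[, oc$col, drop = FALSE]
        oc$level[max.col(block, ties.method = "first")]
      },
      binary = as.numeric(m[, vcol] >= 0.5))
    v[miss] <- NA
    out[[sp$name]] <- v
  }
  cohort_table(as.data.frame(out, stringsAsFactors = FALSE), em$schema)
}

#' Partition the encoded feature space into covariates, treatment, outcome
#'
#' The treatment block is the one-hot columns of the designated treatment
#' variable; the outcome column is the post-treatment lab; the covariate
#' columns are everything else except the post-lab (and its indicator) and
#' variables flagged `covariate = FALSE` in the schema (drugs, prior drugs,
#' zip code). The outcome itself is defined as post-lab minus pre-lab on the
#' original (decoded) measurement scale; see [outcome_delta()].
#'
#' @param em An `encoded_matrix`.
#' @return An object of class `domain_partition` with index sets
#'   `covariate_cols`, `treatment_cols`, `outcome_col`, plus `pre_col`,
#'   `treatment_levels` and the no-treatment `reference` level.
#' @export
partition <- function(em) {
  stopifnot(inherits(em, "encoded_matrix"))
  sc <- em$schema
  cm <- em$colmap
  tsp <- schema_spec(sc, sc$treatment)
  treat_cols <- cm$col[cm$variable == sc$treatment & cm$role == "onehot"]
  post_cols <- cm$col[cm$variable == sc$post_lab]
  pre_col <- cm$col[cm$variable == sc$pre_lab & cm$role == "value"]
  excluded_vars <- names(sc$specs)[!vapply(sc$specs, `[[`, TRUE, "covariate")]
  excluded_vars <- union(excluded_vars, c(sc$treatment, sc$post_lab))
  cov_cols <- cm$col[!(cm$variable %in% excluded_vars)]
  out <- structure(list(covariate_cols = cov_cols,
                        treatment_cols = treat_cols,
                        outcome_col = post_cols[1],
                        pre_col = pre_col,
                        treatment_levels = tsp$categories,
                        reference = tsp$reference),
                   class = "domain_partition")
  stopifnot(length(intersect(cov_cols, treat_cols)) == 0L,
            !(out$outcome_col %in% cov_cols),
            ncol(em$data) >= length(cov_cols) + length(treat_cols) + 1L)
  out
}

#' Outcome on the original measurement scale
#'
#' Returns post-treatment lab minus pre-treatment lab (e.g. change in systolic
#' blood pressure in mmHg) for every patient, decoded from the encoded matrix.
#'
#' @param em An `encoded_matrix`.
#' @return Numeric vector of length N.
#' @export
outcome_delta <- function(em) {
  sc <- em$schema
  cm <- em$colmap
  pre_sp <- schema_spec(sc, sc$pre_lab)
  post_sp <- schema_spec(sc, sc$post_lab)
  pre_col <- cm$col[cm$variable == sc$pre_lab & cm$role == "value"]
  post_col <- cm$col[cm$variable == sc$post_lab & cm$role == "value"]
  pre <- em$data[, pre_col] * (pre_sp$range[2] - pre_sp$range[1]) +
    pre_sp$range[1]
  post <- em$data[, post_col] * (post_sp$range[2] - post_sp$range[1]) +
    post_sp$range[1]
  post - pre
}

#' Assigned treatment level per patient
#'
#' Resolves the treatment one-hot block of an encoded matrix to a character
#' vector of levels (argmax, lowest index on ties).
#'
#' @param em An `encoded_matrix`.
#' @param part Optional [partition()] (recomputed if omitted).
#' @return Character vector of treatment levels.
#' @export
treatment_of <- function(em, part = NULL) {
  if (is.null(part)) part <- partition(em)
  block <- em$data[, part$treatment_cols, drop = FALSE]
  part$treatment_levels[max.col(block, ties.method = "first")]
}

# ---- I/O --------------------------------------------------------------------

#' Write / read a cohort as CSV with a YAML schema sidecar
#'
#' The CSV is RFC-4180, UTF-8, with a header row; missing cells are empty;
#' dates are ISO-8601. The schema travels in a YAML sidecar so that a
#' write/read roundtrip reproduces the cohort exactly.
#'
#' @param cohort A [cohort_table()].
#' @param path CSV file path.
#' @param schema_path Optional YAML path for the schema sidecar.
#' @return `write_cohort` invisibly returns `path`; `read_cohort` returns a
#'   [cohort_table()].
#' @export
write_cohort <- function(cohort, path, schema_path = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$data
  for (sp in cohort$schema$specs)
    if (sp$kind == "date") df[[sp$name]] <- format(df[[sp$name]], "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  if (!is.null(schema_path)) write_schema(cohort$schema, schema_path)
  invisible(path)
}

#' @rdname write_cohort
#' @param schema A [cohort_schema()] object or path to a schema YAML file.
#' @export
read_cohort <- function(path, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  stopifnot(inherits(schema, "cohort_schema"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(schema$specs), names(df))
  if (length(missing_cols))
    stop("CSV is missing schema column(s): ",
         paste(missing_cols, collapse = ", "))
  for (sp in schema$specs) {
    v <- df[[sp$name]]
    v[v == ""] <- NA
    df[[sp$name]] <- switch(sp$kind,
      continuous = as.numeric(v),
      binary = as.numeric(v),
      date = as.Date(v),
      categorical = v)
  }
  cohort_table(df, schema)
}

#' Write / read a schema as YAML
#' @param schema A [cohort_schema()].
#' @param path YAML file path.
#' @return `write_schema` invisibly returns `path`; `read_schema` returns a
#'   [cohort_schema()].
#' @export
write_schema <- function(schema, path) {
  vars <- lapply(schema$specs, function(sp) {
    x <- list(name = sp$name, family = sp$family, kind = sp$kind,
              missingness_allowed = sp$missingness_allowed, role = sp$role,
              covariate = sp$covariate)
    if (!is.null(sp$categories)) x$categories <- as.list(sp$categories)
    if (!is.null(sp$range))
      x$range <- if (sp$kind == "date") as.list(format(sp$range, "%Y-%m-%d"))
                 else as.list(sp$range)
    if (!is.null(sp$reference)) x$reference <- sp$reference
    x
  })
  yaml::write_yaml(list(variables = unname(vars)), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- lapply(y$variables, function(x)
    variable_spec(name = x$name, kind = x$kind, family = x$family,
                  categories = if (!is.null(x$categories))
                    unlist(x$categories),
                  range = if (!is.null(x$range)) unlist(x$range),
                  missingness_allowed = isTRUE(x$missingness_allowed),
                  role = x$role %||% "none",
                  covariate = x$covariate %||% TRUE,
                  reference = x$reference))
  cohort_schema(specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an encoded matrix from raw components
#'
#' Low-level constructor used when reconstituting generator output or reading
#' an exported matrix: wraps a numeric matrix with an existing colmap,
#' transforms and schema (all typically taken from the encoding of the
#' original cohort).
#'
#' @param data N x d numeric matrix in `[0,1]`.
#' @param template An `encoded_matrix` supplying colmap/transforms/schema.
#' @return An `encoded_matrix`.
#' @export
encoded_matrix <- function(data, template) {
  stopifnot(inherits(template, "encoded_matrix"),
            ncol(data) == nrow(template$colmap))
  structure(list(data = data, colmap = template$colmap,
                 transforms = template$transforms, schema = template$schema),
            class = "encoded_matrix")
}
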