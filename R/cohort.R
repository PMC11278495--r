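#' Min-max age scaler
#'
#' @param min_age,max_age bounds in years; `max_age` must exceed `min_age`.
#' @return a `cc_age_scaler`.
#' @export
age_scaler <- function(min_age, max_age) {
  stopifnot(is.numeric(min_age), is.numeric(max_age))
  if (!(max_age > min_age)) {
    stop("degenerate age scaler: max_age must exceed min_age", call. = FALSE)
  }
  structure(list(min_age = min_age, max_age = max_age), class = "cc_age_scaler")
}

#' Scale ages to [0, 1]
#'
#' Fits a min-max scaler on `ages` and returns both the scaled vector and the
#' scaler, so that held-out ages can be transformed with the training-set
#' bounds. Out-of-range ages passed through [apply_age_scaler()] are clipped
#' to [0, 1].
#'
#' @param ages numeric vector of ages in years with at least two distinct
#'   values.
#' @return a list with elements `scaled` and `scaler`.
#' @examples
#' scale_age(c(20, 60, 100))$scaled  # 0.0 0.5 1.0
#' @export
scale_age <- function(ages) {
  stopifnot(is.numeric(ages))
  if (anyNA(ages)) stop("ages contain missing values", call. = FALSE)
  rng <- range(ages)
  if (rng[1] == rng[2]) {
    stop("constant age vector: min-max scaling is degenerate", call. = FALSE)
  }
  sc <- age_scaler(rng[1], rng[2])
  list(scaled = apply_age_scaler(sc, ages), scaler = sc)
}

#' @rdname scale_age
#' @param scaler a `cc_age_scaler`.
#' @export
apply_age_scaler <- function(scaler, ages) {
  stopifnot(inherits(scaler, "cc_age_scaler"))
  x <- (ages - scaler$min_age) / (scaler$max_age - scaler$min_age)
  pmin(pmax(x, 0), 1)
}

#' One-hot encode a categorical column
#'
#' Expands a categorical vector into indicator columns, one per level, named
#' `<name>_<level>`; every row has exactly one 1 across the produced columns.
#' Binary yes/no style inputs may instead be kept as a single 0/1 column with
#' `mode = "single"`, which is equivalent for every downstream computation and
#' halves the dimensionality.
#'
#' @param values vector of categorical values.
#' @param levels ordered character vector of allowed levels; every value must
#'   appear here.
#' @param name prefix for the produced column names.
#' @param mode `"onehot"` (one column per level) or `"single"` (0/1 column,
#'   requires exactly two levels; the second level maps to 0).
#' @return a tibble of 0/1 columns.
#' @export
one_hot_encode <- function(values, levels, name = "x", mode = c("onehot", "single")) {
  mode <- match.arg(mode)
  values <- as.character(values)
  unseen <- setdiff(unique(values), levels)
  if (length(unseen)) {
    stop("value(s) not in levels: ", paste(unseen, collapse = ", "), call. = FALSE)
  }
  if (mode == "single") {
    if (length(levels) != 2L) {
      stop("mode = 'single' requires exactly two levels", call. = FALSE)
    }
    out <- tibble::tibble(as.integer(values == levels[1]))
    names(out) <- name
    return(out)
  }
  cols <- lapply(levels, function(l) as.integer(values == l))
  names(cols) <- paste(name, levels, sep = "_")
  tibble::as_tibble(cols)
}

new_cohort <- function(data, schema, scaler = NULL) {
  out <- tibble::as_tibble(data)
  attr(out, "schema") <- schema
  attr(out, "age_scaler") <- scaler
  class(out) <- unique(c("cc_cohort", class(out)))
  out
}

#' @exportS3Method base::print
print.cc_cohort <- function(x, ...) {
  s <- cohort_schema(x)
  cat(sprintf(
    "<cc_cohort> %d patients, %d binary features, outcome rate %.3f\n",
    nrow(x), sum(s$role == "binary_categorical"),
    mean(x[[schema_outcome(s)]])
  ))
  NextMethod()
}

#' Cohort accessors
#'
#' @param cohort a `cc_cohort`.
#' @return `cohort_schema()` the attached `cc_schema`; `cohort_scaler()` the
#'   attached age scaler (or `NULL`).
#' @export
cohort_schema <- function(cohort) {
  s <- attr(cohort, "schema")
  if (is.null(s)) stop("not a cohort table: no schema attached", call. = FALSE)
  s
}

#' @rdname cohort_schema
#' @export
cohort_scaler <- function(cohort) attr(cohort, "age_scaler")

# Re-attach cohort metadata after a row subset (dplyr drops custom attributes).
cohort_slice <- function(cohort, idx) {
  new_cohort(tibble::as_tibble(cohort)[idx, , drop = FALSE],
             cohort_schema(cohort), cohort_scaler(cohort))
}

validate_cohort <- function(data, schema) {
  if (!"patient_id" %in% names(data)) {
    stop("missing required column: patient_id", call. = FALSE)
  }
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols)) {
    stop("schema column(s) missing from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data$patient_id)) {
    dup <- data$patient_id[duplicated(data$patient_id)][1]
    stop("duplicate patient id: ", dup, call. = FALSE)
  }
  if (anyNA(data[schema$name])) {
    bad <- schema$name[vapply(data[schema$name], anyNA, logical(1))][1]
    stop("missing values in column ", bad,
         " (imputation is not performed)", call. = FALSE)
  }
  for (f in c(schema_binary_features(schema), schema_outcome(schema))) {
    v <- data[[f]]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("non-binary value '%s' in column %s at row %d",
                   v[bad[1]], f, bad[1]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Load a cohort table from CSV
#'
#' Reads a patient-level CSV (one row per patient, `patient_id` column, one
#' 0/1 column per binary feature, optional age column, binary outcome),
#' validates it against the schema, reorders columns to schema order and
#' min-max scales age to [0, 1]. Files with missing values, non-binary codes
#' in binary columns or duplicate ids are rejected, never repaired.
#'
#' @param path CSV file path (comma-separated, UTF-8, header row).
#' @param schema a [feature_schema()].
#' @param scaler optional `cc_age_scaler` fitted on a training cohort; when
#'   supplied, ages are scaled with those bounds (and clipped) instead of
#'   bounds fitted on this file. Pass `NULL` for ages already on [0, 1].
#' @return a `cc_cohort` tibble with columns `patient_id`, then the schema
#'   features in schema order.
#' @export
load_cohort <- function(path, schema, scaler = NULL) {
  # base read.csv parses decimal doubles exactly; vroom's fast path can be
  # one ulp off, which would break the load-write-load fixed point
  data <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if ("patient_id" %in% names(data)) {
    data$patient_id <- as.character(data$patient_id)
  }
  validate_cohort(data, schema)
  data <- data[c("patient_id", schema$name)]
  age <- schema_age_feature(schema)
  if (!is.null(age)) {
    if (is.null(scaler)) {
      rng <- range(data[[age]])
      scaler <- if (rng[1] >= 0 && rng[2] <= 1) age_scaler(0, 1) else {
        sa <- scale_age(data[[age]])$scaler
        sa
      }
    }
    data[[age]] <- apply_age_scaler(scaler, data[[age]])
  }
  new_cohort(data, schema, scaler)
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()]: writes `patient_id` plus the schema columns,
#' with ages in their stored (scaled) form, so that load-write-load is an
#' exact fixed point.
#'
#' @param cohort a `cc_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  schema <- cohort_schema(cohort)
  out <- tibble::as_tibble(cohort)[c("patient_id", schema$name)]
  age <- schema_age_feature(schema)
  if (!is.null(age)) {
    # %.17g is lossless for doubles; the default formatter rounds the last ulp
    out[[age]] <- sprintf("%.17g", out[[age]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
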