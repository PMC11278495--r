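#' Define a feature schema for a cohort table
#'
#' A schema names every column of a cohort, assigns each a role, and carries a
#' human-readable display label used in narratives and plots. Roles are:
#' \describe{
#'   \item{binary_categorical}{a 0/1 indicator (diagnosis, medication, social
#'     factor); the only role eligible for class-contrastive perturbation.}
#'   \item{continuous_age}{age in years, min-max scaled to [0, 1] at load time;
#'     at most one such feature.}
#'   \item{outcome}{the binary death-during-observation flag; exactly one.}
#' }
#'
#' @param name character vector of unique, non-empty feature names.
#' @param role character vector of roles, one per feature.
#' @param label optional display labels (defaults to the names).
#' @return a `cc_schema` tibble with columns `name`, `role`, `label`.
#' @examples
#' feature_schema(
#'   name = c("SGA", "self_harm", "age", "died"),
#'   role = c("binary_categorical", "binary_categorical", "continuous_age", "outcome")
#' )
#' @export
feature_schema <- function(name, role, label = name) {
  stopifnot(is.character(name), is.character(role), is.character(label))
  if (length(role) != length(name) || length(label) != length(name)) {
    stop("`name`, `role` and `label` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(name) || any(!nzchar(name)) || anyNA(name)) {
    stop("feature names must be unique and non-empty", call. = FALSE)
  }
  ok_roles <- c("binary_categorical", "continuous_age", "outcome")
  bad <- setdiff(unique(role), ok_roles)
  if (length(bad)) {
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (sum(role == "outcome") != 1L) {
    stop("schema must contain exactly one outcome feature", call. = FALSE)
  }
  if (sum(role == "continuous_age") > 1L) {
    stop("schema may contain at most one continuous_age feature", call. = FALSE)
  }
  out <- tibble::tibble(name = name, role = role, label = label)
  class(out) <- c("cc_schema", class(out))
  out
}

#' @exportS3Method base::print
print.cc_schema <- function(x, ...) {
  cat(sprintf(
    "<cc_schema> %d features: %d binary, %s age, outcome = '%s'\n",
    nrow(x), sum(x$role == "binary_categorical"),
    if (any(x$role == "continuous_age")) "1" else "no",
    schema_outcome(x)
  ))
  NextMethod()
}

#' Schema accessors
#'
#' Convenience accessors over a [feature_schema()]: the binary feature names,
#' the (optional) age feature, the outcome name, and display labels for a set
#' of features.
#'
#' @param schema a `cc_schema`.
#' @return a character vector (or `NULL` for a missing age feature).
#' @export
schema_binary_features <- function(schema) schema$name[schema$role == "binary_categorical"]

#' @rdname schema_binary_features
#' @export
schema_age_feature <- function(schema) {
  f <- schema$name[schema$role == "continuous_age"]
  if (length(f)) f else NULL
}

#' @rdname schema_binary_features
#' @export
schema_outcome <- function(schema) schema$name[schema$role == "outcome"]

#' @rdname schema_binary_features
#' @param features character vector of feature names to label.
#' @export
schema_label <- function(schema, features) {
  idx <- match(features, schema$name)
  if (anyNA(idx)) {
    stop("unknown feature(s): ", paste(features[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  schema$label[idx]
}

#' Read or write a feature schema
#'
#' Schemas are stored as YAML or JSON (chosen by file extension): a list of
#' entries with fields `name`, `role` and optional `label`.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_schema()` returns a `cc_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  feature_schema(
    name = vapply(raw, function(e) e$name, character(1)),
    role = vapply(raw, function(e) e$role, character(1)),
    label = vapply(raw, function(e) e$label %||% e$name, character(1))
  )
}

#' @rdname read_schema
#' @param schema a `cc_schema`.
#' @export
write_schema <- function(schema, path) {
  entries <- lapply(seq_len(nrow(schema)), function(i) {
    list(name = schema$name[i], role = schema$role[i], label = schema$label[i])
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(entries, path)
  }
  invisible(path)
}
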