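#' Define a feature pattern
#'
#' A pattern is a partial assignment of binary features to 0/1 — the unit of
#' contrast, case matching and ablation. `feature_pattern(self_harm = 1, SGA = 1)`
#' matches every patient with both indicators set, whatever their other
#' features.
#'
#' @param ... named 0/1 values, one per feature; names must be unique.
#' @return a `cc_pattern` (named integer vector).
#' @export
feature_pattern <- function(...) {
  vals <- c(...)
  if (length(vals) == 0L) {
    return(structure(integer(0), class = "cc_pattern"))
  }
  if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
    stop("every pattern value must be named by a feature", call. = FALSE)
  }
  if (anyDuplicated(names(vals))) {
    stop("duplicate feature in pattern: ",
         names(vals)[duplicated(names(vals))][1], call. = FALSE)
  }
  if (!all(vals %in% c(0, 1))) {
    stop("pattern values must be 0 or 1", call. = FALSE)
  }
  structure(as.integer(vals), names = names(vals), class = "cc_pattern")
}

as_pattern <- function(x) {
  if (inherits(x, "cc_pattern")) return(x)
  do.call(feature_pattern, as.list(x))
}

#' @exportS3Method base::print
print.cc_pattern <- function(x, ...) {
  if (!length(x)) cat("<cc_pattern> (empty)\n")
  else cat("<cc_pattern>", paste0(names(x), "=", x, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method base::format
format.cc_pattern <- function(x, ...) {
  paste0(names(x), "=", unclass(x), collapse = " & ")
}

check_pattern_features <- function(pattern, schema, binary_only = TRUE) {
  pool <- if (binary_only) schema_binary_features(schema) else schema$name
  unknown <- setdiff(names(pattern), pool)
  if (length(unknown)) {
    stop("pattern names feature(s) not in the schema's binary features: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Logical row mask of pattern matches on a data frame.
pattern_mask <- function(data, pattern) {
  m <- rep(TRUE, nrow(data))
  for (f in names(pattern)) m <- m & (data[[f]] == pattern[[f]])
  m
}

#' Count patients matching a pattern
#'
#' The number of cohort rows satisfying every assignment of the pattern; the
#' empty pattern matches all rows. Patterns with zero support in both the
#' training and test sets mark contrastive narratives as potentially spurious.
#'
#' @param cohort a `cc_cohort` (or plain data frame of 0/1 features).
#' @param pattern a [feature_pattern()] or named 0/1 vector.
#' @return an integer count.
#' @export
pattern_support <- function(cohort, pattern) {
  pattern <- as_pattern(pattern)
  if (inherits(cohort, "cc_cohort")) {
    check_pattern_features(pattern, cohort_schema(cohort))
  } else {
    unknown <- setdiff(names(pattern), names(cohort))
    if (length(unknown)) {
      stop("unknown feature(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  sum(pattern_mask(cohort, pattern))
}
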