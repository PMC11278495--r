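#' Class-contrastive effect of forcing a feature set on and off
#'
#' The elementary class-contrastive operation: for every patient in the test
#' cohort, copy the row, force all named binary features to 1 and record the
#' predicted death probability, force them all to 0 and record it again, and
#' return the difference p(set to 1) - p(set to 0). The model is treated
#' strictly as a black box — two prediction calls, no retraining — so the
#' result is comparable across model families. The patient's own values of
#' the perturbed features never enter (both arms overwrite them); all other
#' features, including age, are left untouched, so age's contribution is
#' baked into both arms. Continuous features cannot be contrasted: there is
#' no canonical "on" value to force them to.
#'
#' @param model a fitted `cc_model`.
#' @param test a `cc_cohort` of held-out patients.
#' @param features character vector of 1-3 binary feature names (the cap is
#'   configurable via `max_order`).
#' @param max_order maximum allowed feature-set size.
#' @return a numeric vector of probability changes in [-1, 1], named by
#'   patient id.
#' @examples
#' sim <- simulate_cohort(default_sim_config(seed = 1, n_patients = 400))
#' parts <- split_cohort(sim$cohort, split_plan(seed = 1))
#' fit <- fit_logistic(parts$train)
#' head(contrast_set(fit, parts$test, c("delirium", "dementia_alzheimers")))
#' @export
contrast_set <- function(model, test, features, max_order = 3L) {
  check_fitted(model)
  schema <- cohort_schema(test)
  if (length(features) < 1L || length(features) > max_order) {
    stop("a contrast set must name between 1 and ", max_order, " features",
         call. = FALSE)
  }
  if (anyDuplicated(features)) {
    stop("duplicate feature in contrast set", call. = FALSE)
  }
  not_binary <- setdiff(features, schema_binary_features(schema))
  if (length(not_binary)) {
    stop("class-contrastive analysis only works with binary categorical ",
         "features; cannot perturb: ", paste(not_binary, collapse = ", "),
         call. = FALSE)
  }
  data1 <- tibble::as_tibble(test)
  data0 <- data1
  for (f in features) {
    data1[[f]] <- 1L
    data0[[f]] <- 0L
  }
  dp <- predict_probability(model, data1) - predict_probability(model, data0)
  names(dp) <- test$patient_id
  dp
}

combo_label <- function(features) paste(features, collapse = "+")

#' Build a class-contrastive matrix
#'
#' Computes [contrast_set()] for every combination of `order` eligible binary
#' features (or of a requested subset), producing the patients-by-feature-
#' combinations matrix behind the class-contrastive heatmap: rows are test
#' patients, columns are feature combinations, values are the change in
#' predicted death probability when the combination is forced from all-0 to
#' all-1. Columns are ordered lexicographically by feature name and each
#' carries the support (number of patients with the combination's all-ones
#' pattern) in the training and test cohorts, which downstream zero-support
#' flagging uses.
#'
#' @param model a fitted `cc_model`.
#' @param test a `cc_cohort` of held-out patients.
#' @param order combination size: 1, 2 or 3.
#' @param features optional subset of binary features to combine (defaults to
#'   all binary features).
#' @param train optional training `cc_cohort` for train-side support counts.
#' @param max_columns guard rail on the number of combinations; exceeding it
#'   is an error, not a silent truncation.
#' @return a `cc_contrast` object: `$deltas` (tibble, `patient_id` plus one
#'   column per combination), `$columns` (per-combination metadata) and
#'   bookkeeping fields.
#' @export
contrast_matrix <- function(model, test, order = 1L, features = NULL,
                            train = NULL, max_columns = 5000L) {
  check_fitted(model)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3", call. = FALSE)
  schema <- cohort_schema(test)
  eligible <- schema_binary_features(schema)
  if (!is.null(features)) {
    bad <- setdiff(features, eligible)
    if (length(bad)) {
      stop("not binary features of the cohort: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    eligible <- intersect(eligible, features)
  }
  if (order > length(eligible)) {
    stop("order ", order, " exceeds the ", length(eligible),
         " eligible binary features", call. = FALSE)
  }
  combos <- utils::combn(sort(eligible), order, simplify = FALSE)
  if (length(combos) > max_columns) {
    stop("contrast would produce ", length(combos), " columns, above the cap ",
         "of ", max_columns, "; pass a feature subset or raise `max_columns`",
         call. = FALSE)
  }
  deltas <- tibble::tibble(patient_id = test$patient_id)
  labels <- vapply(combos, combo_label, character(1))
  for (i in seq_along(combos)) {
    deltas[[labels[i]]] <- unname(contrast_set(model, test, combos[[i]]))
  }
  all_ones <- function(fs) do.call(feature_pattern, as.list(stats::setNames(
    rep(1L, length(fs)), fs)))
  columns <- tibble::tibble(
    label = labels,
    features = combos,
    test_support = vapply(combos, function(fs) pattern_support(test, all_ones(fs)),
                          integer(1)),
    train_support = if (is.null(train)) NA_integer_ else {
      vapply(combos, function(fs) pattern_support(train, all_ones(fs)),
             integer(1))
    }
  )
  structure(list(deltas = deltas, columns = columns, order = as.integer(order),
                 model_kind = model$kind %||% "unknown",
                 schema = schema),
            class = "cc_contrast")
}

#' @exportS3Method base::print
print.cc_contrast <- function(x, ...) {
  cat(sprintf(
    "<cc_contrast> order %d: %d patients x %d feature combinations (model: %s)\n",
    x$order, nrow(x$deltas), nrow(x$columns), x$model_kind))
  rng <- range(as.matrix(x$deltas[-1]))
  cat(sprintf("  delta-p range [%.3f, %.3f]\n", rng[1], rng[2]))
  invisible(x)
}

# Numeric matrix view (patients x combinations) of a cc_contrast.
contrast_values <- function(cm) {
  m <- as.matrix(cm$deltas[-1])
  rownames(m) <- cm$deltas$patient_id
  m
}

#' Flag feature combinations with no supporting patients
#'
#' A contrastive narrative built on a feature combination that occurs in no
#' training and no test patient describes a pattern the model has never seen
#' realised; such columns are flagged so their narratives carry an explicit
#' spurious-pattern caveat. A combination is flagged iff its all-ones pattern
#' has zero support in \emph{both} cohorts.
#'
#' @param cm a `cc_contrast`.
#' @param train,test the training and test `cc_cohort`s (support is
#'   recounted here, so the matrix may have been built without `train`).
#' @return a tibble with one row per column: `label`, `train_support`,
#'   `test_support`, `flagged`.
#' @export
flag_zero_support <- function(cm, train, test) {
  stopifnot(inherits(cm, "cc_contrast"))
  all_ones <- function(fs) do.call(feature_pattern, as.list(stats::setNames(
    rep(1L, length(fs)), fs)))
  tr <- vapply(cm$columns$features,
               function(fs) pattern_support(train, all_ones(fs)), integer(1))
  te <- vapply(cm$columns$features,
               function(fs) pattern_support(test, all_ones(fs)), integer(1))
  tibble::tibble(label = cm$columns$label, train_support = tr,
                 test_support = te, flagged = tr == 0L & te == 0L)
}
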