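#' Specify a case-ablation experiment
#'
#' Case-based data ablation asks which training cases give the model a
#' particular (often counter-intuitive) behaviour: all patients matching a
#' feature pattern \emph{and} an outcome value — e.g. prior suicide attempt
#' = 1, SGA = 1 and alive — are removed, the model is refitted on the
#' remainder, and the fitted log-odds are compared before and after.
#'
#' @param pattern a non-empty [feature_pattern()].
#' @param outcome required outcome value (0 or 1) of matched cases.
#' @param builder model builder used for both fits; defaults to unpenalised
#'   logistic regression, the only kind for which paired odds tables are
#'   produced.
#' @param seed integer seed set before each refit (relevant for stochastic
#'   builders).
#' @return a `cc_ablation_spec`.
#' @export
ablation_spec <- function(pattern, outcome,
                          builder = function(cohort) fit_logistic(cohort),
                          seed = 1L) {
  pattern <- as_pattern(pattern)
  if (!length(pattern)) stop("ablation condition must be non-empty", call. = FALSE)
  if (!outcome %in% c(0, 1)) stop("outcome must be 0 or 1", call. = FALSE)
  structure(list(pattern = pattern, outcome = as.integer(outcome),
                 builder = builder, seed = assert_scalar_int(seed, "seed")),
            class = "cc_ablation_spec")
}

#' Patients matching an ablation condition
#'
#' Exact-match semantics on every pattern assignment and the outcome value;
#' ids are returned in cohort order.
#'
#' @param cohort a `cc_cohort`.
#' @param spec a [ablation_spec()].
#' @return a character vector of patient ids.
#' @export
match_condition <- function(cohort, spec) {
  stopifnot(inherits(spec, "cc_ablation_spec"))
  schema <- cohort_schema(cohort)
  check_pattern_features(spec$pattern, schema)
  m <- pattern_mask(cohort, spec$pattern) &
    cohort[[schema_outcome(schema)]] == spec$outcome
  cohort$patient_id[m]
}

#' Remove matched cases, refit, and compare log-odds
#'
#' The data-centric explanation procedure: fit the model on the full cohort,
#' remove every case matching the condition, refit on the remainder, and
#' report paired odds tables with per-term coefficient deltas and sign
#' changes. The input cohort is never modified. Removal from the supplied
#' table happens before any re-splitting; to ablate the training split only,
#' pass that split as `cohort`.
#'
#' @param cohort a `cc_cohort`.
#' @param spec an [ablation_spec()].
#' @return a `cc_ablation` report: counts (`n_before`, `n_removed`,
#'   `n_after`), `odds_before` / `odds_after` tables, a `deltas` tibble and
#'   the `sign_changes` term list.
#' @export
ablate_and_refit <- function(cohort, spec) {
  stopifnot(inherits(spec, "cc_ablation_spec"))
  schema <- cohort_schema(cohort)
  matched <- match_condition(cohort, spec)
  keep <- !(cohort$patient_id %in% matched)
  remainder <- cohort_slice(cohort, which(keep))
  y_after <- remainder[[schema_outcome(schema)]]
  if (length(unique(y_after)) < 2L) {
    stop("removing cases matching [", format(spec$pattern), " & ",
         schema_outcome(schema), "=", spec$outcome,
         "] leaves a single-class outcome", call. = FALSE)
  }
  set.seed(spec$seed)
  before <- spec$builder(cohort)
  set.seed(spec$seed)
  after <- spec$builder(remainder)

  deltas <- NULL
  sign_changes <- character(0)
  if (!is.null(before$odds) && !is.null(after$odds)) {
    deltas <- dplyr::inner_join(
      dplyr::select(before$odds, "term", before = "estimate"),
      dplyr::select(after$odds, "term", after = "estimate"),
      by = "term")
    deltas$delta <- deltas$after - deltas$before
    deltas$sign_change <- sign(deltas$before) != sign(deltas$after)
    sign_changes <- deltas$term[deltas$sign_change]
  }
  structure(list(
    condition = spec$pattern, outcome = spec$outcome,
    n_before = nrow(cohort), n_removed = length(matched),
    n_after = nrow(remainder), matched_ids = matched,
    odds_before = before$odds, odds_after = after$odds,
    deltas = deltas, sign_changes = sign_changes,
    model_before = before, model_after = after
  ), class = "cc_ablation")
}

#' @exportS3Method base::print
print.cc_ablation <- function(x, ...) {
  cat(sprintf(
    "<cc_ablation> removed %d of %d cases matching [%s & died=%d] -> %d kept\n",
    x$n_removed, x$n_before, format(x$condition), x$outcome, x$n_after))
  if (length(x$sign_changes)) {
    cat("  log-odds sign changes:", paste(x$sign_changes, collapse = ", "), "\n")
  }
  invisible(x)
}
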