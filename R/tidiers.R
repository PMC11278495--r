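#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted logistic mortality model
#'
#' Returns the odds table: one row per term with the log-odds coefficient,
#' odds ratio, Wald 95\% confidence bounds, p-value and significance flag
#' (all `NA` except estimates for L1-penalised fits).
#'
#' @param x a `cc_logistic`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.cc_logistic <- function(x, ...) x$odds

#' @export
glance.cc_logistic <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, lambda = x$lambda,
    n = if (x$lambda == 0) stats::nobs(x$fit) else x$fit$nobs,
    deviance = if (x$lambda == 0) stats::deviance(x$fit) else NA_real_,
    aic = if (x$lambda == 0) stats::AIC(x$fit) else NA_real_,
    warned = length(x$fit_warnings) > 0
  )
}

#' Tidy a contrast matrix into long form
#'
#' @param x a `cc_contrast`.
#' @param ... unused.
#' @return a tibble with one row per (patient, feature combination) cell:
#'   `patient_id`, `label`, `delta_p`, plus the column's support counts.
#' @export
tidy.cc_contrast <- function(x, ...) {
  long <- tidyr::pivot_longer(x$deltas, -"patient_id",
                              names_to = "label", values_to = "delta_p")
  dplyr::left_join(long,
                   dplyr::select(x$columns, "label", "train_support",
                                 "test_support"),
                   by = "label")
}

#' @export
glance.cc_contrast <- function(x, ...) {
  m <- contrast_values(x)
  tibble::tibble(order = x$order, model_kind = x$model_kind,
                 n_patients = nrow(m), n_combinations = ncol(m),
                 max_abs_delta = max(abs(m)), mean_delta = mean(m))
}

#' Tidy an ablation report
#'
#' @param x a `cc_ablation`.
#' @param ... unused.
#' @return the per-term before/after coefficient tibble with deltas and
#'   sign-change flags.
#' @export
tidy.cc_ablation <- function(x, ...) x$deltas

#' @export
glance.cc_ablation <- function(x, ...) {
  tibble::tibble(n_before = x$n_before, n_removed = x$n_removed,
                 n_after = x$n_after,
                 n_sign_changes = length(x$sign_changes))
}

#' @export
tidy.cc_eval <- function(x, ...) x$aucs

#' @export
glance.cc_eval <- function(x, ...) {
  tibble::tibble(model_kind = x$model_kind, auc = x$estimate,
                 conf_low = x$conf_low, conf_high = x$conf_high,
                 n_repeats = x$n_repeats, redraws = x$redraws)
}
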