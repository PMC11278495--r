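SPURIOUS_CAVEAT <- paste(
  "Caution: no patients in the training or test data have this combination",
  "of characteristics, so the model may have picked up a spurious pattern.")

#' Render a templated class-contrastive narrative
#'
#' Turns one (patient, feature pattern, probability change) cell into the
#' templated sentence form: \dQuote{The patient is predicted to have a
#' \{lower|higher\} probability of death because the patient has \{feature
#' labels\}. There are \{n\} other patients with these characteristics, of
#' whom \{d\} have died. If the patient did not have these characteristics,
#' the prediction would be different.} Direction follows the sign of the
#' contrastive change, not the absolute predicted risk. Similar-patient
#' counts match the all-ones pattern in the supplied cohort regardless of
#' outcome (the index patient, when it matches, is excluded), with the
#' outcome breakdown appended. Zero-support patterns get an explicit
#' spurious-pattern caveat.
#'
#' @param cohort the reference `cc_cohort` used to count similar patients
#'   (typically the full cohort the model's splits came from).
#' @param patient_id id of the index patient.
#' @param pattern a [feature_pattern()] (all-ones for the contrasted set).
#' @param delta_p the contrastive probability change.
#' @param flagged_spurious logical; append the zero-support caveat.
#' @param threshold minimum `|delta_p|` worth narrating (default 0.05).
#' @param force render even below the threshold (zero changes get neutral
#'   wording with no higher/lower claim).
#' @return a one-row `Narrative` tibble, or `NULL` when below threshold and
#'   not forced.
#' @export
render_narrative <- function(cohort, patient_id, pattern, delta_p,
                             flagged_spurious = FALSE, threshold = 0.05,
                             force = FALSE) {
  pattern <- as_pattern(pattern)
  schema <- cohort_schema(cohort)
  check_pattern_features(pattern, schema)
  if (abs(delta_p) < threshold && !force) return(NULL)

  mask <- pattern_mask(cohort, pattern)
  idx_self <- cohort$patient_id == patient_id & mask
  n_similar <- sum(mask) - sum(idx_self)
  n_died <- sum(cohort[[schema_outcome(schema)]][mask & !idx_self])
  labels <- schema_label(schema, names(pattern))
  has <- names(pattern)[unclass(pattern) == 1L]
  lacks <- names(pattern)[unclass(pattern) == 0L]
  described <- c(
    if (length(has)) schema_label(schema, has),
    if (length(lacks)) paste("no", schema_label(schema, lacks))
  )
  feats_text <- paste(described, collapse = ", ")

  direction <- if (delta_p > 0) "higher" else if (delta_p < 0) "lower" else "unchanged"
  first <- if (direction == "unchanged") {
    sprintf("The predicted probability of death for the patient is unchanged when the patient has %s.",
            feats_text)
  } else {
    sprintf("The patient is predicted to have a %s probability of death because the patient has %s.",
            direction, feats_text)
  }
  text <- sprintf(
    "%s There are %d other patients with these characteristics, of whom %d have died. If the patient did not have these characteristics, the prediction would be different.",
    first, n_similar, n_died)
  if (flagged_spurious) text <- paste(text, SPURIOUS_CAVEAT)

  tibble::tibble(
    patient_id = as.character(patient_id),
    pattern = combo_label(names(pattern)),
    delta_p = delta_p,
    direction = direction,
    n_similar = as.integer(n_similar),
    n_similar_died = as.integer(n_died),
    flagged_spurious = isTRUE(flagged_spurious),
    text = text
  )
}

#' Strongest class-contrastive narratives from a contrast matrix
#'
#' Selects the `k` cells of largest absolute probability change in the
#' requested direction and renders each as a narrative. Ties are broken
#' lexicographically by (patient id, column label), so repeated runs return
#' byte-identical text. Zero-support columns (no supporting patient in
#' either cohort) are flagged and their narratives carry the spurious
#' caveat.
#'
#' @param cm a `cc_contrast` (build it with `train` supplied, or pass
#'   `train` here for support flags).
#' @param cohort the reference `cc_cohort` for similar-patient counts.
#' @param k number of narratives.
#' @param direction `"both"`, `"higher"` or `"lower"`.
#' @param train optional training `cc_cohort` to (re)compute train-side
#'   support.
#' @return a `Narrative` tibble with up to `k` rows (no padding when fewer
#'   cells qualify).
#' @export
top_narratives <- function(cm, cohort, k = 5L, direction = c("both", "higher", "lower"),
                           train = NULL) {
  stopifnot(inherits(cm, "cc_contrast"), k >= 1L)
  direction <- match.arg(direction)
  long <- tidyr::pivot_longer(cm$deltas, -"patient_id",
                              names_to = "label", values_to = "delta_p")
  if (direction == "higher") long <- long[long$delta_p > 0, ]
  if (direction == "lower") long <- long[long$delta_p < 0, ]
  if (nrow(long) == 0L) return(empty_narratives())
  long <- long[order(-abs(long$delta_p), long$patient_id, long$label), ]
  long <- utils::head(long, k)

  train_support <- cm$columns$train_support
  if (!is.null(train)) {
    all_ones <- function(fs) do.call(feature_pattern, as.list(stats::setNames(
      rep(1L, length(fs)), fs)))
    train_support <- vapply(cm$columns$features,
                            function(fs) pattern_support(train, all_ones(fs)),
                            integer(1))
  }
  flagged <- !is.na(train_support) & train_support == 0L &
    cm$columns$test_support == 0L
  names(flagged) <- cm$columns$label
  feats_by_label <- stats::setNames(cm$columns$features, cm$columns$label)

  out <- lapply(seq_len(nrow(long)), function(i) {
    fs <- feats_by_label[[long$label[i]]]
    pat <- do.call(feature_pattern,
                   as.list(stats::setNames(rep(1L, length(fs)), fs)))
    render_narrative(cohort, long$patient_id[i], pat, long$delta_p[i],
                     flagged_spurious = isTRUE(flagged[[long$label[i]]]),
                     force = TRUE)
  })
  dplyr::bind_rows(out)
}

empty_narratives <- function() {
  tibble::tibble(patient_id = character(0), pattern = character(0),
                 delta_p = numeric(0), direction = character(0),
                 n_similar = integer(0), n_similar_died = integer(0),
                 flagged_spurious = logical(0), text = character(0))
}
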