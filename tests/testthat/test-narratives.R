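# A cohort with exactly 12 patients carrying {self_harm=1, SGA=1, FGA=1}
# (an index patient plus 11 similar ones, of whom 1 died), for narrative
# count checks.
narrative_cohort <- function() {
  n <- 40
  df <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:n),
    self_harm = c(rep(1, 12), rep(0, n - 12)),
    SGA = c(rep(1, 12), rep(0, n - 12)),
    FGA = c(rep(1, 12), rep(1, 8), rep(0, n - 20)),
    age = seq(20, 90, length.out = n),
    died = c(0, 1, rep(0, 10), rep(c(0, 1), length.out = n - 12)))
  schema <- feature_schema(
    name = c("self_harm", "SGA", "FGA", "age", "died"),
    role = c(rep("binary_categorical", 3), "continuous_age", "outcome"),
    label = c("self-harm", "SGA", "FGA", "age", "died"))
  cohort_from_df(df, schema)
}

test_that("narratives instantiate the class-contrastive template", {
  co <- narrative_cohort()
  pat <- feature_pattern(self_harm = 1, SGA = 1, FGA = 1)
  nar <- render_narrative(co, "p01", pat, delta_p = -0.30)
  expect_equal(nar$direction, "lower")
  expect_match(nar$text, "lower probability of death")
  expect_match(nar$text, "self-harm, SGA, FGA")
  expect_match(nar$text, "There are 11 other patients with these characteristics")
  expect_match(nar$text, "of whom 1 have died")
  expect_match(nar$text, "the prediction would be different")
  expect_equal(nar$n_similar, 11L)
  expect_equal(nar$n_similar_died, 1L)
  expect_false(nar$flagged_spurious)
  # similar-count cross-check against pattern_support (12 matches incl. index)
  expect_equal(pattern_support(co, pat), 12L)
})

test_that("zero and sub-threshold changes are handled explicitly", {
  co <- narrative_cohort()
  pat <- feature_pattern(SGA = 1)
  expect_null(render_narrative(co, "p01", pat, delta_p = 0.01))
  forced <- render_narrative(co, "p01", pat, delta_p = 0, force = TRUE)
  expect_equal(forced$direction, "unchanged")
  expect_no_match(forced$text, "higher|lower")
  below <- render_narrative(co, "p01", pat, delta_p = 0.01, force = TRUE)
  expect_equal(below$direction, "higher")
})

test_that("spurious patterns carry the caveat and the flag", {
  co <- narrative_cohort()
  nar <- render_narrative(co, "p30", feature_pattern(self_harm = 1, SGA = 0),
                          delta_p = 0.2, flagged_spurious = TRUE)
  expect_true(nar$flagged_spurious)
  expect_match(nar$text, "spurious pattern")
  expect_error(render_narrative(co, "p01", feature_pattern(Z = 1), 0.2), "Z")
})

test_that("rendering is a pure function of its inputs", {
  co <- narrative_cohort()
  pat <- feature_pattern(self_harm = 1, FGA = 1)
  a <- render_narrative(co, "p05", pat, -0.21)
  b <- render_narrative(co, "p05", pat, -0.21)
  expect_identical(a, b)
})

test_that("top_narratives ranks by |delta-p| with lexicographic tie-breaks", {
  co <- narrative_cohort()
  deltas <- tibble::tibble(
    patient_id = c("p01", "p02", "p03"),
    `FGA+SGA` = c(-0.5, 0.1, 0.2),
    `FGA+self_harm` = c(0.2, -0.1, 0.05))
  cm <- structure(list(
    deltas = deltas,
    columns = tibble::tibble(
      label = c("FGA+SGA", "FGA+self_harm"),
      features = list(c("FGA", "SGA"), c("FGA", "self_harm")),
      test_support = c(5L, 0L), train_support = c(9L, 0L)),
    order = 2L, model_kind = "logistic", schema = cohort_schema(co)),
    class = "cc_contrast")
  low <- top_narratives(cm, co, k = 1, direction = "lower")
  expect_equal(low$patient_id, "p01")
  expect_equal(low$delta_p, -0.5)
  # ties: p01/FGA+self_harm and p03/FGA+SGA both at +0.2; patient id breaks it
  high <- top_narratives(cm, co, k = 2, direction = "higher")
  expect_equal(high$patient_id, c("p01", "p03"))
  expect_equal(high$pattern, c("FGA+self_harm", "FGA+SGA"))
  # k beyond the cell count returns everything without padding
  all_cells <- top_narratives(cm, co, k = 100)
  expect_equal(nrow(all_cells), 6L)
  # deterministic across repeated runs
  expect_identical(top_narratives(cm, co, k = 3), top_narratives(cm, co, k = 3))
})

test_that("zero-support columns propagate the spurious flag into narratives", {
  prev <- c(A = 0.4, B = 0.4, C = 0.3)
  zp <- feature_pattern(A = 1, B = 1)
  sim <- simulate_cohort(sim_config(n_patients = 1200, prevalence = prev,
                                    intercept = -0.5, beta = c(A = 1),
                                    zero_support = list(zp), seed = 44))
  parts <- split_cohort(sim$cohort, split_plan(seed = 2))
  fit <- fit_logistic_quietly(parts$train)
  cm <- contrast_matrix(fit, parts$test, order = 2, train = parts$train)
  nar <- top_narratives(cm, sim$cohort, k = 3, train = parts$train)
  ab <- nar[nar$pattern == "A+B", ]
  if (nrow(ab)) {
    expect_true(all(ab$flagged_spurious))
    expect_match(ab$text[1], "spurious")
  }
  others <- nar[nar$pattern != "A+B", ]
  expect_false(any(others$flagged_spurious))
})
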