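test_that("split_cohort partitions with the planned sizes, deterministically", {
  sim <- simulate_cohort(default_sim_config(seed = 5, n_patients = 1000))
  parts <- split_cohort(sim$cohort, split_plan(seed = 7))
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 500L, test = 250L, validation = 250L))
  ids <- unlist(lapply(parts, function(p) p$patient_id))
  expect_setequal(ids, sim$cohort$patient_id)
  expect_equal(anyDuplicated(ids), 0L)
  parts2 <- split_cohort(sim$cohort, split_plan(seed = 7))
  expect_identical(parts$train$patient_id, parts2$train$patient_id)
  parts3 <- split_cohort(sim$cohort, split_plan(seed = 8))
  expect_false(identical(parts$train$patient_id, parts3$train$patient_id))
  expect_error(split_plan(fractions = c(train = 0.6, test = 0.25,
                                        validation = 0.25)), "sum to 1")
})

test_that("logistic fit satisfies maximum-likelihood identities", {
  sim <- simulate_cohort(default_sim_config(seed = 6, n_patients = 1200))
  fit <- fit_logistic(sim$cohort)
  odds <- tidy(fit)
  # odds ratio is exactly the exponentiated coefficient
  expect_equal(odds$odds_ratio, exp(odds$estimate), tolerance = 1e-12)
  expect_true(all(odds$conf_low <= odds$conf_high))
  # with an intercept, mean fitted probability equals the observed rate
  p <- predict_probability(fit, sim$cohort)
  expect_equal(mean(p), mean(sim$cohort$died), tolerance = 1e-8)
  expect_true(all(p >= 0 & p <= 1))
  # single-class outcome is rejected
  dead <- rewrap_cohort(dplyr::mutate(tibble::as_tibble(sim$cohort), died = 1L),
                        sim$cohort)
  expect_error(fit_logistic(dead), "single class")
})

test_that("interaction terms are estimated with Wald inference", {
  prev <- c(A = 0.3, B = 0.3, C = 0.2)
  cfg <- sim_config(n_patients = 4000, prevalence = prev, intercept = -1,
                    beta = c(A = 0.5, B = 0.3),
                    interactions = list(list(features = c("A", "B"), beta = 1)),
                    seed = 41)
  sim <- simulate_cohort(cfg)
  fit <- fit_logistic(sim$cohort, interactions = list(c("A", "B")))
  row <- tidy(fit)[tidy(fit)$term == "A:B", ]
  expect_equal(nrow(row), 1L)
  expect_lt(abs(row$estimate - 1), 4 * row$std_error)
})

test_that("separation in small cohorts is surfaced as a recorded warning", {
  # 60 training patients against 24 features: quasi-separated by construction
  sim <- simulate_cohort(default_sim_config(seed = 2, n_patients = 120))
  parts <- split_cohort(sim$cohort, split_plan(seed = 1))
  warns <- testthat::capture_warnings(fit <- fit_logistic(parts$train))
  expect_true(any(grepl("logistic fit warned", warns)))
  expect_gt(length(fit$fit_warnings), 0)
})

test_that("select_lambda minimises cross-validated loss with larger-penalty ties", {
  sim <- simulate_cohort(default_sim_config(seed = 8, n_patients = 600))
  expect_error(select_lambda(sim$cohort, grid = numeric(0)), "empty")
  expect_equal(as.numeric(select_lambda(sim$cohort, grid = 0.5)), 0.5)
  l1 <- select_lambda(sim$cohort, grid = c(1e-4, 1e-2, 1), seed = 3)
  l2 <- select_lambda(sim$cohort, grid = c(1e-4, 1e-2, 1), seed = 3)
  expect_identical(as.numeric(l1), as.numeric(l2))
  # pure-noise features: heavy shrinkage wins in most seeds
  prev <- stats::setNames(rep(0.3, 6), paste0("n", 1:6))
  picks <- vapply(1:3, function(s) {
    sim <- simulate_cohort(sim_config(n_patients = 400, prevalence = prev,
                                      intercept = -1, seed = 50 + s))
    as.numeric(select_lambda(sim$cohort, grid = c(1e-4, 10), seed = s))
  }, numeric(1))
  expect_gte(sum(picks == 10), 2)
})

test_that("penalised logistic fits shrink coefficients and still predict", {
  sim <- simulate_cohort(default_sim_config(seed = 10, n_patients = 1000))
  plain <- fit_logistic(sim$cohort)
  shrunk <- fit_logistic(sim$cohort, lambda = 0.05)
  expect_equal(shrunk$kind, "l1_logistic")
  l1 <- function(odds) sum(abs(odds$estimate[odds$term != "(Intercept)"]))
  expect_lt(l1(tidy(shrunk)), l1(tidy(plain)))
  p <- predict_probability(shrunk, sim$cohort)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("all baseline kinds honour the predict-probability contract", {
  sim <- simulate_cohort(default_sim_config(seed = 12, n_patients = 600))
  parts <- split_cohort(sim$cohort, split_plan(seed = 1))
  for (kind in c("rf_raw", "pca_rf", "pca_lr", "l1_logistic")) {
    m <- fit_baseline(parts$train, kind, lambda = 0.01, ntree = 100, seed = 2)
    p <- predict_probability(m, parts$test)
    expect_length(p, nrow(parts$test))
    expect_true(all(p >= 0 & p <= 1), info = kind)
  }
  pca <- fit_baseline(parts$train, "pca_rf", ntree = 50, seed = 2)
  expect_equal(ncol(pca$rotation), 10L)
  # PCA needs at least 10 input features
  small <- tiny_cohort()
  expect_error(fit_baseline(small, "pca_rf"), "at least 10")
})

test_that("prediction before fitting is an error", {
  fake <- structure(list(fitted = FALSE, kind = "logistic"),
                    class = c("cc_logistic", "cc_model"))
  expect_error(predict_probability(fake, tiny_cohort()), "not been fitted")
})

test_that("repeated-split evaluation: separable outcomes give AUC one", {
  sim <- simulate_cohort(default_sim_config(seed = 13, n_patients = 400))
  det <- rewrap_cohort(
    dplyr::mutate(tibble::as_tibble(sim$cohort), died = .data$SGA),
    sim$cohort)
  ev <- suppressWarnings(
    evaluate_auc(det, "logistic", split_plan(seed = 2, n_repeats = 3)))
  expect_equal(nrow(ev$aucs), 3L)
  expect_equal(ev$aucs$auc, rep(1, 3))
  g <- glance(ev)
  expect_true(g$conf_low <= g$auc && g$auc <= g$conf_high)
})
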