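# Closed-form oracle: for a logistic model, the contrastive change is
# sigmoid(eta_rest + sum beta_S) - sigmoid(eta_rest), computable directly
# from the fitted coefficients.
logistic_contrast_oracle <- function(fit, test, features) {
  cf <- coef(fit$fit)
  feats <- fit$features
  x <- as.matrix(as.data.frame(test[feats]))
  eta_rest <- cf[["(Intercept)"]] +
    as.numeric(x[, setdiff(feats, features), drop = FALSE] %*%
                 cf[setdiff(feats, features)])
  plogis(eta_rest + sum(cf[features])) - plogis(eta_rest)
}

test_that("order-1 contrasts equal the analytic sigmoid difference", {
  sim <- simulate_cohort(default_sim_config(seed = 15, n_patients = 1200))
  parts <- split_cohort(sim$cohort, split_plan(seed = 2))
  fit <- fit_logistic_quietly(parts$train)
  for (f in c("SGA", "delirium", "diuretics")) {
    dp <- contrast_set(fit, parts$test, f)
    expect_equal(unname(dp), logistic_contrast_oracle(fit, parts$test, f),
                 tolerance = 1e-10)
  }
  # pairs and triples obey the same closed form
  trip <- c("delirium", "dementia_alzheimers", "cardiovascular_disease")
  expect_equal(unname(contrast_set(fit, parts$test, trip)),
               logistic_contrast_oracle(fit, parts$test, trip),
               tolerance = 1e-10)
})

test_that("zero-coefficient features produce exactly zero contrast", {
  sim <- simulate_cohort(default_sim_config(seed = 16, n_patients = 600))
  parts <- split_cohort(sim$cohort, split_plan(seed = 1))
  fit <- fit_logistic_quietly(parts$train)
  fit$fit$coefficients[["SGA"]] <- 0
  expect_equal(unname(contrast_set(fit, parts$test, "SGA")),
               rep(0, nrow(parts$test)))
  # beta = ln 9 alone, everything else zeroed: delta-p = 0.9 - 0.5 = 0.4
  fit$fit$coefficients[] <- 0
  fit$fit$coefficients[["SGA"]] <- log(9)
  expect_equal(unname(contrast_set(fit, parts$test, "SGA")),
               rep(0.4, nrow(parts$test)), tolerance = 1e-12)
})

test_that("the engine equals the brute-force two-prediction oracle exactly", {
  sim <- simulate_cohort(default_sim_config(seed = 17, n_patients = 500))
  parts <- split_cohort(sim$cohort, split_plan(seed = 2))
  models <- list(
    logistic = fit_logistic_quietly(parts$train),
    ae_rf = fit_ae_rf(parts$train, ae_spec(epochs = 30, seed = 1),
                      ntree = 60, seed = 2),
    rf_raw = fit_baseline(parts$train, "rf_raw", ntree = 60, seed = 3)
  )
  feats <- schema_binary_features(cohort_schema(sim$cohort))
  set.seed(99)
  for (i in 1:30) {
    model <- models[[sample(length(models), 1)]]
    fs <- sample(feats, sample(1:3, 1))
    pid <- sample(nrow(parts$test), 1)
    dp <- contrast_set(model, parts$test, fs)[[pid]]
    row1 <- tibble::as_tibble(parts$test)[pid, ]
    row0 <- row1
    for (f in fs) { row1[[f]] <- 1L; row0[[f]] <- 0L }
    brute <- predict_probability(model, row1) - predict_probability(model, row0)
    expect_equal(dp, brute, tolerance = 1e-12)
    expect_lte(abs(dp), 1)
  }
})

test_that("original values of perturbed features never influence the result", {
  sim <- simulate_cohort(default_sim_config(seed = 18, n_patients = 400))
  parts <- split_cohort(sim$cohort, split_plan(seed = 3))
  fit <- fit_logistic_quietly(parts$train)
  fs <- c("SGA", "self_harm")
  base <- contrast_set(fit, parts$test, fs)
  pre1 <- tibble::as_tibble(parts$test)
  for (f in fs) pre1[[f]] <- 1L
  pre1 <- rewrap_cohort(pre1, parts$test)
  expect_equal(contrast_set(fit, pre1, fs), base)
  pre0 <- tibble::as_tibble(parts$test)
  for (f in fs) pre0[[f]] <- 0L
  expect_equal(contrast_set(fit, rewrap_cohort(pre0, parts$test), fs), base)
})

test_that("sign of the contrast follows the summed coefficients", {
  sim <- simulate_cohort(default_sim_config(seed = 19, n_patients = 1500))
  parts <- split_cohort(sim$cohort, split_plan(seed = 4))
  fit <- fit_logistic_quietly(parts$train)
  cf <- coef(fit$fit)
  set.seed(7)
  feats <- schema_binary_features(cohort_schema(sim$cohort))
  for (i in 1:10) {
    fs <- sample(feats, sample(1:3, 1))
    if (abs(sum(cf[fs])) < 0.01) next  # sign numerically ill-defined
    dp <- contrast_set(fit, parts$test, fs)
    expect_true(all(sign(dp) == sign(sum(cf[fs]))), info = paste(fs, collapse = "+"))
  }
})

test_that("contrast matrices enumerate combinations with support metadata", {
  sim <- simulate_cohort(default_sim_config(seed = 20, n_patients = 400))
  parts <- split_cohort(sim$cohort, split_plan(seed = 5))
  fit <- fit_logistic_quietly(parts$train)
  subset4 <- c("SGA", "FGA", "diuretics", "delirium")
  cm <- contrast_matrix(fit, parts$test, order = 2, features = subset4,
                        train = parts$train)
  expect_equal(nrow(cm$columns), choose(4, 2))
  expect_identical(cm$columns$label, sort(cm$columns$label))
  expect_false(any(is.na(cm$columns$train_support)))
  # order-1 columns agree with contrast_set
  cm1 <- contrast_matrix(fit, parts$test, order = 1, features = subset4)
  expect_equal(cm1$deltas$SGA, unname(contrast_set(fit, parts$test, "SGA")))
  # guard rails
  expect_error(contrast_matrix(fit, parts$test, order = 2,
                               features = subset4, max_columns = 3),
               "above the cap")
  expect_error(contrast_matrix(fit, parts$test, order = 3,
                               features = c("SGA", "FGA")), "exceeds")
  expect_error(contrast_set(fit, parts$test, "age"),
               "only works with binary")
  expect_error(contrast_set(fit, parts$test, c("SGA", "SGA")), "duplicate")
})

test_that("permuting test rows permutes the matrix rows and nothing else", {
  sim <- simulate_cohort(default_sim_config(seed = 22, n_patients = 400))
  parts <- split_cohort(sim$cohort, split_plan(seed = 6))
  fit <- fit_logistic_quietly(parts$train)
  subset3 <- c("SGA", "FGA", "self_harm")
  cm <- contrast_matrix(fit, parts$test, order = 1, features = subset3)
  set.seed(1)
  perm <- sample(nrow(parts$test))
  shuffled <- rewrap_cohort(tibble::as_tibble(parts$test)[perm, ], parts$test)
  cm_p <- contrast_matrix(fit, shuffled, order = 1, features = subset3)
  expect_equal(cm_p$deltas, cm$deltas[perm, ])
})

test_that("zero-support columns are flagged; supported columns are not", {
  prev <- c(A = 0.4, B = 0.4, C = 0.3, D = 0.25)
  zp <- feature_pattern(A = 1, B = 1)
  sim <- simulate_cohort(sim_config(n_patients = 1500, prevalence = prev,
                                    intercept = -0.5, zero_support = list(zp),
                                    seed = 23))
  parts <- split_cohort(sim$cohort, split_plan(seed = 7))
  fit <- fit_logistic_quietly(parts$train)
  cm <- contrast_matrix(fit, parts$test, order = 2, train = parts$train)
  flags <- flag_zero_support(cm, parts$train, parts$test)
  expect_true(flags$flagged[flags$label == "A+B"])
  expect_false(flags$flagged[flags$label == "C+D"])
  # an empty test cohort flags every column (vacuous support)
  empty <- classcontrast:::cohort_slice(parts$test, integer(0))
  empty_train <- classcontrast:::cohort_slice(parts$train, integer(0))
  flags0 <- flag_zero_support(cm, empty_train, empty)
  expect_true(all(flags0$flagged))
})
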