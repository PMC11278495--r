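# Fixtures are built in code at test time; nothing binary is stored.

abc_schema <- function() {
  feature_schema(
    name = c("A", "B", "age", "died"),
    role = c("binary_categorical", "binary_categorical", "continuous_age",
             "outcome"),
    label = c("feature A", "feature B", "age", "died")
  )
}

# Write a data frame as CSV and load it through the package reader.
cohort_from_df <- function(df, schema, scaler = NULL) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  load_cohort(path, schema, scaler = scaler)
}

# A small hand-built cohort: 8 rows, features A and B, ages spanning 20-100.
tiny_cohort <- function() {
  cohort_from_df(tibble::tibble(
    patient_id = paste0("p", 1:8),
    A = c(1, 0, 1, 0, 1, 0, 1, 0),
    B = c(1, 1, 0, 0, 1, 1, 0, 0),
    age = c(20, 30, 40, 50, 60, 70, 80, 100),
    died = c(1, 0, 1, 0, 0, 1, 0, 1)
  ), abc_schema())
}

# Rebuild a cohort after mutating its underlying tibble (tests only).
rewrap_cohort <- function(data, template) {
  classcontrast:::new_cohort(data, cohort_schema(template),
                             cohort_scaler(template))
}

# Planted strong-signal cohort for separability checks: one log-OR-3 feature
# at prevalence 0.5 among ten low-prevalence noise features plus age.
strong_signal_config <- function(seed, n = 2000L) {
  prev <- c(signal = 0.5,
            stats::setNames(rep(0.15, 10), sprintf("noise%02d", 1:10)))
  sim_config(n_patients = n, prevalence = prev, intercept = -1.5,
             beta = c(signal = 3), beta_age = 0.5, seed = seed)
}

# Held-out AUC of a fitted model on a test cohort.
test_auc <- function(model, test) {
  p <- predict_probability(model, test)
  as.numeric(pROC::auc(response = test$died, predictor = p,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

# Quiet wrapper: some tiny fixtures provoke separation warnings by design.
fit_logistic_quietly <- function(...) suppressWarnings(fit_logistic(...))
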