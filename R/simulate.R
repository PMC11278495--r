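#' Configure a synthetic cohort simulation
#'
#' Describes the data-generating process for a synthetic psychiatric cohort:
#' independent Bernoulli binary features with heterogeneous prevalence, age
#' uniform on a range (entering the outcome model feature-scaled), and a
#' binary death outcome drawn from a logistic model with main effects and
#' optional interactions. Co-occurrence excesses can be planted as exact
#' appended strata (making downstream ablation counts exact), and named
#' feature combinations can be guaranteed absent so that zero-support
#' flagging has known ground truth.
#'
#' @param n_patients number of base patients (planted strata are appended on
#'   top of these).
#' @param prevalence named vector of per-feature Bernoulli probabilities, all
#'   strictly inside (0, 1).
#' @param age_range c(min, max) in years.
#' @param intercept intercept of the outcome logistic model (log-odds).
#' @param beta named vector of per-feature log-odds effects on death; features
#'   omitted here get effect 0.
#' @param beta_age log-odds effect of scaled age.
#' @param interactions list of `list(features = c(...), beta = )` product
#'   terms added to the linear predictor.
#' @param planted_strata list of `list(pattern = , outcome = 0/1, n = )`; for
#'   each, `n` extra rows are appended with the pattern's features fixed, the
#'   remaining features drawn from their prevalences, and the outcome fixed.
#' @param zero_support list of [feature_pattern()]s guaranteed absent from the
#'   emitted cohort (violating rows are redrawn, up to a bounded number of
#'   passes).
#' @param seed integer seed; identical seeds give bitwise-identical cohorts.
#' @return a `cc_sim_config` list.
#' @seealso [simulate_cohort()], [default_sim_config()]
#' @export
sim_config <- function(n_patients,
                       prevalence,
                       age_range = c(18, 95),
                       intercept = -2,
                       beta = numeric(0),
                       beta_age = 0,
                       interactions = list(),
                       planted_strata = list(),
                       zero_support = list(),
                       seed = 1L) {
  stopifnot(n_patients >= 1, length(prevalence) >= 1)
  if (is.null(names(prevalence)) || any(!nzchar(names(prevalence)))) {
    stop("`prevalence` must be a named vector", call. = FALSE)
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalences must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (length(beta) && anyNA(match(names(beta), names(prevalence)))) {
    stop("`beta` names a feature absent from `prevalence`", call. = FALSE)
  }
  for (ia in interactions) {
    if (anyNA(match(ia$features, names(prevalence)))) {
      stop("interaction names a feature absent from `prevalence`", call. = FALSE)
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    age_range = age_range, intercept = intercept, beta = beta,
    beta_age = beta_age, interactions = interactions,
    planted_strata = lapply(planted_strata, function(s) {
      list(pattern = as_pattern(s$pattern), outcome = as.integer(s$outcome),
           n = as.integer(s$n))
    }),
    zero_support = lapply(zero_support, as_pattern),
    seed = assert_scalar_int(seed, "seed")
  ), class = "cc_sim_config")
}

#' Default simulation: a schizophrenia-like synthetic cohort
#'
#' A ready-made configuration emulating the structure of a secondary mental
#' healthcare cohort: 1706 patients, 24 binary bio-social features
#' (medication categories, co-morbidities, social and personal risk factors)
#' with prevalences spread over 0.02-0.5 so that rare combinations occur, age
#' 18-95 as the only continuous predictor, and a logistic outcome with a
#' handful of nonzero effects. Prevalences and effects are illustrative
#' defaults, not estimates from any real cohort.
#'
#' @param seed integer seed.
#' @param n_patients cohort size before any planted strata.
#' @return a `cc_sim_config`.
#' @export
default_sim_config <- function(seed = 1L, n_patients = 1706L) {
  feats <- c(
    SGA = 0.50, FGA = 0.30, antidepressants = 0.40, diuretics = 0.06,
    thyroid_medication = 0.05, antimanic = 0.08, dementia_medication = 0.03,
    diabetes = 0.15, cardiovascular_disease = 0.20, respiratory_disease = 0.10,
    antihypertensives = 0.12, dementia_alzheimers = 0.04, delirium = 0.05,
    mild_cognitive_disorder = 0.04, depressive_disorder = 0.25,
    personality_disorder = 0.10, lack_family_support = 0.08,
    personal_risk_factors = 0.12, substance_abuse = 0.22, self_harm = 0.18,
    noncompliance = 0.09, crisis_team_referral = 0.30,
    prior_suicide_attempt = 0.15, gender_male = 0.50
  )
  sim_config(
    n_patients = n_patients,
    prevalence = feats,
    age_range = c(18, 95),
    intercept = -2.5,
    beta = c(
      cardiovascular_disease = 0.8, diabetes = 0.5, respiratory_disease = 0.6,
      dementia_alzheimers = 0.9, delirium = 0.7, diuretics = -0.6,
      antidepressants = -0.4, prior_suicide_attempt = 0.6, substance_abuse = 0.4
    ),
    beta_age = 2.0,
    seed = seed
  )
}

#' Simulate the classic data-ablation scenario
#'
#' Builds a cohort in which a genuinely risk-increasing feature acquires a
#' counter-intuitive negative fitted log-odds purely through a co-occurrence
#' excess in the data: a base cohort where `prior_suicide_attempt` truly
#' increases death odds (and never co-occurs with `SGA`), plus an appended
#' stratum of patients who are alive with both `prior_suicide_attempt = 1`
#' and `SGA = 1`. Ablating the condition
#' `{prior_suicide_attempt = 1, SGA = 1, died = 0}` removes exactly the
#' appended stratum, so removal counts are exact, and refitting flips the
#' feature's log-odds back to positive.
#'
#' @param seed integer seed.
#' @param n_base base cohort size (default 1167).
#' @param n_excess appended alive-stratum size (default 539, giving a
#'   1706-row cohort).
#' @param beta_risk true log-odds effect of `prior_suicide_attempt` in the
#'   base cohort.
#' @return a list with `cohort`, the ablation `condition`
#'   (an [ablation_spec()]-ready pattern plus outcome), and the counts.
#' @export
ablation_demo_cohort <- function(seed = 1L, n_base = 1167L, n_excess = 539L,
                                 beta_risk = 1.0) {
  prev <- c(prior_suicide_attempt = 0.3, SGA = 0.5, antidepressants = 0.4,
            cardiovascular_disease = 0.2, self_harm = 0.15)
  base_cfg <- sim_config(
    n_patients = n_base, prevalence = prev, age_range = c(18, 95),
    intercept = -1, beta = c(prior_suicide_attempt = beta_risk,
                             cardiovascular_disease = 0.5,
                             antidepressants = -0.3),
    beta_age = 1.0,
    zero_support = list(feature_pattern(prior_suicide_attempt = 1, SGA = 1)),
    seed = seed
  )
  base <- simulate_cohort(base_cfg)$cohort
  # appended stratum: alive patients carrying both features; free features
  # drawn from the same prevalences
  xs <- draw_features(n_excess, prev,
                      fixed = list(prior_suicide_attempt = 1L, SGA = 1L))
  scaler <- cohort_scaler(base)
  extra <- tibble::as_tibble(as.data.frame(xs))
  extra$age <- apply_age_scaler(scaler, stats::runif(n_excess, 18, 95))
  extra$died <- 0L
  extra <- tibble::add_column(
    extra, patient_id = sprintf("X%05d", seq_len(n_excess)), .before = 1)
  data <- dplyr::bind_rows(tibble::as_tibble(base),
                           extra[c("patient_id", cohort_schema(base)$name)])
  cohort <- new_cohort(data, cohort_schema(base), scaler)
  list(
    cohort = cohort,
    condition = list(pattern = feature_pattern(prior_suicide_attempt = 1, SGA = 1),
                     outcome = 0L),
    n_base = n_base, n_excess = n_excess
  )
}

draw_features <- function(n, prevalence, fixed = NULL, zero_support = list(),
                          max_passes = 100L) {
  feats <- names(prevalence)
  free <- setdiff(feats, names(fixed))
  draw_rows <- function(k) {
    m <- matrix(0L, nrow = k, ncol = length(feats), dimnames = list(NULL, feats))
    for (f in free) m[, f] <- stats::rbinom(k, 1L, prevalence[[f]])
    for (f in names(fixed)) m[, f] <- fixed[[f]]
    m
  }
  # Reject unavoidable zero-support patterns: every assignment already pinned
  # to the pattern's values by `fixed` means resampling can never help.
  for (zp in zero_support) {
    pinned <- names(zp)[names(zp) %in% names(fixed)]
    if (length(pinned) == length(zp) &&
        all(unclass(zp) == unlist(fixed[names(zp)]))) {
      stop("zero-support pattern [", format(zp),
           "] is forced by a planted stratum and cannot be enforced",
           call. = FALSE)
    }
  }
  x <- draw_rows(n)
  if (length(zero_support)) {
    for (pass in seq_len(max_passes)) {
      viol <- rep(FALSE, n)
      for (zp in zero_support) {
        viol <- viol | pattern_mask(as.data.frame(x), zp)
      }
      if (!any(viol)) break
      if (pass == max_passes) {
        stop("could not enforce zero-support patterns after ", max_passes,
             " resampling passes (pattern probability too high under the ",
             "configured prevalences)", call. = FALSE)
      }
      x[viol, ] <- draw_rows(sum(viol))
    }
  }
  x
}

linear_predictor <- function(x, age_scaled, config) {
  eta <- rep(config$intercept, nrow(x)) + config$beta_age * age_scaled
  for (f in names(config$beta)) eta <- eta + config$beta[[f]] * x[, f]
  for (ia in config$interactions) {
    prod_term <- rep(1, nrow(x))
    for (f in ia$features) prod_term <- prod_term * x[, f]
    eta <- eta + ia$beta * prod_term
  }
  eta
}

#' Simulate a synthetic cohort with a ground-truth manifest
#'
#' Draws a cohort from the data-generating process in a [sim_config()] and
#' returns it together with a manifest recording the configuration and the
#' realized quantities (prevalences, outcome rate, per-pattern support
#' counts), which enables parameter-recovery and support-count tests.
#'
#' @param config a `cc_sim_config`.
#' @return a list with elements `cohort` (a `cc_cohort`) and `manifest`.
#' @examples
#' sim <- simulate_cohort(default_sim_config(seed = 7, n_patients = 300))
#' sim$manifest$realized_outcome_rate
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cc_sim_config"))
  set.seed(config$seed)
  feats <- names(config$prevalence)

  x <- draw_features(config$n_patients, config$prevalence,
                     zero_support = config$zero_support)
  age <- stats::runif(config$n_patients, config$age_range[1], config$age_range[2])
  scaler <- age_scaler(config$age_range[1], config$age_range[2])
  age_s <- apply_age_scaler(scaler, age)
  p_death <- sigmoid(linear_predictor(x, age_s, config))
  y <- stats::rbinom(config$n_patients, 1L, p_death)

  for (st in config$planted_strata) {
    check <- setdiff(names(st$pattern), feats)
    if (length(check)) {
      stop("planted stratum names unknown feature(s): ",
           paste(check, collapse = ", "), call. = FALSE)
    }
    xs <- draw_features(st$n, config$prevalence,
                        fixed = as.list(st$pattern),
                        zero_support = config$zero_support)
    ages <- apply_age_scaler(
      scaler, stats::runif(st$n, config$age_range[1], config$age_range[2]))
    x <- rbind(x, xs)
    age_s <- c(age_s, ages)
    y <- c(y, rep(st$outcome, st$n))
  }

  n_total <- nrow(x)
  schema <- feature_schema(
    name = c(feats, "age", "died"),
    role = c(rep("binary_categorical", length(feats)), "continuous_age", "outcome"),
    label = c(gsub("_", " ", feats), "age", "died during observation")
  )
  data <- tibble::as_tibble(as.data.frame(x))
  data$age <- age_s
  data$died <- as.integer(y)
  data <- tibble::add_column(data,
                             patient_id = sprintf("P%05d", seq_len(n_total)),
                             .before = 1)
  cohort <- new_cohort(data, schema, scaler)

  for (zp in config$zero_support) {
    if (pattern_support(cohort, zp) != 0L) {
      stop("zero-support pattern [", format(zp), "] present after generation",
           call. = FALSE)
    }
  }

  manifest <- list(
    n_patients = n_total,
    n_base = config$n_patients,
    seed = config$seed,
    realized_prevalence = colMeans(x),
    realized_outcome_rate = mean(y),
    planted_support = lapply(config$planted_strata, function(st) {
      list(pattern = format(st$pattern), outcome = st$outcome,
           planted_n = st$n,
           realized_support = sum(pattern_mask(data, st$pattern) &
                                    data$died == st$outcome))
    }),
    zero_support = lapply(config$zero_support, function(zp) {
      list(pattern = format(zp), realized_support = pattern_support(cohort, zp))
    }),
    config = config
  )
  list(cohort = cohort, manifest = manifest)
}
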