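#' Predicted death probability from a fitted model
#'
#' Every model in the package — plain or L1-regularised logistic regression,
#' the autoencoder + random forest, and the baseline models — satisfies one
#' contract: fit on a training cohort, then map a cohort (or plain data frame
#' with the same feature columns) to a per-patient probability of death in
#' [0, 1]. The class-contrastive engine treats fitted models strictly as
#' black boxes through this function.
#'
#' @param model a fitted `cc_model`.
#' @param data a `cc_cohort` or data frame containing the model's feature
#'   columns.
#' @param ... unused.
#' @return a numeric vector of probabilities, one per row of `data`.
#' @export
predict_probability <- function(model, data, ...) {
  UseMethod("predict_probability")
}

check_fitted <- function(model) {
  if (!isTRUE(model$fitted)) {
    stop("model has not been fitted", call. = FALSE)
  }
  invisible(TRUE)
}

# Predictor columns (binary features + scaled age), in schema order.
predictor_features <- function(schema) {
  c(schema_binary_features(schema), schema_age_feature(schema))
}

predictor_frame <- function(model, data) {
  missing_cols <- setdiff(model$features, names(data))
  if (length(missing_cols)) {
    stop("data lacks model feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as.data.frame(data[model$features])
}

# Numeric design matrix with interaction product columns appended.
design_matrix <- function(model, data) {
  df <- predictor_frame(model, data)
  x <- as.matrix(df)
  for (ia in model$interactions) {
    x <- cbind(x, apply(x[, ia, drop = FALSE], 1, prod))
    colnames(x)[ncol(x)] <- paste(ia, collapse = ":")
  }
  x
}

#' Plan a repeated training-test-validation split
#'
#' @param fractions named proportions for `train`, `test` and `validation`;
#'   must sum to 1. The default 50-25-25 split trains on half the cohort,
#'   selects regularisation on the validation quarter and reports metrics on
#'   the test quarter.
#' @param seed integer seed for the permutation.
#' @param n_repeats number of independent re-splits for [evaluate_auc()].
#' @return a `cc_split_plan`.
#' @export
split_plan <- function(fractions = c(train = 0.5, test = 0.25, validation = 0.25),
                       seed = 1L, n_repeats = 1L) {
  if (!setequal(names(fractions), c("train", "test", "validation"))) {
    stop("fractions must be named train, test and validation", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(list(fractions = fractions[c("train", "test", "validation")],
                 seed = assert_scalar_int(seed, "seed"),
                 n_repeats = as.integer(n_repeats)),
            class = "cc_split_plan")
}

#' Partition a cohort into train, test and validation tables
#'
#' Deterministic under the plan's seed; the three parts partition the patient
#' ids disjointly with sizes within rounding of the plan's fractions.
#'
#' @param cohort a `cc_cohort` with at least 8 rows.
#' @param plan a [split_plan()].
#' @return a named list of three `cc_cohort`s.
#' @export
split_cohort <- function(cohort, plan = split_plan()) {
  stopifnot(inherits(plan, "cc_split_plan"))
  n <- nrow(cohort)
  if (n < 8L) stop("cohort too small to split (need >= 8 rows)", call. = FALSE)
  sizes <- floor(n * plan$fractions)
  for (i in seq_len(n - sum(sizes))) {
    sizes[((i - 1L) %% 3L) + 1L] <- sizes[((i - 1L) %% 3L) + 1L] + 1L
  }
  set.seed(plan$seed)
  perm <- sample.int(n)
  idx <- split(perm, rep(c("train", "test", "validation"), times = sizes))
  lapply(idx[c("train", "test", "validation")],
         function(i) cohort_slice(cohort, sort(i)))
}

odds_table_from_glm <- function(fit) {
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  p <- sm[, "Pr(>|z|)"]
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(est),
    std_error = unname(se),
    odds_ratio = exp(unname(est)),
    conf_low = exp(unname(est - stats::qnorm(0.975) * se)),
    conf_high = exp(unname(est + stats::qnorm(0.975) * se)),
    p_value = unname(p),
    significant = unname(p < 0.05)
  )
}

#' Fit a logistic mortality model
#'
#' With `lambda = 0` this is an unpenalised maximum-likelihood fit via
#' [stats::glm()], returning a full odds table (log-odds coefficient, odds
#' ratio, Wald 95\% CI and p-value per term). With `lambda > 0` an L1
#' (lasso) penalised fit via glmnet is used; penalised coefficients carry no
#' standard errors, so the odds table then reports point estimates only.
#' Interaction terms are product columns of named binary feature pairs (or
#' larger sets).
#'
#' @param train a `cc_cohort`; the outcome must show both classes.
#' @param lambda non-negative L1 penalty; 0 for the unpenalised fit.
#' @param interactions list of character vectors of feature names, e.g.
#'   `list(c("self_harm", "FGA"))`.
#' @return a fitted `cc_logistic` model.
#' @export
fit_logistic <- function(train, lambda = 0, interactions = list()) {
  schema <- cohort_schema(train)
  outcome <- schema_outcome(schema)
  y <- train[[outcome]]
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class in the training data", call. = FALSE)
  }
  stopifnot(lambda >= 0)
  if (is.character(interactions)) interactions <- list(interactions)
  feats <- predictor_features(schema)
  for (ia in interactions) {
    if (!all(ia %in% schema_binary_features(schema))) {
      stop("interactions must name binary features", call. = FALSE)
    }
  }
  model <- list(kind = if (lambda > 0) "l1_logistic" else "logistic",
                features = feats, outcome = outcome, schema = schema,
                interactions = interactions, lambda = lambda,
                fit_warnings = character(0), fitted = FALSE)

  if (lambda == 0) {
    terms <- c(feats, vapply(interactions, paste, character(1), collapse = ":"))
    fml <- stats::as.formula(
      paste(outcome, "~", paste(terms, collapse = " + ")))
    df <- as.data.frame(train[c(outcome, feats)])
    warns <- character(0)
    fit <- withCallingHandlers(
      stats::glm(fml, family = stats::binomial(), data = df),
      warning = function(w) warns <<- c(warns, conditionMessage(w))
    )
    # separation / non-convergence is recorded on the model, not swallowed
    model$fit_warnings <- warns
    if (length(warns)) {
      warning("logistic fit warned: ", paste(warns, collapse = "; "),
              call. = FALSE)
    }
    model$fit <- fit
    model$odds <- odds_table_from_glm(fit)
  } else {
    x <- design_matrix(model, train)
    # a singleton lambda makes glmnet's path degenerate; pad and predict at it
    lam_seq <- sort(unique(c(lambda, lambda * c(100, 10, 2))), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          lambda = lam_seq, standardize = FALSE)
    model$fit <- fit
    cf <- as.matrix(stats::coef(fit, s = lambda))
    model$odds <- tibble::tibble(
      term = rownames(cf), estimate = cf[, 1], std_error = NA_real_,
      odds_ratio = exp(cf[, 1]), conf_low = NA_real_, conf_high = NA_real_,
      p_value = NA_real_, significant = NA
    )
  }
  model$fitted <- TRUE
  class(model) <- c("cc_logistic", "cc_model")
  model
}

#' @export
predict_probability.cc_logistic <- function(model, data, ...) {
  check_fitted(model)
  if (model$lambda == 0) {
    p <- stats::predict(model$fit, newdata = predictor_frame(model, data),
                        type = "response")
  } else {
    x <- design_matrix(model, data)
    p <- as.numeric(stats::predict(model$fit, newx = x, s = model$lambda,
                                   type = "response"))
  }
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' Select an L1 penalty by 10-fold cross-validation
#'
#' Scores every grid value by mean 10-fold cross-validated negative
#' log-likelihood of an L1 logistic fit and returns the minimiser; ties are
#' broken toward the larger (more parsimonious) penalty. Fold assignment is
#' seeded and therefore reproducible.
#'
#' @param data a `cc_cohort` (conventionally the validation split).
#' @param grid non-empty vector of candidate penalties.
#' @param nfolds number of folds.
#' @param seed integer seed for fold assignment.
#' @return the selected penalty (scalar), with the per-lambda CV losses in
#'   attribute `"cv"`.
#' @export
select_lambda <- function(data, grid = lambda_grid(), nfolds = 10L, seed = 1L) {
  if (length(grid) == 0L) stop("empty penalty grid", call. = FALSE)
  grid <- sort(unique(grid))
  if (length(grid) == 1L) return(grid)
  schema <- cohort_schema(data)
  y <- data[[schema_outcome(schema)]]
  x <- as.matrix(as.data.frame(data[predictor_features(schema)]))
  n <- nrow(x)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(nfolds), n))
  eps <- 1e-12
  nll <- matrix(NA_real_, nrow = nfolds, ncol = length(grid))
  lam_fit <- sort(unique(c(grid, max(grid) * 10)), decreasing = TRUE)
  for (k in seq_len(nfolds)) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 1L) next
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 1, lambda = lam_fit, standardize = FALSE)
    p <- stats::predict(fit, newx = x[!tr, , drop = FALSE], s = grid,
                        type = "response")
    p <- pmin(pmax(p, eps), 1 - eps)
    yk <- y[!tr]
    nll[k, ] <- -colMeans(yk * log(p) + (1 - yk) * log(1 - p))
  }
  mean_nll <- colMeans(nll, na.rm = TRUE)
  best <- max(grid[mean_nll <= min(mean_nll) + 1e-12])
  attr(best, "cv") <- tibble::tibble(lambda = grid, cv_nll = mean_nll)
  best
}

#' Default logarithmic penalty grid
#'
#' Seven points spanning 1e-4 to 10, wide enough to cover both under- and
#' over-regularised fits on cohorts of a few thousand patients.
#' @return numeric vector.
#' @export
lambda_grid <- function() 10^seq(-4, 1, length.out = 7)

#' Fit a baseline mortality model
#'
#' The comparison models: a random forest on the raw features (`rf_raw`),
#' random forest or logistic regression on the foremost 10 principal
#' components fitted on the training data only (`pca_rf`, `pca_lr`), and an
#' L1-regularised logistic regression (`l1_logistic`, penalty chosen with
#' [select_lambda()] when not supplied).
#'
#' @param train a `cc_cohort`.
#' @param kind one of `"rf_raw"`, `"pca_rf"`, `"pca_lr"`, `"l1_logistic"`.
#' @param lambda penalty for `l1_logistic`; `NULL` selects by 10-fold CV on
#'   `train`.
#' @param n_components principal components kept for the PCA variants.
#' @param ntree,seed random-forest size and seed.
#' @return a fitted `cc_model`.
#' @export
fit_baseline <- function(train, kind = c("rf_raw", "pca_rf", "pca_lr", "l1_logistic"),
                         lambda = NULL, n_components = 10L, ntree = 500L,
                         seed = 1L) {
  kind <- match.arg(kind)
  schema <- cohort_schema(train)
  feats <- predictor_features(schema)
  y <- train[[schema_outcome(schema)]]
  x <- as.matrix(as.data.frame(train[feats]))

  if (kind == "l1_logistic") {
    if (is.null(lambda)) lambda <- as.numeric(select_lambda(train, seed = seed))
    return(fit_logistic(train, lambda = lambda))
  }
  model <- list(kind = kind, features = feats,
                outcome = schema_outcome(schema), schema = schema,
                interactions = list(), seed = as.integer(seed),
                ntree = as.integer(ntree), fitted = FALSE)
  if (kind %in% c("pca_rf", "pca_lr")) {
    if (ncol(x) < n_components) {
      stop("PCA baselines need at least ", n_components, " input features",
           call. = FALSE)
    }
    pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    model$rotation <- pca$rotation[, seq_len(n_components), drop = FALSE]
    model$center <- pca$center
    z <- pca$x[, seq_len(n_components), drop = FALSE]
  } else {
    z <- x
  }
  if (kind == "pca_lr") {
    df <- data.frame(z)
    df$.y <- y
    model$fit <- stats::glm(.y ~ ., family = stats::binomial(), data = df)
  } else {
    set.seed(seed)
    model$fit <- randomForest::randomForest(
      x = z, y = factor(y, levels = c(0, 1)), ntree = ntree,
      mtry = max(1L, floor(sqrt(ncol(z)))))
  }
  model$fitted <- TRUE
  class(model) <- c(paste0("cc_", kind), "cc_model")
  model
}

project_pca <- function(model, data) {
  x <- as.matrix(predictor_frame(model, data))
  sweep(x, 2, model$center) %*% model$rotation
}

#' @export
predict_probability.cc_rf_raw <- function(model, data, ...) {
  check_fitted(model)
  x <- as.matrix(predictor_frame(model, data))
  unname(stats::predict(model$fit, newdata = x, type = "prob")[, "1"])
}

#' @export
predict_probability.cc_pca_rf <- function(model, data, ...) {
  check_fitted(model)
  z <- project_pca(model, data)
  unname(stats::predict(model$fit, newdata = z, type = "prob")[, "1"])
}

#' @export
predict_probability.cc_pca_lr <- function(model, data, ...) {
  check_fitted(model)
  z <- as.data.frame(project_pca(model, data))
  unname(pmin(pmax(stats::predict(model$fit, newdata = z, type = "response"),
                   0), 1))
}

#' Model builders for repeated-split evaluation
#'
#' Returns a `function(train, validation)` producing a fitted model, suitable
#' for [evaluate_auc()]. For `l1_logistic` the penalty is chosen by 10-fold
#' cross-validation on the validation split, then the model is refitted on
#' the training split at that penalty.
#'
#' @param kind one of `"logistic"`, `"l1_logistic"`, `"ae_rf"`, `"rf_raw"`,
#'   `"pca_rf"`, `"pca_lr"`.
#' @param seed integer seed forwarded to stochastic fits.
#' @param ae_spec autoencoder specification for `"ae_rf"` (see [ae_spec()]).
#' @param ... forwarded to the underlying fit function.
#' @return a builder function.
#' @export
model_builder <- function(kind, seed = 1L, ae_spec = NULL, ...) {
  force(seed)
  dots <- list(...)
  switch(kind,
    logistic = function(train, validation = NULL) fit_logistic(train),
    l1_logistic = function(train, validation = NULL) {
      sel_on <- validation %||% train
      lam <- as.numeric(select_lambda(sel_on, seed = seed))
      fit_logistic(train, lambda = lam)
    },
    ae_rf = function(train, validation = NULL) {
      spec <- ae_spec %||% ae_spec_default(seed = seed)
      do.call(fit_ae_rf, c(list(train = train, spec = spec), dots))
    },
    rf_raw = ,
    pca_rf = ,
    pca_lr = function(train, validation = NULL) {
      do.call(fit_baseline, c(list(train = train, kind = kind, seed = seed), dots))
    },
    stop("unknown model kind: ", kind, call. = FALSE)
  )
}

ae_spec_default <- function(seed = 1L) ae_spec(seed = seed)

#' Repeated-split AUC evaluation
#'
#' For each repeat: draw a fresh 50-25-25 split, fit the model on the
#' training part (selecting any penalty on the validation part), and score
#' the area under the ROC curve on the held-out test part. The summary
#' interval is the 2.5/97.5 percentile of the repeat AUCs. A repeat whose
#' test split contains a single outcome class is re-drawn under a new seed
#' and the event recorded in the report.
#'
#' @param cohort a `cc_cohort`.
#' @param builder a `function(train, validation)` returning a fitted model,
#'   or a model kind string accepted by [model_builder()].
#' @param plan a [split_plan()] whose `n_repeats` sets the number of repeats.
#' @return a `cc_eval` with per-repeat AUCs, the mean estimate and the
#'   percentile interval.
#' @export
evaluate_auc <- function(cohort, builder, plan = split_plan(n_repeats = 10L)) {
  stopifnot(plan$n_repeats >= 1L)
  kind <- if (is.character(builder)) builder else "custom"
  if (is.character(builder)) builder <- model_builder(builder, seed = plan$seed)
  outcome <- schema_outcome(cohort_schema(cohort))
  aucs <- numeric(plan$n_repeats)
  redraws <- 0L
  for (r in seq_len(plan$n_repeats)) {
    for (attempt in 0:19) {
      seed_r <- derive_seed(plan$seed + 131L * attempt, "split") + r
      parts <- split_cohort(cohort, split_plan(seed = seed_r))
      y_test <- parts$test[[outcome]]
      if (length(unique(y_test)) == 2L) break
      redraws <- redraws + 1L
      message("repeat ", r, ": single-class test split, re-drawing")
      if (attempt == 19L) {
        stop("could not draw a two-class test split", call. = FALSE)
      }
    }
    model <- builder(parts$train, parts$validation)
    p <- predict_probability(model, parts$test)
    aucs[r] <- as.numeric(pROC::auc(
      response = y_test, predictor = p,
      levels = c(0, 1), direction = "<", quiet = TRUE))
  }
  structure(list(
    aucs = tibble::tibble(rep = seq_len(plan$n_repeats), auc = aucs),
    estimate = mean(aucs),
    conf_low = unname(stats::quantile(aucs, 0.025)),
    conf_high = unname(stats::quantile(aucs, 0.975)),
    model_kind = kind, n_repeats = plan$n_repeats, redraws = redraws,
    seed = plan$seed
  ), class = "cc_eval")
}

#' @exportS3Method base::print
print.cc_eval <- function(x, ...) {
  cat(sprintf("<cc_eval> %s: AUC %.3f (95%% interval [%.3f, %.3f], %d repeats)\n",
              x$model_kind, x$estimate, x$conf_low, x$conf_high, x$n_repeats))
  invisible(x)
}
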