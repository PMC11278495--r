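#' Autoencoder specification
#'
#' A compact single-hidden-layer autoencoder used for dimensionality
#' reduction of the bio-social feature vector: inputs in [0, 1] are projected
#' through a ReLU hidden layer (default 10 neurons, fewer than the input
#' width) and reconstructed through a sigmoid output layer. Weights start
#' from Xavier (Glorot uniform) initialisation and are trained full-batch
#' with Adadelta. The reconstruction loss is either a Kullback-Leibler
#' divergence between the per-row-normalised input and reconstruction
#' (`loss = "kl"`, the default) or an element-wise Bernoulli cross-entropy
#' (`loss = "cross_entropy"`); an L1 penalty `lambda` on the weights may be
#' added.
#'
#' @param n_hidden hidden-layer width; must stay below the input width.
#' @param loss `"kl"` or `"cross_entropy"`.
#' @param lambda non-negative L1 penalty on the weight matrices.
#' @param epochs training epochs (default 1000).
#' @param rho,adadelta_eps Adadelta decay and stabiliser.
#' @param seed integer seed for the weight initialisation.
#' @return a `cc_ae_spec`.
#' @export
ae_spec <- function(n_hidden = 10L, loss = c("kl", "cross_entropy"),
                    lambda = 0, epochs = 1000L, rho = 0.95,
                    adadelta_eps = 1e-6, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(n_hidden >= 1L, epochs >= 1L, lambda >= 0)
  structure(list(n_hidden = as.integer(n_hidden), loss = loss, lambda = lambda,
                 epochs = as.integer(epochs), rho = rho,
                 adadelta_eps = adadelta_eps,
                 seed = assert_scalar_int(seed, "seed")),
            class = "cc_ae_spec")
}

AE_EPS <- 1e-7

ae_init <- function(m, h, seed) {
  set.seed(seed)
  lim1 <- sqrt(6 / (m + h))
  lim2 <- sqrt(6 / (h + m))
  list(
    W1 = matrix(stats::runif(m * h, -lim1, lim1), m, h),
    b1 = numeric(h),
    W2 = matrix(stats::runif(h * m, -lim2, lim2), h, m),
    b2 = numeric(m)
  )
}

# One full-batch forward + backward pass; returns the penalised loss and the
# gradient of every parameter. Loss is the mean over rows so the gradient
# scale is independent of cohort size.
ae_forward_backward <- function(params, X, loss, lambda) {
  n <- nrow(X)
  Z1 <- sweep(X %*% params$W1, 2, params$b1, `+`)
  H <- pmax(Z1, 0)
  Z2 <- sweep(H %*% params$W2, 2, params$b2, `+`)
  S <- sigmoid(Z2)

  if (loss == "cross_entropy") {
    Sc <- pmin(pmax(S, AE_EPS), 1 - AE_EPS)
    L <- -sum(X * log(Sc) + (1 - X) * log(1 - Sc)) / n
    dZ2 <- (S - X) / n
  } else {
    U <- (X + AE_EPS) / rowSums(X + AE_EPS)
    Tm <- S + AE_EPS
    Ts <- rowSums(Tm)
    V <- Tm / Ts
    L <- sum(U * (log(U) - log(V))) / n
    dS <- (-U / Tm + 1 / Ts) / n
    dZ2 <- dS * S * (1 - S)
  }
  L <- L + lambda * (sum(abs(params$W1)) + sum(abs(params$W2)))

  gW2 <- crossprod(H, dZ2) + lambda * sign(params$W2)
  gb2 <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(params$W2)) * (Z1 > 0)
  gW1 <- crossprod(X, dZ1) + lambda * sign(params$W1)
  gb1 <- colSums(dZ1)
  list(loss = L, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

ae_loss <- function(params, X, loss, lambda) {
  ae_forward_backward(params, X, loss, lambda)$loss
}

#' Fit an autoencoder on a cohort's features
#'
#' Trains the reconstruction network of [ae_spec()] on the cohort's predictor
#' columns (binary features plus scaled age; the outcome is never shown to
#' the autoencoder) and returns an encoder mapping feature rows to the
#' hidden-layer representation. The per-epoch penalised training loss is
#' retained in `$loss_trace`; a non-finite loss aborts with an error rather
#' than training on silently.
#'
#' @param train a `cc_cohort` (or data frame of features in [0, 1]).
#' @param spec an [ae_spec()].
#' @return a `cc_autoencoder` with weights, `$loss_trace`, and the feature
#'   names it encodes.
#' @export
fit_autoencoder <- function(train, spec = ae_spec()) {
  stopifnot(inherits(spec, "cc_ae_spec"))
  if (inherits(train, "cc_cohort")) {
    feats <- predictor_features(cohort_schema(train))
  } else {
    feats <- names(train)
  }
  X <- as.matrix(as.data.frame(train[feats]))
  if (any(X < 0 | X > 1)) {
    stop("autoencoder inputs must lie in [0, 1]", call. = FALSE)
  }
  m <- ncol(X)
  if (spec$n_hidden >= m) {
    stop("n_hidden (", spec$n_hidden, ") must be below the input width (",
         m, ") for dimensionality reduction", call. = FALSE)
  }
  params <- ae_init(m, spec$n_hidden, spec$seed)
  acc_g <- lapply(params, function(p) p * 0)
  acc_x <- lapply(params, function(p) p * 0)
  trace <- numeric(spec$epochs)
  for (epoch in seq_len(spec$epochs)) {
    fb <- ae_forward_backward(params, X, spec$loss, spec$lambda)
    if (!is.finite(fb$loss)) {
      stop("autoencoder training diverged (non-finite loss at epoch ",
           epoch, ")", call. = FALSE)
    }
    trace[epoch] <- fb$loss
    for (nm in names(params)) {
      g <- fb$grads[[nm]]
      acc_g[[nm]] <- spec$rho * acc_g[[nm]] + (1 - spec$rho) * g^2
      step <- -sqrt(acc_x[[nm]] + spec$adadelta_eps) /
        sqrt(acc_g[[nm]] + spec$adadelta_eps) * g
      acc_x[[nm]] <- spec$rho * acc_x[[nm]] + (1 - spec$rho) * step^2
      params[[nm]] <- params[[nm]] + step
    }
  }
  structure(list(params = params, features = feats, spec = spec,
                 loss_trace = trace, n_hidden = spec$n_hidden, fitted = TRUE),
            class = "cc_autoencoder")
}

#' Encode features into the hidden representation
#'
#' @param ae a fitted `cc_autoencoder`.
#' @param data a `cc_cohort` or data frame containing the encoder's features.
#' @return a numeric matrix with `n_hidden` columns.
#' @export
encode <- function(ae, data) {
  stopifnot(inherits(ae, "cc_autoencoder"))
  X <- as.matrix(as.data.frame(data[ae$features]))
  Z1 <- sweep(X %*% ae$params$W1, 2, ae$params$b1, `+`)
  pmax(Z1, 0)
}

#' Autoencoder + random forest mortality model
#'
#' The main machine-learning model: an autoencoder compresses the bio-social
#' features into its hidden representation, and a random forest classifier is
#' fitted on (encoded features, outcome). Prediction encodes new rows with
#' the trained encoder and returns the forest's class-1 (death) probability.
#'
#' @param train a `cc_cohort`.
#' @param spec an [ae_spec()]; its seed also drives the encoder
#'   initialisation.
#' @param ntree number of forest trees.
#' @param seed seed for forest growth (distinct stream from the encoder).
#' @return a fitted `cc_ae_rf` model.
#' @export
fit_ae_rf <- function(train, spec = ae_spec(), ntree = 500L, seed = 1L) {
  schema <- cohort_schema(train)
  ae <- fit_autoencoder(train, spec)
  z <- encode(ae, train)
  colnames(z) <- paste0("h", seq_len(ncol(z)))
  y <- factor(train[[schema_outcome(schema)]], levels = c(0, 1))
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = z, y = y, ntree = as.integer(ntree),
    mtry = max(1L, floor(sqrt(ncol(z)))))
  structure(list(kind = "ae_rf", features = ae$features,
                 outcome = schema_outcome(schema), schema = schema,
                 interactions = list(), ae = ae, forest = forest,
                 ntree = as.integer(ntree), seed = as.integer(seed),
                 fitted = TRUE),
            class = c("cc_ae_rf", "cc_model"))
}

#' @export
predict_probability.cc_ae_rf <- function(model, data, ...) {
  check_fitted(model)
  z <- encode(model$ae, predictor_frame(model, data))
  colnames(z) <- paste0("h", seq_len(ncol(z)))
  unname(stats::predict(model$forest, newdata = z, type = "prob")[, "1"])
}
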