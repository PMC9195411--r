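# The hybrid VAE/classifier network. The architecture is an encoder
# (input -> relu hidden -> mu and log-variance heads), a Gaussian latent
# layer sampled by the reparameterisation trick during training, a decoder
# (latent -> relu hidden -> sigmoid output) and a classifier head
# (latent -> relu hidden -> softmax). The joint objective is
#   vae_weight * (reconstruction CE + vae_beta * KL) + clf_weight * CE,
# averaged over the samples of a batch. Forward and backward passes are
# written directly as dense matrix algebra; no external autodiff is used.

.EPS_CLAMP <- 1e-7

#' Model configuration
#'
#' Bundles every architecture and optimisation hyperparameter of the hybrid
#' VAE/classifier. The defaults are the full-scale settings used for the
#' 450K pan-cancer problem; tests and desk-scale runs pass smaller sizes.
#'
#' @param n_features Input width (number of cluster features; full scale
#'   24565).
#' @param hidden_size Width of the encoder/decoder relu layers (default
#'   1000).
#' @param latent_size Dimension of the Gaussian latent layer (default 100).
#' @param n_classes Number of output classes (default 34: 33 cancers +
#'   NORM).
#' @param classifier_hidden Width of the classifier relu layer (default
#'   100).
#' @param vae_beta Multiplier on the KL term inside the VAE loss; 1 for a
#'   plain VAE, > 1 for a disentangled variant.
#' @param vae_weight Weight of the VAE loss in the joint objective
#'   (default 0.01).
#' @param clf_weight Weight of the classifier cross-entropy (default 1).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param patience_epochs Early-stopping patience: training stops after
#'   this many consecutive epochs without validation-accuracy improvement
#'   (default 50).
#' @param recon_reduction How the reconstruction cross-entropy is reduced
#'   over features: `"sum"` (default) or `"mean"`. The choice rescales the
#'   effective VAE weight by `1/n_features`.
#' @param batch_size Minibatch size (default 128).
#' @param max_epochs Hard cap on training epochs guarding non-converging
#'   runs (default 2000).
#' @param seed Integer seed fixing initialisation, shuffling and latent
#'   sampling.
#' @return An object of class `model_config` (a validated list).
#' @export
model_config <- function(n_features, hidden_size = 1000L, latent_size = 100L,
                         n_classes = 34L, classifier_hidden = 100L,
                         vae_beta = 1, vae_weight = 0.01, clf_weight = 1,
                         learning_rate = 0.001, patience_epochs = 50L,
                         recon_reduction = c("sum", "mean"),
                         batch_size = 128L, max_epochs = 2000L, seed = 1L) {
  cfg <- list(
    n_features = as.integer(n_features),
    hidden_size = as.integer(hidden_size),
    latent_size = as.integer(latent_size),
    n_classes = as.integer(n_classes),
    classifier_hidden = as.integer(classifier_hidden),
    vae_beta = vae_beta, vae_weight = vae_weight, clf_weight = clf_weight,
    learning_rate = learning_rate,
    patience_epochs = as.integer(patience_epochs),
    recon_reduction = match.arg(recon_reduction),
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    seed = as.integer(seed)
  )
  sizes <- c(cfg$n_features, cfg$hidden_size, cfg$latent_size, cfg$n_classes,
             cfg$classifier_hidden, cfg$batch_size, cfg$max_epochs)
  if (any(sizes < 1)) stop("all layer and batch sizes must be >= 1")
  if (cfg$vae_beta < 0 || cfg$vae_weight < 0 || cfg$clf_weight < 0) {
    stop("loss weights and vae_beta must be non-negative")
  }
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$patience_epochs < 0) stop("patience_epochs must be >= 0")
  structure(cfg, class = "model_config")
}

.glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

#' Initialise network parameters
#'
#' Creates a freshly initialised parameter set for a configuration: weights
#' drawn from a fan-based uniform (Glorot) scheme under the configuration
#' seed, biases zero.
#'
#' @param cfg A [model_config()].
#' @return An object of class `network_state`: a named list of weight
#'   matrices and bias vectors for encoder, decoder and classifier, with
#'   the configuration attached as `$config`.
#' @export
init_network <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  state <- withr::with_seed(cfg$seed, list(
    enc_W1 = .glorot(cfg$n_features, cfg$hidden_size),
    enc_b1 = numeric(cfg$hidden_size),
    enc_Wmu = .glorot(cfg$hidden_size, cfg$latent_size),
    enc_bmu = numeric(cfg$latent_size),
    enc_Wlv = .glorot(cfg$hidden_size, cfg$latent_size),
    enc_blv = numeric(cfg$latent_size),
    dec_W1 = .glorot(cfg$latent_size, cfg$hidden_size),
    dec_b1 = numeric(cfg$hidden_size),
    dec_W2 = .glorot(cfg$hidden_size, cfg$n_features),
    dec_b2 = numeric(cfg$n_features),
    clf_W1 = .glorot(cfg$latent_size, cfg$classifier_hidden),
    clf_b1 = numeric(cfg$classifier_hidden),
    clf_W2 = .glorot(cfg$classifier_hidden, cfg$n_classes),
    clf_b2 = numeric(cfg$n_classes)
  ))
  state$config <- cfg
  class(state) <- "network_state"
  state
}

.param_names <- function() {
  c("enc_W1", "enc_b1", "enc_Wmu", "enc_bmu", "enc_Wlv", "enc_blv",
    "dec_W1", "dec_b1", "dec_W2", "dec_b2",
    "clf_W1", "clf_b1", "clf_W2", "clf_b2")
}

.as_row_matrix <- function(x, width, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != width) {
    stop(what, " has width ", ncol(x), ", expected ", width)
  }
  x
}

#' Encode samples to their latent posterior
#'
#' Runs the encoder: relu hidden layer, then the mu and log-variance
#' projection heads. Deterministic given the parameters.
#'
#' @param state A `network_state`.
#' @param x Feature vector of length `n_features`, or a samples-by-features
#'   matrix.
#' @return An object of class `latent_posterior` with matrices `mu` and
#'   `logvar` (one row per sample).
#' @export
encode <- function(state, x) {
  cfg <- state$config
  x <- .as_row_matrix(x, cfg$n_features, "input")
  if (anyNA(x) || any(!is.finite(x))) stop("encoder input must be finite")
  h <- pmax(x %*% state$enc_W1 +
              rep(state$enc_b1, each = nrow(x)), 0)
  structure(list(
    mu = h %*% state$enc_Wmu + rep(state$enc_bmu, each = nrow(x)),
    logvar = h %*% state$enc_Wlv + rep(state$enc_blv, each = nrow(x))
  ), class = "latent_posterior")
}

#' Sample the latent layer by reparameterisation
#'
#' Draws `z = mu + exp(logvar / 2) * eps` with `eps` standard normal, so
#' the draw is differentiable in the posterior parameters. Reproducible
#' under a seed.
#'
#' @param posterior A `latent_posterior` from [encode()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Matrix of latent draws, one row per sample.
#' @export
sample_latent <- function(posterior, seed = NULL) {
  draw <- function() {
    eps <- matrix(stats::rnorm(length(posterior$mu)),
                  nrow(posterior$mu), ncol(posterior$mu))
    posterior$mu + exp(posterior$logvar / 2) * eps
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Decode latent vectors to reconstructions
#'
#' Runs the decoder: relu hidden layer then a sigmoid output layer, so
#' every reconstructed value lies strictly in (0, 1).
#'
#' @param state A `network_state`.
#' @param z Latent vector of length `latent_size`, or a matrix of rows.
#' @return Matrix of reconstructions in (0, 1), one row per sample.
#' @export
decode <- function(state, z) {
  cfg <- state$config
  z <- .as_row_matrix(z, cfg$latent_size, "latent vector")
  h <- pmax(z %*% state$dec_W1 + rep(state$dec_b1, each = nrow(z)), 0)
  stats::plogis(h %*% state$dec_W2 + rep(state$dec_b2, each = nrow(z)))
}

#' Classify latent vectors
#'
#' Runs the classifier head: relu hidden layer then softmax over the class
#' vocabulary. At inference the latent input is the posterior mean (no
#' sampling), giving deterministic predictions.
#'
#' @param state A `network_state`.
#' @param z Latent vector or matrix of rows.
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
classify <- function(state, z) {
  cfg <- state$config
  z <- .as_row_matrix(z, cfg$latent_size, "latent vector")
  h <- pmax(z %*% state$clf_W1 + rep(state$clf_b1, each = nrow(z)), 0)
  .softmax(h %*% state$clf_W2 + rep(state$clf_b2, each = nrow(z)))
}

.softmax <- function(logits) {
  shifted <- logits - apply(logits, 1, max)
  e <- exp(shifted)
  e / rowSums(e)
}

#' KL divergence of a diagonal-Gaussian posterior from the standard normal
#'
#' Closed form `sum_i 0.5 * (mu_i^2 + exp(logvar_i) - 1 - logvar_i)` per
#' sample; non-negative, and zero exactly at the standard normal.
#'
#' @param posterior A `latent_posterior`, or a list with `mu` and `logvar`.
#' @return Numeric vector of per-sample KL divergences.
#' @export
kl_divergence <- function(posterior) {
  mu <- posterior$mu
  lv <- posterior$logvar
  if (is.null(dim(mu))) { mu <- matrix(mu, 1); lv <- matrix(lv, 1) }
  rowSums(0.5 * (mu^2 + exp(lv) - 1 - lv))
}

#' Reconstruction cross-entropy
#'
#' Element-wise cross-entropy between an input vector in \[0, 1\] and its
#' sigmoid reconstruction, `-sum_j [x log xhat + (1 - x) log(1 - xhat)]`,
#' reduced over features by sum (default) or mean. Reconstructions are
#' clamped away from 0/1 by 1e-7 before the logs.
#'
#' @param x Input matrix or vector, values in \[0, 1\].
#' @param xhat Reconstruction of the same shape, values in (0, 1).
#' @param reduction `"sum"` or `"mean"` over features.
#' @return Numeric vector of per-sample losses.
#' @export
reconstruction_loss <- function(x, xhat, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(dim(xhat))) xhat <- matrix(xhat, 1)
  stopifnot(all(dim(x) == dim(xhat)))
  xh <- pmin(pmax(xhat, .EPS_CLAMP), 1 - .EPS_CLAMP)
  ce <- -(x * log(xh) + (1 - x) * log(1 - xh))
  if (reduction == "sum") rowSums(ce) else rowMeans(ce)
}

#' Combine loss components into the joint objective
#'
#' `vae_weight * (recon + vae_beta * kl) + clf_weight * clf_ce` — the exact
#' decomposition logged per epoch during training.
#'
#' @param recon Reconstruction cross-entropy (scalar or vector).
#' @param kl KL divergence term.
#' @param clf_ce Classifier cross-entropy.
#' @param cfg A [model_config()] supplying the weights.
#' @return The combined loss, same shape as the inputs.
#' @export
total_loss <- function(recon, kl, clf_ce, cfg) {
  cfg$vae_weight * (recon + cfg$vae_beta * kl) + cfg$clf_weight * clf_ce
}

# Forward pass on a batch with caches for backprop. `eps` (same shape as
# mu) reparameterises the latent draw; NULL means use the posterior mean.
.forward <- function(state, X, eps = NULL) {
  cfg <- state$config
  n <- nrow(X)
  pre_e <- X %*% state$enc_W1 + rep(state$enc_b1, each = n)
  H <- pmax(pre_e, 0)
  MU <- H %*% state$enc_Wmu + rep(state$enc_bmu, each = n)
  LV <- H %*% state$enc_Wlv + rep(state$enc_blv, each = n)
  Z <- if (is.null(eps)) MU else MU + exp(LV / 2) * eps
  pre_d <- Z %*% state$dec_W1 + rep(state$dec_b1, each = n)
  Hd <- pmax(pre_d, 0)
  XH <- stats::plogis(Hd %*% state$dec_W2 + rep(state$dec_b2, each = n))
  pre_c <- Z %*% state$clf_W1 + rep(state$clf_b1, each = n)
  Hc <- pmax(pre_c, 0)
  P <- .softmax(Hc %*% state$clf_W2 + rep(state$clf_b2, each = n))
  list(pre_e = pre_e, H = H, MU = MU, LV = LV, Z = Z,
       pre_d = pre_d, Hd = Hd, XH = XH, pre_c = pre_c, Hc = Hc, P = P)
}

# Batch loss (mean over samples) and analytic gradients w.r.t. every
# parameter. Y is a one-hot matrix; eps fixes the latent draw so the loss
# is a deterministic function of the parameters (used by training steps
# and by finite-difference gradient checks alike).
.loss_and_grads <- function(state, X, Y, eps, want_grads = TRUE) {
  cfg <- state$config
  n <- nrow(X)
  fw <- .forward(state, X, eps)
  recon <- reconstruction_loss(X, fw$XH, cfg$recon_reduction)
  kl <- kl_divergence(list(mu = fw$MU, logvar = fw$LV))
  p_true <- rowSums(fw$P * Y)
  clf_ce <- -log(pmax(p_true, .EPS_CLAMP))
  loss <- mean(total_loss(recon, kl, clf_ce, cfg))
  comps <- c(loss = loss, recon = mean(recon), kl = mean(kl),
             clf_ce = mean(clf_ce))
  if (!want_grads) return(list(components = comps))

  wv <- cfg$vae_weight; wc <- cfg$clf_weight; bet <- cfg$vae_beta
  recon_scale <- if (cfg$recon_reduction == "mean") 1 / ncol(X) else 1
  g <- list()
  # decoder head: d(recon)/d(pre-sigmoid) = xhat - x
  dA <- wv * recon_scale * (fw$XH - X) / n
  g$dec_W2 <- crossprod(fw$Hd, dA)
  g$dec_b2 <- colSums(dA)
  dHd <- (dA %*% t(state$dec_W2)) * (fw$pre_d > 0)
  g$dec_W1 <- crossprod(fw$Z, dHd)
  g$dec_b1 <- colSums(dHd)
  dZ <- dHd %*% t(state$dec_W1)
  # classifier head: d(CE)/d(logits) = p - y
  dL <- wc * (fw$P - Y) / n
  g$clf_W2 <- crossprod(fw$Hc, dL)
  g$clf_b2 <- colSums(dL)
  dHc <- (dL %*% t(state$clf_W2)) * (fw$pre_c > 0)
  g$clf_W1 <- crossprod(fw$Z, dHc)
  g$clf_b1 <- colSums(dHc)
  dZ <- dZ + dHc %*% t(state$clf_W1)
  # latent: reparameterised draw + KL term
  dMU <- dZ + wv * bet * fw$MU / n
  dLV <- wv * bet * 0.5 * (exp(fw$LV) - 1) / n
  if (!is.null(eps)) dLV <- dLV + dZ * eps * 0.5 * exp(fw$LV / 2)
  g$enc_Wmu <- crossprod(fw$H, dMU)
  g$enc_bmu <- colSums(dMU)
  g$enc_Wlv <- crossprod(fw$H, dLV)
  g$enc_blv <- colSums(dLV)
  dH <- (dMU %*% t(state$enc_Wmu) + dLV %*% t(state$enc_Wlv)) *
    (fw$pre_e > 0)
  g$enc_W1 <- crossprod(X, dH)
  g$enc_b1 <- colSums(dH)
  list(components = comps, grads = g)
}

#' Save a trained network to disk
#'
#' Serialises the parameter list and its configuration with
#' [base::saveRDS()] (version 3, portable across platforms), together with
#' a schema version field.
#'
#' @param state A `network_state`.
#' @param path Output path for the checkpoint file.
#' @return `path`, invisibly.
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "network_state"))
  saveRDS(list(schema = 1L, config = unclass(state$config),
               params = state[.param_names()]),
          path, version = 3)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path Checkpoint written by [save_model()].
#' @return The restored `network_state`; round-trips every parameter
#'   bit-exactly.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema != 1L) {
    stop("unrecognised checkpoint schema: ", obj$schema)
  }
  state <- obj$params
  state$config <- structure(obj$config, class = "model_config")
  class(state) <- "network_state"
  state
}

#' @export
print.network_state <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x[.param_names()], length, numeric(1)))
  cat("Hybrid VAE/classifier network\n",
      "  features: ", cfg$n_features, ", hidden: ", cfg$hidden_size,
      ", latent: ", cfg$latent_size, ", classes: ", cfg$n_classes, "\n",
      "  parameters: ", n_par, "\n", sep = "")
  invisible(x)
}

#' Predict class labels from a feature matrix
#'
#' Inference path: encode to the posterior mean (no sampling) and apply
#' the classifier head.
#'
#' @param object A `network_state`.
#' @param features Normalised feature matrix (samples x features).
#' @param labels Optional character vector of class names, one per
#'   classifier output, used to name the prediction; defaults to
#'   `class1..classK`.
#' @param ... Unused.
#' @return List with `class` (character vector of argmax labels) and
#'   `prob` (probability matrix).
#' @export
predict.network_state <- function(object, features, labels = NULL, ...) {
  cfg <- object$config
  if (is.null(labels)) labels <- paste0("class", seq_len(cfg$n_classes))
  stopifnot(length(labels) == cfg$n_classes)
  post <- encode(object, features)
  prob <- classify(object, post$mu)
  colnames(prob) <- labels
  rownames(prob) <- rownames(features)
  list(class = labels[max.col(prob, ties.method = "first")], prob = prob)
}
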