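# Latent-space analysis: posterior-mean embeddings, 2-D projections for
# visualisation, and cross-validated linear-SVM separability in the full
# latent dimension. Separability is always measured in the full latent
# space — the 2-D projections are for plotting only, since apparent overlap
# in two dimensions says nothing about overlap in the full space.

#' Embed samples at their posterior means
#'
#' Deterministic latent representation: row s is mu(x_s) from the encoder.
#'
#' @param state A `network_state`.
#' @param features Normalised feature matrix (samples x features).
#' @return Numeric matrix (samples x latent_size) with the feature
#'   matrix's rownames.
#' @export
embed_samples <- function(state, features) {
  post <- encode(state, features)
  coords <- post$mu
  rownames(coords) <- rownames(features)
  coords
}

#' Project an embedding to two dimensions
#'
#' Reduces a latent embedding to 2-D for qualitative plots, by PCA
#' (deterministic) or t-SNE (seeded). The projection is for visualisation
#' only; quantitative separability should use [svm_separability()] on the
#' full embedding.
#'
#' @param embedding Numeric matrix, one row per sample, >= 3 rows.
#' @param method `"pca"` or `"tsne"`.
#' @param seed Integer seed (t-SNE initialisation).
#' @param perplexity t-SNE perplexity (default 30; reduced automatically
#'   when there are too few samples).
#' @param max_iter t-SNE gradient-descent iterations (default 500).
#' @return Numeric matrix (samples x 2) with rownames preserved.
#' @export
project_2d <- function(embedding, method = c("pca", "tsne"), seed = 1L,
                       perplexity = 30, max_iter = 500L) {
  method <- match.arg(method)
  if (nrow(embedding) < 3) stop("need at least 3 samples to project")
  coords <- if (method == "pca") {
    p <- stats::prcomp(embedding, center = TRUE, scale. = FALSE)
    k <- ncol(p$x)
    out <- p$x[, seq_len(min(2, k)), drop = FALSE]
    if (ncol(out) < 2) out <- cbind(out, 0)
    out
  } else {
    .tsne(embedding, seed = seed, perplexity = perplexity,
          max_iter = max_iter)
  }
  colnames(coords) <- c("dim1", "dim2")
  rownames(coords) <- rownames(embedding)
  coords
}

# Exact (dense) t-SNE, adequate for the few hundred to few thousand points
# of a test-set embedding: perplexity calibration by bisection on the
# per-point precision, early exaggeration, and momentum gradient descent.
.tsne <- function(X, seed = 1L, perplexity = 30, max_iter = 500L) {
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { p <- rep(1 / length(di), length(di)); break }
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withr::with_seed(as.integer(seed), {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    momentum <- 0.5
    eta <- 200
    for (iter in seq_len(max_iter)) {
      Pit <- if (iter <= 100) P * 12 else P  # early exaggeration
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pit - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      momentum <- if (iter < 250) 0.5 else 0.8
      inc <- momentum * inc - eta * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Linear-SVM separability of a binary label in the latent space
#'
#' Mean stratified k-fold cross-validation accuracy of a linear-kernel SVM
#' (cost 1) trained on the full latent embedding to separate two label
#' values. High accuracy demonstrates that the two groups occupy
#' non-overlapping regions of the latent space even when a 2-D projection
#' suggests otherwise.
#'
#' @param embedding Numeric matrix, one row per sample.
#' @param labels Binary label vector (two distinct values), one per row.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Mean cross-validated accuracy in \[0, 1\].
#' @export
svm_separability <- function(embedding, labels, folds = 10L, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(nrow(embedding) == length(labels))
  counts <- table(labels)
  if (length(counts) != 2) {
    stop("separability needs exactly two label values; got ",
         length(counts))
  }
  if (any(counts < folds)) {
    stop("label '", names(counts)[which.min(counts)], "' has ",
         min(counts), " members, fewer than ", folds,
         " folds; use a smaller k")
  }
  fold_id <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (lv in names(counts)) {
      idx <- which(labels == lv)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  y <- factor(labels)
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fold_id != k
    fit <- e1071::svm(x = embedding[tr, , drop = FALSE], y = y[tr],
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- stats::predict(fit, embedding[!tr, , drop = FALSE])
    mean(pred == y[!tr])
  }, numeric(1))
  mean(acc)
}
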