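test_that("an all-zero encoder maps everything to the standard-normal posterior", {
  state <- toy_state(fill = 0)
  post <- encode(state, c(0.3, 0.9))
  expect_equal(unname(post$mu[1, ]), c(0, 0))
  expect_equal(unname(post$logvar[1, ]), c(0, 0))
})

test_that("encoding is deterministic and matches a hand-computed toy", {
  state <- toy_state(n_features = 1, hidden = 1, latent = 1, classes = 2,
                     clf_hidden = 1, fill = NULL)
  state$enc_W1[] <- 2; state$enc_b1[] <- 0.5
  state$enc_Wmu[] <- 3; state$enc_bmu[] <- -1
  state$enc_Wlv[] <- 0.5; state$enc_blv[] <- 0.2
  post <- encode(state, 0.4)
  # affine -> relu -> affine: h = relu(0.4*2 + 0.5) = 1.3
  expect_equal(post$mu[1, 1], 1.3 * 3 - 1)
  expect_equal(post$logvar[1, 1], 1.3 * 0.5 + 0.2)
  expect_identical(encode(state, 0.4), post)
  expect_error(encode(state, c(0.1, 0.2)), "width")
})

test_that("latent sampling reparameterises correctly", {
  post <- structure(list(mu = matrix(c(2, -1), 1),
                         logvar = matrix(c(-60, -60), 1)),
                    class = "latent_posterior")
  # variance ~ 0 collapses the draw onto mu
  expect_equal(unname(sample_latent(post, seed = 5)[1, ]), c(2, -1),
               tolerance = 1e-8)

  std <- structure(list(mu = matrix(0, 10000, 1),
                        logvar = matrix(0, 10000, 1)),
                   class = "latent_posterior")
  z <- sample_latent(std, seed = 6)
  expect_lt(abs(mean(z)), 3 / sqrt(10000))            # 3 SE of the mean
  expect_lt(abs(var(as.vector(z)) - 1), 3 * sqrt(2 / 10000))
  expect_identical(sample_latent(std, seed = 7), sample_latent(std, seed = 7))
})

test_that("an all-zero decoder outputs 0.5 and any decoder stays in (0,1)", {
  state <- toy_state(fill = 0)
  expect_equal(unname(decode(state, c(0, 0))[1, ]), c(0.5, 0.5))
  rnd <- toy_state(fill = NULL, seed = 9)
  out <- decode(rnd, matrix(rnorm(10 * 2), 10, 2))
  expect_true(all(out > 0 & out < 1))
})

test_that("decoding matches a hand-computed sigmoid(affine(relu(affine)))", {
  state <- toy_state(n_features = 2, hidden = 1, latent = 1, classes = 2,
                     clf_hidden = 1, fill = NULL)
  state$dec_W1[] <- 1.5; state$dec_b1[] <- -0.2
  state$dec_W2[] <- c(0.5, -1); state$dec_b2[] <- c(0.1, 0.3)
  out <- decode(state, 0.8)
  h <- max(0.8 * 1.5 - 0.2, 0)
  expect_equal(unname(out[1, ]),
               c(plogis(h * 0.5 + 0.1), plogis(h * -1 + 0.3)))
})

test_that("the classifier head is a softmax over the class logits", {
  state <- toy_state(fill = 0)          # 4 classes
  expect_equal(unname(classify(state, c(0, 0))[1, ]), rep(0.25, 4))

  two <- toy_state(classes = 2, fill = 0)
  two$clf_b2[] <- c(1, 0)
  p <- classify(two, c(0.3, -0.7))
  expect_equal(unname(p[1, ]), c(exp(1), 1) / (exp(1) + 1))

  rnd <- toy_state(fill = NULL, seed = 10)
  probs <- classify(rnd, matrix(rnorm(40), 20, 2))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-6)
})

test_that("KL divergence matches its closed form and a Monte-Carlo estimate", {
  expect_equal(kl_divergence(list(mu = 0, logvar = 0)), 0)
  expect_equal(kl_divergence(list(mu = 1, logvar = 0)), 0.5)
  mu <- c(1, -0.5); lv <- c(0.3, -0.2)
  closed <- kl_divergence(list(mu = mu, logvar = lv))
  expect_true(closed > 0)
  # MC oracle: E_q[log q(z) - log p(z)] over 1e6 draws
  set.seed(81)
  n <- 1e6
  z <- cbind(rnorm(n, mu[1], exp(lv[1] / 2)), rnorm(n, mu[2], exp(lv[2] / 2)))
  logq <- dnorm(z[, 1], mu[1], exp(lv[1] / 2), log = TRUE) +
    dnorm(z[, 2], mu[2], exp(lv[2] / 2), log = TRUE)
  logp <- dnorm(z[, 1], log = TRUE) + dnorm(z[, 2], log = TRUE)
  mc <- mean(logq - logp)
  expect_lt(abs(mc - closed) / closed, 0.01)
})

test_that("KL divergence is non-negative, zero only at the standard normal", {
  set.seed(91)
  for (i in 1:50) {
    mu <- rnorm(4); lv <- rnorm(4, sd = 0.7)
    expect_gte(kl_divergence(list(mu = mu, logvar = lv)), 0)
  }
  expect_gt(kl_divergence(list(mu = c(0, 0), logvar = c(0, 1e-3))), 0)
})

test_that("reconstruction cross-entropy matches closed forms and is minimised at x", {
  expect_equal(reconstruction_loss(c(0.5, 0.5), c(0.5, 0.5)), 2 * log(2))
  expect_equal(reconstruction_loss(1, 0.5), log(2))
  set.seed(101)
  x <- runif(6)
  at_x <- reconstruction_loss(x, x)
  for (i in 1:20) {
    other <- pmin(pmax(x + rnorm(6, sd = 0.1), 0.01), 0.99)
    expect_gte(reconstruction_loss(x, other), at_x)
  }
  # clamp keeps exact 0/1 reconstructions finite
  expect_true(is.finite(reconstruction_loss(c(0, 1), c(1, 0))))
})

test_that("the joint loss combines components with the configured weights", {
  cfg <- model_config(n_features = 2, vae_beta = 1, vae_weight = 0.01,
                      clf_weight = 1)
  expect_equal(total_loss(10, 2, 1, cfg), 0.01 * 12 + 1)
  cfg0 <- model_config(n_features = 2, vae_weight = 0)
  expect_equal(total_loss(10, 2, 1.7, cfg0), 1.7)
  cfgc <- model_config(n_features = 2, clf_weight = 0)
  expect_equal(total_loss(10, 2, 1.7, cfgc), 0.01 * 12)
})

test_that("analytic gradients match central finite differences on a toy network", {
  cfg <- model_config(n_features = 6, hidden_size = 4, latent_size = 2,
                      n_classes = 3, classifier_hidden = 3, seed = 111)
  state <- init_network(cfg)
  set.seed(112)
  X <- matrix(runif(5 * 6, 0.1, 0.9), 5, 6)
  Y <- methylnet:::.one_hot(sample.int(3, 5, replace = TRUE), 3)
  eps <- matrix(rnorm(5 * 2), 5, 2)
  analytic <- methylnet:::.loss_and_grads(state, X, Y, eps)$grads
  worst <- 0
  for (nm in methylnet:::.param_names()) {
    num <- numeric_grad(state, X, Y, eps, nm)
    rel <- abs(analytic[[nm]] - num) /
      pmax(abs(analytic[[nm]]) + abs(num), 1e-6)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-4)
})

test_that("checkpoints round-trip the network bit-exactly", {
  state <- toy_state(fill = NULL, seed = 121)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(state, path)
  back <- load_model(path)
  for (nm in methylnet:::.param_names()) {
    expect_identical(back[[nm]], state[[nm]])
  }
  x <- matrix(runif(2), 1, 2)
  expect_identical(encode(back, x), encode(state, x))
  expect_identical(decode(back, c(0.1, -0.2)), decode(state, c(0.1, -0.2)))
})
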