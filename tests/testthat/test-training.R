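fake_meta <- function(n, classes = c("BRCA", "COAD"),
                      patients = NULL) {
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    patient_id = patients %||% sprintf("p%03d", seq_len(n)),
    class_label = rep_len(classes, n),
    sample_type = "primary",
    stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("splits have rounded 80/10/10 sizes and are seed-reproducible", {
  meta <- fake_meta(10, classes = "BRCA")
  sp <- make_split(meta, seed = 1)
  expect_length(sp$train_ids, 8)
  expect_length(sp$val_ids, 1)
  expect_length(sp$test_ids, 1)
  expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), meta$sample_id)
  expect_identical(make_split(meta, seed = 1), sp)
  expect_false(identical(make_split(meta, seed = 2)$train_ids, sp$train_ids))
})

test_that("split fractions hold within a sample per class on 1000 samples", {
  meta <- fake_meta(1000, classes = c("BRCA", "COAD", "NORM", "LUAD"))
  sp <- make_split(meta, seed = 3)
  expect_equal(length(sp$val_ids), 100, tolerance = 0)
  expect_equal(length(sp$test_ids), 100, tolerance = 0)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_length(intersect(sp$val_ids, sp$test_ids), 0)
  # stratification keeps every class in every partition
  cls <- function(ids) table(meta$class_label[match(ids, meta$sample_id)])
  expect_true(all(cls(sp$val_ids) == 25))
  expect_true(all(cls(sp$test_ids) == 25))
})

test_that("splitting refuses metastatic samples and warns on empty classes", {
  meta <- fake_meta(10)
  meta$sample_type[1] <- "metastatic"
  expect_error(make_split(meta), "evaluation-only")
  meta2 <- fake_meta(10)
  meta2$class_label <- factor(meta2$class_label,
                              levels = c("BRCA", "COAD", "UVM"))
  expect_warning(make_split(meta2, seed = 1), "UVM")
})

test_that("patient deduplication removes matched pairs from training", {
  meta <- fake_meta(6, classes = "BRCA",
                    patients = c("p1", "p1", "p2", "p3", "p4", "p5"))
  split <- structure(list(train_ids = c("s001", "s002", "s003", "s004"),
                          val_ids = "s005", test_ids = "s006", seed = 1L),
                     class = "dataset_split")
  out <- deduplicate_patients(split, meta, seed = 2)
  pats <- meta$patient_id[match(out$train_ids, meta$sample_id)]
  expect_false(anyDuplicated(pats) > 0)
  expect_equal(out$val_ids, "s005")
  expect_equal(out$test_ids, "s006")
})

test_that("deduplication is a no-op without duplicate patients", {
  meta <- fake_meta(5, classes = "BRCA")
  split <- make_split(meta, seed = 4)
  out <- deduplicate_patients(split, meta, seed = 4)
  expect_setequal(out$train_ids, split$train_ids)
})

test_that("a removed sample is replaced by the unique same-class candidate", {
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5"),
    patient_id = c("pA", "pA", "pB", "pC", "pD"),
    class_label = c("BRCA", "BRCA", "BRCA", "BRCA", "COAD"),
    sample_type = "primary", stringsAsFactors = FALSE)
  # s4 is the only unassigned BRCA sample; s5 is the wrong class
  split <- structure(list(train_ids = c("s1", "s2"), val_ids = "s3",
                          test_ids = character(), seed = 1L),
                     class = "dataset_split")
  out <- deduplicate_patients(split, meta, seed = 5)
  expect_length(out$train_ids, 2)
  expect_true("s4" %in% out$train_ids)
  expect_true(sum(c("s1", "s2") %in% out$train_ids) == 1)
})

test_that("unfillable slots stay unfilled rather than reusing assigned samples", {
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    patient_id = c("pA", "pA", "pB"),
    class_label = "BRCA", sample_type = "primary",
    stringsAsFactors = FALSE)
  split <- structure(list(train_ids = c("s1", "s2"), val_ids = "s3",
                          test_ids = character(), seed = 1L),
                     class = "dataset_split")
  out <- deduplicate_patients(split, meta, seed = 6)
  expect_length(out$train_ids, 1)
})

separable_toy <- function(seed = 131) {
  # 3 well-separated Gaussian classes in 20 features
  withr::with_seed(seed, {
    centers <- matrix(c(0.2, 0.8, 0.5), 3, 20)
    centers[1, 1:7] <- 0.9; centers[2, 8:14] <- 0.9; centers[3, 15:20] <- 0.9
    X <- do.call(rbind, lapply(1:3, function(k) {
      matrix(pmin(pmax(rnorm(50 * 20, centers[k, ], 0.05), 0), 1),
             50, 20, byrow = TRUE)
    }))
    rownames(X) <- sprintf("s%03d", 1:150)
    y <- rep(c("A", "B", "C"), each = 50)
    idx <- sample(150)
    list(X = X[idx, ], y = y[idx])
  })
}

test_that("training solves a linearly separable toy and logs a consistent history", {
  toy <- separable_toy()
  tr <- 1:120; va <- 121:150
  cfg <- model_config(n_features = 20, hidden_size = 16, latent_size = 4,
                      n_classes = 3, classifier_hidden = 8,
                      patience_epochs = 50, batch_size = 32, seed = 132)
  fit <- train_model(cfg, toy$X[tr, ], toy$y[tr], toy$X[va, ], toy$y[va])
  expect_equal(max(fit$history$val_acc), 1.0)
  # per-epoch loss decomposes exactly as w_v*(recon + beta*kl) + w_c*ce
  h <- fit$history
  expect_equal(h$loss, 0.01 * (h$recon + 1 * h$kl) + 1 * h$clf_ce,
               tolerance = 1e-12)
  expect_true(all(is.finite(h$loss)))
  # returned parameters are the best-validation-epoch parameters
  pred <- predict(fit$state, toy$X[va, ], labels = fit$class_levels)
  expect_equal(mean(pred$class == toy$y[va]), max(h$val_acc))
})

test_that("early stopping obeys its patience and degenerate patience stops immediately", {
  toy <- separable_toy(seed = 141)
  tr <- 1:120; va <- 121:150
  cfg <- model_config(n_features = 20, hidden_size = 16, latent_size = 4,
                      n_classes = 3, classifier_hidden = 8,
                      patience_epochs = 5, batch_size = 32, seed = 142)
  fit <- train_model(cfg, toy$X[tr, ], toy$y[tr], toy$X[va, ], toy$y[va])
  expect_lte(fit$stopped_epoch - fit$best_epoch, 5)

  cfg0 <- model_config(n_features = 20, hidden_size = 16, latent_size = 4,
                       n_classes = 3, classifier_hidden = 8,
                       patience_epochs = 0, batch_size = 32, seed = 142)
  fit0 <- train_model(cfg0, toy$X[tr, ], toy$y[tr], toy$X[va, ], toy$y[va])
  # stops after the first non-improving epoch
  expect_lte(fit0$stopped_epoch - fit0$best_epoch, 1)
})

test_that("training is bit-reproducible from the same data and seed", {
  toy <- separable_toy(seed = 151)
  tr <- 1:100; va <- 101:150
  cfg <- model_config(n_features = 20, hidden_size = 8, latent_size = 4,
                      n_classes = 3, classifier_hidden = 4,
                      patience_epochs = 3, batch_size = 32, seed = 152)
  a <- train_model(cfg, toy$X[tr, ], toy$y[tr], toy$X[va, ], toy$y[va])
  b <- train_model(cfg, toy$X[tr, ], toy$y[tr], toy$X[va, ], toy$y[va])
  expect_identical(a$history, b$history)
  expect_identical(a$state[methylnet:::.param_names()],
                   b$state[methylnet:::.param_names()])
})
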