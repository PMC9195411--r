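# Dataset splitting with patient deduplication and the minibatch Adam
# training loop with early stopping on validation accuracy.

#' Keep samples eligible for training splits
#'
#' Metastatic and recurrent samples are evaluation-only; this drops them,
#' keeping primary tumours and normal tissue.
#'
#' @param metadata Metadata data frame.
#' @return The eligible subset of `metadata`.
#' @export
filter_eligible <- function(metadata) {
  metadata[metadata$sample_type %in% c("primary", "normal_tissue"), ,
           drop = FALSE]
}

#' Split samples into train/validation/test sets
#'
#' Random 80/10/10 split (by default), reproducible under a seed. With
#' `stratify = TRUE` (default) the split is drawn per class so rare classes
#' stay represented in the validation and test slices; `stratify = FALSE`
#' gives a plain random split. Validation and test sizes are rounded
#' shares; training takes the remainder.
#'
#' @param metadata Eligible metadata (no metastatic/recurrent rows; see
#'   [filter_eligible()]).
#' @param fractions Numeric triple (train, val, test) summing to 1.
#' @param seed Integer seed.
#' @param stratify Stratify by `class_label` (default TRUE).
#' @return An object of class `dataset_split`: list with character vectors
#'   `train_ids`, `val_ids`, `test_ids` (pairwise disjoint, union = all
#'   samples) and the `seed`.
#' @export
make_split <- function(metadata, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                       stratify = TRUE) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  if (any(metadata$sample_type %in% c("metastatic", "recurrent"))) {
    stop("metastatic/recurrent samples are evaluation-only; ",
         "filter them out (filter_eligible) before splitting")
  }
  labels <- metadata$class_label
  if (is.factor(labels)) {
    empty <- setdiff(levels(labels), unique(as.character(labels)))
    if (length(empty) > 0) {
      warning("class(es) with 0 samples: ", paste(empty, collapse = ", "))
    }
    labels <- as.character(labels)
  }
  allocate <- function(ids) {
    n <- length(ids)
    n_val <- round(fractions[2] * n)
    n_test <- round(fractions[3] * n)
    ids <- sample(ids)
    list(val = ids[seq_len(n_val)],
         test = ids[n_val + seq_len(n_test)],
         train = ids[-seq_len(n_val + n_test)])
  }
  parts <- withr::with_seed(as.integer(seed), {
    if (stratify) {
      by_class <- split(metadata$sample_id, labels)
      allocs <- lapply(by_class, allocate)
      list(val = unlist(lapply(allocs, `[[`, "val"), use.names = FALSE),
           test = unlist(lapply(allocs, `[[`, "test"), use.names = FALSE),
           train = unlist(lapply(allocs, `[[`, "train"), use.names = FALSE))
    } else {
      allocate(metadata$sample_id)
    }
  })
  structure(list(train_ids = parts$train, val_ids = parts$val,
                 test_ids = parts$test, seed = as.integer(seed)),
            class = "dataset_split")
}

#' Enforce one training sample per patient
#'
#' Whenever a patient contributes more than one sample to the training set
#' (e.g. tumour/normal matched pairs), one is kept at random and each
#' removed sample is replaced by a uniformly drawn unused sample of the
#' same class — a sample not currently assigned to any split whose patient
#' is not already in training. When no such candidate exists the slot is
#' left unfilled. Validation and test sets are untouched.
#'
#' @param split A `dataset_split`.
#' @param metadata Metadata covering every sample id in the split.
#' @param seed Integer seed for the keep/replace draws.
#' @return A `dataset_split` whose training set has no repeated
#'   `patient_id`.
#' @export
deduplicate_patients <- function(split, metadata, seed = 1L) {
  meta <- metadata[match(split$train_ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("training sample(s) missing from metadata: ",
         paste(split$train_ids[is.na(meta$sample_id)], collapse = ", "))
  }
  withr::with_seed(as.integer(seed), {
    train <- split$train_ids
    by_patient <- split(train, meta$patient_id[match(train, meta$sample_id)])
    removed <- character()
    for (ids in by_patient) {
      if (length(ids) > 1) {
        keep <- sample(ids, 1)
        removed <- c(removed, setdiff(ids, keep))
      }
    }
    train <- setdiff(train, removed)
    assigned <- c(train, split$val_ids, split$test_ids, removed)
    pool <- metadata[!(metadata$sample_id %in% assigned), , drop = FALSE]
    for (rid in removed) {
      cls <- metadata$class_label[match(rid, metadata$sample_id)]
      train_patients <- metadata$patient_id[
        match(train, metadata$sample_id)]
      cand <- pool$sample_id[pool$class_label == cls &
                               !(pool$patient_id %in% train_patients)]
      if (length(cand) > 0) {
        pick <- if (length(cand) == 1) cand else sample(cand, 1)
        train <- c(train, pick)
        pool <- pool[pool$sample_id != pick, , drop = FALSE]
      }
    }
    structure(list(train_ids = train, val_ids = split$val_ids,
                   test_ids = split$test_ids, seed = split$seed),
              class = "dataset_split")
  })
}

.one_hot <- function(y, n_classes) {
  stopifnot(all(y >= 1), all(y <= n_classes))
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

# Coerce labels to integer codes 1..n_classes against an explicit class
# order (factor levels win if present).
.label_codes <- function(labels, class_levels) {
  if (is.factor(labels)) labels <- as.character(labels)
  codes <- match(labels, class_levels)
  if (anyNA(codes)) {
    stop("label(s) outside the class set: ",
         paste(unique(labels[is.na(codes)]), collapse = ", "))
  }
  codes
}

#' Train the hybrid VAE/classifier
#'
#' Minibatch Adam on the joint objective
#' `vae_weight * (recon + vae_beta * KL) + clf_weight * CE`, with early
#' stopping on validation accuracy: training stops once the accuracy has
#' not improved for `patience_epochs` consecutive epochs (ties broken by
#' the earliest epoch), or at `max_epochs`. The returned parameters are
#' those of the best validation epoch. The whole run — initialisation,
#' shuffling, latent sampling — is a deterministic function of the data
#' and `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @param train_x,val_x Normalised feature matrices (samples x features).
#' @param train_y,val_y Class labels: factors, or characters matched
#'   against `class_levels`.
#' @param class_levels Character vector giving class order for the
#'   classifier outputs; defaults to the factor levels of `train_y` or the
#'   sorted unique labels.
#' @param verbose Print one line per epoch to stderr (default FALSE).
#' @return List with `state` (the best-epoch `network_state`), `history`
#'   (data frame: epoch, loss, recon, kl, clf_ce, val_acc), `best_epoch`,
#'   `stopped_epoch` and `class_levels`.
#' @export
train_model <- function(cfg, train_x, train_y, val_x, val_y,
                        class_levels = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "model_config"))
  if (is.null(class_levels)) {
    class_levels <- if (is.factor(train_y)) levels(train_y) else
      sort(unique(as.character(train_y)))
  }
  if (length(class_levels) != cfg$n_classes) {
    stop("cfg$n_classes (", cfg$n_classes, ") does not match the ",
         length(class_levels), " class levels")
  }
  if (ncol(train_x) != cfg$n_features) {
    stop("cfg$n_features (", cfg$n_features, ") does not match feature ",
         "matrix width (", ncol(train_x), ")")
  }
  y_tr <- .label_codes(train_y, class_levels)
  y_val <- .label_codes(val_y, class_levels)
  Y_tr <- .one_hot(y_tr, cfg$n_classes)

  state <- init_network(cfg)
  adam <- .adam_init(state)
  n <- nrow(train_x)
  history <- vector("list", cfg$max_epochs)
  best_acc <- -Inf
  best_epoch <- 0L
  best_params <- state[.param_names()]
  since_best <- 0L
  stopped_epoch <- 0L

  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      comp_sum <- c(loss = 0, recon = 0, kl = 0, clf_ce = 0)
      n_seen <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        X <- train_x[idx, , drop = FALSE]
        Y <- Y_tr[idx, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(idx) * cfg$latent_size),
                      length(idx), cfg$latent_size)
        lg <- .loss_and_grads(state, X, Y, eps)
        if (!all(is.finite(lg$components))) {
          stop("non-finite loss at epoch ", epoch, ", batch starting at ",
               s, "; components: ",
               paste(names(lg$components), signif(lg$components, 4),
                     sep = "=", collapse = ", "))
        }
        adam <- .adam_step(adam, state, lg$grads, cfg$learning_rate)
        state <- adam$state
        comp_sum <- comp_sum + lg$components * length(idx)
        n_seen <- n_seen + length(idx)
      }
      comps <- comp_sum / n_seen
      val_pred <- predict(state, val_x, labels = class_levels)
      val_acc <- mean(.label_codes(val_pred$class, class_levels) == y_val)
      history[[epoch]] <- data.frame(
        epoch = epoch, loss = comps[["loss"]], recon = comps[["recon"]],
        kl = comps[["kl"]], clf_ce = comps[["clf_ce"]], val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %d  loss %.4f  val_acc %.4f",
                        epoch, comps[["loss"]], val_acc))
      }
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_epoch <- epoch
        best_params <- state[.param_names()]
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= max(cfg$patience_epochs, 1L)) {
          stopped_epoch <- epoch
          break
        }
      }
      stopped_epoch <- epoch
    }
  })
  state[.param_names()] <- best_params
  list(state = state,
       history = do.call(rbind, history[!vapply(history, is.null,
                                                logical(1))]),
       best_epoch = best_epoch, stopped_epoch = stopped_epoch,
       class_levels = class_levels)
}

.adam_init <- function(state) {
  zeros <- lapply(state[.param_names()], function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  list(state = state, m = zeros, v = zeros, t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

.adam_step <- function(adam, state, grads, lr) {
  adam$t <- adam$t + 1L
  bc1 <- 1 - adam$beta1^adam$t
  bc2 <- 1 - adam$beta2^adam$t
  for (nm in .param_names()) {
    g <- grads[[nm]]
    adam$m[[nm]] <- adam$beta1 * adam$m[[nm]] + (1 - adam$beta1) * g
    adam$v[[nm]] <- adam$beta2 * adam$v[[nm]] + (1 - adam$beta2) * g^2
    state[[nm]] <- state[[nm]] -
      lr * (adam$m[[nm]] / bc1) / (sqrt(adam$v[[nm]] / bc2) + adam$eps)
  }
  adam$state <- state
  adam
}
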