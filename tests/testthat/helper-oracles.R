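# Independent brute-force oracles and tiny fixture builders shared across
# test files. The oracles deliberately use naive algorithms, not the
# package's own code paths.

# O(n^2) transitive-closure clustering oracle: probes i, j are linked when
# they share a chromosome and |pos_i - pos_j| <= max_gap; clusters are the
# connected components of that relation, computed by label propagation.
oracle_cluster <- function(probes, max_gap = 100) {
  n <- nrow(probes)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (probes$chrom[i] == probes$chrom[j] &&
            abs(probes$pos[i] - probes$pos[j]) <= max_gap &&
            comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # canonical form: sorted probe ids per component, components sorted
  groups <- split(probes$probe_id[order(probes$pos)], comp[order(probes$pos)])
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}

# canonical form of cluster_probes() output for comparison with the oracle
canonical_clusters <- function(clusters) {
  groups <- lapply(clusters$probe_ids, as.character)
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}

random_manifest <- function(n_probes, n_chrom = 3, max_pos = 3000) {
  data.frame(
    probe_id = sprintf("cg%05d", seq_len(n_probes)),
    chrom = paste0("chr", sample.int(n_chrom, n_probes, replace = TRUE)),
    pos = sample.int(max_pos, n_probes),
    in_island = TRUE,
    stringsAsFactors = FALSE
  )
}

# naive per-cell double loop for cluster beta averaging
oracle_average <- function(beta, clusters) {
  out <- matrix(NA_real_, nrow(beta), nrow(clusters),
                dimnames = list(rownames(beta), clusters$cluster_id))
  for (s in seq_len(nrow(beta))) {
    for (k in seq_len(nrow(clusters))) {
      v <- beta[s, clusters$probe_ids[[k]]]
      v <- v[!is.na(v)]
      if (length(v) > 0) out[s, k] <- sum(v) / length(v)
    }
  }
  out
}

# tiny network with every parameter set to a constant (default zero)
toy_state <- function(n_features = 2, hidden = 3, latent = 2, classes = 4,
                      clf_hidden = 3, fill = 0, seed = 1) {
  cfg <- model_config(n_features = n_features, hidden_size = hidden,
                      latent_size = latent, n_classes = classes,
                      classifier_hidden = clf_hidden, seed = seed)
  state <- init_network(cfg)
  if (!is.null(fill)) {
    for (nm in methylnet:::.param_names()) {
      state[[nm]][] <- fill
    }
  }
  state
}

# central finite-difference gradient of the batch loss for one parameter
numeric_grad <- function(state, X, Y, eps_mat, name, h = 1e-5) {
  p <- state[[name]]
  g <- p
  for (i in seq_along(p)) {
    sp <- state; sp[[name]][i] <- p[i] + h
    up <- methylnet:::.loss_and_grads(sp, X, Y, eps_mat,
                                      want_grads = FALSE)$components[["loss"]]
    sm <- state; sm[[name]][i] <- p[i] - h
    dn <- methylnet:::.loss_and_grads(sm, X, Y, eps_mat,
                                      want_grads = FALSE)$components[["loss"]]
    g[i] <- (up - dn) / (2 * h)
  }
  g
}

# shared small trained model for the slower integration tests; built once
# per test run on first use
.test_cache <- new.env(parent = emptyenv())

trained_toy_run <- function() {
  if (is.null(.test_cache$run)) {
    spec <- synthetic_spec(n_classes = 4, samples_per_class = 40,
                           n_islands = 80, seed = 400)
    cohort <- generate_cohort(spec)
    fb <- build_features(cohort$manifest, cohort$beta)
    meta <- filter_eligible(cohort$metadata)
    split <- deduplicate_patients(make_split(meta, seed = 401), meta,
                                  seed = 401)
    cfg <- model_config(n_features = ncol(fb$features), hidden_size = 32,
                        latent_size = 8, n_classes = 4,
                        classifier_hidden = 8, patience_epochs = 20,
                        seed = 402)
    levels <- sort(unique(meta$class_label))
    lab <- function(ids) meta$class_label[match(ids, meta$sample_id)]
    fit <- train_model(cfg, fb$features[split$train_ids, ],
                       lab(split$train_ids),
                       fb$features[split$val_ids, ], lab(split$val_ids),
                       class_levels = levels)
    .test_cache$run <- list(spec = spec, cohort = cohort, fb = fb,
                            meta = meta, split = split, cfg = cfg,
                            levels = levels, lab = lab, fit = fit)
  }
  .test_cache$run
}
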