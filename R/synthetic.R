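# Synthetic-data generator: probe manifests with known island structure,
# cohorts with class-specific methylation signatures (beta values drawn
# from bimodal high/low Beta distributions), patient-matched sample pairs,
# and metastasis-like / age-drift variants. Everything is a deterministic
# function of the spec seed, and the expected cluster decomposition of a
# generated manifest is known by construction.

#' Specification of a synthetic methylation corpus
#'
#' Fixes every parameter of the generator. Defaults give the desk-scale
#' study corpus used throughout the package's tests: 8 classes (7 cancer
#' codes + NORM) of 100 samples over 400 CpG islands, with disjoint
#' class signatures covering 10% of islands per class, high/low beta modes
#' centred near 0.8 and 0.15, a 5-percentage-point age-drift shift and
#' mild metastasis-like dispersion.
#'
#' @param n_classes Number of classes including NORM (default 8).
#' @param samples_per_class Samples per class (default 100).
#' @param n_islands Number of CpG islands (default 400); each island
#'   becomes one cluster feature.
#' @param probes_per_island Integer range `c(min, max)` of probes per
#'   island (default 4..8, so no island is eliminated by the size filter).
#' @param nonisland_fraction Non-island probes added as a fraction of the
#'   island probe count, to exercise the island filter (default 0.2).
#' @param signature_fraction Fraction of islands carrying each class's
#'   signature (default 0.1). Zero gives exchangeable classes (no signal).
#' @param signature_mode `"disjoint"` (classes own non-overlapping island
#'   sets) or `"random"` (independent draws, overlaps allowed).
#' @param high_shape,low_shape `c(a, b)` shape parameters of the Beta
#'   distributions for the hypermethylated (mean 0.8) and hypomethylated
#'   (mean 0.15) modes.
#' @param drift_shift Global hypomethylation offset for age-drift variants
#'   (default 0.05).
#' @param metastasis_noise Extra Gaussian dispersion (sd) for
#'   metastasis-like variants (default 0.05).
#' @param paired_fraction Fraction of each class's samples contributed as
#'   a second sample of an existing patient (default 0.1), to exercise
#'   patient deduplication.
#' @param seed Integer seed fixing the whole corpus.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 8L, samples_per_class = 100L,
                           n_islands = 400L, probes_per_island = c(4L, 8L),
                           nonisland_fraction = 0.2,
                           signature_fraction = 0.1,
                           signature_mode = c("disjoint", "random"),
                           high_shape = c(8, 2), low_shape = c(1.5, 8.5),
                           drift_shift = 0.05, metastasis_noise = 0.05,
                           paired_fraction = 0.1, seed = 1L) {
  spec <- list(
    n_classes = as.integer(n_classes),
    samples_per_class = as.integer(samples_per_class),
    n_islands = as.integer(n_islands),
    probes_per_island = as.integer(probes_per_island),
    nonisland_fraction = nonisland_fraction,
    signature_fraction = signature_fraction,
    signature_mode = match.arg(signature_mode),
    high_shape = high_shape, low_shape = low_shape,
    drift_shift = drift_shift, metastasis_noise = metastasis_noise,
    paired_fraction = paired_fraction,
    seed = as.integer(seed)
  )
  stopifnot(spec$n_classes >= 2, spec$n_classes <= 34,
            spec$samples_per_class >= 1, spec$n_islands >= 1,
            length(spec$probes_per_island) == 2,
            spec$probes_per_island[1] >= 1,
            spec$probes_per_island[1] <= spec$probes_per_island[2])
  if (spec$signature_fraction < 0 || spec$signature_fraction > 1 ||
      spec$nonisland_fraction < 0 || spec$paired_fraction < 0 ||
      spec$paired_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (any(c(spec$high_shape, spec$low_shape) <= 0)) {
    stop("Beta-distribution shape parameters must be positive")
  }
  if (spec$signature_mode == "disjoint" &&
      spec$n_classes * floor(spec$signature_fraction * spec$n_islands) >
        spec$n_islands) {
    stop("disjoint signatures need n_classes * signature islands <= ",
         "n_islands")
  }
  structure(spec, class = "synthetic_spec")
}

# Class labels for a spec: the first (n_classes - 1) TCGA codes, then NORM.
synthetic_classes <- function(spec) {
  vocab <- class_vocabulary()
  c(vocab[seq_len(spec$n_classes - 1)], "NORM")
}

#' Generate a probe manifest with known island structure
#'
#' Islands are laid out on chromosomes chr1..chr22 with within-island probe
#' gaps of 20-80 bp (at most 100, so an island chains into exactly one
#' cluster) and between-island gaps of 10 kb (well over 100 bp, so islands
#' never merge). Non-island probes are placed on a distant region of each
#' chromosome to exercise the island filter. The expected cluster
#' decomposition — one cluster per island with all its probes — is
#' therefore known by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return Manifest data frame (`probe_id`, `chrom`, `pos`, `in_island`)
#'   with an `island_of` attribute mapping island probe ids to island
#'   index.
#' @export
generate_manifest <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    chroms <- paste0("chr", (seq_len(spec$n_islands) - 1) %% 22 + 1)
    sizes <- seq(spec$probes_per_island[1], spec$probes_per_island[2])
    n_probes <- sizes[sample.int(length(sizes), spec$n_islands,
                                 replace = TRUE)]
    cursor <- stats::setNames(rep(1000L, 22), paste0("chr", 1:22))
    rows <- vector("list", spec$n_islands)
    island_of <- character()
    for (i in seq_len(spec$n_islands)) {
      ch <- chroms[i]
      gaps <- sample(20:80, n_probes[i], replace = TRUE)
      pos <- cursor[ch] + cumsum(gaps)
      cursor[ch] <- pos[length(pos)] + 10000L
      ids <- sprintf("cg_isl%04d_%02d", i, seq_len(n_probes[i]))
      rows[[i]] <- data.frame(probe_id = ids, chrom = ch,
                              pos = as.integer(pos), in_island = TRUE,
                              stringsAsFactors = FALSE)
      island_of[ids] <- i
    }
    manifest <- do.call(rbind, rows)
    n_non <- round(spec$nonisland_fraction * nrow(manifest))
    if (n_non > 0) {
      ch <- paste0("chr", (seq_len(n_non) - 1) %% 22 + 1)
      # placed beyond 10 Mb, far from every island region
      pos <- 10000000L + 1000L * (seq_len(n_non) - 1)
      manifest <- rbind(manifest, data.frame(
        probe_id = sprintf("cg_open%05d", seq_len(n_non)),
        chrom = ch, pos = pos, in_island = FALSE,
        stringsAsFactors = FALSE))
    }
    attr(manifest, "island_of") <- island_of
    validate_manifest(manifest)
    manifest
  })
}

# Draw the per-class signature island sets.
.signatures <- function(spec) {
  classes <- synthetic_classes(spec)
  sig_size <- floor(spec$signature_fraction * spec$n_islands)
  withr::with_seed(spec$seed + 101L, {
    if (spec$signature_mode == "disjoint") {
      perm <- sample.int(spec$n_islands)
      sigs <- lapply(seq_along(classes), function(k) {
        if (sig_size == 0) integer() else
          sort(perm[(k - 1) * sig_size + seq_len(sig_size)])
      })
    } else {
      sigs <- lapply(seq_along(classes), function(k) {
        if (sig_size == 0) integer() else
          sort(sample.int(spec$n_islands, sig_size))
      })
    }
    stats::setNames(sigs, classes)
  })
}

#' Generate a synthetic cohort
#'
#' Draws a probe-level beta matrix and matching metadata. Each class has a
#' signature set of islands whose probes are drawn from the
#' hypermethylated mode; all other island probes come from the
#' hypomethylated mode (non-island probes are always hypomethylated).
#' A `paired_fraction` of each class's samples shares a patient with an
#' earlier sample, giving matched pairs for deduplication. NORM samples
#' are typed `normal_tissue`, all others `primary`.
#'
#' @param spec A [synthetic_spec()].
#' @param manifest Optional manifest from [generate_manifest()]; generated
#'   from `spec` when `NULL`.
#' @return List with `beta` (samples x probes matrix), `metadata` (data
#'   frame), `manifest`, and `signatures` (per-class island index sets).
#' @export
generate_cohort <- function(spec, manifest = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(manifest)) manifest <- generate_manifest(spec)
  island_of <- attr(manifest, "island_of")
  classes <- synthetic_classes(spec)
  sigs <- .signatures(spec)
  n_per <- spec$samples_per_class
  n_total <- n_per * spec$n_classes

  # island index of each probe column; NA = non-island
  probe_island <- island_of[manifest$probe_id]
  probe_island <- suppressWarnings(as.integer(probe_island))

  withr::with_seed(spec$seed + 202L, {
    meta <- do.call(rbind, lapply(classes, function(cl) {
      n_second <- round(spec$paired_fraction * n_per)
      n_patients <- n_per - n_second
      patients <- sprintf("%s_p%03d", cl, seq_len(n_patients))
      # second samples reuse the first patients
      pat <- c(patients, patients[seq_len(n_second)])
      data.frame(
        sample_id = sprintf("%s_s%03d", cl, seq_len(n_per)),
        patient_id = pat,
        class_label = cl,
        sample_type = ifelse(cl == "NORM", "normal_tissue", "primary"),
        stringsAsFactors = FALSE)
    }))
    beta <- matrix(NA_real_, n_total, nrow(manifest),
                   dimnames = list(meta$sample_id, manifest$probe_id))
    for (cl in classes) {
      rows <- which(meta$class_label == cl)
      high <- !is.na(probe_island) & probe_island %in% sigs[[cl]]
      n_high <- sum(high); n_low <- sum(!high)
      vals <- matrix(NA_real_, length(rows), nrow(manifest))
      vals[, high] <- stats::rbeta(length(rows) * n_high,
                                   spec$high_shape[1], spec$high_shape[2])
      vals[, !high] <- stats::rbeta(length(rows) * n_low,
                                    spec$low_shape[1], spec$low_shape[2])
      beta[rows, ] <- vals
    }
    validate_metadata(meta)
    list(beta = beta, metadata = meta, manifest = manifest,
         signatures = sigs)
  })
}

#' Derive metastasis-like or age-drift variants of a cohort
#'
#' `metastasis_like` keeps each cancer sample's class signature but adds
#' Gaussian dispersion of sd `metastasis_noise` (clipped to \[0, 1\]) and
#' flags the copies `metastatic`. `age_drift` models age-related global
#' hypomethylation: NORM samples' betas are shifted down by `drift_shift`
#' (clipped at 0) while the labels stay NORM.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param spec The [synthetic_spec()] that produced it.
#' @param kind `"metastasis_like"` or `"age_drift"`.
#' @return List with `beta` and `metadata` for the variant samples (ids
#'   suffixed `_met` / `_drift`).
#' @export
generate_variants <- function(cohort, spec,
                              kind = c("metastasis_like", "age_drift")) {
  kind <- match.arg(kind)
  meta <- cohort$metadata
  if (kind == "metastasis_like") {
    keep <- meta$class_label != "NORM"
    sub <- meta[keep, , drop = FALSE]
    vals <- cohort$beta[sub$sample_id, , drop = FALSE]
    vals <- withr::with_seed(spec$seed + 303L, {
      pmin(pmax(vals + stats::rnorm(length(vals),
                                    sd = spec$metastasis_noise), 0), 1)
    })
    sub$sample_id <- paste0(sub$sample_id, "_met")
    sub$sample_type <- "metastatic"
  } else {
    keep <- meta$class_label == "NORM"
    sub <- meta[keep, , drop = FALSE]
    vals <- pmax(cohort$beta[sub$sample_id, , drop = FALSE] -
                   spec$drift_shift, 0)
    sub$sample_id <- paste0(sub$sample_id, "_drift")
  }
  rownames(vals) <- sub$sample_id
  rownames(sub) <- NULL
  list(beta = vals, metadata = sub)
}

#' Write a synthetic corpus to disk
#'
#' Emits `manifest.csv`, `beta.tsv` and `metadata.csv` in the dialects the
#' readers of this package consume.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"), "csv")
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.csv"))
  invisible(dir)
}
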