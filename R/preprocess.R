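# CpG-island feature construction: island filter, 100 bp probe chaining,
# small-cluster elimination, per-cluster beta averaging, and leakage-safe
# per-sample normalisation. Every step that touches a sample uses only that
# sample's own values, so a sample's feature vector never depends on which
# other samples are present.

#' Keep only CpG-island probes
#'
#' Drops every probe not assigned to a CpG island, preserving input order.
#'
#' @param probes Manifest data frame (see [read_manifest()]).
#' @return The island-positive subset of `probes`.
#' @export
filter_island_probes <- function(probes) {
  probes[probes$in_island, , drop = FALSE]
}

#' Chain probes within a gap threshold into clusters
#'
#' Per chromosome, probes are sorted by position and chained by single
#' linkage: a new cluster starts whenever the gap to the previous probe
#' exceeds `max_gap` base pairs. A boundary gap of exactly `max_gap` joins
#' ("within 100 bp" is inclusive). Every probe belongs to exactly one
#' cluster and cluster ids are the deterministic `chrom:start-end` span.
#'
#' @param probes Manifest data frame, typically already island-filtered.
#' @param max_gap Maximum gap (bp) between consecutive probes of one
#'   cluster; default 100.
#' @return Data frame with columns `cluster_id`, `chrom`, `start`, `end`,
#'   `n_probes` and a list-column `probe_ids` of member probe ids sorted by
#'   position. Clusters are ordered by chromosome then start.
#' @export
cluster_probes <- function(probes, max_gap = 100L) {
  stopifnot(is.numeric(max_gap), length(max_gap) == 1, max_gap >= 0)
  if (nrow(probes) == 0) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_probes = integer(),
                      probe_ids = I(list())))
  }
  if (anyNA(probes$pos) || any(!is.finite(probes$pos))) {
    stop("probe positions must be finite to cluster")
  }
  pieces <- lapply(split(probes, probes$chrom), function(p) {
    p <- p[order(p$pos), , drop = FALSE]
    gap_breaks <- c(FALSE, diff(p$pos) > max_gap)
    grp <- cumsum(gap_breaks)
    ids <- split(p$probe_id, grp)
    pos <- split(p$pos, grp)
    data.frame(
      chrom = p$chrom[1],
      start = vapply(pos, min, numeric(1)),
      end = vapply(pos, max, numeric(1)),
      n_probes = lengths(ids),
      probe_ids = I(unname(ids)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- data.frame(
    cluster_id = sprintf("%s:%d-%d", out$chrom, out$start, out$end),
    out, row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Drop clusters with too few probes
#'
#' Retains clusters with at least `min_probes` member probes. The default
#' of 4 eliminates clusters of 3 CpG probes or fewer.
#'
#' @param clusters Cluster data frame from [cluster_probes()].
#' @param min_probes Minimum number of member probes to keep; default 4.
#' @return The filtered cluster data frame, order preserved.
#' @export
filter_clusters <- function(clusters, min_probes = 4L) {
  clusters[clusters$n_probes >= min_probes, , drop = FALSE]
}

#' Average probe betas within clusters
#'
#' Collapses a probe-level beta matrix to one feature per cluster: each
#' cell is the arithmetic mean of the cluster's member probes with
#' non-missing beta for that sample, and is missing only when every member
#' is missing. Output feature order equals cluster order.
#'
#' @param beta Probe-level beta matrix (samples x probes).
#' @param clusters Cluster data frame; every member probe must be a column
#'   of `beta`.
#' @return Beta matrix (samples x clusters) with `cluster_id` colnames and
#'   a `provenance` attribute mapping cluster_id to member probe ids.
#' @export
average_beta <- function(beta, clusters) {
  stopifnot(is.matrix(beta))
  for (k in seq_len(nrow(clusters))) {
    absent <- setdiff(clusters$probe_ids[[k]], colnames(beta))
    if (length(absent) > 0) {
      stop("cluster ", clusters$cluster_id[k],
           " references probe(s) absent from the beta matrix: ",
           paste(absent, collapse = ", "))
    }
  }
  out <- matrix(NA_real_, nrow(beta), nrow(clusters),
                dimnames = list(rownames(beta), clusters$cluster_id))
  for (k in seq_len(nrow(clusters))) {
    sub <- beta[, clusters$probe_ids[[k]], drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[, k] <- m
  }
  prov <- clusters$probe_ids
  names(prov) <- clusters$cluster_id
  attr(out, "provenance") <- prov
  out
}

#' Normalise one sample's feature vector
#'
#' Per-sample normalisation that uses no cross-sample statistics: values
#' are clipped to \[0, 1\] and missing entries are imputed with the sample's
#' own mean over its non-missing entries. The output therefore depends only
#' on the input vector, which is what makes the pipeline leakage-safe.
#'
#' @param x Numeric vector of one sample's feature values.
#' @return Numeric vector of the same length, in \[0, 1\], with no missing
#'   values.
#' @export
normalize_sample <- function(x) {
  if (all(is.na(x))) {
    stop("cannot normalise an all-missing sample (uninformative sample)")
  }
  x <- pmin(pmax(x, 0), 1)
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  x
}

#' Normalise every sample of a feature matrix
#'
#' Applies [normalize_sample()] row-wise; rows are independent.
#'
#' @param features Feature matrix, samples as rows.
#' @return Matrix of the same shape and dimnames, all values in \[0, 1\].
#' @export
normalize_features <- function(features) {
  out <- t(apply(features, 1, normalize_sample))
  dimnames(out) <- dimnames(features)
  out
}

#' Full feature-construction pipeline
#'
#' Convenience wrapper chaining island filtering, probe chaining,
#' small-cluster elimination, per-cluster averaging and per-sample
#' normalisation.
#'
#' @param probes Probe manifest data frame.
#' @param beta Probe-level beta matrix (samples x probes).
#' @param max_gap Maximum intra-cluster probe gap in bp (default 100).
#' @param min_probes Minimum cluster size retained (default 4).
#' @param normalize Clip/impute each sample after averaging (default TRUE).
#' @return List with `features` (samples x clusters matrix) and `clusters`
#'   (the retained cluster data frame).
#' @export
build_features <- function(probes, beta, max_gap = 100L, min_probes = 4L,
                           normalize = TRUE) {
  island <- filter_island_probes(validate_manifest(probes))
  clusters <- filter_clusters(cluster_probes(island, max_gap), min_probes)
  features <- average_beta(beta, clusters)
  if (normalize) {
    prov <- attr(features, "provenance")
    features <- normalize_features(features)
    attr(features, "provenance") <- prov
  }
  list(features = features, clusters = clusters)
}
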