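# Readers/writers for the three on-disk inputs: probe manifest, beta-value
# matrix and sample metadata. All genomic coordinates are 0-based internally;
# conversion from 1-based CSV positions happens here and nowhere else.

.na_tokens <- c("na", "nan", "")

.is_na_token <- function(x) tolower(trimws(x)) %in% .na_tokens

#' Read a probe manifest
#'
#' Parses an Illumina-450K-style probe manifest into a data frame of probe
#' records (`probe_id`, `chrom`, `pos`, `in_island`). Two dialects are
#' supported:
#'
#' * `"csv"`: header `probe_id,chrom,pos,in_island`, positions 1-based.
#' * `"bed"`: headerless BED-like TSV with columns chrom, start, end,
#'   probe_id and an island flag (0/1 or TRUE/FALSE) in column 5; start is
#'   0-based half-open.
#'
#' Positions are normalised to the internal 0-based convention on read.
#'
#' @param path Path to the manifest file.
#' @param dialect Either `"csv"` or `"bed"`.
#' @return A data frame with columns `probe_id` (character), `chrom`
#'   (character), `pos` (integer, 0-based) and `in_island` (logical), one
#'   row per probe in file order.
#' @export
read_manifest <- function(path, dialect = c("csv", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("manifest file not found: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    required <- c("probe_id", "chrom", "pos", "in_island")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("manifest is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
    probes <- data.frame(
      probe_id = df$probe_id,
      chrom = df$chrom,
      pos = suppressWarnings(as.integer(df$pos)) - 1L,
      in_island = .parse_flag(df$in_island),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.table(path, sep = "\t", colClasses = "character")
    if (ncol(df) < 5) {
      stop("BED-like manifest needs 5 columns ",
           "(chrom, start, end, probe_id, island flag); found ", ncol(df))
    }
    probes <- data.frame(
      probe_id = df[[4]],
      chrom = df[[1]],
      pos = suppressWarnings(as.integer(df[[2]])),
      in_island = .parse_flag(df[[5]]),
      stringsAsFactors = FALSE
    )
  }
  validate_manifest(probes)
}

.parse_flag <- function(x) {
  out <- rep(NA, length(x))
  low <- tolower(trimws(x))
  out[low %in% c("1", "true", "t")] <- TRUE
  out[low %in% c("0", "false", "f")] <- FALSE
  if (anyNA(out)) {
    stop("unparseable island flag value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Validate a probe manifest data frame
#'
#' Checks the probe-record invariants: unique probe ids, non-empty
#' chromosome names, non-negative finite positions, logical island flags.
#'
#' @param probes Data frame with columns `probe_id`, `chrom`, `pos`,
#'   `in_island`.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_manifest <- function(probes) {
  required <- c("probe_id", "chrom", "pos", "in_island")
  missing <- setdiff(required, names(probes))
  if (length(missing) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- unique(probes$probe_id[duplicated(probes$probe_id)])
  if (length(dup) > 0) {
    stop("duplicate probe_id(s) in manifest: ", paste(dup, collapse = ", "))
  }
  if (anyNA(probes$pos) || any(probes$pos < 0)) {
    stop("manifest positions must be non-negative integers")
  }
  if (anyNA(probes$chrom) || any(!nzchar(probes$chrom))) {
    stop("manifest chromosome names must be non-empty")
  }
  if (!is.logical(probes$in_island) || anyNA(probes$in_island)) {
    stop("in_island must be TRUE/FALSE for every probe")
  }
  probes
}

#' Write a probe manifest
#'
#' Inverse of [read_manifest()]: CSV output carries 1-based positions, BED
#' output 0-based half-open intervals of width 1 (one CpG per probe row).
#'
#' @param probes Manifest data frame (internal 0-based positions).
#' @param path Output path.
#' @param dialect `"csv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(probes, path, dialect = c("csv", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    out <- data.frame(
      probe_id = probes$probe_id,
      chrom = probes$chrom,
      pos = probes$pos + 1L,
      in_island = as.integer(probes$in_island)
    )
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- data.frame(
      chrom = probes$chrom,
      start = probes$pos,
      end = probes$pos + 1L,
      probe_id = probes$probe_id,
      in_island = as.integer(probes$in_island)
    )
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a beta-value matrix
#'
#' Reads a samples-by-features table of methylation beta values. The first
#' column holds sample ids and the header row feature ids. Cells must be
#' numeric in \[0, 1\], or one of the missing-value tokens `NA`, `NaN` or the
#' empty string (case-insensitive). Sample and feature order on disk is
#' preserved in memory.
#'
#' @param path Path to a TSV (or CSV, chosen by `sep`) file.
#' @param sep Field separator, tab by default.
#' @return Numeric matrix with sample ids as rownames and feature ids as
#'   colnames; missing cells are `NA`.
#' @export
read_beta_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("beta matrix file not found: ", path)
  fields <- utils::count.fields(path, sep = sep, quote = "",
                                blank.lines.skip = FALSE)
  if (length(fields) < 1) stop("beta matrix file is empty: ", path)
  ragged <- which(fields != fields[1])
  if (length(ragged) > 0) {
    stop("ragged beta matrix: row ", ragged[1], " has ", fields[ragged[1]],
         " fields, expected ", fields[1])
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                          colClasses = "character", check.names = FALSE,
                          quote = "", na.strings = character(0))
  sample_ids <- df[[1]]
  feature_ids <- names(df)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in beta matrix: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id(s) in beta matrix: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  vals[.is_na_token(raw)] <- NA_real_
  bad <- which(!.is_na_token(raw) &
                 (is.na(vals) | vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("beta value out of [0,1] or unparseable at sample '", sample_ids[i],
         "' (row ", i, "), feature '", feature_ids[j], "' (column ", j,
         "): ", raw[i, j])
  }
  dimnames(vals) <- list(sample_ids, feature_ids)
  vals
}

#' Write a beta-value matrix
#'
#' Writes a beta matrix as TSV at 17 significant digits, so that a
#' write-then-read round trip reproduces every double bit-exactly.
#'
#' @param beta Numeric matrix, samples as rows.
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, sep = "\t") {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  txt <- matrix(sprintf("%.17g", beta), nrow = nrow(beta))
  txt[is.na(beta)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(beta)), collapse = sep), con)
  writeLines(paste(rownames(beta),
                   apply(txt, 1, paste, collapse = sep), sep = sep), con)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Reads the CSV linking each array sample to its patient, class label and
#' sample type. Class labels are validated against [class_vocabulary()] and
#' sample types against [sample_types()].
#'
#' @param path Path to a CSV with columns `sample_id`, `patient_id`,
#'   `class_label`, `sample_type`.
#' @return Validated data frame, one row per sample in file order.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  validate_metadata(df)
}

#' Validate a sample-metadata data frame
#'
#' @param metadata Data frame with columns `sample_id`, `patient_id`,
#'   `class_label`, `sample_type`.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_metadata <- function(metadata) {
  required <- c("sample_id", "patient_id", "class_label", "sample_type")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id(s) in metadata: ", paste(dup, collapse = ", "))
  }
  bad_label <- setdiff(unique(metadata$class_label), class_vocabulary())
  if (length(bad_label) > 0) {
    stop("unknown class label(s): ", paste(bad_label, collapse = ", "),
         "; expected one of the 33 TCGA codes or NORM")
  }
  bad_type <- setdiff(unique(metadata$sample_type), sample_types())
  if (length(bad_type) > 0) {
    stop("unknown sample_type(s): ", paste(bad_type, collapse = ", "),
         "; expected ", paste(sample_types(), collapse = "/"))
  }
  metadata
}

#' Write a sample-metadata table
#'
#' @param metadata Metadata data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(
    metadata[, c("sample_id", "patient_id", "class_label", "sample_type")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate a manifest, beta matrix and metadata trio
#'
#' Checks the joint invariants the pipeline relies on: every sample in the
#' beta matrix has exactly one metadata row, and (when the beta matrix is at
#' probe level) every feature appears in the manifest.
#'
#' @param probes Manifest data frame, or `NULL` to skip the feature check.
#' @param beta Beta matrix (samples x features).
#' @param metadata Metadata data frame.
#' @return `TRUE`, invisibly, if all checks pass; otherwise an error.
#' @export
validate_inputs <- function(probes, beta, metadata) {
  validate_metadata(metadata)
  orphan <- setdiff(rownames(beta), metadata$sample_id)
  if (length(orphan) > 0) {
    stop("beta matrix sample(s) without metadata: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  if (!is.null(probes)) {
    validate_manifest(probes)
    unknown <- setdiff(colnames(beta), probes$probe_id)
    if (length(unknown) > 0) {
      stop("beta matrix feature(s) absent from manifest: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}
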