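#' Class-label vocabulary
#'
#' The fixed 34-label vocabulary used throughout the package: the 33 TCGA
#' study abbreviations plus `"NORM"` for non-cancerous tissue. Every
#' metadata table, confusion matrix and classifier head is validated and
#' ordered against this single vector, so per-class results line up across
#' modules.
#'
#' @return Character vector of length 34, TCGA codes first, `"NORM"` last.
#' @examples
#' class_vocabulary()
#' @export
class_vocabulary <- function() {
  c(
    "ACC", "BLCA", "BRCA", "CESC", "CHOL", "COAD", "DLBC", "ESCA", "GBM",
    "HNSC", "KICH", "KIRC", "KIRP", "LAML", "LGG", "LIHC", "LUAD", "LUSC",
    "MESO", "OV", "PAAD", "PCPG", "PRAD", "READ", "SARC", "SKCM", "STAD",
    "TGCT", "THCA", "THYM", "UCEC", "UCS", "UVM", "NORM"
  )
}

#' Sample-type vocabulary
#'
#' Allowed values of the `sample_type` metadata column. Only `primary` and
#' `normal_tissue` samples are eligible for training splits; `metastatic`
#' and `recurrent` samples are held out for evaluation.
#'
#' @return Character vector of the four recognised sample types.
#' @export
sample_types <- function() {
  c("primary", "metastatic", "recurrent", "normal_tissue")
}
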