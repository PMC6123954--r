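#' Consequence-class vocabulary
#'
#' The controlled vocabulary of per-variant consequence classes used
#' throughout the filtering cascade, ordered from most to least severe.
#' The first five classes are the loss-of-function (LoF) classes: they are
#' expected to abolish the gene product and pass every pathogenicity tier
#' without requiring predictor support. "Essential splice site" means the
#' +/- 2 bp splice dinucleotide; deeper intronic positions near a splice
#' junction are `splice_region` (or plain `intronic`).
#'
#' @format A character vector of class labels.
#' @export
consequence_classes <- c(
  "transcript_ablation", "essential_splice_site", "frameshift_indel",
  "stop_gained", "start_lost",
  "missense", "inframe_indel", "splice_region",
  "synonymous", "intronic", "intergenic", "other", "unknown"
)

#' Loss-of-function consequence classes
#' @format Character vector, a subset of [consequence_classes].
#' @export
lof_classes <- consequence_classes[1:5]

#' Is a consequence class loss-of-function?
#'
#' @param consequence Character vector of consequence-class labels.
#' @return Logical vector; `TRUE` where the class is one of the five LoF
#'   classes. Unrecognised labels are an error.
#' @export
is_lof <- function(consequence) {
  bad <- setdiff(unique(consequence), c(consequence_classes, NA))
  if (length(bad) > 0) {
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  }
  !is.na(consequence) & consequence %in% lof_classes
}

# Display names used in tabular reports (Table-1-style "Type of variants").
consequence_display <- c(
  transcript_ablation = "Transcript ablation",
  essential_splice_site = "Essential splice site",
  frameshift_indel = "Frameshift",
  stop_gained = "Stop gain",
  start_lost = "Start loss",
  missense = "Non-synonymous",
  inframe_indel = "In-frame indel",
  splice_region = "Splice region",
  synonymous = "Synonymous",
  intronic = "Intronic",
  intergenic = "Intergenic",
  other = "Other",
  unknown = "Unknown"
)
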