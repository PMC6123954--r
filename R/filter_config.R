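#' Filtering-cascade configuration
#'
#' Bundles every threshold and switch of the variant-prioritisation cascade:
#' the site-quality gate, the minor-allele-frequency (MAF) gate with its
#' population fallback, the consequence-severity gate, and the pathogenicity
#' vote tier.
#'
#' @param maf_threshold MAF cut-off as a fraction in (0, 1]. The standard
#'   tiers are 0.10 and 0.01 for the common-variant screen, 0.005 for the
#'   very-rare (recessive) screen and 0.0005 for a strict dominant screen.
#' @param maf_inclusive If `TRUE` the MAF gate passes frequencies equal to
#'   the threshold (`<=`); if `FALSE` the comparison is strict (`<`). The
#'   10% screen is conventionally inclusive, the very-rare screens strict.
#' @param vote_mode Pathogenicity tier required for a variant to pass:
#'   `"majority"` (deleterious calls from more than half of the informative
#'   predictors), `"all"` (unanimous) or `"lof_only"` (loss-of-function
#'   consequence classes only). LoF variants pass every tier.
#' @param min_site_quality,min_depth,min_mapping_quality Quality-gate
#'   thresholds (phred-scaled call quality, read depth, phred-scaled mapping
#'   quality), applied inclusively.
#' @param quality_gate_enabled Set `FALSE` for pre-validated call sets
#'   (e.g. reference-project genotypes) where the quality gate is skipped.
#' @param primary_population,fallback_population Labels of the allele
#'   frequency columns consulted in order by [resolve_maf()]. Variants with
#'   neither recorded are treated as novel (MAF 0).
#' @param retained_consequences Consequence classes that survive the
#'   severity gate. Default: the five LoF classes plus missense, in-frame
#'   indel and splice-region.
#' @param cross_population_flag_threshold Frequency above which presence in
#'   any non-primary population raises an informational flag (never a
#'   filter); default 0.10.
#' @return An object of class `filter_config` (a named list).
#' @seealso [filter_preset()] for the named presets used by the analyses.
#' @export
filter_config <- function(maf_threshold = 0.10,
                          maf_inclusive = TRUE,
                          vote_mode = c("majority", "all", "lof_only"),
                          min_site_quality = 30,
                          min_depth = 20,
                          min_mapping_quality = 45,
                          quality_gate_enabled = TRUE,
                          primary_population = "nfe",
                          fallback_population = "eur",
                          retained_consequences = c(
                            lof_classes, "missense", "inframe_indel",
                            "splice_region"
                          ),
                          cross_population_flag_threshold = 0.10) {
  vote_mode <- match.arg(vote_mode)
  stopifnot(
    is.numeric(maf_threshold), length(maf_threshold) == 1,
    maf_threshold > 0, maf_threshold <= 1,
    min_site_quality >= 0, min_depth >= 0, min_mapping_quality >= 0,
    is.logical(maf_inclusive), is.logical(quality_gate_enabled)
  )
  bad <- setdiff(retained_consequences, consequence_classes)
  if (length(bad) > 0) {
    stop("retained_consequences outside vocabulary: ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      maf_threshold = maf_threshold,
      maf_inclusive = maf_inclusive,
      vote_mode = vote_mode,
      min_site_quality = min_site_quality,
      min_depth = min_depth,
      min_mapping_quality = min_mapping_quality,
      quality_gate_enabled = quality_gate_enabled,
      primary_population = primary_population,
      fallback_population = fallback_population,
      retained_consequences = retained_consequences,
      cross_population_flag_threshold = cross_population_flag_threshold
    ),
    class = "filter_config"
  )
}

#' Named filter presets
#'
#' Three presets mirror the two analyses the cascade was designed for and
#' the stricter dominant screen recommended for dominant hearing loss:
#'
#' * `"common"`: MAF <= 10% (inclusive), majority vote — the low-stringency
#'   common-variant screen.
#' * `"very_rare"`: MAF < 0.5% (strict), majority vote — the very-rare
#'   screen used for recessive-model discovery.
#' * `"dominant_strict"`: MAF < 0.05% (strict), majority vote.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [filter_config()].
#' @return A `filter_config`.
#' @export
filter_preset <- function(name = c("common", "very_rare", "dominant_strict"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    common = list(maf_threshold = 0.10, maf_inclusive = TRUE),
    very_rare = list(maf_threshold = 0.005, maf_inclusive = FALSE),
    dominant_strict = list(maf_threshold = 0.0005, maf_inclusive = FALSE)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(filter_config, args)
}

#' @export
print.filter_config <- function(x, ...) {
  cmp <- if (x$maf_inclusive) "<=" else "<"
  cat("<filter_config>\n")
  cat(sprintf("  MAF gate: %s %.4g%% (%s, fallback %s; novel passes)\n",
              cmp, 100 * x$maf_threshold, x$primary_population,
              x$fallback_population))
  cat(sprintf("  quality gate: %s (QUAL>=%g, DP>=%g, MQ>=%g)\n",
              if (x$quality_gate_enabled) "on" else "off",
              x$min_site_quality, x$min_depth, x$min_mapping_quality))
  cat(sprintf("  vote tier: %s\n", x$vote_mode))
  invisible(x)
}
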