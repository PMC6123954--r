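#' Annotated exome cohort container
#'
#' A cohort holds one row per annotated alternate allele plus a long table of
#' non-reference genotype calls. Population frequencies live in `maf_<pop>`
#' columns (minor allele frequency as a fraction, `NA` when unrecorded) and
#' predictor verdicts in `pred_<name>` columns taking values
#' `"deleterious"`, `"benign"` or `"unknown"` (`NA` is read as `"unknown"`).
#'
#' @param variants Tibble with at least `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`; optional `variant_id`, `site_quality`,
#'   `read_depth`, `mapping_quality`, `maf_*`, `pred_*` columns. One row per
#'   (site, alt allele, gene annotation).
#' @param genotypes Tibble with `key`, `sample_id`, `zygosity` (one of
#'   `"heterozygous"`, `"homozygous_alt"`, `"missing"`; reference calls are
#'   implicit and never stored) and optional `haplotype` (1 or 2 for phased
#'   heterozygous calls, `NA` otherwise).
#' @param samples Character vector of all sample ids in the cohort,
#'   including samples that carry no variant.
#' @return An object of class `exome_cohort`.
#' @export
exome_cohort <- function(variants, genotypes, samples) {
  variants <- tibble::as_tibble(variants)
  genotypes <- tibble::as_tibble(genotypes)
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(variants$pos >= 1), all(nzchar(variants$ref)),
            all(nzchar(variants$alt)))
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must differ")
  }
  bad <- setdiff(unique(variants$consequence), consequence_classes)
  if (length(bad) > 0) {
    stop("consequence outside vocabulary: ", paste(bad, collapse = ", "))
  }
  for (col in c("variant_id", "site_quality", "read_depth", "mapping_quality")) {
    if (!col %in% names(variants)) {
      variants[[col]] <- if (col == "variant_id") NA_character_ else NA_real_
    }
  }
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  if (!"haplotype" %in% names(genotypes)) genotypes$haplotype <- NA_integer_
  stopifnot(all(c("key", "sample_id", "zygosity") %in% names(genotypes)))
  bad_z <- setdiff(unique(genotypes$zygosity),
                   c("heterozygous", "homozygous_alt", "missing"))
  if (length(bad_z) > 0) {
    stop("unknown zygosity value(s): ", paste(bad_z, collapse = ", "))
  }
  unknown_samples <- setdiff(unique(genotypes$sample_id), samples)
  if (length(unknown_samples) > 0) {
    stop("genotypes reference sample(s) absent from the cohort: ",
         paste(unknown_samples, collapse = ", "))
  }
  fr <- freq_populations(variants)
  structure(
    list(variants = variants, genotypes = genotypes,
         samples = as.character(samples)),
    class = "exome_cohort"
  )
}

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt Vectors describing one alternate allele each.
#' @return `"chrom:pos:ref:alt"` strings; identical variants in different
#'   samples share a key.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Population labels present in a variants table (from maf_<pop> columns).
freq_populations <- function(variants) {
  cols <- grep("^maf_", names(variants), value = TRUE)
  vals <- unlist(variants[cols], use.names = FALSE)
  if (length(vals) && any(vals < 0 | vals > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  sub("^maf_", "", cols)
}

# Predictor labels present in a variants table (from pred_<name> columns).
predictor_names <- function(variants) {
  sub("^pred_", "", grep("^pred_", names(variants), value = TRUE))
}

#' @export
print.exome_cohort <- function(x, ...) {
  cat("<exome_cohort>\n")
  cat(sprintf("  %d annotated alternate alleles across %d samples\n",
              nrow(x$variants), length(x$samples)))
  cat(sprintf("  populations: %s\n",
              paste(freq_populations(x$variants), collapse = ", ")))
  cat(sprintf("  predictors: %s\n",
              paste(predictor_names(x$variants), collapse = ", ")))
  invisible(x)
}

#' Read a cohort manifest
#'
#' A manifest assigns every sample to a phenotype subgroup (for this
#' package's motivating study: `Dominant`, `Recessive`, `Metabolic`,
#' `Sensory`; any labels are accepted).
#'
#' @param path Tab-separated file with columns `sample_id` and `subgroup`.
#' @return A tibble with columns `sample_id` and `subgroup`, with the
#'   subgroup sizes reported as the `"subgroup_sizes"` attribute.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  if (!all(c("sample_id", "subgroup") %in% names(m))) {
    stop("manifest must have columns sample_id and subgroup: ", path)
  }
  m <- tibble::as_tibble(m[, c("sample_id", "subgroup")])
  if (anyDuplicated(m$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  }
  if (any(!nzchar(m$subgroup) | is.na(m$subgroup))) {
    stop("manifest has empty subgroup entries")
  }
  attr(m, "subgroup_sizes") <- table(m$subgroup)
  m
}

# Members of one subgroup, validated against the manifest.
subgroup_members <- function(manifest, subgroup) {
  if (!subgroup %in% manifest$subgroup) {
    stop("unknown subgroup: ", subgroup)
  }
  manifest$sample_id[manifest$subgroup == subgroup]
}
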