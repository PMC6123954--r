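#' Per-sample audit of variants surviving each stage
#'
#' The cascade's count ledger: for every sample, the number of carried
#' variants surviving cumulatively after each stage (all variants, quality
#' gate, MAF gate, consequence gate, pathogenicity tier). Counts are
#' monotone non-increasing along the stage order by construction.
#'
#' @param cohort An [exome_cohort()].
#' @param cfg A [filter_config()].
#' @return A tibble with columns `sample_id`, `total`, `quality`, `maf`,
#'   `consequence`, `tier`, plus a `"cohort_means"` attribute (named numeric
#'   vector of stage means across samples).
#' @export
audit_counts <- function(cohort, cfg) {
  va <- cohort$variants
  out <- filter_variant(va, cfg)
  qual <- quality_gate(va, cfg)
  maf_ok <- maf_gate(resolve_maf(va, cfg)$effective_maf, cfg)
  csq_ok <- consequence_gate(va, cfg)
  tier_ok <- pathogenicity_tiers(va)[[cfg$vote_mode]]
  stage <- tibble::tibble(
    key = out$key,
    s1 = qual,
    s2 = qual & maf_ok,
    s3 = qual & maf_ok & csq_ok,
    s4 = qual & maf_ok & csq_ok & tier_ok
  )
  stage <- stage[!duplicated(stage$key), ]  # count variants once per site
  g <- cohort$genotypes[
    cohort$genotypes$zygosity %in% c("heterozygous", "homozygous_alt"),
    c("key", "sample_id")
  ]
  g <- g[!duplicated(g), ]
  joined <- dplyr::inner_join(g, stage, by = "key")
  per_sample <- dplyr::summarise(
    dplyr::group_by(joined, .data$sample_id),
    total = dplyr::n(),
    quality = sum(.data$s1), maf = sum(.data$s2),
    consequence = sum(.data$s3), tier = sum(.data$s4),
    .groups = "drop"
  )
  missing <- setdiff(cohort$samples, per_sample$sample_id)
  if (length(missing)) {
    per_sample <- dplyr::bind_rows(
      per_sample,
      tibble::tibble(sample_id = missing, total = 0L, quality = 0L,
                     maf = 0L, consequence = 0L, tier = 0L)
    )
  }
  per_sample <- per_sample[match(cohort$samples, per_sample$sample_id), ]
  attr(per_sample, "cohort_means") <- vapply(
    per_sample[, c("total", "quality", "maf", "consequence", "tier")],
    mean, 0
  )
  per_sample
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end run over a cohort: the common-variant screen
#' (burden grid across panels, MAF thresholds and tiers; subgroup-shared
#' genes; dominant-gene carrier summary) and the very-rare screen
#' (recurrent genes, recurrent identical variants, apparently-homozygous
#' variants, multi-variant genes, candidate-gene lookup), with a
#' per-stage count audit for each preset. All outputs are deterministic:
#' rerunning on the same inputs gives byte-identical files.
#'
#' @param cohort An [exome_cohort()].
#' @param manifest Manifest tibble ([read_manifest()]).
#' @param panels Named list of [gene_panel()]s; `deafness` (with its
#'   dominant subset), `exclusion` and `gwas` drive the flagged reports
#'   when present.
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   writing.
#' @param presets Named list of [filter_config()]s; default the `common`
#'   and `very_rare` presets.
#' @param maf_thresholds,tiers Grid swept by the burden analysis.
#' @return A list of results: `burden_grid`, `shared_genes`,
#'   `dominant_summary`, `recurrent_genes`, `recurrent_variants`,
#'   `homozygous`, `multi_hit`, `candidates`, `audit` (one entry per
#'   preset) and `paths` of written files (when `out_dir` is given).
#' @export
run_pipeline <- function(cohort, manifest, panels, out_dir = NULL,
                         presets = list(common = filter_preset("common"),
                                        very_rare = filter_preset("very_rare")),
                         maf_thresholds = c(0.10, 0.01),
                         tiers = c("majority", "all", "lof_only")) {
  stopifnot(inherits(cohort, "exome_cohort"))
  unknown <- setdiff(manifest$sample_id, cohort$samples)
  if (length(unknown)) {
    stop("manifest lists sample(s) absent from the cohort: ",
         paste(unknown, collapse = ", "))
  }
  common <- presets$common %||% filter_preset("common")
  very_rare <- presets$very_rare %||% filter_preset("very_rare")
  deaf <- panels$deafness
  excl <- panels$exclusion

  res <- list()
  res$burden_grid <- burden_grid(cohort, panels[!vapply(panels, function(p)
    p$is_exclusion_list, TRUE)], common,
    maf_thresholds = maf_thresholds, tiers = tiers, exclusion_panel = excl)
  res$shared_genes <- dplyr::bind_rows(lapply(
    unique(manifest$subgroup),
    function(sg) shared_mutated_genes(cohort, manifest, sg, common,
                                      deafness_panel = deaf,
                                      exclusion_panel = excl)
  ))
  res$dominant_summary <- if (!is.null(deaf)) {
    dominant_carrier_summary(cohort, deaf, common)
  }
  res$recurrent_genes <- recurrent_genes(cohort, very_rare,
                                         deafness_panel = deaf,
                                         exclusion_panel = excl)
  res$recurrent_variants <- recurrent_identical_variants(cohort, very_rare)
  res$homozygous <- homozygous_rare(cohort, very_rare)
  res$multi_hit <- multi_hit_genes(cohort, very_rare)
  res$candidates <- if (!is.null(panels$gwas) && length(panels$gwas$genes)) {
    candidate_lookup(cohort, very_rare, panels$gwas)
  }
  res$audit <- lapply(list(common = common, very_rare = very_rare),
                      function(cfg) audit_counts(cohort, cfg))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      burden_grid = write_report(res$burden_grid,
                                 file.path(out_dir, "burden_grid.tsv")),
      shared_genes = write_report(res$shared_genes,
                                  file.path(out_dir, "shared_genes.tsv")),
      recurrent_genes = write_report(res$recurrent_genes,
                                     file.path(out_dir, "recurrent_genes.tsv")),
      recurrent_variants = write_report(
        res$recurrent_variants, file.path(out_dir, "recurrent_variants.tsv")),
      homozygous = write_report(res$homozygous$records,
                                file.path(out_dir, "homozygous.tsv")),
      multi_hit = write_report(res$multi_hit,
                               file.path(out_dir, "multi_hit.tsv"))
    )
    if (!is.null(res$candidates)) {
      paths["candidates"] <- write_report(
        res$candidates, file.path(out_dir, "candidates.tsv"))
    }
    audit <- lapply(res$audit, function(a) {
      list(per_sample = a, cohort_means = as.list(attr(a, "cohort_means")))
    })
    paths["audit"] <- write_report(audit, file.path(out_dir, "audit.json"),
                                   format = "json")
    res$paths <- paths
  }
  res
}
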