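#' Panel genes hit by one sample
#'
#' The set of distinct panel genes in which a sample carries (heterozygous
#' or homozygous — zygosity is deliberately ignored, as in a dominant-model
#' screen) at least one variant passing the filter cascade under `cfg`.
#' Exclusion-candidate genes are included but flagged.
#'
#' @param cohort An [exome_cohort()].
#' @param sample Sample id; must belong to the cohort.
#' @param panel A [gene_panel()].
#' @param cfg A [filter_config()].
#' @param exclusion_panel Optional exclusion-candidate [gene_panel()] used
#'   to flag artifact-prone genes.
#' @return Tibble with columns `gene` and `exclusion_candidate`, sorted by
#'   gene.
#' @export
genes_hit <- function(cohort, sample, panel, cfg, exclusion_panel = NULL) {
  if (!sample %in% cohort$samples) stop("unknown sample: ", sample)
  carried <- cohort$genotypes$key[
    cohort$genotypes$sample_id == sample &
      cohort$genotypes$zygosity %in% c("heterozygous", "homozygous_alt")
  ]
  pv <- passing_variants(cohort, cfg)
  genes <- sort(unique(pv$gene[pv$key %in% carried & pv$gene %in% panel$genes]))
  tibble::tibble(
    gene = genes,
    exclusion_candidate = if (is.null(exclusion_panel)) {
      rep(FALSE, length(genes))
    } else {
      genes %in% exclusion_panel$genes
    }
  )
}

#' Per-individual gene-burden distribution
#'
#' For every sample, the number of distinct panel genes bearing at least
#' one passing variant, summarised as a histogram over the cohort — the
#' screen asking "how many known disease genes does each exome implicate?".
#'
#' @inheritParams genes_hit
#' @param drop_exclusion Recompute with exclusion-candidate genes removed
#'   (default `FALSE`: they count, flagged downstream).
#' @return An object of class `burden_distribution`: a list with
#'   `panel_name`, `tier` (the vote mode), `maf_threshold`,
#'   `per_individual` (named integer vector over all samples), `histogram`
#'   (named count -> number of individuals) and `carrier_count`
#'   (individuals with at least one hit gene).
#' @export
burden_distribution <- function(cohort, panel, cfg, exclusion_panel = NULL,
                                drop_exclusion = FALSE) {
  if (length(cohort$samples) == 0) stop("cohort has no samples")
  panel_genes <- panel$genes
  if (drop_exclusion && !is.null(exclusion_panel)) {
    panel_genes <- setdiff(panel_genes, exclusion_panel$genes)
  }
  pv <- passing_variants(cohort, cfg)
  pv <- pv[!is.na(pv$gene) & pv$gene %in% panel_genes, c("key", "gene")]
  g <- cohort$genotypes[
    cohort$genotypes$zygosity %in% c("heterozygous", "homozygous_alt"), ]
  hits <- dplyr::inner_join(g, pv, by = "key", relationship = "many-to-many")
  counts <- tapply(hits$gene, hits$sample_id, function(x) length(unique(x)))
  per_individual <- stats::setNames(rep(0L, length(cohort$samples)),
                                    cohort$samples)
  per_individual[names(counts)] <- as.integer(counts)
  histogram <- table(per_individual)
  structure(
    list(
      panel_name = panel$name,
      tier = cfg$vote_mode,
      maf_threshold = cfg$maf_threshold,
      per_individual = per_individual,
      histogram = histogram,
      carrier_count = sum(per_individual > 0)
    ),
    class = "burden_distribution"
  )
}

#' @export
print.burden_distribution <- function(x, ...) {
  cat(sprintf(
    "<burden_distribution> panel %s, tier %s, MAF %.4g%%\n",
    x$panel_name, x$tier, 100 * x$maf_threshold))
  cat(sprintf("  %d/%d individuals carry >=1 hit gene; burden range %d-%d\n",
              x$carrier_count, length(x$per_individual),
              min(x$per_individual), max(x$per_individual)))
  invisible(x)
}

#' Dominant-gene carrier summary
#'
#' How many individuals carry at least one predicted-pathogenic variant —
#' and at least one loss-of-function variant — in the panel's
#' dominant-model subset, where a single damaged allele is expected to
#' matter.
#'
#' @inheritParams genes_hit
#' @param panel A [gene_panel()] whose `dominant_subset` is used (may be
#'   empty, giving zero counts).
#' @return A list with `n_cohort`, `n_with_any_pathogenic` (passing at the
#'   configured vote tier) and `n_with_lof` (passing with the tier forced
#'   to loss-of-function-only); `n_with_lof <= n_with_any_pathogenic`.
#' @export
dominant_carrier_summary <- function(cohort, panel, cfg) {
  count_carriers <- function(mode) {
    if (length(panel$dominant_subset) == 0) return(0L)
    cfg2 <- cfg
    cfg2$vote_mode <- mode
    sub <- gene_panel(paste0(panel$name, "_dominant"), panel$dominant_subset)
    burden_distribution(cohort, sub, cfg2)$carrier_count
  }
  list(
    n_cohort = length(cohort$samples),
    n_with_any_pathogenic = count_carriers(cfg$vote_mode),
    n_with_lof = count_carriers("lof_only")
  )
}

#' Compare two burden distributions
#'
#' Two-sample comparison of per-individual burden counts: means, medians
#' and a Wilcoxon rank-sum statistic. The comparison is symmetric in
#' magnitude; the p-value is identical either way round.
#'
#' @param a,b [burden_distribution()] objects (nonempty).
#' @return A list with `mean_a`, `mean_b`, `median_a`, `median_b`,
#'   `statistic` (the rank-sum W for `a` versus `b`) and `p_value`.
#' @export
compare_distributions <- function(a, b) {
  if (length(a$per_individual) == 0 || length(b$per_individual) == 0) {
    stop("cannot compare an empty burden distribution")
  }
  x <- as.numeric(a$per_individual)
  y <- as.numeric(b$per_individual)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  )
  list(
    mean_a = mean(x), mean_b = mean(y),
    median_a = stats::median(x), median_b = stats::median(y),
    statistic = unname(wt$statistic),
    p_value = wt$p.value
  )
}

#' Burden grid across panels, thresholds and tiers
#'
#' The full screening grid: every combination of gene panel, MAF threshold
#' and pathogenicity tier, one [burden_distribution()] each, flattened into
#' a tidy table.
#'
#' @param cohort An [exome_cohort()].
#' @param panels Named list of [gene_panel()] objects.
#' @param cfg Base [filter_config()]; thresholds and tiers vary around it.
#' @param maf_thresholds Numeric vector of thresholds (default the two
#'   common-variant screens, 10% and 1%).
#' @param tiers Vote modes to sweep.
#' @param exclusion_panel Optional exclusion-candidate panel.
#' @return Tibble with one row per (panel, threshold, tier, sample):
#'   columns `panel`, `maf_threshold`, `tier`, `sample_id`, `n_genes`.
#' @export
burden_grid <- function(cohort, panels, cfg = filter_preset("common"),
                        maf_thresholds = c(0.10, 0.01),
                        tiers = c("majority", "all", "lof_only"),
                        exclusion_panel = NULL) {
  rows <- list()
  for (pname in names(panels)) {
    for (t in maf_thresholds) {
      for (tier in tiers) {
        cfg2 <- cfg
        cfg2$maf_threshold <- t
        cfg2$vote_mode <- tier
        bd <- burden_distribution(cohort, panels[[pname]], cfg2,
                                  exclusion_panel = exclusion_panel)
        rows[[length(rows) + 1]] <- tibble::tibble(
          panel = pname, maf_threshold = t, tier = tier,
          sample_id = names(bd$per_individual),
          n_genes = unname(bd$per_individual)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
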