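# Subgroup- and cohort-level discovery analyses over filtered variants.

# Passing (variant, carrier) pairs: one row per carried passing annotation row.
passing_hits <- function(cohort, cfg) {
  pv <- passing_variants(cohort, cfg)
  g <- cohort$genotypes[
    cohort$genotypes$zygosity %in% c("heterozygous", "homozygous_alt"), ]
  dplyr::inner_join(g, pv, by = "key", relationship = "many-to-many")
}

flag_in <- function(genes, panel) {
  if (is.null(panel)) rep(FALSE, length(genes)) else genes %in% panel$genes
}

# Table-1-style "Type of variants" summary, e.g. "Six non-synonymous, one frameshift".
summarise_types <- function(consequences) {
  tab <- sort(table(consequence_display[consequences]), decreasing = TRUE)
  paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", ")
}

#' Genes mutated in every member of a subgroup
#'
#' Finds genes in which each member of a phenotype subgroup carries at
#' least one passing variant — the screen for shared candidate genes within
#' a phenotypically homogeneous subgroup. Run at the common-variant preset
#' this reproduces the Table-1-style analysis (gene, subgroup, number of
#' distinct variants, variant-type summary).
#'
#' @param cohort An [exome_cohort()].
#' @param manifest Manifest tibble from [read_manifest()].
#' @param subgroup Subgroup label (must appear in the manifest and have at
#'   least two members).
#' @param cfg A [filter_config()]; conventionally `filter_preset("common")`.
#' @param deafness_panel,exclusion_panel Optional panels used to set the
#'   `deafness_flag` and `exclusion_flag` columns.
#' @return Tibble sorted by gene: `gene`, `subgroup`,
#'   `n_distinct_variants` (across the subgroup), `variant_types`,
#'   `exclusion_flag`, `deafness_flag`.
#' @export
shared_mutated_genes <- function(cohort, manifest, subgroup, cfg,
                                 deafness_panel = NULL,
                                 exclusion_panel = NULL) {
  members <- subgroup_members(manifest, subgroup)
  if (length(members) < 2) stop("subgroup has fewer than 2 members: ", subgroup)
  hits <- passing_hits(cohort, cfg)
  hits <- hits[hits$sample_id %in% members & !is.na(hits$gene), ]
  if (nrow(hits) == 0) {
    return(tibble::tibble(gene = character(), subgroup = character(),
                          n_distinct_variants = integer(),
                          variant_types = character(),
                          exclusion_flag = logical(),
                          deafness_flag = logical()))
  }
  per_gene <- dplyr::summarise(
    dplyr::group_by(hits, .data$gene),
    n_members = length(unique(.data$sample_id)),
    n_distinct_variants = length(unique(.data$key)),
    variant_types = summarise_types(
      .data$consequence[!duplicated(.data$key)]),
    .groups = "drop"
  )
  shared <- per_gene[per_gene$n_members == length(members), ]
  shared <- shared[order(shared$gene), ]
  tibble::tibble(
    gene = shared$gene,
    subgroup = subgroup,
    n_distinct_variants = shared$n_distinct_variants,
    variant_types = shared$variant_types,
    exclusion_flag = flag_in(shared$gene, exclusion_panel),
    deafness_flag = flag_in(shared$gene, deafness_panel)
  )
}

#' Genes recurrently mutated across individuals
#'
#' Genes bearing passing variants (any zygosity; heterozygous included) in
#' at least `min_individuals` distinct samples, ordered by descending
#' carrier count then gene symbol — the Table-2-style recurrence screen,
#' conventionally run at the very-rare preset.
#'
#' @inheritParams shared_mutated_genes
#' @param min_individuals Minimum number of distinct carriers (default 2).
#' @return Tibble: `gene`, `n_individuals`, `sample_ids` (comma-joined,
#'   sorted), `deafness_flag`, `exclusion_flag`.
#' @export
recurrent_genes <- function(cohort, cfg, min_individuals = 2,
                            deafness_panel = NULL, exclusion_panel = NULL) {
  hits <- passing_hits(cohort, cfg)
  hits <- hits[!is.na(hits$gene), ]
  per_gene <- dplyr::summarise(
    dplyr::group_by(hits, .data$gene),
    n_individuals = length(unique(.data$sample_id)),
    sample_ids = paste(sort(unique(.data$sample_id)), collapse = ","),
    .groups = "drop"
  )
  rec <- per_gene[per_gene$n_individuals >= min_individuals, ]
  rec <- rec[order(-rec$n_individuals, rec$gene), ]
  tibble::tibble(
    gene = rec$gene,
    n_individuals = rec$n_individuals,
    sample_ids = rec$sample_ids,
    deafness_flag = flag_in(rec$gene, deafness_panel),
    exclusion_flag = flag_in(rec$gene, exclusion_panel)
  )
}

#' Identical variants shared across individuals
#'
#' Exact (chrom, pos, ref, alt) matches carried by at least
#' `min_individuals` distinct samples. Same position with a different
#' alternate allele is never merged.
#'
#' @inheritParams recurrent_genes
#' @return Tibble: `key`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `n_individuals`, `sample_ids`, sorted by descending carrier count then
#'   key.
#' @export
recurrent_identical_variants <- function(cohort, cfg, min_individuals = 2) {
  hits <- passing_hits(cohort, cfg)
  hits <- hits[!duplicated(hits[c("key", "sample_id")]), ]
  per_var <- dplyr::summarise(
    dplyr::group_by(hits, .data$key, .data$chrom, .data$pos, .data$ref,
                    .data$alt, .data$gene),
    n_individuals = length(unique(.data$sample_id)),
    sample_ids = paste(sort(unique(.data$sample_id)), collapse = ","),
    .groups = "drop"
  )
  rec <- per_var[per_var$n_individuals >= min_individuals, ]
  rec[order(-rec$n_individuals, rec$key), ]
}

#' Apparently-homozygous passing variants
#'
#' Passing variants called homozygous for the alternate allele,
#' conventionally at the very-rare preset. "Apparently" because short-read
#' calls cannot distinguish true homozygosity from hemizygosity or an
#' overlapping deletion; X-linked genes in males are also
#' hemizygous-compatible, and sample sex is not modelled here, so every
#' record carries the caveat.
#'
#' @inheritParams recurrent_genes
#' @return A list with `records` (tibble: `sample_id`, `key`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`), `multi_person_genes` (tibble of genes
#'   homozygous-mutated in two or more people: `gene`, `n_individuals`) and
#'   `caveat` (the apparently-homozygous note).
#' @export
homozygous_rare <- function(cohort, cfg) {
  pv <- passing_variants(cohort, cfg)
  hom <- cohort$genotypes[cohort$genotypes$zygosity == "homozygous_alt", ]
  hits <- dplyr::inner_join(hom, pv, by = "key", relationship = "many-to-many")
  records <- hits[order(hits$sample_id, hits$key),
                  c("sample_id", "key", "chrom", "pos", "ref", "alt", "gene")]
  records <- tibble::as_tibble(records)
  by_gene <- dplyr::summarise(
    dplyr::group_by(records[!is.na(records$gene), ], .data$gene),
    n_individuals = length(unique(.data$sample_id)), .groups = "drop"
  )
  multi <- by_gene[by_gene$n_individuals >= 2, ]
  multi <- multi[order(-multi$n_individuals, multi$gene), ]
  list(
    records = records,
    multi_person_genes = multi,
    caveat = paste("apparently-homozygous: hemizygosity or an overlapping",
                   "deletion cannot be excluded; sample sex unknown")
  )
}

#' Multi-variant genes within one individual
#'
#' Per (sample, gene) pairs carrying at least `min_variants` passing
#' variants — candidate compound heterozygotes when the variants are in
#' trans, or a single heavily-mutated allele when in cis. Two variants are
#' `confirmed` to share a chromosome only when they lie within
#' `read_window` base pairs (close enough to fall within one sequencing
#' read) *and* phased genotypes place them on the same haplotype; phased
#' genotypes on opposite haplotypes within the window give `refuted`;
#' otherwise the evidence is `unknown`.
#'
#' @inheritParams recurrent_genes
#' @param min_variants Minimum passing variants per (sample, gene),
#'   default 2.
#' @param read_window Maximum distance (bp) for two variants to be covered
#'   by one read; default 100.
#' @return Tibble: `sample_id`, `gene`, `n_variants`, `zygosities`
#'   (comma-joined in position order), `same_chromosome_evidence`.
#' @export
multi_hit_genes <- function(cohort, cfg, min_variants = 2, read_window = 100) {
  hits <- passing_hits(cohort, cfg)
  hits <- hits[!is.na(hits$gene), ]
  hits <- hits[!duplicated(hits[c("key", "sample_id", "gene")]), ]
  grp <- dplyr::group_by(hits, .data$sample_id, .data$gene)
  out <- dplyr::summarise(
    grp,
    n_variants = dplyr::n(),
    zygosities = paste(.data$zygosity[order(.data$pos)], collapse = ","),
    same_chromosome_evidence = phase_evidence(
      .data$pos[order(.data$pos)], .data$haplotype[order(.data$pos)],
      read_window),
    .groups = "drop"
  )
  out <- out[out$n_variants >= min_variants, ]
  out[order(out$sample_id, out$gene), ]
}

# Evidence that two of the variants share a chromosome: confirmed when a
# within-window pair is phased onto the same haplotype, refuted when phased
# onto opposite haplotypes, else unknown.
phase_evidence <- function(pos, haplotype, read_window) {
  if (length(pos) < 2) return("unknown")
  evidence <- "unknown"
  for (i in seq_len(length(pos) - 1)) {
    j <- i + 1
    if (pos[j] - pos[i] <= read_window &&
        !is.na(haplotype[i]) && !is.na(haplotype[j])) {
      if (haplotype[i] == haplotype[j]) return("confirmed")
      evidence <- "refuted"
    }
  }
  evidence
}

#' Passing variants in candidate genes
#'
#' Looks up all passing variants in a candidate panel (e.g. the strongest
#' GWAS candidate genes for the phenotype) with their carrier lists.
#'
#' @inheritParams recurrent_genes
#' @param candidate_genes A nonempty [gene_panel()].
#' @return Tibble, one row per variant: `gene`, `key`, `chrom`, `pos`,
#'   `ref`, `alt`, `consequence`, `n_individuals`, `sample_ids`,
#'   `zygosities` (aligned with `sample_ids`).
#' @export
candidate_lookup <- function(cohort, cfg, candidate_genes) {
  if (length(candidate_genes$genes) == 0) stop("candidate panel is empty")
  hits <- passing_hits(cohort, cfg)
  hits <- hits[!is.na(hits$gene) & hits$gene %in% candidate_genes$genes, ]
  hits <- hits[!duplicated(hits[c("key", "sample_id")]), ]
  out <- dplyr::summarise(
    dplyr::group_by(hits, .data$gene, .data$key, .data$chrom, .data$pos,
                    .data$ref, .data$alt, .data$consequence),
    n_individuals = length(unique(.data$sample_id)),
    sample_ids = paste(.data$sample_id[order(.data$sample_id)], collapse = ","),
    zygosities = paste(.data$zygosity[order(.data$sample_id)], collapse = ","),
    .groups = "drop"
  )
  out[order(out$gene, out$key), ]
}
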