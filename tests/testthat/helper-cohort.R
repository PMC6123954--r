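# Builders for small hand-made cohorts. Each variant row is specified per
# carrier; identical (chrom, pos, ref, alt) across carriers describe one
# shared variant. Predictor verdicts are given as a 3-character code over
# three predictors: D = deleterious, B = benign, U = unknown, . = no call.

tc_row <- function(sample, gene, maf = 1e-4, csq = "missense",
                   zyg = "heterozygous", pos = NA, chrom = "chr1",
                   preds = "DDD", qual = 99, dp = 100, mq = 60,
                   hap = NA, ref = "A", alt = "G",
                   maf_eur = NA, maf_afr = NA) {
  list(sample = sample, gene = gene, maf = maf, csq = csq, zyg = zyg,
       pos = pos, chrom = chrom, preds = preds, qual = qual, dp = dp,
       mq = mq, hap = hap, ref = ref, alt = alt, maf_eur = maf_eur,
       maf_afr = maf_afr)
}

build_cohort <- function(rows, samples = NULL) {
  decode <- function(code, j) {
    ch <- substr(code, j, j)
    switch(ch, D = "deleterious", B = "benign", U = "unknown", NA_character_)
  }
  pos_counter <- 0L
  recs <- lapply(rows, function(r) {
    pos_counter <<- pos_counter + 10L
    pos <- if (is.na(r$pos)) pos_counter else r$pos
    tibble::tibble(
      sample_id = r$sample, gene = toupper(r$gene), chrom = r$chrom,
      pos = as.integer(pos), ref = r$ref, alt = r$alt,
      site_quality = r$qual, read_depth = as.numeric(r$dp),
      mapping_quality = r$mq, consequence = r$csq,
      maf_nfe = r$maf, maf_eur = r$maf_eur, maf_afr = r$maf_afr,
      pred_p1 = decode(r$preds, 1), pred_p2 = decode(r$preds, 2),
      pred_p3 = decode(r$preds, 3),
      zygosity = r$zyg, haplotype = as.integer(r$hap)
    )
  })
  tall <- dplyr::bind_rows(recs)
  key <- exoburden::variant_key(tall$chrom, tall$pos, tall$ref, tall$alt)
  variants <- tall[!duplicated(key),
                   setdiff(names(tall), c("sample_id", "zygosity", "haplotype"))]
  genotypes <- tibble::tibble(
    key = key, sample_id = tall$sample_id, zygosity = tall$zygosity,
    haplotype = tall$haplotype
  )
  exome_cohort(variants, genotypes,
               samples %||na_null% unique(tall$sample_id))
}

`%||na_null%` <- function(a, b) if (is.null(a)) b else a

small_manifest <- function(...) {
  groups <- list(...)
  tibble::tibble(
    sample_id = unlist(groups, use.names = FALSE),
    subgroup = rep(names(groups), lengths(groups))
  )
}

# A compact synthetic-cohort configuration for property suites: small enough
# to generate dozens of replicates quickly while exercising every feature.
small_sim_config <- function(seed, ...) {
  args <- list(
    seed = seed,
    subgroup_sizes = c(GroupA = 3, GroupB = 3),
    n_background_genes = 120,
    panel_spec = list(deafness = 40, dominant = 5, retinal = 15,
                      exclusion = 30, gwas = 4, exclusion_overlap = 5),
    per_gene_hit_prob = 0.15,
    planted_min_panel_hits = 3,
    planted_recurrent_variants = 2,
    planted_homozygotes = 1
  )
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}
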