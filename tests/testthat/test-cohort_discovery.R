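deafness <- gene_panel("deafness", c("GJB2", "WFS1", "GPR98"))
exclusion <- gene_panel("excl", "TTN", is_exclusion_list = TRUE)

test_that("subgroup-shared genes require every member and summarise types", {
  rows <- list(
    # NEDD4 in all five sensory members, two distinct missense variants
    tc_row("S1", "NEDD4", maf = 0.03, pos = 100),
    tc_row("S2", "NEDD4", maf = 0.03, pos = 100),
    tc_row("S3", "NEDD4", maf = 0.03, pos = 100),
    tc_row("S4", "NEDD4", maf = 0.05, pos = 200),
    tc_row("S5", "NEDD4", maf = 0.05, pos = 200),
    # ALMOST in four of five members only
    tc_row("S1", "ALMOST", pos = 300), tc_row("S2", "ALMOST", pos = 300),
    tc_row("S3", "ALMOST", pos = 300), tc_row("S4", "ALMOST", pos = 300),
    # TTN (exclusion candidate) in both recessive members
    tc_row("R1", "TTN", maf = 0.02, pos = 400),
    tc_row("R2", "TTN", maf = 0.04, pos = 500, csq = "inframe_indel")
  )
  co <- build_cohort(rows)
  manifest <- small_manifest(Sensory = paste0("S", 1:5),
                             Recessive = c("R1", "R2"))
  cfg <- filter_preset("common")
  shared <- shared_mutated_genes(co, manifest, "Sensory", cfg,
                                 deafness_panel = deafness,
                                 exclusion_panel = exclusion)
  expect_equal(shared$gene, "NEDD4")
  expect_equal(shared$subgroup, "Sensory")
  expect_equal(shared$n_distinct_variants, 2L)
  expect_equal(shared$variant_types, "2 Non-synonymous")
  expect_false(shared$exclusion_flag)

  rec <- shared_mutated_genes(co, manifest, "Recessive", cfg,
                              exclusion_panel = exclusion)
  expect_equal(rec$gene, "TTN")
  expect_true(rec$exclusion_flag)
  expect_equal(rec$variant_types, "1 In-frame indel, 1 Non-synonymous")

  expect_error(shared_mutated_genes(co, manifest, "Metabolic", cfg),
               "unknown subgroup")
})

test_that("recurrent genes match brute-force per-gene carrier counting", {
  sim <- generate_cohort(small_sim_config(501))
  cfg <- filter_preset("very_rare")
  rec <- recurrent_genes(sim$cohort, cfg, min_individuals = 2)

  # brute force: for each gene, count distinct carriers of passing variants
  pass_keys <- unique(passing_keys(sim$cohort, cfg))
  g <- sim$cohort$genotypes
  g <- g[g$zygosity %in% c("heterozygous", "homozygous_alt") &
           g$key %in% pass_keys, ]
  va <- sim$cohort$variants
  counts <- new.env()
  for (i in seq_len(nrow(g))) {
    gene <- va$gene[match(g$key[i], va$key)]
    if (is.na(gene)) next
    prev <- if (is.null(counts[[gene]])) character() else counts[[gene]]
    counts[[gene]] <- union(prev, g$sample_id[i])
  }
  brute <- Filter(function(s) length(s) >= 2, as.list(counts))
  expect_setequal(rec$gene, names(brute))
  expect_equal(rec$n_individuals,
               vapply(brute[rec$gene], length, 0L), ignore_attr = TRUE)
  # ordering: descending carrier count, then gene symbol
  expect_false(is.unsorted(rev(rec$n_individuals)))
  expect_true(all(diff(order(-rec$n_individuals, rec$gene)) == 1))
})

test_that("recurrent gene screen excludes single-carrier genes", {
  co <- build_cohort(list(
    tc_row("P1", "GPR98", pos = 10), tc_row("P2", "GPR98", pos = 20),
    tc_row("P1", "WFS1", pos = 30)
  ))
  rec <- recurrent_genes(co, filter_preset("very_rare"), min_individuals = 2,
                         deafness_panel = deafness)
  expect_equal(rec$gene, "GPR98")
  expect_equal(rec$n_individuals, 2L)
  expect_true(rec$deafness_flag)
})

test_that("identical-variant recurrence merges exact allele matches only", {
  co <- build_cohort(list(
    tc_row("P1", "GJB2", pos = 100, alt = "G"),
    tc_row("P2", "GJB2", pos = 100, alt = "G"),
    tc_row("P3", "GJB2", pos = 100, alt = "T"),  # same site, different alt
    tc_row("P4", "WFS1", pos = 200)
  ))
  rec <- recurrent_identical_variants(co, filter_preset("very_rare"))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$key, "chr1:100:A:G")
  expect_equal(rec$sample_ids, "P1,P2")
})

test_that("apparently-homozygous records are reported with the multi-person section", {
  het_only <- build_cohort(list(tc_row("P1", "GJB2"), tc_row("P2", "WFS1")))
  expect_equal(nrow(homozygous_rare(het_only, filter_preset("very_rare"))$records), 0)

  co <- build_cohort(list(
    tc_row("P1", "ZAN", zyg = "homozygous_alt", pos = 10),
    tc_row("P2", "ZAN", zyg = "homozygous_alt", pos = 20),
    tc_row("P3", "SOLO", zyg = "homozygous_alt", pos = 30),
    tc_row("P3", "HETG", pos = 40)
  ))
  hom <- homozygous_rare(co, filter_preset("very_rare"))
  expect_equal(nrow(hom$records), 3)
  expect_setequal(hom$records$gene, c("ZAN", "SOLO"))
  expect_equal(hom$multi_person_genes$gene, "ZAN")
  expect_equal(hom$multi_person_genes$n_individuals, 2L)
  expect_match(hom$caveat, "hemizygosity")
})

test_that("multi-variant genes report counts and phase evidence", {
  co <- build_cohort(list(
    # five variants in WFS1 in one individual
    tc_row("P1", "WFS1", pos = 100), tc_row("P1", "WFS1", pos = 300),
    tc_row("P1", "WFS1", pos = 500), tc_row("P1", "WFS1", pos = 700),
    tc_row("P1", "WFS1", pos = 900),
    # two variants 40 bp apart phased in cis
    tc_row("P2", "GPR98", pos = 1000, hap = 1),
    tc_row("P2", "GPR98", pos = 1040, hap = 1),
    # two variants 40 bp apart phased in trans
    tc_row("P3", "GJB2", pos = 2000, hap = 1),
    tc_row("P3", "GJB2", pos = 2040, hap = 2),
    # distant unphased pair
    tc_row("P4", "OTOF", pos = 3000), tc_row("P4", "OTOF", pos = 9000),
    # single hits in two different genes: no record
    tc_row("P5", "TECTA", pos = 4000), tc_row("P5", "MYO6", pos = 5000)
  ))
  mh <- multi_hit_genes(co, filter_preset("very_rare"))
  expect_equal(mh$n_variants[mh$sample_id == "P1" & mh$gene == "WFS1"], 5L)
  expect_equal(mh$same_chromosome_evidence[mh$sample_id == "P2"], "confirmed")
  expect_equal(mh$same_chromosome_evidence[mh$sample_id == "P3"], "refuted")
  expect_equal(mh$same_chromosome_evidence[mh$sample_id == "P4"], "unknown")
  expect_false("P5" %in% mh$sample_id)
})

test_that("candidate lookup lists carriers per variant for the packaged panel", {
  gwas <- packaged_panels()$gwas
  expect_equal(length(gwas$genes), 8)
  co <- build_cohort(list(
    tc_row("P1", "ACAN", pos = 10), tc_row("P2", "ACAN", pos = 10),
    tc_row("P3", "GRM7", pos = 20, csq = "frameshift_indel", preds = "..."),
    tc_row("P4", "NOTGWAS", pos = 30)
  ))
  found <- candidate_lookup(co, filter_preset("very_rare"), gwas)
  expect_equal(nrow(found), 2)
  acan <- found[found$gene == "ACAN", ]
  expect_equal(acan$n_individuals, 2L)
  expect_equal(acan$sample_ids, "P1,P2")

  none <- build_cohort(list(tc_row("P1", "NOTGWAS")))
  expect_equal(nrow(candidate_lookup(none, filter_preset("very_rare"), gwas)), 0)
})

test_that("subgroup-shared genes are a subset of recurrence at subgroup size", {
  sim <- generate_cohort(small_sim_config(502))
  cfg <- filter_preset("common")
  manifest <- sim$manifest
  for (sg in unique(manifest$subgroup)) {
    members <- manifest$sample_id[manifest$subgroup == sg]
    shared <- shared_mutated_genes(sim$cohort, manifest, sg, cfg)
    sub_cohort <- exome_cohort(
      sim$cohort$variants,
      sim$cohort$genotypes[sim$cohort$genotypes$sample_id %in% members, ],
      members
    )
    rec <- recurrent_genes(sub_cohort, cfg, min_individuals = length(members))
    expect_true(all(shared$gene %in% rec$gene))
  }
})

test_that("discovery output is invariant to input record order", {
  sim <- generate_cohort(small_sim_config(503))
  co <- sim$cohort
  set.seed(1)
  shuffled <- exome_cohort(
    co$variants[sample.int(nrow(co$variants)), ],
    co$genotypes[sample.int(nrow(co$genotypes)), ],
    co$samples
  )
  cfg <- filter_preset("very_rare")
  expect_equal(recurrent_genes(shuffled, cfg), recurrent_genes(co, cfg))
  expect_equal(recurrent_identical_variants(shuffled, cfg),
               recurrent_identical_variants(co, cfg))
  expect_equal(multi_hit_genes(shuffled, cfg), multi_hit_genes(co, cfg))
})
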