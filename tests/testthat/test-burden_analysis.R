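deaf_panel <- gene_panel("deafness", c("GJB2", "MYO6", "WFS1", "HOMER2"),
                         dominant_subset = c("MYO6", "HOMER2", "WFS1"))
excl_panel <- gene_panel("excl", c("TTN"), is_exclusion_list = TRUE)

test_that("genes_hit counts distinct panel genes and respects the MAF gate", {
  co <- build_cohort(list(
    tc_row("P1", "GJB2", maf = 0.001),
    tc_row("P1", "GJB2", maf = 0.002),
    tc_row("P1", "MYO6", maf = 0.001, zyg = "homozygous_alt"),
    tc_row("P1", "OTHER", maf = 0.001),       # off-panel
    tc_row("P2", "WFS1", maf = 0.3),          # fails MAF gate
    tc_row("P2", "GJB2", maf = 0.001, zyg = "missing")  # not a carrier
  ))
  cfg <- filter_preset("common")
  expect_equal(genes_hit(co, "P1", deaf_panel, cfg)$gene, c("GJB2", "MYO6"))
  expect_equal(nrow(genes_hit(co, "P2", deaf_panel, cfg)), 0)
  expect_error(genes_hit(co, "P99", deaf_panel, cfg), "unknown sample")
})

test_that("burden histogram accounts for every individual, carriers and zeros", {
  co <- build_cohort(list(
    tc_row("P1", "GJB2"), tc_row("P1", "MYO6"),
    tc_row("P2", "GJB2"),
    tc_row("P3", "OTHER")
  ), samples = c("P1", "P2", "P3", "P4"))
  bd <- burden_distribution(co, deaf_panel, filter_preset("common"))
  expect_equal(unname(bd$per_individual[c("P1", "P2", "P3", "P4")]),
               c(2L, 1L, 0L, 0L))
  expect_equal(sum(bd$histogram), length(co$samples))
  expect_equal(bd$carrier_count, length(co$samples) - bd$histogram[["0"]])
  expect_equal(bd$carrier_count, 2)
})

test_that("tightening the vote tier never raises any individual burden", {
  sim <- generate_cohort(small_sim_config(77))
  cfg_major <- filter_preset("common")
  cfg_all <- filter_preset("common", vote_mode = "all")
  cfg_lof <- filter_preset("common", vote_mode = "lof_only")
  panel <- sim$panels$deafness
  b1 <- burden_distribution(sim$cohort, panel, cfg_major)$per_individual
  b2 <- burden_distribution(sim$cohort, panel, cfg_all)$per_individual
  b3 <- burden_distribution(sim$cohort, panel, cfg_lof)$per_individual
  expect_true(all(b2 <= b1))
  expect_true(all(b3 <= b2))
})

test_that("burden is invariant to variant ordering and nested for subset panels", {
  sim <- generate_cohort(small_sim_config(78))
  co <- sim$cohort
  cfg <- filter_preset("common")
  shuffled <- exome_cohort(
    co$variants[rev(seq_len(nrow(co$variants))), ],
    co$genotypes[sample.int(nrow(co$genotypes)), ],
    co$samples
  )
  expect_equal(burden_distribution(shuffled, sim$panels$deafness, cfg)$per_individual,
               burden_distribution(co, sim$panels$deafness, cfg)$per_individual)

  dom <- gene_panel("dom", sim$panels$deafness$dominant_subset)
  full <- burden_distribution(co, sim$panels$deafness, cfg)$per_individual
  sub <- burden_distribution(co, dom, cfg)$per_individual
  expect_true(all(sub <= full))
})

test_that("raising the MAF threshold never decreases the carrier count", {
  sim <- generate_cohort(small_sim_config(79))
  carriers <- vapply(c(0.0005, 0.005, 0.01, 0.10), function(t) {
    cfg <- filter_preset("common", maf_threshold = t)
    burden_distribution(sim$cohort, sim$panels$deafness, cfg)$carrier_count
  }, 0)
  expect_true(all(diff(carriers) >= 0))
})

test_that("exclusion-candidate genes are flagged, and removable by switch", {
  co <- build_cohort(list(
    tc_row("P1", "TTN"), tc_row("P1", "GJB2")
  ))
  panel <- gene_panel("mixed", c("TTN", "GJB2"))
  cfg <- filter_preset("common")
  hits <- genes_hit(co, "P1", panel, cfg, exclusion_panel = excl_panel)
  expect_equal(hits$exclusion_candidate, c(FALSE, TRUE))
  with_excl <- burden_distribution(co, panel, cfg, exclusion_panel = excl_panel)
  without <- burden_distribution(co, panel, cfg, exclusion_panel = excl_panel,
                                 drop_exclusion = TRUE)
  expect_equal(unname(with_excl$per_individual["P1"]), 2L)
  expect_equal(unname(without$per_individual["P1"]), 1L)
})

test_that("dominant carrier summary separates any-pathogenic from LoF carriers", {
  co <- build_cohort(list(
    tc_row("P1", "MYO6", csq = "frameshift_indel", preds = "..."),
    tc_row("P2", "WFS1", csq = "missense", preds = "DDD"),
    tc_row("P3", "GJB2", csq = "missense", preds = "DDD")  # not dominant subset
  ))
  s <- dominant_carrier_summary(co, deaf_panel, filter_preset("common"))
  expect_equal(s$n_cohort, 3)
  expect_equal(s$n_with_any_pathogenic, 2)
  expect_equal(s$n_with_lof, 1)
  expect_true(s$n_with_lof <= s$n_with_any_pathogenic)

  empty <- gene_panel("none", "GJB2")
  s0 <- dominant_carrier_summary(co, empty, filter_preset("common"))
  expect_equal(s0$n_with_any_pathogenic, 0)
  expect_equal(s0$n_with_lof, 0)
})

test_that("planted LoF carriers in the generator are counted exactly", {
  sim <- generate_cohort(small_sim_config(80))
  truth <- sim$truth$variant_truth
  lof_set <- lof_classes
  co <- sim$cohort
  lof_keys <- co$variants$key[co$variants$consequence %in% lof_set]
  cfg <- filter_preset("common", vote_mode = "lof_only")
  expected_carriers <- unique(
    truth$sample_id[truth$pass_common &
                      variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
                    %in% lof_keys &
                      truth$gene %in% sim$panels$deafness$genes]
  )
  bd <- burden_distribution(co, sim$panels$deafness, cfg)
  expect_equal(bd$carrier_count, length(expected_carriers))
})

test_that("distribution comparison is symmetric and detects a shift", {
  mk <- function(counts) {
    structure(list(panel_name = "p", tier = "majority", maf_threshold = 0.1,
                   per_individual = stats::setNames(counts, paste0("S", seq_along(counts))),
                   histogram = table(counts),
                   carrier_count = sum(counts > 0)),
              class = "burden_distribution")
  }
  set.seed(5)
  x <- rpois(50, 12)
  a <- mk(x); b <- mk(x + 5)
  same <- compare_distributions(a, a)
  expect_gte(same$p_value, 0.99)
  cmp_ab <- compare_distributions(a, b)
  cmp_ba <- compare_distributions(b, a)
  expect_lt(cmp_ab$p_value, 0.01)
  expect_equal(cmp_ab$p_value, cmp_ba$p_value)
  # permutation check of the shift's significance
  pooled <- c(x, x + 5)
  obs <- mean(x + 5) - mean(x)
  perm <- replicate(499, {
    idx <- sample.int(100, 50)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  expect_lt(mean(abs(perm) >= abs(obs)), 0.01)
  empty_bd <- structure(list(per_individual = numeric()),
                        class = "burden_distribution")
  expect_error(compare_distributions(empty_bd, a), "empty")
})
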