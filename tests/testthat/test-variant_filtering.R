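test_that("quality gate applies inclusive thresholds and honours the off switch", {
  v <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "G", gene = "G1",
    consequence = "missense",
    site_quality = c(29, 30, 99, NA),
    read_depth = c(20, 20, 100, 50),
    mapping_quality = c(45, 45, 60, 50)
  )
  cfg <- filter_config()
  expect_equal(quality_gate(v, cfg), c(FALSE, TRUE, TRUE, FALSE))
  cfg_off <- filter_config(quality_gate_enabled = FALSE)
  expect_equal(quality_gate(v, cfg_off), rep(TRUE, 4))
  out <- filter_variant(v, cfg)
  expect_match(out$failed_stages[1], "quality")
  expect_match(out$failed_stages[4], "quality:missing", fixed = TRUE)
})

test_that("MAF resolution prefers primary, then fallback, then novel", {
  v <- tibble::tibble(
    chrom = "chr1", pos = 1:3, ref = "A", alt = "G", gene = "G1",
    consequence = "missense",
    maf_nfe = c(0.003, NA, NA),
    maf_eur = c(0.02, 0.02, NA)
  )
  r <- resolve_maf(v, filter_config())
  expect_equal(r$effective_maf, c(0.003, 0.02, 0))
  expect_equal(r$maf_source, c("primary", "fallback", "novel"))
})

test_that("MAF gate comparator is inclusive or strict per configuration", {
  inclusive <- filter_config(maf_threshold = 0.10, maf_inclusive = TRUE)
  strict <- filter_config(maf_threshold = 0.005, maf_inclusive = FALSE)
  expect_true(maf_gate(0.10, inclusive))
  expect_false(maf_gate(0.1000001, inclusive))
  expect_true(maf_gate(0.003, strict))
  expect_false(maf_gate(0.005, strict))
  expect_false(maf_gate(0.02, strict))
  # novel variants (effective MAF 0) pass every gate
  expect_true(maf_gate(0, strict))
})

test_that("cross-population flag marks variants common elsewhere, informationally", {
  v <- tibble::tibble(
    chrom = "chr1", pos = 1:3, ref = "T", alt = "C", gene = "LPP",
    consequence = "missense",
    maf_nfe = c(0.003, 0.05, 0.002),
    maf_afr = c(0.60, 0.10, NA),
    pred_p1 = "deleterious", pred_p2 = "deleterious"
  )
  cfg <- filter_preset("very_rare", quality_gate_enabled = FALSE)
  expect_equal(flag_cross_population(v, cfg), c(TRUE, FALSE, FALSE))
  # the flag never filters: the rare-in-primary variant still passes
  out <- filter_variant(v, cfg)
  expect_true(out$pass[1])
  expect_true(out$cross_population_common[1])
})

test_that("consequence gate retains LoF plus missense-grade classes by default", {
  cfg <- filter_config()
  v <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "G", gene = "G1",
    consequence = c("missense", "inframe_indel", "synonymous", "stop_gained")
  )
  expect_equal(consequence_gate(v, cfg), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("tier voting matches the stated rules on hand cases", {
  v <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "G", gene = "G1",
    consequence = c("stop_gained", "missense", "missense", "missense"),
    pred_p1 = c(NA, "deleterious", "deleterious", NA),
    pred_p2 = c(NA, "deleterious", "unknown", NA),
    pred_p3 = c(NA, "benign", "unknown", NA),
    pred_p4 = c(NA, "deleterious", NA, NA),
    pred_p5 = c(NA, "benign", NA, NA)
  )
  t <- pathogenicity_tiers(v)
  # LoF with no predictor calls passes everything
  expect_equal(unlist(t[1, ]), c(majority = TRUE, all = TRUE, lof_only = TRUE))
  # 3 deleterious of 5 informative: majority only
  expect_equal(unlist(t[2, ]), c(majority = TRUE, all = FALSE, lof_only = FALSE))
  # one informative deleterious call among unknowns: majority and all
  expect_equal(unlist(t[3, ]), c(majority = TRUE, all = TRUE, lof_only = FALSE))
  # no informative calls, non-LoF: fails both voting tiers
  expect_equal(unlist(t[4, ]), c(majority = FALSE, all = FALSE, lof_only = FALSE))
})

test_that("tier voting agrees with enumeration of every call vector up to length 5", {
  verdicts <- c("deleterious", "benign", "unknown")
  for (len in 0:5) {
    grid <- if (len == 0) {
      list(character())
    } else {
      g <- expand.grid(rep(list(verdicts), len), stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i) unlist(g[i, ], use.names = FALSE))
    }
    for (calls in grid) {
      v <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                          gene = "G1", consequence = "missense")
      for (j in seq_len(5)) {
        v[[paste0("pred_p", j)]] <- if (j <= len) calls[j] else NA_character_
      }
      got <- pathogenicity_tiers(v)
      n_inf <- sum(calls != "unknown")
      n_del <- sum(calls == "deleterious")
      expect_equal(got$majority, n_del > n_inf / 2)
      expect_equal(got$all, n_inf > 0 && n_del == n_inf)
      expect_false(got$lof_only)
    }
  }
})

test_that("composed filter passes rare LoF and records every failing stage", {
  v <- tibble::tibble(
    chrom = "chr1", pos = 1:2, ref = "A", alt = "G", gene = "G1",
    consequence = c("frameshift_indel", "missense"),
    site_quality = c(60, 60), read_depth = c(50, 50),
    mapping_quality = c(55, 55),
    maf_nfe = c(0.002, 0.15),
    pred_p1 = c(NA, "deleterious"), pred_p2 = c(NA, "deleterious"),
    pred_p3 = c(NA, "deleterious")
  )
  cfg <- filter_preset("common")
  out <- filter_variant(v, cfg)
  expect_true(out$pass[1])
  expect_identical(out$failed_stages[1], "")
  expect_false(out$pass[2])
  expect_identical(out$failed_stages[2], "maf")
})

test_that("filter agrees exactly with the straight-line oracle on a random batch", {
  rv <- random_variants(200, seed = 42)
  for (preset in c("common", "very_rare")) {
    cfg <- filter_preset(preset)
    expect_true(oracle_agrees(rv, cfg), info = preset)
  }
  cfg_off <- filter_preset("common", quality_gate_enabled = FALSE)
  expect_true(oracle_agrees(rv, cfg_off))
})

test_that("pass sets are monotone in the MAF threshold and nested across tiers", {
  rv <- random_variants(400, seed = 7)
  tiers <- c(0.0005, 0.005, 0.01, 0.10)
  prev <- NULL
  for (t in tiers) {
    cfg <- filter_config(maf_threshold = t, maf_inclusive = TRUE)
    pass <- filter_variant(rv$tbl, cfg)$pass
    if (!is.null(prev)) expect_true(all(pass | !prev))  # prev subset of pass
    prev <- pass
  }
  out <- filter_variant(rv$tbl, filter_config())
  expect_true(all(out$tier_majority | !out$tier_all))
  expect_true(all(out$tier_all | !out$tier_lof_only))
})

test_that("disabling the quality gate never shrinks the pass set", {
  rv <- random_variants(400, seed = 11)
  on <- filter_variant(rv$tbl, filter_preset("common"))$pass
  off <- filter_variant(rv$tbl,
                        filter_preset("common", quality_gate_enabled = FALSE))$pass
  expect_true(all(off | !on))
})
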