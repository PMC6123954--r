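# Independent straight-line re-implementation of the filtering rules,
# written against the rule statements (not the package code), used as the
# brute-force oracle. Operates on one plain-list variant at a time.

oracle_lof_set <- c("transcript_ablation", "essential_splice_site",
                    "frameshift_indel", "stop_gained", "start_lost")

# v: list(site_quality, read_depth, mapping_quality, consequence,
#         freqs = named numeric (NA allowed), preds = character verdicts)
oracle_filter_one <- function(v, cfg) {
  # stage 1: quality
  if (!cfg$quality_gate_enabled) {
    qual <- TRUE
  } else if (is.na(v$site_quality) || is.na(v$read_depth) ||
             is.na(v$mapping_quality)) {
    qual <- FALSE
  } else {
    qual <- (v$site_quality >= cfg$min_site_quality) &&
      (v$read_depth >= cfg$min_depth) &&
      (v$mapping_quality >= cfg$min_mapping_quality)
  }

  # stage 2: MAF with primary -> fallback -> novel resolution
  eff <- 0
  p <- v$freqs[cfg$primary_population]
  fb <- v$freqs[cfg$fallback_population]
  if (length(p) == 1 && !is.na(p)) {
    eff <- unname(p)
  } else if (length(fb) == 1 && !is.na(fb)) {
    eff <- unname(fb)
  }
  maf_ok <- if (cfg$maf_inclusive) eff <= cfg$maf_threshold else eff < cfg$maf_threshold

  # stage 3: consequence severity
  csq_ok <- v$consequence %in% cfg$retained_consequences

  # stage 4: vote tiers
  lof <- v$consequence %in% oracle_lof_set
  n_del <- 0L
  n_inf <- 0L
  for (call in v$preds) {
    if (is.na(call) || call == "unknown") next
    n_inf <- n_inf + 1L
    if (call == "deleterious") n_del <- n_del + 1L
  }
  tier <- list(
    majority = lof || (n_inf > 0L && n_del > n_inf / 2),
    all = lof || (n_inf > 0L && n_del == n_inf),
    lof_only = lof
  )
  list(pass = qual && maf_ok && csq_ok && tier[[cfg$vote_mode]],
       qual = qual, maf_ok = maf_ok, csq_ok = csq_ok,
       effective_maf = eff, tier = tier)
}

# Random annotated variants exercising the rule edge cases: missing metrics,
# boundary frequencies, empty/uninformative predictor sets, every
# consequence class. Returns a variants tibble plus the parallel plain-list
# representation for the oracle.
random_variants <- function(n, seed = NULL, n_predictors = 4) {
  if (!is.null(seed)) set.seed(seed)
  boundary <- c(0.10, 0.01, 0.005, 0.0005)
  draw_freq <- function(n) {
    u <- runif(n)
    f <- exp(runif(n, log(1e-6), log(0.9)))
    f[u < 0.15] <- sample(boundary, sum(u < 0.15), replace = TRUE)
    f[u > 0.85] <- NA_real_
    f
  }
  maybe_na <- function(x, p = 0.1) {
    x[runif(length(x)) < p] <- NA
    x
  }
  tb <- tibble::tibble(
    chrom = "chr1",
    pos = seq_len(n),
    ref = "A",
    alt = "T",
    gene = sprintf("G%03d", sample.int(50, n, replace = TRUE)),
    consequence = sample(exoburden::consequence_classes, n, replace = TRUE),
    site_quality = maybe_na(round(runif(n, 10, 90), 1)),
    read_depth = maybe_na(sample(5:100, n, replace = TRUE)),
    mapping_quality = maybe_na(round(runif(n, 20, 60), 1)),
    maf_nfe = draw_freq(n),
    maf_eur = draw_freq(n),
    maf_afr = draw_freq(n)
  )
  tb$site_quality[sample.int(n, max(1, n %/% 50))] <- 30   # exact boundaries
  for (j in seq_len(n_predictors)) {
    tb[[paste0("pred_p", j)]] <- sample(
      c("deleterious", "benign", "unknown", NA_character_), n,
      replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.15)
    )
  }
  plain <- lapply(seq_len(n), function(i) {
    list(
      site_quality = tb$site_quality[i],
      read_depth = tb$read_depth[i],
      mapping_quality = tb$mapping_quality[i],
      consequence = tb$consequence[i],
      freqs = c(nfe = tb$maf_nfe[i], eur = tb$maf_eur[i], afr = tb$maf_afr[i]),
      preds = unlist(tb[i, paste0("pred_p", seq_len(n_predictors))],
                     use.names = FALSE)
    )
  })
  list(tbl = tb, plain = plain)
}

# Compare filter_variant with the oracle on every variant; returns TRUE or
# a description of the first disagreement.
oracle_agrees <- function(rv, cfg) {
  out <- exoburden::filter_variant(rv$tbl, cfg)
  for (i in seq_along(rv$plain)) {
    o <- oracle_filter_one(rv$plain[[i]], cfg)
    if (o$pass != out$pass[i] ||
        o$tier$majority != out$tier_majority[i] ||
        o$tier$all != out$tier_all[i] ||
        o$tier$lof_only != out$tier_lof_only[i] ||
        abs(o$effective_maf - out$effective_maf[i]) > 1e-12) {
      return(sprintf("disagreement at variant %d (csq=%s)", i,
                     rv$plain[[i]]$consequence))
    }
  }
  TRUE
}
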