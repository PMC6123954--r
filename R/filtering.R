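#' Site-quality gate
#'
#' Passes variants whose call quality, read depth and mapping quality all
#' meet their thresholds (inclusively). With the gate disabled — the mode
#' used for pre-validated reference call sets — every variant passes. A
#' missing metric fails the gate when it is enabled.
#'
#' @param variants Variants tibble (see [exome_cohort()]); single rows work.
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per variant row.
#' @export
quality_gate <- function(variants, cfg) {
  if (!cfg$quality_gate_enabled) {
    return(rep(TRUE, nrow(variants)))
  }
  q <- col_or_na(variants, "site_quality") >= cfg$min_site_quality &
    col_or_na(variants, "read_depth") >= cfg$min_depth &
    col_or_na(variants, "mapping_quality") >= cfg$min_mapping_quality
  q[is.na(q)] <- FALSE
  q
}

# A variants column, or NA when the table does not carry it.
col_or_na <- function(variants, col) {
  if (col %in% names(variants)) variants[[col]] else rep(NA_real_, nrow(variants))
}

#' Resolve the effective minor allele frequency
#'
#' The primary reference population's MAF is used when recorded; otherwise
#' the fallback population's; variants recorded in neither are treated as
#' novel with an effective MAF of 0, so they pass every rarity gate.
#'
#' @inheritParams quality_gate
#' @return A tibble with columns `effective_maf` (fraction in \[0,1\]) and
#'   `maf_source` (`"primary"`, `"fallback"` or `"novel"`).
#' @export
resolve_maf <- function(variants, cfg) {
  n <- nrow(variants)
  get_pop <- function(pop) {
    col <- paste0("maf_", pop)
    if (col %in% names(variants)) variants[[col]] else rep(NA_real_, n)
  }
  primary <- get_pop(cfg$primary_population)
  fallback <- get_pop(cfg$fallback_population)
  eff <- ifelse(!is.na(primary), primary, ifelse(!is.na(fallback), fallback, 0))
  src <- ifelse(!is.na(primary), "primary",
                ifelse(!is.na(fallback), "fallback", "novel"))
  tibble::tibble(effective_maf = eff, maf_source = src)
}

#' Minor-allele-frequency gate
#'
#' @param effective_maf Numeric vector of effective MAFs in \[0,1\].
#' @param cfg A [filter_config()]; `maf_inclusive` selects `<=` versus `<`.
#' @return Logical vector.
#' @export
maf_gate <- function(effective_maf, cfg) {
  stopifnot(all(effective_maf >= 0 & effective_maf <= 1))
  if (cfg$maf_inclusive) {
    effective_maf <= cfg$maf_threshold
  } else {
    effective_maf < cfg$maf_threshold
  }
}

#' Flag variants common elsewhere
#'
#' An informational flag (never a filter) marking variants that are rare in
#' the primary reference population but common — above
#' `cross_population_flag_threshold` — in some other population with a
#' recorded frequency. The classic trap this catches is a variant at a
#' fraction of a percent in the reference population but present in most of
#' another population.
#'
#' @inheritParams quality_gate
#' @return Logical vector.
#' @export
flag_cross_population <- function(variants, cfg) {
  pops <- setdiff(freq_populations(variants), cfg$primary_population)
  flag <- rep(FALSE, nrow(variants))
  for (pop in pops) {
    f <- variants[[paste0("maf_", pop)]]
    flag <- flag | (!is.na(f) & f > cfg$cross_population_flag_threshold)
  }
  flag
}

#' Consequence-severity gate
#'
#' @inheritParams quality_gate
#' @return Logical vector: `TRUE` where the variant's consequence class is
#'   in `cfg$retained_consequences`.
#' @export
consequence_gate <- function(variants, cfg) {
  variants$consequence %in% cfg$retained_consequences
}

#' Tiered pathogenicity classification
#'
#' Variants are classified by predictor voting at three nested tiers.
#' Loss-of-function variants pass all tiers unconditionally. For other
#' variants, only informative calls (verdict `"deleterious"` or `"benign"`)
#' enter the vote; `"unknown"` and absent calls are excluded from the
#' denominator:
#'
#' * `lof_only`: the consequence class is loss-of-function;
#' * `all`: at least one informative call and every informative call
#'   deleterious;
#' * `majority`: deleterious calls strictly outnumber half the informative
#'   calls.
#'
#' A non-LoF variant with no informative call fails both voting tiers.
#' Nesting `lof_only => all => majority` holds by construction.
#'
#' @inheritParams quality_gate
#' @return A tibble with logical columns `majority`, `all`, `lof_only`.
#' @export
pathogenicity_tiers <- function(variants) {
  n <- nrow(variants)
  pred_cols <- grep("^pred_", names(variants), value = TRUE)
  n_del <- n_inf <- rep(0L, n)
  for (col in pred_cols) {
    v <- variants[[col]]
    informative <- !is.na(v) & v %in% c("deleterious", "benign")
    n_inf <- n_inf + informative
    n_del <- n_del + (informative & v == "deleterious")
  }
  lof <- is_lof(variants$consequence)
  tibble::tibble(
    majority = lof | (n_del * 2L > n_inf),
    all = lof | (n_inf > 0L & n_del == n_inf),
    lof_only = lof
  )
}

#' Run the full filtering cascade
#'
#' Evaluates the pipeline stages in order — quality, MAF, consequence,
#' pathogenicity tier — and records every failing stage (not only the
#' first). A variant passes overall when all gates pass and it meets the
#' tier selected by `cfg$vote_mode`.
#'
#' @inheritParams quality_gate
#' @return A tibble aligned with `variants`: `key`, `pass`, `failed_stages`
#'   (`";"`-joined stage labels, `""` when passing), `effective_maf`,
#'   `maf_source`, `tier_majority`, `tier_all`, `tier_lof_only` and the
#'   informational `cross_population_common` flag.
#' @export
filter_variant <- function(variants, cfg) {
  if (inherits(variants, "exome_cohort")) variants <- variants$variants
  qual <- quality_gate(variants, cfg)
  qual_missing <- cfg$quality_gate_enabled &
    (is.na(col_or_na(variants, "site_quality")) |
       is.na(col_or_na(variants, "read_depth")) |
       is.na(col_or_na(variants, "mapping_quality")))
  maf <- resolve_maf(variants, cfg)
  maf_ok <- maf_gate(maf$effective_maf, cfg)
  csq_ok <- consequence_gate(variants, cfg)
  tiers <- pathogenicity_tiers(variants)
  tier_ok <- tiers[[cfg$vote_mode]]

  stage_names <- ifelse(qual_missing, "quality:missing", "quality")
  failed <- mapply(function(q, qn, m, c, t) {
    paste(c(if (!q) qn, if (!m) "maf", if (!c) "consequence",
            if (!t) paste0("tier:", cfg$vote_mode)), collapse = ";")
  }, qual, stage_names, maf_ok, csq_ok, tier_ok)

  key <- if ("key" %in% names(variants)) {
    variants$key
  } else {
    variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  }
  tibble::tibble(
    key = key,
    pass = qual & maf_ok & csq_ok & tier_ok,
    failed_stages = unname(failed),
    effective_maf = maf$effective_maf,
    maf_source = maf$maf_source,
    tier_majority = tiers$majority,
    tier_all = tiers$all,
    tier_lof_only = tiers$lof_only,
    cross_population_common = flag_cross_population(variants, cfg)
  )
}

#' Variant keys passing a configuration
#'
#' Convenience wrapper around [filter_variant()] returning the keys of
#' passing variants in an [exome_cohort()].
#'
#' @param cohort An [exome_cohort()].
#' @param cfg A [filter_config()].
#' @return Character vector of passing variant keys (possibly with
#'   duplicates when one variant carries several gene annotations).
#' @export
passing_keys <- function(cohort, cfg) {
  out <- filter_variant(cohort$variants, cfg)
  out$key[out$pass]
}

# Variants table restricted to passing rows, with filter columns attached.
passing_variants <- function(cohort, cfg) {
  out <- filter_variant(cohort$variants, cfg)
  dplyr::bind_cols(
    cohort$variants,
    out[, c("pass", "effective_maf", "maf_source", "cross_population_common")]
  )[out$pass, , drop = FALSE]
}
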