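#' Synthetic-cohort configuration
#'
#' Describes a multi-subgroup annotated exome cohort with the statistical
#' structure the downstream analyses assume: per-gene Bernoulli hit counts,
#' a log-uniform allele-frequency spectrum, partially concordant predictor
#' calls driven by a latent deleteriousness, inflated hit rates in
#' artifact-prone genes, and exactly-planted discovery facts (subgroup-
#' shared genes, recurrent identical variants, homozygotes, one
#' multi-variant gene) recorded in a truth table.
#'
#' Defaults emulate the motivating study design: 30 samples in four
#' phenotype subgroups (10 dominant, 10 recessive, 5 metabolic, 5 sensory),
#' disease/exclusion panels at the published sizes (357 deafness genes with
#' a 33-gene dominant subset, 265 retinal genes, 507 exclusion candidates,
#' 8 GWAS candidates), and a guaranteed minimum of 10 deafness-panel genes
#' per individual bearing a predicted-pathogenic common variant.
#'
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param subgroup_sizes Named integer vector, subgroup label -> size.
#' @param n_background_genes Genes outside every panel.
#' @param panel_spec Named list of panel sizes: `deafness`, `dominant`
#'   (subset of deafness), `retinal`, `exclusion`, `gwas`, plus
#'   `exclusion_overlap` — how many deafness genes also appear on the
#'   exclusion list (artifact-prone disease genes).
#' @param per_gene_hit_prob Probability an individual carries a variant in
#'   a given gene (before exclusion-list inflation).
#' @param exclusion_inflation Hit-rate multiplier for exclusion-panel genes.
#' @param maf_spectrum Log-uniform bounds `c(min, max)` for the true minor
#'   allele frequency.
#' @param frac_novel Fraction of variants recorded in no population
#'   (treated as novel downstream).
#' @param frac_missing_primary_freq Fraction of non-novel variants whose
#'   primary-population frequency is dropped, exercising the fallback.
#' @param n_predictors Number of in-silico predictors annotated per
#'   non-LoF variant.
#' @param predictor_concordance Probability a predictor call agrees with
#'   the variant's latent deleteriousness.
#' @param frac_call_missing Probability an individual predictor call is
#'   `"unknown"`.
#' @param p_deleterious Fraction of variants that are latently deleterious.
#' @param lof_fraction Fraction of deleterious variants with a
#'   loss-of-function consequence.
#' @param hom_prob Probability a background carrier is homozygous.
#' @param cross_pop_common_prob Probability a variant is additionally
#'   common (frequency 0.15-0.8) in a non-primary population, exercising
#'   the cross-population flag.
#' @param planted_min_panel_hits Guaranteed minimum number of deafness-
#'   panel genes per sample with a variant passing the common/majority
#'   screen (top-up planting; 0 disables).
#' @param planted_shared_genes `"auto"` (one gene per subgroup; the
#'   recessive-type subgroup gets an exclusion-only gene, mirroring the
#'   artifact-prone shared-gene case), `NULL` for none, or a named list
#'   subgroup -> gene symbol.
#' @param planted_recurrent_variants Number of very rare identical variants
#'   planted in 2-3 carriers each.
#' @param planted_homozygotes Number of very rare homozygous variants
#'   planted in distinct samples.
#' @param planted_multi_hit `"auto"` (5 very rare variants in one deafness
#'   gene of the first dominant-subgroup sample), `NULL`, or a list with
#'   `sample`, `gene`, `n_variants`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             subgroup_sizes = c(Dominant = 10, Recessive = 10,
                                                Metabolic = 5, Sensory = 5),
                             n_background_genes = 1500,
                             panel_spec = list(deafness = 357, dominant = 33,
                                               retinal = 265, exclusion = 507,
                                               gwas = 8, exclusion_overlap = 20),
                             per_gene_hit_prob = 0.08,
                             exclusion_inflation = 3,
                             maf_spectrum = c(1e-5, 0.5),
                             frac_novel = 0.05,
                             frac_missing_primary_freq = 0.10,
                             n_predictors = 5,
                             predictor_concordance = 0.9,
                             frac_call_missing = 0.15,
                             p_deleterious = 0.35,
                             lof_fraction = 0.12,
                             hom_prob = 0.04,
                             cross_pop_common_prob = 0.02,
                             planted_min_panel_hits = 10,
                             planted_shared_genes = "auto",
                             planted_recurrent_variants = 5,
                             planted_homozygotes = 3,
                             planted_multi_hit = "auto") {
  probs <- c(per_gene_hit_prob, frac_novel, frac_missing_primary_freq,
             predictor_concordance, frac_call_missing, p_deleterious,
             lof_fraction, hom_prob, cross_pop_common_prob)
  stopifnot(all(probs >= 0 & probs <= 1), all(subgroup_sizes >= 0),
            maf_spectrum[1] > 0, maf_spectrum[2] <= 1,
            maf_spectrum[1] < maf_spectrum[2], n_predictors >= 0)
  spec <- utils::modifyList(
    list(deafness = 357, dominant = 33, retinal = 265, exclusion = 507,
         gwas = 8, exclusion_overlap = 20),
    panel_spec
  )
  if (spec$dominant > spec$deafness) {
    stop("dominant subset size exceeds deafness panel size")
  }
  structure(
    list(seed = as.integer(seed), subgroup_sizes = subgroup_sizes,
         n_background_genes = n_background_genes, panel_spec = spec,
         per_gene_hit_prob = per_gene_hit_prob,
         exclusion_inflation = exclusion_inflation,
         maf_spectrum = maf_spectrum, frac_novel = frac_novel,
         frac_missing_primary_freq = frac_missing_primary_freq,
         n_predictors = n_predictors,
         predictor_concordance = predictor_concordance,
         frac_call_missing = frac_call_missing,
         p_deleterious = p_deleterious, lof_fraction = lof_fraction,
         hom_prob = hom_prob, cross_pop_common_prob = cross_pop_common_prob,
         planted_min_panel_hits = planted_min_panel_hits,
         planted_shared_genes = planted_shared_genes,
         planted_recurrent_variants = planted_recurrent_variants,
         planted_homozygotes = planted_homozygotes,
         planted_multi_hit = planted_multi_hit),
    class = "synthetic_config"
  )
}

#' Read a synthetic-cohort configuration from YAML
#'
#' Fields mirror the arguments of [synthetic_config()]; omitted fields take
#' their defaults. `subgroup_sizes` and `panel_spec` are YAML mappings.
#'
#' @param path YAML file.
#' @return A [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  if ("subgroup_sizes" %in% names(y)) {
    y$subgroup_sizes <- unlist(y$subgroup_sizes)
  }
  if ("maf_spectrum" %in% names(y)) {
    y$maf_spectrum <- as.numeric(unlist(y$maf_spectrum))
  }
  do.call(synthetic_config, y)
}

#' Generate the synthetic gene universe and panels
#'
#' Genes are symbolic (`DEAF####`, `RET####`, `EXCL####`, `GWAS###`,
#' `BG#####`) and each is assigned an interval on a synthetic chromosome
#' (22 chromosomes, genes spaced 100 kb apart, 10 kb per gene), so
#' coordinates are internally consistent without any real genome build.
#' The exclusion panel overlaps the deafness panel by
#' `panel_spec$exclusion_overlap` genes.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `panels` (named [gene_panel()] list), and `universe`
#'   — a tibble with `gene`, `chrom`, `start`, `end`.
#' @export
generate_gene_panels <- function(cfg) {
  spec <- cfg$panel_spec
  deaf <- sprintf("DEAF%04d", seq_len(spec$deafness))
  dom <- utils::head(deaf, spec$dominant)
  ret <- if (spec$retinal > 0) sprintf("RET%04d", seq_len(spec$retinal)) else character()
  overlap <- min(spec$exclusion_overlap, spec$exclusion, length(deaf))
  exc_own <- if (spec$exclusion - overlap > 0) {
    sprintf("EXCL%04d", seq_len(spec$exclusion - overlap))
  } else {
    character()
  }
  exc <- c(utils::tail(deaf, overlap), exc_own)
  gwas <- if (spec$gwas > 0) sprintf("GWAS%03d", seq_len(spec$gwas)) else character()
  bg <- if (cfg$n_background_genes > 0) {
    sprintf("BG%05d", seq_len(cfg$n_background_genes))
  } else {
    character()
  }
  genes <- unique(c(deaf, ret, exc, gwas, bg))
  idx <- seq_along(genes) - 1L
  universe <- tibble::tibble(
    gene = genes,
    chrom = sprintf("chr%d", (idx %% 22L) + 1L),
    start = (idx %/% 22L) * 100000L + 1L,
    end = (idx %/% 22L) * 100000L + 10000L
  )
  panels <- list(
    deafness = gene_panel("deafness", deaf, dominant_subset = dom),
    retinal = gene_panel("retinal", if (length(ret)) ret else character()),
    exclusion = gene_panel("exclusion", exc, is_exclusion_list = TRUE),
    gwas = gene_panel("gwas", gwas)
  )
  list(panels = panels, universe = universe)
}

# Straight-line bookkeeping of whether a generated variant passes a screen;
# used only to build the truth table and to top up planted minimum hits.
gen_passes <- function(maf, recorded, lof, retained_csq, n_del, n_inf,
                       qual_ok, threshold, inclusive) {
  eff <- ifelse(recorded, maf, 0)
  maf_ok <- if (inclusive) eff <= threshold else eff < threshold
  tier_ok <- lof | (2 * n_del > n_inf)
  qual_ok & maf_ok & retained_csq & tier_ok
}

#' Generate a synthetic annotated cohort
#'
#' Draws a full annotated cohort under `cfg` (see [synthetic_config()]),
#' plants the configured discovery facts exactly, and returns the cohort
#' with its truth table. All randomness flows from one stream keyed by
#' `cfg$seed`; planted features are injected after background generation so
#' background statistics are unperturbed away from planted loci.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Optional directory: when given, the cohort is also written as
#'   `cohort.vcf` + `cohort.annotations.tsv`, `manifest.tsv`, one
#'   `panel_<name>.txt` per panel and `truth.json`.
#' @return A list with `cohort` ([exome_cohort()]), `manifest`, `panels`,
#'   `universe`, `truth` (see Details) and, when `dir` is given, `paths`.
#'
#' @details The truth table records, per planted fact, what the discovery
#' analyses must report: `shared_genes` (subgroup -> gene),
#' `recurrent_variants` (key + carriers), `homozygotes` (sample, gene,
#' key), `multi_hit` (sample, gene, keys) and `panel_genes_common`
#' (per-sample deafness-panel genes bearing a variant that passes the
#' common/majority screen, by the generator's own bookkeeping).
#' @export
generate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  gp <- generate_gene_panels(cfg)
  universe <- gp$universe
  panels <- gp$panels

  sizes <- cfg$subgroup_sizes[cfg$subgroup_sizes > 0]
  manifest <- tibble::tibble(
    sample_id = unlist(lapply(names(sizes), function(s) {
      sprintf("%s_%02d", s, seq_len(sizes[[s]]))
    })),
    subgroup = rep(names(sizes), sizes)
  )
  samples <- manifest$sample_id

  # -- background variants: per (sample, gene) Bernoulli hits ---------------
  n_g <- nrow(universe)
  hit_p <- rep(cfg$per_gene_hit_prob, n_g)
  hit_p[universe$gene %in% panels$exclusion$genes] <-
    pmin(1, cfg$per_gene_hit_prob * cfg$exclusion_inflation)
  hits <- which(matrix(stats::runif(length(samples) * n_g), length(samples)) <
                  matrix(hit_p, length(samples), n_g, byrow = TRUE),
                arr.ind = TRUE)
  bg <- tibble::tibble(
    sample_id = samples[hits[, 1]],
    gene_idx = as.integer(hits[, 2])
  )
  bg <- bg[order(bg$gene_idx, bg$sample_id), ]
  n <- nrow(bg)

  # distinct positions per gene (offsets 1..9000; planting uses 9001+)
  offset <- integer(n)
  for (gi in unique(bg$gene_idx)) {
    rows <- which(bg$gene_idx == gi)
    offset[rows] <- sample.int(9000L, length(rows))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample.int(3L, n, replace = TRUE) - 1L) %% 4L + 1L]

  latent_del <- stats::runif(n) < cfg$p_deleterious
  csq <- character(n)
  is_lof_v <- latent_del & stats::runif(n) < cfg$lof_fraction
  csq[is_lof_v] <- sample(lof_classes, sum(is_lof_v), replace = TRUE)
  del_nonlof <- latent_del & !is_lof_v
  csq[del_nonlof] <- sample(c("missense", "inframe_indel", "splice_region"),
                            sum(del_nonlof), replace = TRUE,
                            prob = c(0.8, 0.1, 0.1))
  csq[!latent_del] <- sample(c("missense", "synonymous", "intronic", "splice_region"),
                             sum(!latent_del), replace = TRUE,
                             prob = c(0.3, 0.4, 0.2, 0.1))

  a <- cfg$maf_spectrum[1]; b <- cfg$maf_spectrum[2]
  maf <- exp(stats::runif(n, log(a), log(b)))
  novel <- stats::runif(n) < cfg$frac_novel
  primary_missing <- !novel & (stats::runif(n) < cfg$frac_missing_primary_freq)
  maf_nfe <- ifelse(novel | primary_missing, NA_real_, maf)
  maf_eur <- ifelse(novel, NA_real_,
                    ifelse(primary_missing | stats::runif(n) < 0.5, maf, NA_real_))
  cross_common <- stats::runif(n) < cfg$cross_pop_common_prob
  maf_afr <- ifelse(cross_common, stats::runif(n, 0.15, 0.80),
                    ifelse(!novel & stats::runif(n) < 0.5, maf, NA_real_))

  qual <- pmax(1, round(stats::rnorm(n, 55, 15), 1))
  dp <- stats::rpois(n, 60)
  mq <- pmin(60, pmax(10, round(stats::rnorm(n, 55, 6), 1)))

  pred_names <- if (cfg$n_predictors > 0) {
    utils::head(c("sift", "polyphen", "mutation_taster", "lrt", "provean",
                  sprintf("pred%02d", seq_len(max(0, cfg$n_predictors - 5)))),
                cfg$n_predictors)
  } else {
    character()
  }
  pred <- matrix(NA_character_, n, length(pred_names))
  n_del_calls <- n_inf_calls <- integer(n)
  for (j in seq_along(pred_names)) {
    u_miss <- stats::runif(n) < cfg$frac_call_missing
    agree <- stats::runif(n) < cfg$predictor_concordance
    call <- ifelse(u_miss, "unknown",
                   ifelse(latent_del == agree, "deleterious", "benign"))
    call[is_lof_v] <- NA_character_  # LoF variants carry no predictor calls
    pred[, j] <- call
    informative <- !is.na(call) & call != "unknown"
    n_inf_calls <- n_inf_calls + informative
    n_del_calls <- n_del_calls + (informative & call == "deleterious")
  }

  zyg <- ifelse(stats::runif(n) < cfg$hom_prob, "homozygous_alt", "heterozygous")

  retained_default <- c(lof_classes, "missense", "inframe_indel", "splice_region")
  qual_ok <- qual >= 30 & dp >= 20 & mq >= 45
  recorded <- !novel
  pass_common <- gen_passes(maf, recorded, is_lof_v, csq %in% retained_default,
                            n_del_calls, n_inf_calls, qual_ok, 0.10, TRUE)
  pass_very_rare <- gen_passes(maf, recorded, is_lof_v, csq %in% retained_default,
                               n_del_calls, n_inf_calls, qual_ok, 0.005, FALSE)

  vt <- tibble::tibble(
    sample_id = bg$sample_id,
    gene = universe$gene[bg$gene_idx],
    chrom = universe$chrom[bg$gene_idx],
    pos = universe$start[bg$gene_idx] + offset - 1L,
    ref = ref, alt = alt,
    site_quality = qual, read_depth = as.numeric(dp), mapping_quality = mq,
    consequence = csq,
    maf_nfe = maf_nfe, maf_eur = maf_eur, maf_afr = maf_afr,
    zygosity = zyg, haplotype = NA_integer_,
    latent_deleterious = latent_del,
    planted = "background",
    pass_common = pass_common, pass_very_rare = pass_very_rare
  )
  for (j in seq_along(pred_names)) {
    vt[[paste0("pred_", pred_names[j])]] <- pred[, j]
  }

  # -- planting -------------------------------------------------------------
  plant <- plant_features(cfg, vt, manifest, panels, universe, pred_names)
  vt <- plant$vt
  truth_planted <- plant$truth

  # per-sample deafness-panel genes passing the common/majority screen
  carrier_rows <- vt[vt$pass_common & vt$gene %in% panels$deafness$genes, ]
  panel_genes_common <- lapply(
    stats::setNames(samples, samples),
    function(s) sort(unique(carrier_rows$gene[carrier_rows$sample_id == s]))
  )

  variants <- vt[!duplicated(variant_key(vt$chrom, vt$pos, vt$ref, vt$alt)),
                 !(names(vt) %in% c("sample_id", "zygosity", "haplotype",
                                    "latent_deleterious", "planted",
                                    "pass_common", "pass_very_rare"))]
  variants$variant_id <- NA_character_
  genotypes <- tibble::tibble(
    key = variant_key(vt$chrom, vt$pos, vt$ref, vt$alt),
    sample_id = vt$sample_id,
    zygosity = vt$zygosity,
    haplotype = vt$haplotype
  )
  cohort <- exome_cohort(variants, genotypes, samples)

  truth <- c(truth_planted, list(
    panel_genes_common = panel_genes_common,
    variant_truth = vt[, c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                           "latent_deleterious", "planted",
                           "pass_common", "pass_very_rare")]
  ))

  out <- list(cohort = cohort, manifest = manifest, panels = panels,
              universe = universe, truth = truth)
  if (!is.null(dir)) {
    out$paths <- write_synthetic_bundle(out, dir)
  }
  out
}

# Inject planted discovery facts into the per-carrier variant table.
plant_features <- function(cfg, vt, manifest, panels, universe, pred_names) {
  samples <- manifest$sample_id
  next_offset <- stats::setNames(rep(9001L, nrow(universe)), universe$gene)
  gene_row <- function(g) match(g, universe$gene)

  planted_rows <- list()
  new_row <- function(sample_id, gene, maf, zygosity = "heterozygous",
                      kind, consequence = "missense", pos = NULL) {
    gi <- gene_row(gene)
    if (is.na(gi)) stop("planted gene outside the generated universe: ", gene)
    if (is.null(pos)) {
      pos <- universe$start[gi] + next_offset[[gene]] - 1L
      next_offset[[gene]] <<- next_offset[[gene]] + 1L
    }
    row <- tibble::tibble(
      sample_id = sample_id, gene = gene, chrom = universe$chrom[gi],
      pos = pos, ref = "A", alt = "G",
      site_quality = 99, read_depth = 100, mapping_quality = 60,
      consequence = consequence,
      maf_nfe = maf, maf_eur = NA_real_, maf_afr = NA_real_,
      zygosity = zygosity, haplotype = NA_integer_,
      latent_deleterious = TRUE, planted = kind,
      pass_common = TRUE, pass_very_rare = !is.na(maf) && maf < 0.005
    )
    for (p in pred_names) row[[paste0("pred_", p)]] <- "deleterious"
    row
  }

  truth <- list(shared_genes = list(),
                recurrent_variants = tibble::tibble(
                  chrom = character(), pos = integer(), ref = character(),
                  alt = character(), gene = character(),
                  n_carriers = integer(), sample_ids = character()),
                homozygotes = tibble::tibble(
                  sample_id = character(), gene = character(),
                  chrom = character(), pos = integer(), ref = character(),
                  alt = character()),
                multi_hit = NULL,
                min_panel_hits = cfg$planted_min_panel_hits)

  bg_genes <- universe$gene[startsWith(universe$gene, "BG")]
  exc_only <- setdiff(panels$exclusion$genes, panels$deafness$genes)

  # subgroup-shared genes at the common tier (MAF 2-9%: passes the 10% screen
  # but not the very-rare one, so the fact cannot leak into the rare analyses)
  shared_spec <- cfg$planted_shared_genes
  if (identical(shared_spec, "auto")) {
    subgroups <- unique(manifest$subgroup)
    pool <- utils::head(bg_genes, length(subgroups))
    shared_spec <- as.list(stats::setNames(pool, subgroups))
    rec_like <- grep("recessive", subgroups, ignore.case = TRUE, value = TRUE)
    if (length(rec_like) && length(exc_only)) {
      shared_spec[[rec_like[1]]] <- exc_only[1]
    }
  }
  if (!is.null(shared_spec)) {
    for (sg in names(shared_spec)) {
      g <- toupper(shared_spec[[sg]])
      for (s in subgroup_members(manifest, sg)) {
        planted_rows[[length(planted_rows) + 1]] <-
          new_row(s, g, maf = stats::runif(1, 0.02, 0.09), kind = "shared")
      }
      truth$shared_genes[[sg]] <- g
    }
  }

  # recurrent identical very rare variants (2-3 carriers each)
  if (cfg$planted_recurrent_variants > 0) {
    pool <- setdiff(bg_genes, unlist(truth$shared_genes))
    genes <- pool[seq_len(cfg$planted_recurrent_variants) + length(truth$shared_genes)]
    for (i in seq_len(cfg$planted_recurrent_variants)) {
      k <- sample(2:3, 1)
      carriers <- sample(samples, k)
      maf <- exp(stats::runif(1, log(cfg$maf_spectrum[1]), log(0.004)))
      gi <- gene_row(genes[i])
      pos <- universe$start[gi] + next_offset[[genes[i]]] - 1L
      next_offset[[genes[i]]] <- next_offset[[genes[i]]] + 1L
      for (s in carriers) {
        planted_rows[[length(planted_rows) + 1]] <-
          new_row(s, genes[i], maf = maf, kind = "recurrent", pos = pos)
      }
      truth$recurrent_variants <- rbind(
        truth$recurrent_variants,
        tibble::tibble(chrom = universe$chrom[gi], pos = pos, ref = "A",
                       alt = "G", gene = genes[i], n_carriers = k,
                       sample_ids = paste(sort(carriers), collapse = ","))
      )
    }
  }

  # very rare homozygotes in distinct samples and genes
  if (cfg$planted_homozygotes > 0) {
    hom_samples <- sample(samples, cfg$planted_homozygotes)
    used <- c(unlist(truth$shared_genes), truth$recurrent_variants$gene)
    hom_genes <- utils::head(setdiff(bg_genes, used), cfg$planted_homozygotes)
    for (i in seq_len(cfg$planted_homozygotes)) {
      maf <- exp(stats::runif(1, log(cfg$maf_spectrum[1]), log(0.004)))
      row <- new_row(hom_samples[i], hom_genes[i], maf = maf,
                     zygosity = "homozygous_alt", kind = "homozygote")
      planted_rows[[length(planted_rows) + 1]] <- row
      truth$homozygotes <- rbind(
        truth$homozygotes,
        tibble::tibble(sample_id = hom_samples[i], gene = hom_genes[i],
                       chrom = row$chrom, pos = row$pos, ref = "A", alt = "G")
      )
    }
  }

  # one multi-variant gene in a single individual (five very rare variants
  # in a dominant-subset deafness gene of a dominant-subgroup sample)
  mh <- cfg$planted_multi_hit
  if (identical(mh, "auto")) {
    dom_like <- grep("dominant", unique(manifest$subgroup), ignore.case = TRUE,
                     value = TRUE)
    sg <- if (length(dom_like)) dom_like[1] else manifest$subgroup[1]
    gene <- if (length(panels$deafness$dominant_subset)) {
      panels$deafness$dominant_subset[1]
    } else {
      utils::tail(bg_genes, 1)
    }
    mh <- list(sample = subgroup_members(manifest, sg)[1], gene = gene,
               n_variants = 5)
  }
  if (!is.null(mh)) {
    keys <- character(mh$n_variants)
    for (i in seq_len(mh$n_variants)) {
      maf <- exp(stats::runif(1, log(cfg$maf_spectrum[1]), log(0.004)))
      row <- new_row(mh$sample, toupper(mh$gene), maf = maf, kind = "multi_hit")
      planted_rows[[length(planted_rows) + 1]] <- row
      keys[i] <- variant_key(row$chrom, row$pos, row$ref, row$alt)
    }
    truth$multi_hit <- list(sample = mh$sample, gene = toupper(mh$gene),
                            n_variants = mh$n_variants, keys = keys)
  }

  # top up each sample to the guaranteed minimum of deafness-panel genes
  # passing the common/majority screen
  if (cfg$planted_min_panel_hits > 0) {
    planted_df <- dplyr::bind_rows(planted_rows)
    for (s in samples) {
      hit_genes <- unique(c(
        vt$gene[vt$sample_id == s & vt$pass_common &
                  vt$gene %in% panels$deafness$genes],
        if (nrow(planted_df)) {
          planted_df$gene[planted_df$sample_id == s & planted_df$pass_common &
                            planted_df$gene %in% panels$deafness$genes]
        }
      ))
      deficit <- cfg$planted_min_panel_hits - length(hit_genes)
      if (deficit > 0) {
        fresh <- sample(setdiff(panels$deafness$genes, hit_genes), deficit)
        for (g in fresh) {
          planted_rows[[length(planted_rows) + 1]] <-
            new_row(s, g, maf = stats::runif(1, 0.02, 0.09), kind = "min_hit")
        }
      }
    }
  }

  list(vt = dplyr::bind_rows(list(vt), planted_rows), truth = truth)
}

# Write the generated bundle: VCF + sidecar, manifest, panels, truth JSON.
write_synthetic_bundle <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(dir, "cohort.vcf")
  write_cohort_vcf(x$cohort, vcf)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(x$manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  panel_paths <- character()
  for (pname in names(x$panels)) {
    p <- file.path(dir, sprintf("panel_%s.txt", pname))
    writeLines(x$panels[[pname]]$genes, p)
    panel_paths[pname] <- p
    if (length(x$panels[[pname]]$dominant_subset)) {
      pd <- file.path(dir, sprintf("panel_%s_dominant.txt", pname))
      writeLines(x$panels[[pname]]$dominant_subset, pd)
      panel_paths[paste0(pname, "_dominant")] <- pd
    }
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- x$truth
  truth$variant_truth <- NULL  # tabular truth stays in memory; JSON keeps facts
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(vcf = vcf, sidecar = sub("\\.vcf$", ".annotations.tsv", vcf),
    manifest = manifest_path, truth = truth_path, panel_paths)
}
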