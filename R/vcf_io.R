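#' Read an annotated cohort from a VCF
#'
#' Parses a multi-sample VCF into an [exome_cohort()]. Multiallelic records
#' are decomposed into one row per alternate allele, and per-sample
#' genotypes become explicit zygosity calls (`0/1` -> heterozygous with
#' respect to that allele, `1/1` -> homozygous alternate, `./.` -> missing;
#' reference calls are implicit). Phased heterozygous genotypes (`1|0`)
#' retain the haplotype carrying the alternate allele.
#'
#' Annotations (gene, consequence, population frequencies, predictor
#' verdicts) come either from VCF INFO fields (`GENE`, `CSQ`, `MAF_<POP>`,
#' and `PRED` as `name:D|name:B|name:U` triples) or from a sidecar TSV keyed
#' by chrom/pos/ref/alt. When both are available the sidecar wins. Variants
#' with no annotation are kept with `consequence = "unknown"` and no
#' predictor calls — never silently dropped — and a warning is raised.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param annotation_source `"sidecar"` or `"inline"`.
#' @param sidecar_path Annotation TSV; required for `"sidecar"`.
#' @param gene_universe Optional character vector of accepted gene symbols
#'   (e.g. an Ensembl-derived universe). Variants whose symbol falls outside
#'   it are flagged in the `gene_in_universe` column, not dropped.
#' @return An [exome_cohort()].
#' @export
read_cohort_vcf <- function(path,
                            annotation_source = c("sidecar", "inline"),
                            sidecar_path = NULL,
                            gene_universe = NULL) {
  annotation_source <- match.arg(annotation_source)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) stop("VCF contains no records: ", path)

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  bad <- which(n_alt == 0 | is.na(fix[, "ALT"]))
  if (length(bad) > 0) {
    stop("malformed VCF '", path, "': record ", bad[1], " (",
         fix[bad[1], "CHROM"], ":", fix[bad[1], "POS"], ") has no ALT allele")
  }
  rec <- rep(seq_len(nrow(fix)), n_alt)       # source record of each row
  alt_index <- sequence(n_alt)                # allele index within record

  info_num <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key, as.numeric = TRUE))
    if (is.null(x)) rep(NA_real_, nrow(fix)) else x
  }
  variants <- tibble::tibble(
    chrom = fix[rec, "CHROM"],
    pos = as.integer(fix[rec, "POS"]),
    ref = fix[rec, "REF"],
    alt = unlist(alts),
    variant_id = ifelse(is.na(fix[rec, "ID"]) | fix[rec, "ID"] == ".",
                        NA_character_, fix[rec, "ID"]),
    site_quality = suppressWarnings(as.numeric(fix[rec, "QUAL"])),
    read_depth = info_num("DP")[rec],
    mapping_quality = info_num("MQ")[rec]
  )

  if (annotation_source == "inline") {
    ann <- inline_annotations(v)[rec, , drop = FALSE]
    variants <- dplyr::bind_cols(variants, ann)
  } else {
    if (is.null(sidecar_path)) stop("sidecar annotation path required")
    variants <- join_sidecar(variants, read_sidecar(sidecar_path))
  }
  variants$consequence[is.na(variants$consequence)] <- "unknown"
  if (!"gene" %in% names(variants)) variants$gene <- NA_character_
  if (!is.null(gene_universe)) {
    variants$gene_in_universe <- !is.na(variants$gene) &
      variants$gene %in% toupper(gene_universe)
  }

  variants[] <- lapply(variants, unname)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt) %||% character()
  genotypes <- genotypes_from_gt(gt, rec, alt_index,
                                 variant_key(variants$chrom, variants$pos,
                                             variants$ref, variants$alt))
  exome_cohort(variants, genotypes, samples)
}

# Long zygosity table from a vcfR GT matrix, one block per decomposed allele.
genotypes_from_gt <- function(gt, rec, alt_index, keys) {
  if (is.null(gt) || ncol(gt) == 0) {
    return(tibble::tibble(key = character(), sample_id = character(),
                          zygosity = character(), haplotype = integer()))
  }
  out <- vector("list", length(rec))
  for (i in seq_along(rec)) {
    calls <- gt[rec[i], ]
    phased <- !is.na(calls) & grepl("|", calls, fixed = TRUE)
    alleles <- strsplit(ifelse(is.na(calls), ".", calls), "[/|]")
    n_match <- vapply(alleles, function(a) sum(a == as.character(alt_index[i])), 0L)
    n_miss <- vapply(alleles, function(a) sum(a == "."), 0L)
    zyg <- rep(NA_character_, length(calls))
    zyg[n_miss > 0] <- "missing"
    zyg[n_miss == 0 & n_match == 1] <- "heterozygous"
    zyg[n_miss == 0 & n_match >= 2] <- "homozygous_alt"
    keep <- !is.na(zyg)
    hap <- rep(NA_integer_, length(calls))
    het_phased <- keep & zyg == "heterozygous" & phased
    hap[het_phased] <- vapply(alleles[het_phased],
                              function(a) which(a == as.character(alt_index[i]))[1],
                              0L)
    out[[i]] <- tibble::tibble(
      key = keys[i],
      sample_id = names(calls)[keep],
      zygosity = zyg[keep],
      haplotype = hap[keep]
    )
  }
  dplyr::bind_rows(out)
}

# Annotations held in INFO fields GENE, CSQ, MAF_<POP>, PRED.
inline_annotations <- function(v) {
  meta <- v@meta
  ids <- sub("^##INFO=<ID=([^,]+),.*$", "\\1", grep("^##INFO=", meta, value = TRUE))
  n <- nrow(v@fix)
  get <- function(key, numeric = FALSE) {
    if (!key %in% ids) {
      return(rep(if (numeric) NA_real_ else NA_character_, n))
    }
    suppressWarnings(vcfR::extract.info(v, element = key, as.numeric = numeric))
  }
  ann <- tibble::tibble(
    gene = toupper(get("GENE")),
    consequence = get("CSQ")
  )
  for (pop in sub("^MAF_", "", grep("^MAF_", ids, value = TRUE))) {
    ann[[paste0("maf_", tolower(pop))]] <- get(paste0("MAF_", pop), numeric = TRUE)
  }
  pred <- get("PRED")
  if (any(!is.na(pred))) {
    parsed <- lapply(strsplit(pred, "|", fixed = TRUE), function(x) {
      if (length(x) == 1 && is.na(x)) return(character())
      parts <- strsplit(x, ":", fixed = TRUE)
      stats::setNames(
        vapply(parts, function(p) verdict_from_code(p[2]), ""),
        vapply(parts, `[`, "", 1)
      )
    })
    for (name in unique(unlist(lapply(parsed, names)))) {
      ann[[paste0("pred_", name)]] <-
        vapply(parsed, function(p) p[name] %||na% NA_character_, "")
    }
  }
  ann
}

verdict_from_code <- function(code) {
  switch(code, D = "deleterious", B = "benign", U = "unknown",
         deleterious = "deleterious", benign = "benign", "unknown")
}
verdict_to_code <- function(v) {
  unname(c(deleterious = "D", benign = "B", unknown = "U")[v])
}
`%||na%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a

#' Read a sidecar annotation table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, any number of `maf_<pop>` frequency columns and
#'   `pred_<name>` predictor-verdict columns.
#' @return A tibble.
#' @export
read_sidecar <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  if (!all(req %in% names(ann))) {
    stop("sidecar must have columns ", paste(req, collapse = ", "), ": ", path)
  }
  ann <- tibble::as_tibble(ann)
  ann$pos <- as.integer(ann$pos)
  ann$gene <- toupper(ann$gene)
  ann$gene[!nzchar(ann$gene)] <- NA_character_
  for (col in grep("^maf_", names(ann), value = TRUE)) {
    ann[[col]] <- suppressWarnings(as.numeric(ann[[col]]))
  }
  for (col in grep("^pred_", names(ann), value = TRUE)) {
    ann[[col]][!nzchar(ann[[col]])] <- NA_character_
  }
  ann
}

# Attach sidecar annotations; unannotated variants get unknown markers.
join_sidecar <- function(variants, ann) {
  ann$.__annotated <- TRUE
  joined <- dplyr::left_join(variants, ann,
                             by = c("chrom", "pos", "ref", "alt"),
                             relationship = "many-to-many")
  n_missing <- sum(is.na(joined$.__annotated[!duplicated(joined[c(
    "chrom", "pos", "ref", "alt")])]))
  if (n_missing > 0) {
    warning(n_missing, " variant(s) absent from the sidecar annotation; ",
            "kept with consequence 'unknown' and no predictor calls")
  }
  joined$consequence[is.na(joined$.__annotated)] <- "unknown"
  joined$.__annotated <- NULL
  joined
}

#' Write a cohort as VCF plus sidecar annotations
#'
#' Emits a deterministic, plain-text VCF 4.2 (sorted by chrom, pos, alt; no
#' timestamps, so identical cohorts give byte-identical files), with the
#' annotations both inline in INFO and in a sidecar TSV next to it.
#' Variants carrying several gene annotations are written once with the
#' duplicate gene rows preserved in the sidecar only.
#'
#' @param cohort An [exome_cohort()].
#' @param vcf_path Output VCF path; the sidecar is written to
#'   `sidecar_path`.
#' @param sidecar_path Output TSV path; default replaces the `.vcf`
#'   extension with `.annotations.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_cohort_vcf <- function(cohort, vcf_path,
                             sidecar_path = sub("\\.vcf$", ".annotations.tsv",
                                                vcf_path)) {
  va <- cohort$variants
  ord <- order(va$chrom, va$pos, va$alt, va$gene, method = "radix")
  va <- va[ord, , drop = FALSE]
  site <- va[!duplicated(va$key), , drop = FALSE]

  pops <- freq_populations(va)
  preds <- predictor_names(va)
  chroms <- unique(site$chrom)
  contig_len <- vapply(chroms, function(c) max(site$pos[site$chrom == c]) + 10000L, 0L)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chroms, contig_len),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Most severe consequence\">",
    sprintf("##INFO=<ID=MAF_%s,Number=1,Type=Float,Description=\"MAF in population %s\">",
            toupper(pops), pops),
    "##INFO=<ID=PRED,Number=1,Type=String,Description=\"Predictor verdicts name:D|B|U\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )

  fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.10g", x))
  info <- character(nrow(site))
  for (i in seq_len(nrow(site))) {
    parts <- c(
      if (!is.na(site$read_depth[i])) sprintf("DP=%d", as.integer(site$read_depth[i])),
      if (!is.na(site$mapping_quality[i])) sprintf("MQ=%.10g", site$mapping_quality[i]),
      if (!is.na(site$gene[i])) paste0("GENE=", site$gene[i]),
      paste0("CSQ=", site$consequence[i])
    )
    for (pop in pops) {
      f <- site[[paste0("maf_", pop)]][i]
      if (!is.na(f)) parts <- c(parts, sprintf("MAF_%s=%.10g", toupper(pop), f))
    }
    calls <- character()
    for (p in preds) {
      verdict <- site[[paste0("pred_", p)]][i]
      if (!is.na(verdict)) calls <- c(calls, paste0(p, ":", verdict_to_code(verdict)))
    }
    if (length(calls)) parts <- c(parts, paste0("PRED=", paste(calls, collapse = "|")))
    info[i] <- paste(parts, collapse = ";")
  }

  gt <- matrix("0/0", nrow = nrow(site), ncol = length(cohort$samples),
               dimnames = list(site$key, cohort$samples))
  g <- cohort$genotypes
  idx_row <- match(g$key, site$key)
  idx_col <- match(g$sample_id, cohort$samples)
  code <- ifelse(g$zygosity == "homozygous_alt", "1/1",
                 ifelse(g$zygosity == "missing", "./.",
                        ifelse(!is.na(g$haplotype) & g$haplotype == 1L,
                               "1|0",
                               ifelse(!is.na(g$haplotype) & g$haplotype == 2L,
                                      "0|1", "0/1"))))
  gt[cbind(idx_row, idx_col)] <- code

  body <- paste(
    site$chrom, site$pos,
    ifelse(is.na(site$variant_id), ".", site$variant_id),
    site$ref, site$alt, fmt_num(site$site_quality), "PASS", info, "GT",
    sep = "\t"
  )
  if (length(cohort$samples)) {
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), vcf_path)

  sidecar <- va[, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                    paste0("maf_", pops), paste0("pred_", preds)),
                drop = FALSE]
  for (pop in pops) {
    col <- paste0("maf_", pop)
    sidecar[[col]] <- ifelse(is.na(sidecar[[col]]), "",
                             sprintf("%.10g", sidecar[[col]]))
  }
  utils::write.table(sidecar, sidecar_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(vcf = vcf_path, sidecar = sidecar_path))
}
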