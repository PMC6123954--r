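#' Curated gene panel
#'
#' @param name Panel label.
#' @param genes Character vector of gene symbols (upper-cased, deduplicated).
#' @param dominant_subset Optional subset of `genes` acting under a dominant
#'   model.
#' @param is_exclusion_list `TRUE` for panels of artifact-prone genes
#'   ("candidates for exclusion"): such genes are flagged in every report
#'   but never silently removed from an analysis.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(name, genes, dominant_subset = character(),
                       is_exclusion_list = FALSE) {
  genes <- unique(toupper(trimws(genes)))
  genes <- genes[nzchar(genes)]
  dominant_subset <- unique(toupper(trimws(dominant_subset)))
  dominant_subset <- dominant_subset[nzchar(dominant_subset)]
  extra <- setdiff(dominant_subset, genes)
  if (length(extra) > 0) {
    stop("dominant subset contains genes absent from the panel: ",
         paste(extra, collapse = ", "))
  }
  structure(
    list(name = name, genes = genes, dominant_subset = dominant_subset,
         is_exclusion_list = isTRUE(is_exclusion_list)),
    class = "gene_panel"
  )
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %s: %d genes", x$name, length(x$genes)))
  if (length(x$dominant_subset)) {
    cat(sprintf(" (dominant subset: %d)", length(x$dominant_subset)))
  }
  if (x$is_exclusion_list) cat(" [exclusion candidates]")
  cat("\n")
  invisible(x)
}

#' Read a gene panel from disk
#'
#' Panels are newline-delimited symbol lists (or the first column of a TSV).
#' Symbols are upper-cased and deduplicated; an empty file is an error.
#'
#' @param path Panel file.
#' @param name Panel label; defaults to the file name.
#' @param dominant_path Optional file listing the dominant-model subset.
#' @param is_exclusion Flag the panel as an exclusion-candidate list.
#' @return A [gene_panel].
#' @export
read_gene_panel <- function(path, name = NULL, dominant_path = NULL,
                            is_exclusion = FALSE) {
  read_symbols <- function(p) {
    lines <- readLines(p, warn = FALSE)
    lines <- trimws(vapply(strsplit(lines, "\t", fixed = TRUE),
                           function(x) if (length(x)) x[[1]] else "", ""))
    lines[nzchar(lines)]
  }
  genes <- read_symbols(path)
  if (length(genes) == 0) stop("empty gene panel file: ", path)
  dom <- if (!is.null(dominant_path)) read_symbols(dominant_path) else character()
  gene_panel(
    name = name %||% sub("\\.[^.]*$", "", basename(path)),
    genes = genes, dominant_subset = dom, is_exclusion_list = is_exclusion
  )
}

#' Packaged reference panels
#'
#' Loads the gene panels shipped with the package: a deafness panel of 357
#' genes with a dominant-model subset of 33, a retinal-disease panel of 265
#' genes, a panel of 507 platform-artifact exclusion candidates, and the 8
#' GWAS candidate genes for adult hearing ability. The disease and
#' exclusion panels mix genuinely implicated genes with clearly-labelled
#' synthetic filler symbols (`SYNDEAF###` etc.), as the full curated lists
#' are not redistributable; sizes and role structure match the curated
#' originals.
#'
#' @return A named list of [gene_panel] objects: `deafness`, `retinal`,
#'   `exclusion`, `gwas`.
#' @export
packaged_panels <- function() {
  p <- function(f) system.file("extdata", f, package = "exoburden", mustWork = TRUE)
  list(
    deafness = read_gene_panel(
      p("deafness_genes_synthetic.txt"), name = "deafness",
      dominant_path = p("dominant_deafness_genes_synthetic.txt")
    ),
    retinal = read_gene_panel(p("retinal_genes_synthetic.txt"), name = "retinal"),
    exclusion = read_gene_panel(p("exclusion_candidates_synthetic.txt"),
                                name = "exclusion", is_exclusion = TRUE),
    gwas = read_gene_panel(p("gwas_candidate_genes.txt"), name = "gwas")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
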