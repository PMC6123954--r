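#!/usr/bin/env Rscript
# Subgroup-shared genes at the common-variant screen: genes in which every
# member of a phenotype subgroup carries a predicted pathogenic variant
# (MAF <= 10%, majority tier). Exclusion candidates are flagged, never
# dropped. Writes results/shared_genes.tsv.

suppressMessages(library(exoburden))

cohort <- read_cohort_vcf("results/cohort/cohort.vcf",
                          annotation_source = "sidecar",
                          sidecar_path = "results/cohort/cohort.annotations.tsv")
manifest <- read_manifest("results/cohort/manifest.tsv")
deaf <- read_gene_panel("results/cohort/panel_deafness.txt", name = "deafness")
excl <- read_gene_panel("results/cohort/panel_exclusion.txt",
                        name = "exclusion", is_exclusion = TRUE)

cfg <- filter_preset("common")
shared <- dplyr::bind_rows(lapply(unique(manifest$subgroup), function(sg) {
  shared_mutated_genes(cohort, manifest, sg, cfg,
                       deafness_panel = deaf, exclusion_panel = excl)
}))
write_report(shared, "results/shared_genes.tsv")

cat(sprintf("%d gene/subgroup pairs are mutated in every member of a subgroup:\n",
            nrow(shared)))
print(as.data.frame(shared), row.names = FALSE)
if (any(shared$exclusion_flag)) {
  cat("Genes flagged as exclusion candidates are platform-artifact-prone;\n")
  cat("they are marked, not removed.\n")
}
cat("Table written to results/shared_genes.tsv\n")
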