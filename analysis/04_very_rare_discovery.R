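#!/usr/bin/env Rscript
# Very-rare-variant discovery (MAF < 0.5%, majority tier): genes recurrently
# mutated across individuals, identical variants shared between individuals,
# apparently-homozygous variants, multi-variant genes within one individual
# (candidate compound heterozygotes), and the GWAS-candidate lookup.
# Writes tables under results/very_rare/.

suppressMessages(library(exoburden))

cohort <- read_cohort_vcf("results/cohort/cohort.vcf",
                          annotation_source = "sidecar",
                          sidecar_path = "results/cohort/cohort.annotations.tsv")
deaf <- read_gene_panel("results/cohort/panel_deafness.txt", name = "deafness")
excl <- read_gene_panel("results/cohort/panel_exclusion.txt",
                        name = "exclusion", is_exclusion = TRUE)
gwas <- read_gene_panel("results/cohort/panel_gwas.txt", name = "gwas")

cfg <- filter_preset("very_rare")
dir.create("results/very_rare", recursive = TRUE, showWarnings = FALSE)

rec_genes <- recurrent_genes(cohort, cfg, deafness_panel = deaf,
                             exclusion_panel = excl)
write_report(rec_genes, "results/very_rare/recurrent_genes.tsv")
cat(sprintf("%d genes bear very rare predicted pathogenic variants in 2+ people;\n",
            nrow(rec_genes)))
cat(sprintf("  the most recurrent: %s (%d individuals)\n",
            rec_genes$gene[1], rec_genes$n_individuals[1]))

rec_vars <- recurrent_identical_variants(cohort, cfg)
write_report(rec_vars, "results/very_rare/recurrent_variants.tsv")
cat(sprintf("%d identical very rare variants are shared by 2+ individuals\n",
            nrow(rec_vars)))

hom <- homozygous_rare(cohort, cfg)
write_report(hom$records, "results/very_rare/homozygous.tsv")
write_report(hom$multi_person_genes, "results/very_rare/homozygous_multi_person.tsv")
cat(sprintf("%d apparently-homozygous very rare variants (%s)\n",
            nrow(hom$records), hom$caveat))

mh <- multi_hit_genes(cohort, cfg)
write_report(mh, "results/very_rare/multi_hit.tsv")
top <- mh[which.max(mh$n_variants), ]
cat(sprintf("%d (sample, gene) pairs carry 2+ very rare variants; the extreme case:\n",
            nrow(mh)))
cat(sprintf("  %s carries %d variants in %s (same-chromosome evidence: %s)\n",
            top$sample_id, top$n_variants, top$gene,
            top$same_chromosome_evidence))

cand <- candidate_lookup(cohort, cfg, gwas)
write_report(cand, "results/very_rare/gwas_candidates.tsv")
cat(sprintf("%d very rare passing variants fall in the %d GWAS candidate genes\n",
            nrow(cand), length(gwas$genes)))
cat("Tables written under results/very_rare/\n")
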