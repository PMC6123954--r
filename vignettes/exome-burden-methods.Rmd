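---
title: "Methods: variant prioritisation, gene burden and cohort discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritisation, gene burden and cohort discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoburden)
```

## The problem

Whole-exome sequencing of a patient with a heterogeneous disorder such as
adult-onset hearing loss yields tens of thousands of coding variants, of
which at most a handful are causal. The standard clinical approach is a
prioritisation cascade: discard low-confidence calls, discard variants too
common to cause a rare or strongly penetrant phenotype, keep only
protein-altering consequence classes, and then require support from
in-silico pathogenicity predictors. What survives is screened against
curated disease-gene panels and examined for patterns across a cohort —
genes shared by all members of a phenotype subgroup, genes or identical
variants recurring across unrelated individuals, homozygous very rare
variants, and genes carrying several rare variants in one person
(candidate compound heterozygotes).

A central and counter-intuitive fact about this screen is how *leaky* it
is: under permissive settings essentially every exome — affected or not —
implicates many known disease genes. `exoburden` implements the cascade
and the downstream cohort analyses as tested, reusable functions, together
with a synthetic cohort generator whose truth table makes every stage
verifiable, so that both the screen and its failure modes can be studied
quantitatively.

## The filtering cascade

Each annotated alternate allele passes through four stages, in order.
Every failing stage is recorded, not just the first, so audit counts can
be reconstructed for any stage ordering.

1. **Site quality.** `QUAL >= 30`, read depth `>= 20`, mapping quality
   `>= 45`, all inclusive. Variants with a missing metric fail with the
   stage label `quality:missing`. For pre-validated call sets (e.g.
   reference-project genotypes that have already been filtered upstream)
   the gate is disabled and everything passes; disabling the gate can only
   enlarge the pass set.
2. **Minor allele frequency.** The variant's MAF in the primary reference
   population is compared with the configured threshold. When the primary
   population has no record, a fallback population is consulted; when
   neither has a record the variant is treated as *novel* with an
   effective MAF of 0, so novel variants pass every rarity gate — the
   conventional choice in rare-disease work, where an unobserved allele is
   presumed rare. The comparator is configurable because usage mixes both
   conventions: the 10% screen is inclusive (`<=`), the 0.5% and 0.05%
   screens strict (`<`). Thresholds of interest are 10% and 1% for the
   common-variant screen, 0.5% for recessive-model discovery and 0.05%
   for a strict dominant screen.
3. **Consequence severity.** The controlled vocabulary has thirteen
   classes; the retained set defaults to the five loss-of-function (LoF)
   classes — transcript ablation, essential splice site (the ±2 bp
   dinucleotide only; deeper intronic positions near a junction are
   `splice_region`), frameshift indel, stop gain, start loss — plus
   missense, in-frame indel and splice region.
4. **Pathogenicity tier.** Predictor verdicts are one-vote annotations in
   {deleterious, benign, unknown}. Only informative (non-unknown) calls
   enter the vote. The three nested tiers are: `majority` (deleterious
   calls strictly outnumber half the informative calls), `all` (at least
   one informative call, all deleterious) and `lof_only`. LoF variants
   pass every tier without predictor support. A non-LoF variant with no
   informative call fails both voting tiers: with the vote denominator
   undefined, neither auto-pass nor auto-fail is defensible, so the
   conservative choice is to require at least one informative call. The
   nesting `lof_only ⊆ all ⊆ majority` holds by construction and is
   enforced by property tests.

A separate *cross-population flag* marks variants that are rare in the
primary population but common (frequency above 10% by default) in another
population with a recorded frequency. This is informational only — such
variants are retained, because excluding them would silently encode an
ancestry assumption — but the flag matters for interpretation: a variant
at 0.3% in the reference population can be present in more than half of
another population.

## Burden and discovery analyses

**Gene burden** is the number of distinct panel genes in which an
individual carries at least one passing variant. Zygosity is deliberately
ignored (a dominant-model screen: one damaged allele suffices), and genes
on the platform-artifact exclusion list contribute to counts but are
flagged; a switch recomputes with them removed. Burden distributions
across a cohort are compared with a Wilcoxon rank-sum test
(normal approximation without continuity correction, since burden counts
are heavily tied).

**Subgroup-shared genes** require a passing variant in *every* member of
a phenotype subgroup; reports carry the distinct-variant count and a
consequence-type summary. **Recurrent genes** and **recurrent identical
variants** count distinct carriers per gene and per exact
(chrom, pos, ref, alt) allele respectively. **Apparently-homozygous**
records are reported with an explicit caveat: short-read genotypes cannot
distinguish homozygosity from hemizygosity or an overlapping deletion,
and sample sex is not modelled, so X-linked calls in males are
indistinguishable from true homozygotes here. **Multi-variant genes** per
(sample, gene) are candidate compound heterozygotes; two variants are
`confirmed` to share a chromosome only when they lie within one
read-length (100 bp default) *and* phased genotypes put them on the same
haplotype, `refuted` when phasing puts them on opposite haplotypes within
the window, otherwise `unknown` — without family members, phasing
evidence of this kind is all that is available.

Report ordering is always deterministic (descending carrier count, then
gene symbol; variants by key), so reruns give byte-identical files.

## The synthetic cohort generator

The generator emulates the structure of a 30-exome study: subgroups
`Dominant`/`Recessive`/`Metabolic`/`Sensory` of sizes 10/10/5/5; a
deafness panel of 357 genes with a 33-gene dominant-model subset; 265
retinal genes; 507 platform-artifact exclusion candidates (20 of which
also sit on the deafness panel, exercising the dual-flag case); and 8
GWAS candidate genes. Genes are intervals on synthetic chromosomes, so no
genome build is needed.

Per sample and gene, a variant is drawn Bernoulli(`per_gene_hit_prob`,
default 0.08 — yielding a few hundred annotation-level candidate variants
per exome, the scale at which such screens operate after upstream
annotation); exclusion-panel genes get a 3× inflated rate, emulating
their artifact-proneness. True MAFs are log-uniform on [1e-5, 0.5]; 5% of
variants are novel (no population record) and 10% of the rest lack the
primary-population record, exercising the fallback. A latent
deleteriousness (35% of variants) drives consequence class (12% of
deleterious variants are LoF) and five predictor verdicts that agree with
the latent state with probability 0.9 and are `unknown` with probability
0.15. Background carriers are homozygous with probability 0.04.

Planted facts are injected *after* background generation, at positions
reserved so they never collide with background variants: one
subgroup-shared gene per subgroup (at MAF 2–9%, so the fact exists at the
common tier and *cannot* leak into the very-rare analyses — the
recessive-type subgroup's gene is drawn from the exclusion-only list,
reproducing the artifact-prone shared-gene case), five recurrent
identical variants with 2–3 carriers each, three homozygotes, and one
five-variant gene in a single dominant-subgroup individual, all at
MAF < 0.4%. A top-up pass guarantees each sample at least 10
deafness-panel genes passing the common/majority screen, mirroring the
qualitative behaviour of real exomes against large disease panels. The
truth table records every planted fact and, per variant, the generator's
own bookkeeping of which screens it passes.

What the generator does **not** model: linkage disequilibrium and
population sharing of specific background alleles (background variants
are unique to one carrier; only planted variants recur), mutation-rate
heterogeneity, sample relatedness, sex chromosomes, and annotation error.
Passing tests therefore demonstrate the correctness of the pipeline's
logic under a clean independence model, not robustness to the
correlation structure of real call sets.

## Numerical and design choices

* Effective MAF comparisons are exact floating-point comparisons; the
  thresholds are round decimals and frequencies are data, so no epsilon
  is applied.
* Multiallelic records are decomposed into one row per alternate allele;
  a `1/2` genotype is heterozygous for each allele. Variants annotated to
  several genes are duplicated rows sharing one key; keyed analyses
  deduplicate by (key, sample).
* The sidecar annotation table wins over inline INFO fields when both are
  supplied, since sidecars are typically the more recent re-annotation.
* Missing genotypes (`./.`) never count as carriers.
* The "worst consequence across supplied annotations" convention is used
  per variant; per-transcript resolution is out of scope.
* Monte-Carlo calibration: the expected number of background genes shared
  by all `m` members of a subgroup is `G · p^m` with `G` background genes
  and per-individual passing-hit probability
  `p = per_gene_hit_prob × [frac_novel + (1 − frac_novel) · P(MAF ≤ t)]`
  under full predictor concordance, with `P(MAF ≤ t)` from the
  log-uniform spectrum. The test suite checks the empirical mean over 200
  replicates (subgroup size 5, 1200 background genes, hit probability
  0.35 — chosen so the expectation is ≈3 genes, large enough for a
  non-degenerate Monte-Carlo error) against this value within three
  Monte-Carlo standard errors.
* Problem sizes in the test suite: property suites run on 50 seeded
  compact cohorts (6 samples, ~200 genes); recovery tests on the full
  default 30-sample design; the oracle-equivalence check on 1000 random
  variants across 4 thresholds × 3 tiers. These sizes give stable
  statistics while keeping a full run to a few minutes.

## Known limitations

* Predictors are interchangeable one-vote annotations; no weighting or
  calibration of individual tools is attempted, and the package never
  computes predictions itself.
* The packaged gene panels mix genuinely implicated genes with clearly
  synthetic filler symbols (`SYNDEAF###` …) at the curated panels'
  published sizes; they are fixtures for reproducible analysis, not
  clinical panels.
* Burden comparison is a rank test on per-individual counts; formal
  rare-variant association (SKAT/CMC-style collapsing) is out of scope.
* No segregation, pedigree or phasing-from-reads analysis: the package
  targets the single-proband setting where none of these are available.
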