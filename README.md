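# mpralleles

Analysis of massively parallel reporter assay (MPRA) screens of
disease-associated regulatory variants: from allele-specific oligo design
and barcode counting to the identification of **enhancer variants
(enVars)**, **allelic enVars**, resampling-based functional-genomics
enrichment, allele-specific ChIP-seq imbalance, and the classification of
**variant overlapping** versus **variant adjacent** transcription factors.

The package is aimed at regulatory-genomics groups running MPRA screens
over GWAS risk loci (for example autoimmune-disease fine-mapping panels)
who need a self-contained, reproducible calling pipeline with explicit
decision thresholds, plus a seeded synthetic-data module that generates
ground-truth inputs for every stage.

## The statistics at the core

**Enhancer activity.** Each designed oligo *i* (one allele of one variant,
170 bp of genomic sequence centred on the variant) is tagged by many
20-bp barcodes. Barcode counts are summed per oligo; oligos with fewer
than 30 distinct plasmid barcodes are dropped. With median-of-ratios size
factors *s<sub>j</sub>*, normalized counts *q<sub>ij</sub> =
K<sub>ij</sub>/s<sub>j</sub>*, and group means μ<sub>R</sub> (mRNA) and
μ<sub>D</sub> (plasmid), the activity test is a negative-binomial Wald
test of

&nbsp;&nbsp;log2FC<sub>i</sub> = log₂(μ<sub>R</sub>/μ<sub>D</sub>),&nbsp;&nbsp;
SE² = (1/ln2)² [ (1/n<sub>R</sub>)(1/μ<sub>R</sub> + α<sub>i</sub>) +
(1/n<sub>D</sub>)(1/μ<sub>D</sub> + α<sub>i</sub>) ]

with a trended moment estimate of the dispersion α<sub>i</sub>, and
Benjamini–Hochberg correction. An **enAllele** has p<sub>adj</sub> < 0.05
and fold ≥ 1.5; an **enVar** is any variant with an enAllele; the negative
set for enrichment is the variants with no allele at p<sub>adj</sub> < 0.05
and fold > 1.10.

**Allelic activity.** For each enVar, per-barcode plasmid-normalized log
ratios r<sub>b</sub> = log₂((RNA<sub>b</sub>/sf + 1)/(DNA<sub>b</sub>/sf + 1))
are compared between alleles with a pooled-variance Student's t-test,
BH-corrected; an **allelic enVar** needs p<sub>adj</sub> < 0.05 and a
≥ 25% activity difference between alleles.

**Peak-set enrichment.** The overlap of a variant set with a peak set is
compared against 2000 draws of size-matched sets from the negative pool;
z = (obs − mean)/sd with a one-sided normal p and Bonferroni correction
across peak datasets.

**Allelic binding.** At heterozygous in-peak variants, imbalance strength
is 1 − weak/strong read counts (0.5 ⇔ a 2:1 ratio). A (variant, dataset)
is allelic when all replicates prefer the same allele with
min-replicate strength > 0.4, a binomial test against 0.5 gives p < 0.05,
and ≥ 6 reads are available; three consistency filters (≥ 50% of
heterozygous datasets allelic, ≥ 75% preferring the same allele,
replicate-consistent direction) are then applied per protein.

**Motifs.** PWMs are scored by log₂ likelihood over both strands; the
best score is expressed as a percentage of the motif's maximum (the
*relative PWM score*). A **binding-site altering event** is one allele
scoring ≥ 70% and the other < 40% in windows covering the variant.
Allelically bound TFs with such an event are *variant overlapping*;
without one they are *variant adjacent*. Family-level enrichment uses
two-proportion z-tests, with dinucleotide-shuffled backgrounds for the
adjacent analysis.

## Worked example

```r
library(mpralleles)
cfg <- default_config(seed = 1, out_dir = "mpra_demo")
report <- run_pipeline(cfg)
unlist(report[c("n_variants", "n_oligos_retained", "n_enAlleles",
                "n_enVars", "n_allelic_enVars", "n_loci_with_allelic")])
#>          n_variants   n_oligos_retained         n_enAlleles
#>                  24                  48                  16
#>            n_enVars    n_allelic_enVars n_loci_with_allelic
#>                   8                   4                   3
```

The synthetic study plants 8 enhancer variants (activity fold 2.5) and 4
allelic variants (2-fold allele ratio) among 24 variants at 6 loci; the
report shows the pipeline recovering exactly those: 16 enAlleles (both
alleles of each planted enhancer are active), 8 enVars, and the 4 planted
allelic enVars spread over 3 loci. Per-stage TSVs land in `mpra_demo/`,
e.g. the top of `activity_results.tsv`:

```
    oligo_id log2_fold_change    p_adj is_enAllele
   var0009|C             2.31 3.87e-84        TRUE
   var0011|T             2.31 3.87e-84        TRUE
   var0003|G             2.30 7.58e-84        TRUE
```

Individual stages are exposed directly, e.g.

```r
strength(100, 50)      # allelic binding strength of a 2:1 imbalance
#> [1] 0.5
strength(77, 18)       # a strongly imbalanced site
#> [1] 0.7662
```

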