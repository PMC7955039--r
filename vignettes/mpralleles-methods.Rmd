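---
title: "Methods and design notes for mpralleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mpralleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpralleles)
```

# Scope

`mpralleles` implements an end-to-end analysis for massively parallel
reporter assay (MPRA) screens of candidate regulatory variants: oligo
design, barcode processing, enhancer-activity and allelic-activity
calling, resampling-based peak-set enrichment, allele-specific ChIP-seq
imbalance with consistency filtering, relative-PWM-score motif analysis,
and tiered target-gene annotation. A synthetic-data module generates
seeded inputs with known ground truth for every stage; it is first-class,
tested code, and the basis of the package's calibration and power tests.

# Oligo design

Each allele of each variant yields a genomic core sequence with the
variant centred: for SNPs, 84 bases upstream + the allele base + 85
bases downstream (170 bp exactly). For indels the flanks are chosen so
that the longest allele reaches exactly 170 bp, and all alleles share
byte-identical flanks. The indel anchor is a genuine design choice — the
length rule alone does not fix it — and we anchor the first base of the
longest allele at core position 85 (1-based), truncating the 3' flank.
Fixed 15-bp adapters (`ACTGGCCGCTTGACG`, `CACTGCGGCTCCTGC`) bring a SNP
oligo to 200 bp. Forward and reverse-complement records are produced per
allele and merged again at counting time, since they measure the same
allele. Coordinates are 1-based in variant tables (VCF-like), and BED
files are read and written in their native 0-based half-open convention
through `rtracklayer`.

# Barcode processing

Reads are laid out as a 20-bp barcode followed by a constant region.
A read is kept iff the Levenshtein distance of its constant segment from
the reference is at most 4 **and** the two bases directly adjacent to
the barcode match exactly; rejections are tallied by reason. Barcodes
observed with more than one oligo are discarded outright. Counts are
summed to oligo level, and oligos with fewer than 30 distinct barcodes
in the plasmid control are removed. The 30-barcode floor matters: the
per-oligo totals inherit their stability from averaging hundreds of
barcodes, and the activity model below leans on that.

# Enhancer-activity model

Let $K_{ij}$ be the barcode-summed count of oligo $i$ in sample $j$,
$s_j$ the median-of-ratios size factor, and $q_{ij} = K_{ij}/s_j$. With
group means $\mu_R$ (mRNA, $n_R$ replicates) and $\mu_D$ (plasmid,
$n_D$), the reported effect is
$\widehat{\mathrm{LFC}}_i = \log_2(\mu_R/\mu_D)$ and the Wald statistic
uses the delta-method standard error under a negative-binomial model
with dispersion $\alpha_i$:

$$\mathrm{SE}^2 = \frac{1}{\ln^2 2}\left[
  \frac{1}{n_R}\left(\frac{1}{\mu_R} + \alpha_i\right) +
  \frac{1}{n_D}\left(\frac{1}{\mu_D} + \alpha_i\right)\right].$$

P-values are two-sided normal, BH-corrected across all tested oligos
(controls included, one family per run). The decision thresholds are
$p_{adj} < 0.05$ with fold $\ge 1.5$ for enAlleles, the any-allele rule
for enVars, and the "no allele with $p_{adj} < 0.05$ and fold $> 1.10$"
rule for the negative set used by the enrichment stage.

## Dispersion estimation

Per-oligo method-of-moments dispersions
$\hat\alpha_i = (s_i^2 - \mu_i)/\mu_i^2$ (within-group moments averaged
across groups) are far too noisy at $n = 3$ replicates per arm: plugging
them directly into the Wald test yields a null type-I error around
0.10–0.12 (measured by simulation), because the Wald z treats a 4-df
variance estimate as known. The default `"trended"` method therefore
fits $\alpha(\mu) = a_0 + a_1/\mu$ across all oligos by least squares
and uses the fitted value per oligo, floored at 0.01. This is the same
information-sharing idea as DESeq2's dispersion trend or limma-trend,
reduced to its simplest form; with hundreds of oligos the trend is
estimated accurately and the null rejection rate sits at the nominal
5% (the test suite asserts the 0.03–0.07 band). The per-oligo estimator
remains available (`dispersion_method = "per_oligo"`) for users who
want strictly row-local inference. A consequence of trend-only
dispersions is that single oligos with genuinely extreme dispersion are
tested slightly anti-conservatively; at MPRA barcode depths this is a
minor effect.

Oligos with zero plasmid counts cannot be normalized against and are
excluded with a flag; oligos with zero mRNA everywhere get the sentinel
$\mathrm{LFC} = -10$ and are never called active.

# Allelic-activity model

Only enVars are tested. For each barcode $b$ of an allele, counts are
pooled across replicates within each arm, and the per-barcode ratio is

$$r_b = \log_2\frac{\mathrm{RNA}_b/\mathrm{sf}_R + 1}
                    {\mathrm{DNA}_b/\mathrm{sf}_D + 1},$$

with the pseudocount applied after size-factor scaling. We deliberately
produce **one ratio per barcode**: computing one ratio per (barcode ×
mRNA replicate) would reuse the same plasmid denominator several times,
and the resulting correlation inflates the Student's t type-I error to
about 0.10 (measured). With independent per-barcode ratios the t-test
(pooled variance, as named) calibrates at the nominal level. All allele
pairs of all enVars form one BH family; an allelic enVar needs
$p_{adj} < 0.05$ and a between-allele fold $\ge 1.25$ (or $\le 0.8$).
For multi-allelic variants the variant-level genotype dependence is
reported from the pair with the smallest adjusted p, with all pairs
retained in the output.

# Resampling enrichment

For each peak dataset, the observed number of input variants overlapping
a peak (by $\ge 1$ base; each variant counted once; variants are 1-base
ranges, indels span their reference allele) is compared against a null
of 2000 draws of $|{\rm input}|$ loci sampled **without replacement**
from the negative set. $z = (\mathrm{obs} - \mathrm{mean})/\mathrm{sd}$,
one-sided upper normal p, Bonferroni across the datasets actually
tested. Degenerate nulls (sd = 0) report $p = 1$ when the observation
does not exceed the mean, otherwise a flagged upper bound of
$1/n_{\mathrm{iter}}$. Matching is on the number of loci only; matching
on further covariates (e.g. allele frequency) is out of scope.

# Allelic ChIP-seq imbalance

The strength statistic is $1 - \min(a,b)/\max(a,b)$: 0 for balanced
reads, 0.5 when the strong allele has twice the reads. The per-dataset
reproducibility score is the minimum replicate strength when all
replicates prefer the same allele and 0 otherwise (a tied replicate
prefers neither and breaks consistency). A dataset call additionally
requires a two-sided binomial test against 0.5 on the replicate-summed
reads ($p < 0.05$) and at least 6 total reads — below that the binomial
test has essentially no power, so the floor only removes calls that
could never be significant. The score function is pluggable
(`score_fun`), so a different replicate-combination scheme can be
swapped in without touching the filters; the 0.4 score threshold is
calibrated for the default score and should be revisited for any
replacement. Three consistency filters then act per (variant, protein):
allelic in $\ge 50\%$ of heterozygous datasets, the same allele
preferred in $\ge 75\%$ of allelic datasets, and replicate-consistent
direction everywhere; summaries report the median strength (per cell
line, then across cell lines) and "(k of n)" dataset counts.

# Motif analysis

PWMs (any MEME-minimal collection; a `FAMILY` line or the alternate
name supplies the family label) are regularized with a $10^{-3}$
per-cell pseudocount and scored as $\sum_j \log_2 (p_{b_j j}/\pi_{b_j})$
over both strands, with a uniform background by default. The *relative
score* is $100 \times \mathrm{score}/\mathrm{max\ score}$; negative
scores are left negative rather than floored, since only the $\ge 70$ /
$< 40$ comparisons matter and flooring would discard the ordering of
poor matches. Alleles are padded with 25 bp of genomic flank. For
altering-event detection, only windows covering at least one variant
base compete: with identical flanks, a distal strong site would
otherwise mask the variant's local effect. Both thresholds and the
restriction are configurable.

Family-level testing uses the pooled two-proportion z-test (two-sided,
BH across families). The variant overlapping analysis compares the
fraction of allelic enVars carrying an altering event per family against
non-allelic enVars; the variant adjacent analysis compares motif-hit
fractions (best relative score $\ge 70$ anywhere in the 170-bp core)
against dinucleotide-shuffled versions of the same sequences, one
shuffle per input, via the Altschul–Erickson Eulerian-walk shuffle
(exact dinucleotide preservation, seeded). Reported rows additionally
need $\ge 3$ allelic events (overlapping) or $\ge 5$ predicted sites
(adjacent) and $p_{adj} < 10^{-4}$; the full tables always carry every
family. The same 70% cutoff defines a "hit" in both analyses — one
consistent definition rather than a second tunable threshold.

# Annotation

Target genes are the union of promoter-looping genes and eQTL genes,
falling back to the nearest gene (distance to the transcript span, ties
broken lexicographically — the anchor is otherwise ambiguous). Tiers:
1 = same gene supported by both eQTL and looping; 2 = any eQTL;
3 = looping only; 4 = neither.

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of (parameters, seed) and ship their
truth tables. Defaults mirror the study conditions the pipeline is built
for: 3 replicates per arm, barcode multiplicities from a rounded
lognormal with median 729 (log-sd 0.4, approximating the observed
near-normal histogram), negative-binomial barcode counts with dispersion
0.05 (typical for MPRA plasmid libraries), planted enhancer folds
$\ge 1.5$ and allelic ratios $\ge 1.25$, peak widths 200–1000 bp,
and replicated binomial allelic reads at heterozygous sites. Barcode
abundances are lognormal and shared between arms, emulating library
composition carried from plasmid to transfection.

Not emulated: sequencing-error read profiles (only small read fixtures
for the constant-region filter), PCR jackpotting, batch effects between
replicates, linkage structure between variants, and real genomic
sequence composition (flanks are i.i.d. uniform ACGT). Passing the
calibration and recovery tests therefore demonstrates correctness of
the statistical machinery under the stated model, not robustness to
real-data artifacts such as replicate-level overdispersion beyond the
NB model.

A note on composition: the power tests plant effects in a minority
(20–25%) of oligos because median-of-ratios normalization anchors on
the null majority; a library where half the oligos are strong enhancers
shifts the anchor and biases all fold changes — a property of the
normalization, not an implementation artifact.

# Problem sizes and numerical choices

The shipped tests and the default pipeline run at desk scale, chosen so
the full suite exercises every stage on realistic distributions: null
calibration at 1000 oligos / 500 variant pairs, power at 100–150 oligos
with study-scale (median 729) barcode multiplicities, enrichment at
40 input / 400 negative variants with 2000 iterations (200 for the
repeated-null uniformity check), and a 24-variant end-to-end run. The
default pipeline completes in well under a minute; determinism is
asserted byte-for-byte across repeated runs with the same seed. All
randomness flows through a single master seed via a fixed integer
derivation per stage. Ties and degenerate inputs are handled explicitly:
equal read counts give strength 0 and no preferred allele; all-zero
oligo rows are excluded; degenerate resampling nulls are flagged rather
than assigned fake z-scores.

# Known limitations

- The activity test shares dispersion information only through a trend;
  no per-oligo empirical-Bayes shrinkage, outlier handling, or LFC
  shrinkage is attempted.
- The replicate-reproducibility score is a deliberately simple stand-in
  interface for more elaborate allelic-reproducibility schemes; its 0.4
  threshold is meaningful for this score, and comparability to other
  scores' thresholds is not claimed.
- Enrichment matching is on locus count only.
- The relative-score scale ties hits to the motif's own maximum;
  information-poor motifs reach 70% more easily than sharp ones, which
  is inherent to percent-of-maximum scoring.
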