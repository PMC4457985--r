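---
title: "Methods: subgroup allelic screening, the two-locus protective score, and altitude clines"
author: "ClineScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgroup allelic screening, the two-locus protective score, and altitude clines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClineScreen)
```

## The scientific setting

ClineScreen implements a stratified association analysis for a cohort of
healthy individuals phenotyped into contrasting constitution subgroups
(labelled V, P and K) drawn from a single, genetically homogeneous
Indo-European background, together with a larger pool of unphenotyped
controls from the same background (the IE pool). The working hypothesis is
that phenotype-based stratification of healthy people can expose common
SNP allele-frequency differences that are averaged out when the subgroups
are pooled — and that two such loci, one in the hypoxia sensor *EGLN1*
(rs480902) and one in the hemostasis gene *VWF* (rs1063856), act
additively on a thrombosis/altitude-adaptation axis. At both loci the T
allele is designated **protective** (high-altitude-associated at *EGLN1*,
derived non-thrombotic at *VWF*) and the C allele is the **risk** allele.
Protective/risk and ancestral/derived status are annotation inputs
asserted by the analyst; the package never infers them.

The pipeline has four analysis stages, each usable on its own:

1. **Allelic screen** (`screenAssociations`): per-SNP Fisher exact tests
   between subgroups, with FDR control.
2. **Combined score** (`scoreSamples`, `enumerateComboTable`): an
   unweighted count of protective alleles over designated loci.
3. **Score regressions** (`fitScoreBinary`, `fitScoreMultinomial`):
   association of the score with subgroup or altitude-class labels.
4. **Altitude cline** (`summarizePopulations`, `clineTest`): rank
   correlation of per-population mean scores with altitude across a
   worldwide panel.

A synthetic-data module (`simCohort`, `simPanel`, `simStudyCohort`)
generates Hardy–Weinberg cohorts with exactly the statistical structure
the analysis assumes, so every stage can be exercised, calibrated and
power-checked without access to restricted individual-level genotypes.

## Genotype representation

Genotypes live in a `GenotypeExperiment`, a `SummarizedExperiment` whose
single assay holds the per-(locus, sample) dosage of the locus'
*effect allele*: 0, 1, 2 or `NA`. Coding against a user-designated effect
allele (rather than a computed ancestral/derived state) keeps the
container agnostic about downstream interpretation; the score stage
recodes to protective-allele dosage where the protective allele is the
non-effect member of the pair. Readers exist for a simple genotype TSV
dialect (two-letter unphased genotype strings, missing token `"NN"`,
strand-naive — letters must match the annotations exactly, no flipping)
and for VCF (GT subfield only, indices mapped through REF/ALT). Missing
genotypes are excluded per SNP per comparison (complete-case per SNP),
the standard convention when per-SNP missingness varies.

## The allelic screen

For each locus and each ordered comparison `"G1vsG2"` (either side may
pool labels with `+`, e.g. `"V+P+KvsIE"`), the screen builds the 2×2
allele-count table and, optionally, the 2×3 genotype-class table, and
computes two-sided exact p-values. The 2×2 p-value is implemented
directly on the hypergeometric density with the point-probability
(minimum-likelihood) two-sided rule — the convention of mainstream
packages — using a relative tolerance of 1e-7 to absorb floating-point
ties between table probabilities; this in-package kernel is vectorisable
over thousands of tables, which matters for simulation-based
calibration. The 2×3 test delegates to `stats::fisher.test` (network
algorithm, same two-sided rule). Any table with a zero margin is
reported as p = 1 with a `degenerate` flag rather than an error: an
empty margin carries no information about association. No dominant or
recessive collapse of the genotype table is computed; the 2×3 dosage
classes are tested as observed.

Multiple testing is corrected with the Benjamini–Hochberg step-up
procedure (`bhAdjust`, delegating to `stats::p.adjust`), the default
meaning of "FDR" in this literature; Benjamini–Yekutieli is available
for dependent tests. The FDR family is, by default, *all loci within one
comparison* — each subgroup contrast is a separate screening question —
with `family = "joint"` pooling everything into one family. Both the
allelic and genotypic arms are emitted with their own q-values, since
which arm carries a given claim is usually left unstated in published
screens; the package's own calibration and recovery tests key on the
allelic arm, matching the fact that published contrast tables print
allele frequencies.

## The combined protective score

With k designated loci the score of an individual is the total count of
protective alleles, an integer in 0..2k; for the default two-locus
EGLN1/VWF configuration the nine two-locus genotype combinations map to
scores 0 (CC/CC) through 4 (TT/TT), enumerated by
`enumerateComboTable()`:

```{r combo}
enumerateComboTable()
```

Loci are unweighted (the score is a count, not an effect-size-weighted
burden score), and a sample missing a call at any configured locus is
excluded from score analyses by default (`missingPolicy = "keep_na"`
retains it with `NA`): listwise exclusion is the conservative reading of
a per-individual count.

## Score regressions

The score enters the regressions as a *numeric* predictor with the group
as outcome; a three-level outcome uses a baseline-category (multinomial)
logit, a two-level outcome a binary logistic model. P-values are
likelihood-ratio tests against the intercept-only model (chi-square,
df = levels − 1), preferred over Wald tests at subgroup sizes near 30.
The binary fit is `stats::glm`; the multinomial fit takes starting
values from `nnet::multinom` and is then polished by Newton–Raphson with
step-halving on the full likelihood, so the attained deviance — and
therefore the omnibus LRT — is invariant to the choice of reference
level and to sign-flips of the score coding to high precision (the
intercept-only multinomial deviance has the closed form
−2·Σ nⱼ log(nⱼ/n) and is computed exactly). Per-level contrasts against
the reference are fitted as binary logistics on the corresponding sample
subsets. Perfect separation is detected heuristically (diverging
coefficients / saturated fitted probabilities); the fit is then flagged
`converged = FALSE` with a warning and the LRT is reported at the
boundary. No covariates are modelled. Score-as-categorical and ordinal
models are out of scope.

## The altitude cline

`summarizePopulations` reduces scored samples to one row per population
(n, mean score, frequency of the maximum score 2k — the fully protective
homozygous combination — and altitude in metres; population altitudes
are metadata supplied by the analyst). `spearmanCorrelation` computes
Spearman's rho as the Pearson correlation of mid-ranks (ties receive
average ranks) and a **two-sided** p-value: exact permutation
enumeration over all n! orderings when n ≤ 8, and the t-approximation
with n − 2 degrees of freedom otherwise. Two-sided is the conservative
choice when the claimed direction (protective scores rising with
altitude) is not certain a priori; the exact/approximate cutover at
n = 8 (40,320 permutations) keeps desk-scale runtime while giving exact
inference for very small panels. Either vector having zero variance is
flagged degenerate (rho undefined, p = 1). `clineTest` applies this to
mean score vs altitude and, in parallel, to the top-score frequency vs
altitude.

## The synthetic-data generator

`simCohort` draws each dosage as Binomial(2, group frequency) —
Hardy–Weinberg proportions — with loci independent. No linkage
disequilibrium is simulated: the screen tests tag SNPs marginally and
the score treats loci additively, so LD would change none of the tested
quantities' definitions, only their joint sampling noise. Calls are
masked missing independently at a configurable rate. Draws are
reproducible from an integer seed, with spawn-keyed per-group sub-seeds
so one group's genotypes do not depend on the other groups' sizes.

`simStudyCohort` encodes the default study conditions: subgroups V/P/K
of sizes 39/29/28 plus an IE pool of 92 (188 samples), and 2,800 loci —
eight named SNPs in seven genes (*LEPR*, *OR6K3*, *UCP2*, *OLR1*,
*SPTA1* ×2, *VWF*, *OR10Z1*) carrying nine published per-group
allele-frequency contrasts (e.g. *VWF* rs1063856 risk-C frequency 0.05
in P vs 0.37 in K), the *EGLN1* score locus rs480902, and 2,791 null
SNPs whose shared frequency is drawn uniformly on (0.05, 0.95). Two
gaps in the published table are filled by explicit convention: the
subgroup not involved in a SNP's printed comparison receives the
midpoint of the two printed frequencies, and the IE pool receives the
size-weighted mean of the three subgroup frequencies (so pooled
subgroups match the background, as observed). The rs480902 per-group
frequencies (protective T: V 0.55, P 0.82, K 0.30) are *synthetic
defaults* — its cohort frequencies were published separately — chosen to
contrast P against K in the protective direction. The generating truth
travels with the object in `metadata()`.

`simPanel` builds population panels along a logistic-in-altitude
frequency cline (`logisticCline` anchors the curve at two
altitude/frequency pairs; the logistic form keeps frequencies in [0, 1]
over any altitude range, and a flat cline gives the exchangeable null
panel used for calibration).

What the generator deliberately does **not** emulate: linkage
disequilibrium and haplotype structure, array ascertainment bias,
population substructure within groups, genotyping error, and non-HWE
inbreeding. Tests passing on these cohorts therefore validate the
statistical machinery under the stated sampling model, not robustness
of the original biological claims to those real-data complications.

## Calibration and problem sizes

The test suite calibrates every stochastic stage at fixed seeds: the
2×2 exact test is checked against a full enumeration oracle over every
table with total ≤ 30; BH against a brute-force step-up oracle on 1,000
random p-vectors; the exact-permutation Spearman p against full n!
enumeration for n ≤ 6; the multinomial LRT and the cline test against
1,000 null simulations each (size-96 cohorts; 20-population × 30-sample
flat panels); logistic slope recovery and planted-cline detection over
200 replicates (n = 500; 20 × 30 panels); and planted-contrast recovery
over 200 regenerations of the full 188 × 2,800 default cohort at FDR
5%, counting false discoveries over the null loci. These sizes keep the
whole suite at a few minutes on one core while leaving Monte-Carlo
standard errors of a few percent on the calibrated rates. One honest
finding from that calibration is worth stating: at subgroup sizes
39/29/28, contrasts whose exact p-values sit near 3–4 × 10⁻⁵ are at the
boundary of what BH at 5% over 2,800 SNPs can redetect when their
comparison family contains few other true signals, so resimulated
per-contrast recovery power hovers around one half for the weakest
published contrasts — a reminder that a published significant set is a
post-selection set.

## Known limitations

- Exact tests are conservative at these sample sizes (discrete p-value
  support); realized false-discovery proportions run below the nominal
  FDR level.
- The multinomial separation heuristic (coefficient magnitude) can
  misclassify extreme-but-identifiable fits; the LRT remains valid
  either way.
- The t-approximation for Spearman p at 8 < n ≲ 15 is approximate in
  the tails; the null-calibration test bounds the practical impact.
- No population-structure correction (genomic control, PCA) is offered:
  the intended cohorts are single-background by design.
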