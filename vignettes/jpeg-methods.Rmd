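---
title: "Joint analysis of phenotypes, effects, and generations: models and design choices"
author: "jpegwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint analysis of phenotypes, effects, and generations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jpegwas)
```

## The problem

In hybrid crop breeding, candidate (male) inbred lines are crossed to a
small panel of common tester (female) lines, and both the inbred parents
and the resulting testcross hybrids are phenotyped. Dissecting such data
genetically is harder than an ordinary inbred GWAS: hybrid performance
mixes additive allele-substitution effects with dominance deviations that
only heterozygotes can express, and the information about those two effect
classes is spread unevenly across the inbred and hybrid generations.

JPEG (joint analysis of phenotypes, effects, and generations) addresses
this by analysing four phenotype sources at once:

* **V** — the inbred parents' own phenotypes,
* **T** — the testcross hybrids' phenotypes,
* **G** — each male parent's general combining ability,
  $G_i = \bar{y}_{i\cdot} - \bar{y}_{\cdot\cdot}$, the mean of its
  testcrosses minus the grand testcross mean,
* **H** — each hybrid's mid-parent heterosis,
  $H_{ij} = T_{ij} - (V_i + V_j)/2$.

Each source is standardized within itself (sample-sd convention by
default; the population-sd convention is available and recorded in the
output) and stacked into one response vector $Y$. Every stacked row
carries an additive genotype row $A$ (dosage 0/1/2 of the alphabetically
higher allele) and a dominant row $D$ (heterozygosity indicator); V and G
rows reuse the parent's genotype and have identically zero $D$, T and H
rows use the hybrid genotype inferred from its parents.

## Genotypes

Parental genotypes come from a VCF of biallelic SNPs; sites with missing
rate above 20% or minor allele frequency below 5% (boundary kept) are
removed, and remaining no-calls are imputed by the per-SNP modal call with
ties resolved to the homozygote of the alphabetically lower allele. The
additive coding is **alphabetical by nucleotide**, not REF/ALT: for a
T/C SNP, C/C codes 0 and T/T codes 2. Hybrid genotypes are inferred from
the parents; by default residual parental heterozygotes (inbreds should
have none) are collapsed to the SNP's major homozygote and the hybrid call
is the union of the two parental alleles. An `expectation` mode instead
propagates Mendelian expectations (fractional dosages and heterozygosity
probabilities), for partially inbred parents.

## The association model

For each SNP $j$ the additive and dominant effects are tested in two
general linear models sharing the covariates $B$:

$$Y_i = b_0 + \sum_t B_{it} b_t + A_{ij} a_j + e_i
\qquad\text{and}\qquad
Y_i = b_0 + \sum_t B_{it} b_t + D_{ij} d_j + e_i .$$

$B$ contains per-block intercepts, the three leading principal components
of the additive genotypes of the unique individuals (each individual
enters the PCA once; scores are broadcast to its stacked rows), and one
0/1 dummy per tester female per hybrid block (T and H separately, first
female as reference). The scan is a multi-locus iteration: significant
markers are incorporated into $B$ as pseudo-QTNs and all markers are
re-tested, until the pseudo-QTN set stops changing.

### Why the marker test is whitened

The derived blocks are deterministic functions of the primary ones, so the
same measurement noise appears in several stacked rows: a male's V-noise
reappears (halved, negated) in all of his H rows, and a hybrid's T-noise
reappears in its H row and, averaged, in its male's G row. Treating the
stacked rows as independent overstates the information roughly twofold
(genomic inflation $\lambda \approx 2$ in no-signal simulations). The
package therefore keeps the OLS coefficient of the model above but tests
it against its *design-implied* variance: each stack stores a sparse
loading matrix $L$ mapping independent unit noises (one per phenotyped
parent and hybrid) to the standardized rows, and

$$\widehat{\mathrm{Var}}(\hat\beta_j) =
\hat\sigma^2_j \frac{x_j'^{\!\top} L^{\top} L\, x_j'}{(x_j'^{\top}x_j')^2},
\qquad
\hat\sigma^2_j = \frac{\mathrm{RSS}_j}
{\mathrm{tr}(\Sigma_0) - \mathrm{tr}(P_B \Sigma_0) - x_j'^{\top}\Sigma_0 x_j' / x_j'^{\top}x_j'},$$

with $x_j'$ the residualized marker column and $\Sigma_0 = L^{\top}L$.
The per-block intercepts and per-block female dummies make the residualized
markers orthogonal to every block-constant noise term, so the sparse $L$
is exact under the no-signal model. With only primary blocks stacked
($L = I$) the test reduces to the ordinary iid t-test, which is also
available everywhere as `se_type = "iid"`. In no-QTL simulations the
whitened test gives $\lambda \approx 1.00{-}1.04$ and no Bonferroni
exceedances in 20 runs, where the naive test shows $\lambda \approx 2$.

### Pseudo-QTN selection

The genome-wide threshold is $\alpha/(2m)$ for $m$ SNPs (both effect scans
Bonferroni-counted; $\alpha/m$ available). Selection per iteration:

1. candidates are the below-threshold (SNP, effect) columns plus the
   incumbent pseudo-QTNs;
2. a greedy filter in p-value order drops any candidate whose squared
   correlation with an already-kept column exceeds 0.7 (`ld_r2_max`);
3. the kept columns are re-ordered by greedy forward RSS reduction —
   with few founder genomes a marker can partially tag several true loci
   at once through chance linkage disequilibrium and outrank each of them
   marginally, and conditioning at each step lets markers carrying
   independent signal surface;
4. BIC over the prefixes of that forward path fixes the model size;
5. backward elimination in the joint model removes, one at a time, any
   marker whose joint-model p-value exceeds the genome-wide threshold —
   this enforces that every pseudo-QTN is genome-wide significant jointly
   with the others and removes chance-LD proxies of true loci.

Keeping incumbents as candidates (step 1) makes the iteration monotone in
practice; without it the selection can alternate indefinitely between
disjoint sets of mutually-correlated proxies. When a previously visited
set recurs (a cycle), iteration stops and the current scan is reported.
When testing a marker that is itself a pseudo-QTN, both of its effect
columns are removed from the covariates for its own test. Reported
p-values are those of the final iteration.

Significant SNPs within 200 kb of each other are chained (single linkage,
per chromosome) into loci positioned at the midpoint (rounded down) of
their outermost members, and classified additive, dominant, or both from
the union of their members' significant effect types.

### Power at small design scales

Detection power is bounded by the founder count, not only the row count:
all genotype columns live in a space of dimension at most the number of
parents, so with tens of founders and $10^4$ markers, chance
correlations between unlinked columns reach $|r| \approx 0.5$ and an
oracle given the true loci as covariates still leaves QTLs explaining
less than about 10% of variance hovering at the genome-wide threshold. In
our simulations, equal-share additive QTLs at 8% of hybrid variance are
recovered at only ~50–60% even by that oracle in a 50-male × 3-female
design, while the same pipeline on a 113 × 5 design (the default
`sim_config()`, the scale `scripts/acceptance.R` reruns) recovers about
two thirds of them and ~90% of dominant-only QTLs. Conclusions about
mapping power should therefore be drawn at realistic panel sizes.

## Variance components and heritability

Additive kinship follows VanRaden,
$K_a = ZZ^{\top} / 2\sum_j p_j(1-p_j)$ with $Z$ the column-centred
dosages; the dominance kinship applies the same pattern to centred
heterozygosity codes, $K_d = WW^{\top} / \sum_j h_j(1-h_j)$. Frequencies
are computed on exactly the sample set each kinship is built for.
Variance components of $y = Bb + u_a + u_d + e$ are estimated by REML —
a profiled eigen-decomposition path for a single kinship, bounded
quasi-Newton on log-variances for two — with components constrained
nonnegative. Heritabilities are reported as proportions of the total
variance including the residual; among inbreds only the additive
component is estimable (no heterozygotes). A deterministic REML estimator
was chosen over Monte-Carlo posterior sampling because it is directly
testable by parameter recovery; with the identity kinship it reproduces
the analytic OLS restricted likelihood to $10^{-6}$.

Parameter recovery is assessed under a polygenic architecture (hundreds
of QTLs), which matches the infinitesimal model the genomic-relationship
estimator assumes; under sparse architectures (a handful of QTLs) the
genome-wide kinship only partially captures the realized relationship at
the causal loci and estimates of the split between components are
noticeably noisier, although the null is clean (estimated total
heritability ≈ 0 for pure-noise traits).

## Prediction and cross-validation

Two predictors are compared by repeated twofold cross-validation in which
the hybrids are split at random into halves; all inbreds plus one half
train, the other half is predicted, both halves serve once as test, and
the split is repeated (100 times by default). Reported accuracy is the
squared Pearson correlation between predicted and observed testcross
phenotypes.

* **gBLUP** solves the mixed model with the additive kinship over the
  stacked training rows and predicts test hybrids by the conditional
  expectation $\hat u_{\mathrm{test}} = G_{\mathrm{test,train}}
  V^{-1}(y - X\hat b)$ — verified against a dense mixed-model-equation
  solve to $10^{-8}$.
* **Locus-based prediction** re-runs the full GWAS *on the training fold
  only*, uses the detected additive and dominant SNP columns as fixed
  effects, and keeps polygenic random effects with both the additive and
  dominance kinships. Detected-SNP effects are refit jointly by
  generalized least squares rather than reusing the scan estimates.

Nothing derived from phenotypes crosses the fold boundary: GCA, heterosis
and the block standardizations are recomputed from training testcrosses,
variance components are re-estimated per fold, and the PC covariates are
computed once from genotypes only. Removing the test half's phenotypes
from the input leaves the training fit bit-identical (a tested property).
On sparse architectures with detectable loci the locus-based predictor
outperforms gBLUP; when the training GWAS detects nothing it degrades to
gBLUP with an extra (dominance) kinship.

## The simulator

`sim_config()` defaults encode the study design the pipeline targets:
113 male inbreds × 5 female testers crossed factorially (565 hybrids),
fully homozygous parents, allele frequencies uniform on [0.05, 0.5], a
rice-like genome of 12 × 25 Mb chromosomes, and a trait with additive
heritability 0.4 (5 QTLs) and dominance heritability 0.2 (3 dominant-only
QTLs) among hybrids. Effects are rescaled to the *realized* sample
variances so the targets hold for each generated dataset; with
`equal_var_qtls = TRUE` every QTL contributes an equal share. QTLs are
drawn only from SNPs segregating, in the relevant coding, among the
hybrids. Inbred phenotypes use the same additive effects and residual
scale; their dominance contribution is structurally zero.

Linkage disequilibrium is emulated by block copying — within a block each
SNP copies the block founder's indicator with a per-sample flip
probability calibrated to an adjacent-pair $r^2$ of 0.8 — and optional
subpopulations draw Balding–Nichols frequencies at a configurable
$F_{st}$. The default is independent SNPs (`ld_block_size = 1`). This LD
model is controllable and fast but not population-genetically realistic:
there is no recombination map, no allele-frequency spectrum skew, and no
LD decay with distance, so passing tests here says nothing about, e.g.,
fine-mapping resolution in real rice panels.

## Numerical and degenerate-input conventions

* Markers whose tested column is constant or collinear with the
  covariates are reported as `NA`, not errors — the dominant scan of an
  inbred-only stack is entirely `NA` by construction.
* p-values are floored at the smallest positive double; RSS is floored at
  zero.
* Collinear covariate columns are dropped by QR pivot with a warning.
* Zero-variance phenotype blocks and all-missing SNPs are errors that
  name the offender.
* Ties: p-value ordering breaks by chromosome, position, additive before
  dominant; modal imputation and heterozygote collapse break toward the
  alphabetically lower allele's homozygote.
* All randomness flows from explicit seeds; reruns are bit-identical, and
  every pipeline output file carries the hash of the configuration that
  produced it.

## Problem sizes used by the test suite

The automated checks run at desk scale, chosen so the full suite
completes in minutes on one CPU: null calibration on a 34 × 2 factorial
with 5,000 SNPs (20 seeds); mapping power on a 50 × 3 factorial with
10,000 SNPs (20 seeds); the power-ordering comparison on a 60 × 4
factorial with 4,000 SNPs; heritability recovery on 500 hybrids with
2,000 SNPs (20 seeds); and cross-validated prediction on a 100 × 5 design
with 5,000 SNPs and 20 repeats. The acceptance script reruns the headline
quantities at the default 113 × 5 design.

## Known limitations

* The whitened test assumes the trait was measured once per individual;
  replicated or multi-environment designs (BLUEs) are out of scope.
* The noise-loading model treats block standardization scalings as known;
  their sampling error is second-order but not zero at very small panels.
* Dominance kinship normalization follows the VanRaden pattern on
  heterozygosity codes; other normalizations are not implemented.
* Epistatic codings (additive×additive and similar) are not implemented.
* F2 or later generations are not modelled; hybrid genotypes are F1.
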