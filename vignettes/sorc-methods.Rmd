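---
title: "Ranking functional rare variants by stability selection on random collapsing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking functional rare variants by stability selection on random collapsing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorc)
```

## The problem

Single-marker association tests are underpowered for rare variants (minor
allele frequency, MAF, below 5%): each variant is carried by a handful of
individuals, so its marginal signal is weak. Burden ("collapsing") methods
pool the rare variants of a gene into one carrier indicator — an individual
scores 1 when it carries a minor allele at any member site — which enriches
the signal but requires a collapsing criterion chosen in advance, and a bad
criterion (say, pooling causal with neutral variants) dilutes power.

SORC (stability selection on random collapsing) removes the need to choose.
Per repetition, each gene's $M_k$ rare variants are split into two random
subgroups: a size $S_k$ is drawn uniformly from $\{1,\dots,M_k\}$, $S_k$
variants are sampled without replacement as the first subgroup, the rest
form the second, and each subgroup is collapsed into a carrier indicator.
The LASSO

$$\min_{\beta,\gamma}\;\|Y - X\beta - U\gamma\|_2^2
  + \lambda\big(\|\beta\|_1 + \|\gamma\|_1\big)$$

is then fit, where $X$ holds the collapsed indicators, $U$ the uncollapsed
common-variant carrier columns, and $\lambda$ is chosen by cross-validation.
Variants surviving the selection are recorded; after $R$ repetitions each
variant's *stability* — the fraction of repetitions in which it was
selected — ranks the candidates. Unlike classical stability selection,
the randomness is imposed on the collapsing, not on subsampling the
individuals; a causal variant keeps contributing signal whichever subgroup
it lands in, while a neutral variant's subgroup is only sporadically
selected.

## Model and conventions

* **Coding.** Analysis is on carrier indicators: each variant is 0/1 for
  absence/presence of a minor allele. Dosage input (0/1/2) is first folded
  so the minor allele is counted, then thresholded at $\geq 1$.
* **MAF.** From dosages, $\hat p_j = \min(s_j, 2N-s_j)/(2N)$. From carrier
  data only the carrier fraction $c_j$ is observable; we invert
  Hardy–Weinberg, $\hat p_j = 1-\sqrt{1-c_j}$, an approximation that is
  exact under HWE and documented as such.
* **Rare vs common.** Rare means $0 < \hat p_j < 0.05$ (strict), the
  conventional threshold; the cut is configurable. Monomorphic variants are
  dropped with a message — they carry no information and break
  standardization.
* **Missing data** are an error, not imputed; synonymy annotation, when
  used to restrict the candidate set, is taken as given input.
* **Attribution.** The LASSO operates on collapsed columns, but the method
  reports per-variant stabilities. When a collapsed column is selected,
  every rare variant of its subgroup is recorded as selected that
  repetition; over many random partitions this discriminates the members,
  because a subgroup containing a causal variant is selected far more often
  than one that does not. Common variants keep their own columns and their
  own selection events, so a strongly associated common variant can reach
  stability 1.
* **Degenerate partitions.** $S_k$ is drawn from the full
  $\{1,\dots,M_k\}$, so $S_k = M_k$ leaves the second subgroup empty; the
  empty indicator is dropped and the gene degenerates to a whole-gene
  collapse for that repetition. We follow the sampling law as stated rather
  than re-drawing, which would bias the subgroup-size distribution.
  Single-variant genes are never collapsed: their column is the variant's
  carrier column in every repetition, so their stability equals a fixed-
  design selection frequency (a property the test suite asserts exactly).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `R` | 100 | random-collapsing repetitions; stabilities live on `{0, 1/R, ..., 1}` |
| `rare_threshold` | 0.05 | MAF below which a variant is collapsed |
| `cv_folds` | 10 | folds for choosing $\lambda$ |
| `nlambda`, `lambda_min_ratio` | 100, 0.001 | geometric $\lambda$ grid down from $\lambda_{\max}$ |
| `top_t` | 15 | gene-identification cut-off across phenotype replicates |
| `zero_tol` | 1e-8 | coefficient magnitude counting as "selected" |

$\lambda$ is taken at the minimum mean cross-validated error (not the
one-standard-error rule): the method is a *ranker*, and the liberal choice
gives non-degenerate selection frequencies to rank; the same choice is the
long-standing default of penalized-regression software. Both $\beta$ and
$\gamma$ share one penalty weight — with a single $\lambda$ written in the
objective, equal penalization is the minimal reading, and differential
weighting is left to future work. Design columns are standardized inside
the solver (configurable). The fold assignment uses an RNG stream separate
from the partition stream, so the sequence of random partitions is
invariant to `cv_folds`.

## Ranking and replicate summaries

Variants are ranked by stability, ties broken lexicographically by id. A
gene's score is the maximum stability over its members, with ties broken by
the number of members at stability $\geq 0.5$, then by id — a gene backed
by several stable variants outranks one carried by a lone column. Across
phenotype replicates, a gene is *identified* in a replicate when it ranks
in the top `top_t` (default 15), and genes are summarized by their
identification counts.

The three comparison methods rank by $-\log_{10}(P)$: the single-marker
test (slope t-test of the trait on one carrier column), the gene-collapsing
test (the same test on the whole-gene indicator), and the CMC test (rare
variants collapsed by a fixed MAF criterion, common variants kept separate,
and the gene assessed by the overall F-test of the multiple regression).
CMC was formulated for case–control multivariate tests; the regression
F-test is its natural Gaussian-trait realization, and the default
predefined criterion is a single whole-gene rare bin with an optional
two-bin split (e.g. at MAF 1%). Collinear design columns are dropped by the
QR pivot in input order, and the numerator degrees of freedom equal the
retained rank. No multiple-testing correction is applied anywhere: all four
methods are compared as rankers.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates a mini-exome-style cohort: true MAFs with a
configurable rare fraction (default 0.87, matching the proportion of rare
sites in large exome panels), rare MAFs drawn as $0.05\,\mathrm{Beta}(0.35,1)$
so that roughly half the rare mass sits below 1%, common MAFs uniform on
$[0.05, 0.5]$, genotypes i.i.d. $\mathrm{Binomial}(2, p_j)$ under HWE with
no linkage disequilibrium, and gene sizes uniform on a configured range.
Functional genes are drawn among genes with enough rare variants to host
the configured number of functional variants; effects are uniform on
$[0.17, 1.2]$ trait units per allele copy — the span reported for the
simulated quantitative trait this design emulates — and phenotype
replicates share one genotype matrix with fresh Gaussian noise per
replicate. Effects act on dosage while the analysis recodes to carrier
status, deliberately mirroring the mismatch between the generative model
and the analysis coding.

The simulator does **not** model linkage disequilibrium (an optional
within-gene correlation mode is a seam, not a default), population
structure, relatedness, covariates, or binary traits. Passing tests on
this cohort therefore show that the machinery behaves as specified under a
clean generative model; they do not certify performance under LD-induced
confounding or stratification, which real exome data exhibit.

## Problem sizes used in the shipped studies

The packaged study (tests and `scripts/acceptance.R`) uses the default
profile — 700 individuals, 50 genes of 4–12 variants, 3 functional genes
with 5 functional rare variants each, unit noise, 20 phenotype replicates,
$R = 50$ — chosen so a full multi-replicate SORC run with all three
baselines completes in minutes on one core while keeping per-gene signal
in the realistic range (per-gene heritability of a few percent). Five
functional variants per gene sits in the middle of the 1-to-11 span that
the emulated design exhibits. The null calibration uses 2,000 genes at
$N = 500$; under Gaussian noise the t and F baseline tests are exact, so
the empirical size check is pure binomial noise around 0.05.

With these sizes the study sits near a performance ceiling: all four
methods place essentially all three functional genes in their top 10 in
almost every replicate, so the method contrast is a check that SORC does
not *lose* ground, not a demonstration of the large gap seen on messier
real data (where LD, covariates and weaker marginal signals penalize the
single-marker ranking). Occasionally a replicate's functional gene slips
just below a pack of stability-1.0 singleton genes — a known trait of
choosing $\lambda$ at minimum CV error, which keeps chance-correlated
fixed columns selected in every repetition.

## Numerical choices and edge cases

* Stability ties and gene-score ties are broken deterministically (ids),
  so rankings are reproducible byte for byte under a fixed seed.
* `p`-values are floored at the smallest positive double before taking
  $-\log_{10}$, so perfect separations rank first instead of producing
  infinities.
* A repetition whose LASSO fails aborts the run — silent skipping would
  bias stabilities downward for whichever variants that repetition would
  have selected.
* Zero-variance design columns (e.g. an indicator saturated at 1) are
  excluded from the fit and reported; a design with fewer than two
  informative columns is an error.
* All seeds are 32-bit integers; two named child streams (partitions,
  folds) are derived from the user seed, and each repetition gets its own
  sub-seed, so results are independent of evaluation order.

## Known limitations

Choosing the number of reported variants $T$ has no error-control theory
here; stabilities are a ranking, not calibrated probabilities. Common
variants' columns never change across repetitions, so their stabilities are
0/1-inflated relative to rare variants'. The HWE inversion for carrier-only
input is biased under inbreeding or strong substructure. Alternative
selectors (elastic net, SCAD) and collapsing kernels are interface seams
only.
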