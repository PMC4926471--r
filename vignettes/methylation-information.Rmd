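---
title: "Information-thermodynamic analysis of methylomes with methylDI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-thermodynamic analysis of methylomes with methylDI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDI)
```

## The model

`methylDI` treats the methylation status of a cytosine as a Bernoulli
variable with success probability equal to the methylation level
$p_i = \#C_i / (\#C_i + \#nonC_i)$ estimated from bisulfite read counts.
The per-site uncertainty is the binary Shannon entropy
$H(p) = -p\log_2 p - (1-p)\log_2(1-p)$ (bits), with the continuity
convention $0\log 0 = 0$. Over a genomic region $R$ the information gained
(or lost) by a subject methylome relative to a reference is

$$I_R \;=\; \sum_{i\in R} H(C_i^{\mathrm{before}}) \;-\;
            \sum_{i\in R} H(C_i^{\mathrm{after}}),$$

the reference playing the "before" role. $I_R$ is additive over
sub-partitions and bounded by one bit per shared site; its physical anchor
is Landauer's principle — erasing one bit dissipates at least
$k_B T\ln 2 \approx 3\times10^{-21}$ J at room temperature
(`landauer_bound()`).

Mutational structure enters through the region statistic
$LC_R = \sum_{i\in R}\log_2(rN_i)$, where $rN = r\times\mathrm{concordance}$
is the normalized count of non-repetitive reads supporting a substitution.
Per site, the probability that a SNP is fixed is modelled by the Boltzmann
law $p = 1 - \lambda e^{-\beta\,LC}$ ($LC > 0$), so
$q = \lambda e^{-\beta LC}$ — the Boltzmann factor — is the probability of
*not* observing the SNP and $LC$ is interpretable as fixation uncertainty.

### Assumptions worth stating

* Methylation levels at different sites are treated as independent when
  entropies are summed; $I_R$ is a sum of marginal entropy differences, not
  a joint entropy.
* The two samples entering $I_R$ must share a coordinate system; sites are
  matched by (chromosome, position, strand) and strands are never merged
  (merging would change $p_i$).
* The genome partition need not have any particular width — what matters is
  that the *same* partition is applied to every sample. Width is a
  configuration knob (default 2 kb), not a constant; different widths
  reveal patterns at different scales because $I_R$ scales with the number
  of sites in the region.

## Parameters that matter

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `bin_width` | 2000 | bp | a conventional regional scale for plant methylomes; the method itself is width-agnostic, so it is exposed rather than fixed |
| `min_coverage` | 1 | reads | sites absent or below coverage in *either* sample are excluded from the site sum rather than imputed — imputation would manufacture information |
| `min_quality` | 25 | score | the standard reporting cutoff for the SNP tables this format comes from |
| `t1`, `t2` | 2, 10 | bits | region taxonomy thresholds: LMR below `t1`, VMR between, HMR at or above `t2`; 10 bits anchors the published "highly variable" exemplar scale, crisp borders being a convention (a fuzzy-set treatment is out of scope) |
| `variance_threshold` | 0.80 | fraction | PCA retains the smallest leading set of components reaching 80% explained variance |
| `auc_min` | 0.8 | — | AUC-selection keeps regions with Hand–Till $M \ge 0.8$; a top-$k$ mode is provided because the selection rule behind published region counts is not derivable |
| `n_repeats`, `n_folds` | 1000, 10 | — | repeated stratified cross-validation at the conventional benchmark setting; accuracies are summarized by mean and 2.5%/97.5% quantiles |
| `mantel_permutations` | 7000 | — | the conventional permutation count for the topology-association test |

## Numerical and design choices

* **Coordinates.** Input files are 1-based inclusive; internally regions are
  0-based half-open. Conversion happens only at the I/O boundary, and the
  partition covers every base exactly once.
* **$0\log 0$.** Defined as 0 (continuity), so fully methylated and fully
  unmethylated sites carry zero entropy exactly.
* **$rN < 1$ sites.** Dropped from $LC_R$: the Boltzmann law is stated for
  $LC > 0$, and a sub-unit normalized count would contribute negative
  "uncertainty".
* **Boltzmann fitting.** The loss behind the published "non-linear
  regression" is unstated; the default here is least squares between the
  model CDF and the empirical CDF at the sorted positive points, with MLE as
  an alternative. For $\lambda < 1$ the law puts mass $1-\lambda$ at
  $LC = 0$; empirical ranks are computed over the full sample *including
  zeros*, because that atom is what identifies $\lambda$ — from positive
  draws alone only $\beta$ is identifiable. During optimization $\lambda$
  is constrained so predicted probabilities stay in $[0,1]$ on the observed
  support, and a deterministic multi-start grid makes the fit reproducible.
* **Multi-class AUC of a single attribute.** With one numeric attribute as
  the ranking score, the two one-vs-one midrank AUCs of a class pair are
  complementary ($A(i|j) + A(j|i) = 1$), so averaging them is identically
  ½ and carries no information. The pairwise statistic used is therefore the
  orientation-free $\hat A(i,j) = \max(A(i|j),\, 1 - A(i|j))$, averaged over
  all class pairs. This reduces to the familiar direction-free rank AUC for
  two classes, is invariant to monotone transforms, and is 0.5 for constant
  attributes.
* **MDL discretization.** Fayyad–Irani exactly: a binary split is accepted
  only when its information gain exceeds
  $(\log_2(N-1) + \Delta)/N$ with
  $\Delta = \log_2(3^k-2) - [k\,Ent(S) - k_1 Ent(S_1) - k_2 Ent(S_2)]$;
  attributes with no accepted cut score $\chi^2 = 0$.
* **PCA.** Centered, unscaled: $I_R$ and $LC_R$ are already on a common bit
  scale, and scaling would inflate low-variance regions relative to
  hotspots. PC-correlation region selection uses absolute Pearson
  correlation (loading signs are arbitrary), with both top-$k$ and
  threshold modes because the rule behind published region counts is
  ambiguous.
* **Cross-validation.** Every chain stage — selection, PCA, classifier — is
  refitted inside each training fold; per-fold selection is the
  statistically correct default (a global pre-selection mode would
  leak). Fold assignment is stratified and re-randomized per repeat from
  `seed + repeat`, so any repeat is independently reproducible.
* **SVM.** No SVM library ships with the target environment, so the package
  carries a compact deterministic SMO solver (one-vs-one voting,
  RBF/linear kernels, features standardized, $\gamma = 1/d$, $C = 1$ —
  the conventional defaults of the library this family of analyses
  typically cites). The second working-set index is chosen by maximal
  $|E_i - E_j|$ rather than at random, making training deterministic.
* **UPGMA and Newick.** Average linkage via `stats::hclust`; merge heights
  are half the average distances (ultrametric scale). The Newick writer
  orders the earlier-formed cluster first within each merge, making the
  string deterministic; the test suite checks the whole construction
  against an independent naive agglomerator.
* **Mantel test.** Hand-written because the permutation estimator and
  seeding are part of the contract: $p = (1+b)/(1+m)$ with joint
  row/column permutation of the second matrix, so $p$ is never zero. The
  correlation statistic is checked against `vegan::mantel` in the tests.
* **FGM copula.** $c(u,v) = 1 + \theta(1-2u)(1-2v)$, $|\theta|\le1$ — a
  deliberately weak-dependence family ($\rho_S = \theta/3$, so
  $|\rho_S| \le 1/3$), matching the expectation that most regions sit near
  $|I_R| \approx 0$ with small $LC_R$. $\theta$ is estimated by Spearman
  inversion ($\hat\theta = 3\rho_S$, clipped with a warning) by default:
  closed-form and robust to marginal misfit; pseudo-observation MLE is the
  alternative. Marginals are fitted by MLE (Weibull for $LC_R$ via
  `MASS::fitdistr`; the asymmetric Laplace for $I_R$ by multi-start
  Nelder–Mead over $(\mu, \log\alpha, \log\beta)$). Kernel density
  estimation uses per-axis normal-reference bandwidths, configurable.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces the statistical structure the analysis
assumes:

* a **bimodal CG baseline** (Beta(1,8)/Beta(8,1) mixture, 60/40), because
  real CG methylomes concentrate near fully unmethylated and fully
  methylated states;
* **group-structured hotspots**: a configurable fraction of regions (dealt
  round-robin to groups) whose owner group carries an additive
  methylation-level shift, clipped into $[0,1]$ with a warning;
* **read-count noise**: Poisson coverage (floor 1) with binomial methylated
  counts, so empirical $I_R$ converges to the analytic `expected_ir()` as
  coverage grows;
* **Boltzmann SNP support**: candidate mutational events per region are
  Poisson; each draws its $LC$ from the full law including the zero atom,
  and only positive draws materialize as SNP records whose
  $(r, \mathrm{concordance})$ pair encodes $LC$ bit-exactly
  ($r = \lceil 2^{LC}\rceil$, concordance $= 2^{LC}/r$);
* **tunable IR–LCR coupling**: per hotspot region an FGM pair $(u,v)$ maps
  to (shift magnitude, SNP-intensity multiplier), coupling the two
  statistics at region level — the level at which the dependence is
  observed. Note that the coupling parameter applies to these region-level
  latent magnitudes, not to the pooled per-cell $(I_R, LC_R)$ scatter,
  whose rank correlation is additionally shaped by group structure and
  count noise.

It does **not** emulate linkage disequilibrium, recombination,
demography, context-specific methylation pathways (all sites are "CG"), or
chromosome-scale features like pericentromeric hotspot density. A green
end-to-end test therefore establishes that the pipeline's statistics,
selection and classification machinery behave correctly on data with the
assumed structure — not that any particular biological dataset will
classify at a given accuracy.

## Degenerate inputs and edge behavior

* Regions with no shared qualifying site get $I_R = 0$ and are flagged
  (`empty_regions` attribute) rather than dropped, keeping the matrix
  rectangular across samples.
* Subject = reference (same id) warns and returns zeros.
* A constant attribute yields AUC 0.5 and $\chi^2 = 0$; AUC selection never
  selects an empty set (it falls back to the single best region), so CV
  folds cannot crash on unlucky training splits.
* LDA on rank-deficient matrices fails with a message advising a `pca`
  stage; `p = 1` in the Boltzmann inverse signals overflow; copula
  $\hat\theta$ beyond $[-1,1]$ is clipped with a warning.

## Known limitations

* $I_R$ ignores within-tissue heterogeneity beyond what the binomial level
  estimate captures; no differential-methylation calling is attempted (by
  design — the approach is positioned as an alternative to DMP/DMR
  pipelines).
* The SMO solver targets the small-sample regime of cohort
  classification (tens to hundreds of samples); it is not tuned for large
  $n$.
* Heatmap output is numeric export only (value grids with the color scale
  clipped to the observed min/max); figure aesthetics are out of scope.
* The classifier-chain grammar covers the published chain variants
  (AUC/χ²-selection, PCA, LDA/SVM); wrapper or embedded feature selection
  is deliberately not offered.

## Reproducibility

All stochastic stages take explicit seeds. The pipeline driver fans a
single global seed out to per-stage seeds via `stage_seed()` (an additive
hash of the stage name, kept below $2^{31}$), logs the effective config
with its md5, and re-running any stage from the logged config reproduces
its outputs byte-identically. Nothing in this vignette states an empirical
result that the test suite does not itself compute.
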