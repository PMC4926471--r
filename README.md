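# methylDI

Discriminatory information patterns of cytosine DNA methylation.

`methylDI` analyses whole-genome bisulfite methylomes and SNP tables in an
information-thermodynamics framework. It is aimed at epigenomics groups who
have per-cytosine methylation count tables (and, optionally, per-site SNP
tables) for a structured population — natural accessions, mutant panels,
treatment groups — and want to ask: *which genomic regions carry enough
information to tell the individuals and subpopulations apart, and how does
that methylation signal relate to the mutational landscape?*

## The statistics at the core

For a cytosine at coordinate *i* with methylation level
*p<sub>i</sub>* = #C<sub>i</sub> / (#C<sub>i</sub> + #nonC<sub>i</sub>), the
methylation status carries Shannon entropy (in bits)

> H(p) = −p log₂ p − (1−p) log₂ (1−p).

Over a genomic region *R*, the **information gained or lost** by a subject
methylome relative to a reference ("before") methylome is

> I<sub>R</sub> = Σ<sub>i∈R</sub> H(C<sub>i</sub><sup>before</sup>) −
> Σ<sub>i∈R</sub> H(C<sub>i</sub><sup>after</sup>),

summed over cytosine sites observed in both samples. One bit is the most a
site can contribute; erasing it costs at least k<sub>B</sub>T ln 2 ≈ 3×10⁻²¹ J
(Landauer's bound, `landauer_bound()`), which is what grounds I<sub>R</sub>
as a physical quantity.

On the SNP side, with rN = r × concordance the normalized supporting-read
count of a substitution, the **SNP-fixation uncertainty** of a region is

> LC<sub>R</sub> = Σ<sub>i∈R</sub> log₂(rN<sub>i</sub>),  rN<sub>i</sub> ≥ 1,

and per site the fixation probability follows a Boltzmann law
p = 1 − λ e<sup>−β·LC</sup> (fitted by `fit_boltzmann()`).

Downstream, regions are scored for discriminatory power (Hand–Till
multi-class AUC; Chi-squared after Fayyad–Irani MDL discretization), reduced
(PCA at 80% explained variance), classified (LDA or SVM chains under
repeated stratified 10-fold cross-validation), clustered (UPGMA on the
linear-discriminant coordinates), compared across data types (Mantel test),
and the joint (I<sub>R</sub>, LC<sub>R</sub>) dependence is modelled with a
Farlie–Gumbel–Morgenstern copula over Weibull and skew-Laplace marginals.

## Worked example

No downloads are needed: the package ships a synthetic cohort generator that
emulates the data structure the method assumes (bimodal CG methylome,
group-structured hotspot regions, Boltzmann-distributed SNP support).

```r
library(methylDI)

cfg <- simulation_config(n_groups = 3, samples_per_group = 10,
                         n_regions = 200, sites_per_region = 20,
                         hotspot_effect = 0.5, theta = 0.6, seed = 7)
cohort <- simulate_cohort(cfg)

rm_ir  <- ir_matrix(cohort$samples, cohort$reference, cohort$partition)
rm_lcr <- lcr_matrix(cohort$snp_samples, cohort$partition)
labels <- cohort$labels[rownames(rm_ir$values)]

table(classify_regions(rm_ir))            # HMR / VMR / LMR taxonomy
cv <- repeated_cv(classifier_chain("auc+pca+lda"), rm_ir, labels,
                  n_repeats = 50, n_folds = 10, seed = 7)
cv

ch    <- classifier_chain("pca+lda")
d_ir  <- ld_distance_matrix(fit_chain(ch, rm_ir,  labels)$ld_coordinates)
d_lcr <- ld_distance_matrix(fit_chain(ch, rm_lcr, labels)$ld_coordinates)
mantel_test(d_ir, d_lcr, n_perm = 999, seed = 7)

fit_boltzmann(cohort$truth$lc_draws)
```

This prints (exactly, given the seed):

```
LMR VMR HMR
 46 154   0
<cv_result> mean 100.00% [100.00, 100.00] over 50 x 10-fold CV
<mantel_result> pearson r = 0.9143, p = 0.001 (999 permutations)
<boltzmann_fit> lambda = 0.896639, beta = 0.499576 (per bit), rss = 0.019, n = 30598 [cdf]
```

Reading it: most regions are low- or mid-variability (LMR/VMR) and none of
the 200 reach the 10-bit highly-variable (HMR) exemplar threshold at this
effect size; the AUC+PCA+LDA chain separates the three groups perfectly
under repeated cross-validation; the methylation-based and SNP-based
population topologies are strongly concordant (Mantel r = 0.91, the smallest
achievable p at 999 permutations); and the Boltzmann fit recovers the
generating parameters (λ = 0.9, β = 0.5) from ~3×10⁴ candidate draws.

The same analysis is scriptable end-to-end from a JSON config:

```r
run_pipeline("run-all", "config.json")   # simulate → ir → lcr → ... → copula
```

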