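---
title: "MVMR with correlated instrumental variable sets: models, estimators, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MVMR with correlated instrumental variable sets: models, estimators, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvmrset)
```

## The model

`mvmrset` works in linear structural equation models (SEMs). Variables
$\{X_1,\dots,X_p\}$ obey $X_i = \sum_j c_{ij} X_j + U_i$ with disturbances of
covariance $\Psi$; the implied covariance matrix is
$\Sigma = (I-C)^{-1}\Psi(I-C^\top)^{-1}$. A causal diagram encodes the
non-zero $c_{ij}$ as directed edges and the non-zero off-diagonal $\Psi_{ij}$
as bidirected edges: in our setting the bidirected edges between instruments
represent linkage disequilibrium (LD), and bidirected edges among exposures
and outcome represent unmeasured confounding. Genotype randomization
justifies the key structural assumption: no bidirected edges between
instruments and the other variables.

Wright's method of path coefficients expresses every covariance as a sum
over unblocked (collider-free) simple paths of the product of edge
parameters (`wright_path_sum()`). The rule as implemented is exact for
*standardized* SEMs (all variables unit variance); for unstandardized
variables a root-variance correction is available via the `variances`
argument, and the matrix formula (`implied_covariance()`) is always exact.
The package's randomized tests build standardized SEMs by solving for the
error variances in topological order and verify path-rule/matrix agreement
to $10^{-10}$.

## Identification with correlated instruments

A set $\{E_1,\dots,E_K\}$ is an *instrumental set* for exposures
$\{X_1,\dots,X_K\}$ and outcome $Y$ when a pairing of instruments to
unblocked paths exists satisfying three graphical conditions (non-descendance
plus an unblocked path ending in $X_i \to Y$; d-separation from $Y$ once all
$X_j \to Y$ edges are removed; and a no-shared-non-collider condition across
paths). `check_instrumental_set()` verifies the conditions constructively and
returns either a certificate (the pairing) or the first violated condition.
Because condition 3 depends on the instrument ordering, all $K!$ orderings
are searched for $K \le 6$ and a fixed-order backtracking search beyond;
loci in this problem domain rarely exceed a handful of exposures.

When the condition holds, the direct effects solve
$\Sigma_{EX} c = \Sigma_{EY}$ — LD between the instruments appears on both
sides and drops out. With more instruments than exposures the system is
overdetermined but consistent at the population level; with fewer *causal*
variants than exposures $\Sigma_{EX}$ is rank-deficient and
`identify_effects()` refuses (relative singular-value tolerance
$10^{-8}$; the threshold is a numerical choice, as the theory gives no
tolerance).

## Estimators

All estimators consume a `summary_covariances` object: $\hat\Sigma_{EX}$,
$\hat\Sigma_{EY}$, the LD matrix $\hat\Sigma_{EE}$ and sample sizes. The GMM
family is

$$\hat c(\Delta) = (\hat\Sigma_{EX}^\top \Delta \hat\Sigma_{EX})^{-1}
\hat\Sigma_{EX}^\top \Delta \hat\Sigma_{EY},$$

with `ls_estimate()` ($\Delta = I$), `gmm_estimate()`
($\Delta = \hat\Sigma_{EE}^{-1}$, equivalent to two-stage least squares) and
`gmm_weighted()` (any positive-definite $\Delta$). For $L = K$ all choices
coincide. Solutions go through QR and Cholesky decompositions, never
explicit inverses; a singular LD matrix (perfect LD) raises an error
directing the user to `prune_instruments()`, and a condition number above
$10^8$ warns.

**Scale convention.** Genotypes are standardized to unit variance, so
$\hat\Sigma_{EE}$ is the LD correlation matrix and columns of
$\hat\Sigma_{EX}$ match standardized eQTL coefficients. Exposures and the
outcome are centered but kept on their structural scale. Rescaling them to
unit SD would multiply the estimand by $\mathrm{SD}(X_k)/\mathrm{SD}(Y)$ and
the recovered coefficients would no longer equal the structural effects; in
the simulator's idealization (unit error variance) the structural scale *is*
approximately the standardized scale. For real summary statistics,
`beta_to_covariance()` converts per-allele betas via
$\beta\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})}$, and log-odds GWAS betas stay
on the log-odds scale, so locus effects read "log-odds per SD of
expression". The exact standardization of logistic-regression betas is not
fully determined by summary data; this conversion is the package's
documented choice and a target for sensitivity analysis.

## Inference

Summary-based standard errors use the asymptotic covariance of the
estimator actually fitted: for the optimal weighting,
$\hat\sigma^2 (\hat\Sigma_{EX}^\top\hat\Sigma_{EE}^{-1}\hat\Sigma_{EX})^{-1}/n$;
for any other weighting the corresponding sandwich form. Using the optimal
formula for the LS estimator would understate its variance when $L > K$ (we
observed type-I error near 0.085 instead of 0.05 in null simulations), so
the sandwich is the default for LS. The residual outcome variance
$\hat\sigma^2$ defaults to 1 — conservative for a standardized outcome —
with `sigma2 = "genetic"` subtracting the genetically explained variance.
`se_individual()` provides the classical homoskedastic two-stage
least-squares standard error from individual-level data; on one-sample
simulated data at $n \ge 2000$ the two agree within 15%, which is the
package's validation of the summary formula. In two-sample mode the extra
variability from estimating $\hat\Sigma_{EX}$ and $\hat\Sigma_{EY}$ in
different cohorts is *not* modeled (it cannot be, from summary data alone);
a warning is emitted.

P-values are two-sided normal. The locus pipeline's Bonferroni denominator
is the number of gene–tissue combinations actually tested in the run, not a
fixed constant.

## Instrument strength and determinacy

`conditional_f()` computes, from summary covariances alone, a
Sanderson–Windmeijer-style conditional F: with
$Q = \hat\Sigma_{EX}^\top \hat\Sigma_{EE}^{-1}\hat\Sigma_{EX}$ (the
covariance of the genetically predicted exposures),
$F_k \propto$ the variance of predicted exposure $k$ net of the other
predicted exposures. It is validated against a direct two-stage regression
F-test on individual-level data.

`determinacy_check()` reports $\det\hat\Sigma_{EE}$, the determinant of the
(square or Gram) instrument–exposure matrix, the conditional F vector, and
three flags. The key design choice is how to detect *under-determination*
(fewer causal variants than exposures) from noisy data: a finite-sample
$\hat\Sigma_{EX}$ is never exactly rank-deficient, and a fixed determinant
cut-off cannot separate "true zero plus noise" from "small but real". The
conditional F statistic is, up to scaling, the minimum-eigenvalue test of
the rank of $\Sigma_{EX}$, so the flag fires when the minimum conditional F
falls below a conservative critical value (default 30, roughly a
$\chi^2$ tail probability below $10^{-7}$ under the rank-deficient null).
In the package's simulations this flags rank-deficient designs in 100% of
replicates at $n = 10^4$ while flagging identifiable two-instrument designs
essentially never. The conventional weak-instrument flag uses the familiar
threshold of 10. A consequence worth knowing: at loci where several genes
share the *same* causal variants with similar effect sizes, the genetically
predicted exposures are nearly collinear and conditional F is honestly low
even when every instrument–exposure association is strong — the data then
barely separate the exposures, which shows up as large estimator spread.

## The simulator

`scenario_config()` fixes a "locus" (MAFs, successive LD, which instruments
are causal) once per configuration, and `simulate_dataset()` redraws the
instrument-effect matrix and all samples per replicate.

**Genotypes.** Binomial(2, maf) allele counts from two independent allele
chains: the first SNP's alleles are Bernoulli(maf); each next SNP's alleles
are drawn conditionally on the previous SNP's with the bivariate-Bernoulli
conditional probabilities chosen so that the marginal MAF and the successive
genotype correlation match their targets (allele-level correlation equals
genotype-level correlation because genotypes are sums of two iid allele
pairs). Non-adjacent correlations then follow the Markov product
$r_{ij} = \prod_k r_k$ — an emergent property verified by moment tests.
Infeasible (MAF, r) corners are clipped to the Fréchet bound with a warning;
scenario configurations clamp drawn correlations into the feasible range up
front, reflecting the population-genetic fact that high LD requires similar
allele frequencies.

**Structural equations.** Exposures are
$X_j \mid E \sim N(\sum_i a_{ij} E_i, \sigma^2)$ on standardized genotypes
and the outcome $Y \mid X \sim N(\sum_k c_k X_k, \sigma^2)$, with
$\sigma^2 = 1$ by default. Instrument effects are uniform in the scenario's
strength range (strong 0.1–0.3; weak 0.001–0.01); for the two-instrument
diagrams the effect matrix is rejection-sampled to have determinant above
0.05 ("well-oriented", the signed determinant), and the weak variant below
0.001 in magnitude. The idealized two-instrument diagrams use MAF 0.3 — a
typical common-variant frequency; the realistic loci draw MAFs in 0.1–0.4
and successive LD in 0.3–0.8.

**Causal-variant assignment.** In the three-gene locus all causal variants
affect all genes ("shared", the stated design for that locus), which makes
the genes' genetic components strongly correlated — the realistic hard case.
The two-gene locus assigns each gene its own causal variant ("dedicated"),
matching the basic multi-exposure identification diagram; with shared
positive effect vectors the two genes would be almost indistinguishable and
the finite-sample estimator visibly biased at the simulated sizes, which is
not the regime that locus represents.

**LD misspecification and two-sample designs.** `wishart_perturb_ld()` draws
$W \sim \mathrm{Wishart}(\nu, \Sigma_{\mathrm{ref}}/\nu)$ rescaled to unit
diagonal, emulating an LD matrix estimated from $\nu$ individuals (the
misspecification experiments use $\nu = 50$). `two_sample_scenario()`
samples independent exposure- and outcome-study datasets whose chains follow
two independently perturbed LD matrices (degrees of freedom defaulting to
the study sample sizes) and assembles cross-sample summary covariances. In
this design the estimates are biased at small exposure-study sizes and the
bias decays along the sample-size grid, vanishing around eQTL/GWAS sizes of
4,000/140,000.

**Reproducibility.** Every generator takes a seed and restores the caller's
RNG stream; `replicate_experiment()` derives per-replicate seeds from the
master seed with a counter scheme, so any replicate can be regenerated in
isolation.

**What the simulator does not emulate.** Haplotype/recombination block
structure beyond a first-order Markov chain; selection of instruments by
significance (winner's curse); case–control ascertainment of the outcome
(the outcome is Gaussian, with log-odds effects only entering through the
real-data conversion); genotyping error and imputation; population
stratification. Passing tests therefore demonstrate correctness of the
estimators and pipeline under the stated SEM, not robustness to these
real-data phenomena.

## Instrument correlation and estimator spread

For a fixed effect matrix the asymptotic covariance of the exactly
determined estimator is $A^{-1}\Sigma_E^{-1}A^{-\top}\sigma^2/n$, whose
scale grows like $1/(1-\alpha^2)$ in the instrument correlation $\alpha$ —
an SD ratio of about $\sqrt{(1-0.1^2)/(1-0.9^2)} \approx 2.3$ between
$\alpha = 0.9$ and $\alpha = 0.1$. The package's replications confirm that
the *bulk* spread (IQR-based SD) grows by a factor of roughly 2.3–2.9 at
$n = 2000$. The raw variance, however, is dominated by a handful of
replicates in which the sampled covariance system is nearly singular at high
correlation; those few explosions make the plain variance ratio orders of
magnitude larger and essentially a property of the tails, not of typical
precision. The correlation-robustness test therefore compares robust
spreads in a paired design (same effect matrix and replicate seeds at both
correlation levels).

## Locus pipeline choices

Coordinates are 1-based and windows are closed intervals
$[\mathrm{lead} - r, \mathrm{lead} + r]$ with $r = 500$ kb. "Non-zero LD"
means $|r| > 0.01$ (a numeric LD is never exactly zero). Pruning removes one
SNP from every pair with $r^2 \ge 0.95$ (per-locus override available),
keeping the smaller GWAS p-value, with position and then identifier as tie
breaks. Exposure-set closure alternates adding genes sharing any instrument
and instruments of any included gene until a fixed point; it is idempotent
by construction and tested as such. Allele harmonization matches effect
alleles, flips betas for swapped or strand-flipped records and drops
strand-ambiguous (A/T, C/G) SNPs; eQTL tables without allele columns are
assumed pre-harmonized. SNP–gene pairs with no recorded association enter
the covariance matrix as zeros (no cis-eQTL effect). The per-tissue
significance filter is applied before locus construction; whether it should
instead apply after is a documented sensitivity question. A locus left with
fewer instruments than exposures is reported as non-identifiable rather
than estimated.

## Problem sizes used by the test suite

The packaged tests replicate the validation experiments at sizes chosen to
make Monte-Carlo error small relative to the effects under test: 500
replicates of $n = 10^4$ for the recovery experiments, 1,000 replicates of
$n = 2000$ for the correlation sweep, 2,000 null replicates of $n = 2000$
for test calibration, and 200 replicates per point of the pleiotropy grid.
The full suite runs in a few minutes on one CPU.

## Known limitations

* Identification search is exhaustive over simple paths and orderings;
  graphs far larger than a GWAS locus (hundreds of nodes) are out of scope.
* Only marginal (empty conditioning set) d-separation is implemented — all
  the theory used here requires nothing more.
* Two-sample standard errors ignore between-cohort variability (see above).
* The liability scale is not modeled; case–control effects remain log-odds.
* Robust/median/penalized MVMR variants and PCA-based instrument reduction
  are intentionally out of scope.
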