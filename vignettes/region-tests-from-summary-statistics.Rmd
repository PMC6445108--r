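---
title: "Region-based association tests from summary statistics: model, methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based association tests from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumraa)
```

## The model

Region-based association analysis tests whether any of the $m$ SNPs in a
genomic region are associated with a continuous trait measured in $n$
unrelated individuals. The classical generative model is a multiple
linear regression with additive genotype effects,

$$ y = e_n\mu + G W C \beta + \xi_n,\qquad \xi_n \sim N(0,\sigma_y^2 I_n), $$

where $G$ is the $n\times m$ dosage matrix, $W$ a diagonal matrix of SNP
weights, $C$ an $m\times k$ method-dependent linear operator, and
$\beta$ the $k$ effects of the $WC$-transformed genotypes. Centering and
scaling (projecting out the intercept, dividing the trait by
$\sigma_y$ and each genotype column by $\sigma_{g_i}$) give the
standardized form $\bar y = \bar G S^{-1} W C\beta + \bar\xi_n$ with
$S = \mathrm{diag}(\sigma_y/\sigma_{g_i})$.

Two hypotheses about $\beta$ give the two test statistics:

* **Fixed effects** ($H_0\!: \beta = 0$): with $M = \bar G S^{-1} W C$
  and $r = \operatorname{rank}(M)$,
  $R^2 = \tfrac1n \bar y^T M (M^TM)^{-1} M^T\bar y$ and
  $F = \tfrac{n-1-r}{r}\tfrac{R^2}{1-R^2}$ follows $F_{r,\,n-1-r}$.
  This covers MLR ($C=I$), principal-component regression ($C$ =
  truncated eigenvectors of the weighted genotype covariance) and
  functional linear models ($C$ = basis functions evaluated at
  normalized SNP positions).
* **Random effects** ($\beta \sim (0,\tau^2 CC^T)$, $H_0\!:\tau^2=0$):
  the score statistic $Q = \tfrac1n\bar y^T M M^T \bar y$ is, under the
  null, a weighted sum of independent $\chi^2_1$ variables with weights
  $\lambda = \operatorname{eigen}(\tfrac1n M^TM)$ — the nonzero spectrum
  of the $n\times n$ kernel and of the $k\times k$ Gram matrix coincide.
  This covers burden ($C=e_m$), SKAT ($C=I$) and SKAT-O
  ($CC^T = \rho e_m e_m^T + (1-\rho)I$).

### Compression to summary statistics

Pre-multiplying the standardized model by $A = \bar G^T/\sqrt n$ maps
individual data to GWAS summary quantities: $z = \bar G^T\bar y/\sqrt n$
(the per-SNP Z scores) and $U = \bar G^T\bar G/n$ (the SNP-by-SNP
correlation matrix), giving $z = U\tilde S^{-1}WC\beta + \bar\xi_m$ with
$\bar\xi_m\sim N(0,U)$ and $\tilde S = S/\sqrt n$ (the diagonal of GWAS
beta standard errors). Writing $X = \tilde S^{-1}WC$, the key algebraic
facts are

$$ X^Tz = M^T\bar y \quad\text{and}\quad X^TUX = M^TM $$

exactly, not asymptotically. Every statistic above is a function of
these two objects, so the summary-level tests reproduce the
individual-level tests *identically* whenever $z$, $U$ (and the
$\tilde S$ used for weighting) come from the same genotype data. The
compression also preserves $\operatorname{rank}(UX) =
\operatorname{rank}(\bar G X)$ — no information the region test uses is
lost. That exactness is the core claim the test suite verifies, at
relative tolerance $10^{-10}$, across all six families and a grid of
simulated regions ($n\in\{50,200,500\}$, $m\in\{2,10,30\}$, latent LD
$\rho\in\{0,0.5,0.9\}$).

### Normalization convention

The literature writes the individual-level $Q$ with $1/n$ factors and
the summary-level $Q$ without, and some tabulations use $n_0 = n-1$
where the derivations use $n$; taken literally, the two sides then
differ by a factor of $n$ in both the statistic and the eigenvalues
(which cancels in the p-value, so published "identity" statements refer
to the test result). `sumraa` instead makes the identity literal: one
`normalizer` argument (`"n"` by default, `"n_minus_1"`, or `"unit"` for
the raw-score convention of the summary tables) is applied on **both**
data paths, under which statistic, eigenvalues and p-value all agree
exactly. The p-value is invariant to the choice.

Similarly, one variance-denominator convention (population form, $n$,
configurable to $n-1$) is used for all standard deviations, so that the
compressed LD matrix has an exactly unit diagonal and the back-computed
beta standard errors satisfy
$\tilde s_{ii} = \sigma_y/(\sqrt n\,\sigma_{g_i})$ exactly.

## Tunable parameters

* **SNP weights** (`weight_spec`): `threshold` (indicator
  $\mathrm{MAF}_i > c$, default $c = 0.05$) filters variants;
  `beta_density` evaluates the Beta$(a,b)$ density at the MAF
  (default $a=1$, $b=25$, the field-standard strong up-weighting of
  rare variants; $a=b=1$ is unweighted); `external` accepts
  user-supplied nonnegative weights such as functional-annotation
  scores. MAFs must be minor-allele frequencies in $(0, 0.5]$. One
  published formulation prints the beta weight with two powers of MAF;
  this package uses the standard density
  $\mathrm{MAF}^{a-1}(1-\mathrm{MAF})^{b-1}/B(a,b)$, consistent with the
  kernel-test literature the weight originates from.
* **PCA** (`k_components`, `var_explained`): either an explicit number
  of components or the smallest $k$ covering a variance-explained
  fraction (default 0.85, within the conventional 80–90% band). The
  eigenvectors are taken from $W\tilde G^T\tilde GW$ (individual level)
  or $W\tilde S^{-1}U\tilde S^{-1}W$ (summary level); the two matrices
  are proportional (factor $1/\sigma_y^2$), hence share eigenvectors up
  to sign, and a deterministic sign convention (largest loading
  positive) makes the operator reproducible. Sign flips cannot affect
  any statistic, which depends only on the column span.
* **FLM** (`basis`, `k_basis`, `spline_order`): Fourier basis
  $\{1, \sin 2\pi jt, \cos 2\pi jt,\dots\}$ or B-splines of the given
  order on uniform interior knots, evaluated at SNP positions
  normalized affinely to $[0,1]$ — so the operator is invariant to any
  affine rescaling of physical coordinates. $k$ must not exceed $m$,
  and B-splines need $k \ge$ order.
* **SKAT-O** (`rho`, `rho_grid`): a single $\rho$ runs the fixed-$\rho$
  kernel exactly ($\rho=0$ is SKAT, $\rho=1$ collapses to the burden
  statistic). The operator is the closed-form symmetric square root of
  $\rho e e^T + (1-\rho)I$ (eigenvalues $1+(m-1)\rho$ and $1-\rho$).
* **Normalizer and denominators**: above.

## The SKAT-O $\rho$ combination

$\rho$ is treated in the literature as an estimable parameter, but no
estimator is prescribed alongside the kernel definition. `sumraa` uses
the min-p approach: the grid $\{0, 0.1^2, \dots, 0.5^2, 1\}$ (denser
near the SKAT end, where the optimum typically lies), statistic
$\min_\rho p_\rho$, and a null calibration by `n_draws` (default
$10^4$) seeded Monte-Carlo draws of $z \sim N(0, U)$. Within the min-p
ranking the same moment-matched tail approximation is applied to the
observed and to the drawn statistics, so the combination compares like
with like (the per-$\rho$ p-values reported in the result use the
primary inversion); the combined p-value is the usual
$(1 + \#\{\text{draws} \le \text{observed}\})/(B+1)$, which is itself
uniform under the null by construction. The analytic one-dimensional
integration used elsewhere in the SKAT-O literature is deliberately out
of scope.

## Weighted-$\chi^2$ tail probabilities

$P(\sum_i\lambda_i\chi^2_1 > q)$ is computed by numerical inversion of
the characteristic function (the Davies approach, using Imhof's
integrand): the integrand is even, so a midpoint sum over
$(k-\tfrac12)\Delta$ is a full-line trapezoid discretization whose
error is an aliasing term controlled through the $\chi^2$ tail bound,
with truncation controlled by an integration-by-parts envelope bound;
the accuracy target is $10^{-9}$. Numerical choices worth knowing:

* All-equal weights collapse to an exact scaled $\chi^2_m$; $q=0$
  returns 1.
* Inputs are canonicalized to 10 significant digits before inversion.
  The Gil–Pelaez form computes a small tail as $\tfrac12$ minus a
  number close to $\tfrac12$, so sub-$10^{-9}$ jitter in how
  $(\lambda, q)$ were assembled would otherwise be amplified, in
  relative terms, for small $p$; after canonicalization, algebraically
  identical pipelines return bit-identical p-values.
* Near-degenerate spectra (one dominant eigenvalue) would need enormous
  grids at the default target; the conservative error bounds are then
  relaxed stepwise before the moment-matched (Liu-type, noncentral
  $\chi^2$ surrogate) fallback is used — with a warning, never
  silently, and recorded in the result's `method_used`.
* The moment-matched approximation tracks the inversion to well under
  $5\times10^{-3}$ absolute in the significance-relevant range
  ($p \lesssim 0.1$) but can deviate by $\sim 10^{-2}$ for central
  probabilities on skewed spectra; it is a fallback, not the primary.
* Eigenvalues below $10^{-12}$ of the largest are numerical noise from
  rank-deficient kernels and are dropped; genuinely negative
  eigenvalues (beyond $-10^{-10}$ of the scale) indicate inconsistent
  inputs and raise an error.

A seeded Monte-Carlo estimator (`mixture_sf_montecarlo`) serves as the
independent oracle in the test suite, with its binomial standard error.

## The lasso extension

Effect sizes can be estimated from summary data by minimizing

$$ (z - UX\beta)^T U^{-1} (z - UX\beta) + \lambda\sum_j|\beta_j|, $$

done here by cyclic coordinate descent on the equivalent quadratic form
($A = X^TUX$, $b = X^Tz$), with the coordinate update
$\beta_j \leftarrow \mathrm{soft}(b_j - \sum_{l\ne j}A_{jl}\beta_l,
\lambda/2)/A_{jj}$. At $\lambda = 0$ this converges to the closed form
$(X^TUX)^{-1}X^Tz$; for an orthogonal design ($U = I$, $X = I$) the
solution is exact soft-thresholding of $z$ at $\lambda/2$; large
$\lambda$ drives all coefficients to zero (objective
$z^TU^{-1}z$). Near-singular $U$ (smallest eigenvalue below $10^{-8}$
of the largest) is ridge-stabilized as $U + 10^{-6}I$ with a message.
Convergence is declared when the largest coordinate update falls below
$10^{-12}$; non-convergence returns the partial solution, flagged.

## Combining Z scores of any level

Because under the null the correlation between two Z scores computed on
the same trait equals the genotype correlation, and between two traits
on the same genotype equals the trait correlation, the model
generalizes beyond SNPs: `combine_object_level` runs the same machinery
on Z scores of arbitrary genetic objects (regions, genes, traits) with
$W = \tilde S = I$ — no weighting, since contributions of object-level
statistics are rarely hypothesizable. Fixed-effects combination
requires the sample size; random-effects combination defaults to the
unit normalizer, as object-level scores carry no per-observation
scale. The SKAT-O-style combiner uses
$CC^T = \rho U + (1-\rho)I$, the form underlying score-based
multi-trait methods.

## The simulator: what it emulates, what it does not

`simulate_genotypes` draws two haplotypes per individual by
thresholding a latent first-order autoregressive Gaussian at the
allele-frequency quantile, so genotypes are Hardy–Weinberg dosages with
a single LD parameter (`ld_decay_rho`) whose implied adjacent-SNP
dosage correlation has a closed form (`expected_adjacent_ld`, a 1-D
orthant-probability quadrature) used as the generator's own test
oracle. Allele frequencies are uniform on `maf_range` (default
0.05–0.5); sampled-monomorphic columns are dropped with a warning.
`simulate_phenotype` adds unweighted additive effects — fixed
(`effect_sizes`) or drawn $N(0,\tau^2)$ — plus Gaussian noise
(`noise_sd`, default 1); weights and the operator $C$ belong to
analysis, not to the data-generating truth. Everything is a pure
function of the configuration (the seed is a config field; genotypes
use `seed`, phenotypes `seed + 1`).

Deliberately **not** emulated: coalescent genealogies, population
structure and relatedness, binary traits, genotyping error, and
long-range LD beyond the AR(1) decay. Equivalence between the two data
paths is an algebraic identity and holds regardless; but the null
calibration and power behavior demonstrated on these simulations do not
by themselves establish calibration under population stratification or
case-control sampling, which the model's assumptions exclude.

## Problem sizes in the checks

The equivalence suite uses 54 simulated regions (three sample sizes ×
three region widths × three LD levels × null/causal), each run through
up to nine method variants on both data levels. Null calibration uses
2,000 replicates at $n=500$, $m=10$; the correlation identities use
$10^4$ replicates; the mixture oracle uses 20 random spectra against
$10^5$-draw Monte-Carlo. These sizes give the KS and binomial bands
used in the tests their intended resolution while keeping a full run in
the minutes range on one CPU.

## Known limitations

* The F test requires $X^TUX$ (equivalently $M^TM$) to be of full rank;
  collinear regions raise an error rather than being silently
  regularized (reduce $k$, or use the random-effects tests, which
  handle rank deficiency naturally through the spectrum).
* Meta-analysis Z scores with heterogeneous per-SNP sample sizes are
  accepted but the user must supply one effective $n$; it is a required
  argument, never guessed.
* Allele harmonization between a user's Z-score file and LD file is
  limited to matching SNP identifiers (mismatched sets are intersected
  with a warning); strand/allele-flip correction is the caller's
  responsibility.
* p-values below the inversion's absolute accuracy ($\sim10^{-9}$; far
  below any region-level significance threshold) are reported as
  clamped small values, without saddlepoint refinement.
* Binary traits, covariates and related individuals are out of scope at
  the individual level; the summary-level machinery consumes Z scores
  agnostically, so scores that already account for such structure can
  be combined.
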