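---
title: "Bayesian functional regression for multi-environment hyperspectral yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian functional regression for multi-environment hyperspectral yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Plant breeding programs phenotype thousands of plots per season.
Hyperspectral cameras measure canopy reflectance in hundreds of narrow
wavelength bands cheaply and early, raising the question of whether
reflectance can substitute for, or add to, genomic information when
predicting grain yield — in particular for *unobserved* combinations of
line and environment. funbandr implements a complete pipeline for this
question: a two-stage analysis of replicated field trials, a catalogue
of fourteen Bayesian prediction models combining genetic kernels and
band information (as individual covariates or as functional data), a
Gibbs sampler, the cross-validation schemes used in multi-environment
breeding trials, and a synthetic-trial generator with exported ground
truth.

## Stage one: from plots to adjusted cell means

Trials are laid out as alpha-lattices: each trial has `r` replicates,
each replicate split into incomplete blocks. The plot model per
environment is

$$y = \mu_{j} + t + r + b + \varepsilon,$$

with a fixed mean per genotype $j$, and random trial, replicate-within-
trial and block effects with environment-specific variances.
`reml_varcomps()` estimates the four variance components by REML. We
deliberately back this with `lme4::lmer` rather than a hand-rolled
EM-REML: REML for crossed/nested Gaussian random effects is standard,
heavily-tested functionality, and the interesting (novel) computation
in this package lies elsewhere. `blues()` then computes the
generalized-least-squares genotype means
$\hat\mu = (X'\Sigma^{-1}X)^{-1}X'\Sigma^{-1}y$ with sparse matrix
algebra, together with the inverse-variance weights
$\omega_{j} = [X'\Sigma^{-1}X]_{jj}$. Those weights carry the
first-stage precision into the second stage: rows of the second-stage
design are scaled by $\sqrt{\omega}$ and the residual variance is then
pinned at 1 by a near-degenerate prior (scale = df = $2\times10^{10}$),
so a cell measured with twice the precision gets twice the weight.

Band reflectances pass through the same adjustment, either with their
own REML fit per band (`band_varcomps = "per_band"`) or reusing the
yield components (`"share_yield"`), which shares one sparse
factorization of $\Sigma$ across all band columns and is orders of
magnitude faster at 2,250 band columns.

`assemble_second_stage()` produces one row per environment × line with
yield BLUE, weight, and band BLUEs; check entries (the repeated control
genotypes) are dropped at this point.

## The model catalogue

All fourteen models share fixed environment means and a line effect
$g \sim N(0, K\sigma_g^2)$, where $K$ is one of: genomic
(`WG`, $G = WW'/m$ from centered marker dosages), pedigree (`WA`,
the additive relationship matrix by the tabular method) or identity
(`WO`). Model variants add:

* `gE`: a line-by-environment interaction with covariance
  $(K \otimes I)\sigma_{gE}^2$ (M2, M4, M7, M8, M10, M13, M14);
* band covariates, either one regression coefficient per band (M3, M4,
  M9, M10) or a functional representation (M5–M8, M11–M14);
* band-by-environment interaction: environment-specific band
  coefficients (M9, M10) or environment-specific coefficient curves
  (M11–M14).

In the functional models the reflectance of a cell is treated as a
curve $x_{ij}(k)$ over wavelength $k$; its contribution to yield is
$\int x_{ij}(k)\beta(k)\,dk$. Both the curve and the coefficient
function are expanded in truncated bases ($L = S = 21$ by default;
B-splines for M5/M7/M11/M13, Fourier for M6/M8/M12/M14), which turns
the integral into a product of per-cell *scores* and basis
coefficients: with $\hat c_{ij}$ the least-squares curve coefficients
and $J_{ls} = \int \phi_l(k)\psi_s(k)\,dk$,
the score vector is $\hat c_{ij}' J$. This reduces 250 band columns
to 21 informative columns per curve.

### Numerical choices

* Integrals ($J$, penalties, simulated functional contributions) use
  composite Simpson quadrature with 4,096 subintervals. For B-spline
  penalties the quadrature is aligned with the knot spans (16
  subintervals per span), because the integrand
  $\psi_l''\psi_s''$ is piecewise polynomial with breaks at the knots;
  a global grid that straddles knots cannot reach the package's 1e-6
  oracle tolerance, while span-aligned Simpson is exact up to rounding.
* The Fourier basis is orthonormal on the band domain; its curvature
  penalty is diagonal. The constant function has zero curvature, so
  its penalty entry is replaced by 1 to keep the prior proper.
* The roughness prior $N(0, \sigma^2 P^{-1})$ on coefficient functions
  is realized by *whitening*: scores are post-multiplied by the
  symmetric pseudo-inverse square root of the penalty $P$, after which
  the sampler sees a plain ridge block. The null space of the cubic
  B-spline curvature penalty (constant and linear functions) carries
  no roughness information and is kept as separate **unpenalized**
  columns — dropping it would make the model unable to represent the
  linear trend of a coefficient curve.
* Score columns are centered at compile time. Reflectance curves share
  a large mean component; without centering the coefficient block is
  nearly collinear with the intercepts, which both miscalibrates the
  variance prior and slows the per-coordinate Gibbs mixing. A column
  shift only moves the environment intercepts.
* `penalty_mode = "identity"` is provided as the alternative reading
  of a basis-coefficient prior with identity covariance; the default
  is the roughness penalty.

### Identifiability of the coefficient curves

Models with environment-specific curves (a common $\beta_1$ plus one
$\beta_2^{(i)}$ per environment) are over-parameterized: only
$\beta_1 + \overline{\beta_2}$ and the environment contrasts of
$\beta_2$ are identified. `reconstruct_beta_function()` therefore
reports the canonical decomposition with the interaction curves
centered across environments and their mean folded into $\beta_1$.

## The Gibbs sampler

The sampler (RcppArmadillo core) updates each coefficient from its
normal full conditional, tracking the residual vector; each ridge
block's variance from its scaled inverse-$\chi^2$ full conditional
(prior mode = scale/(df+2), df = 5 by default, prior modes resolved
per block from a target fraction $r^2 = 0.5$ of the response variance
split across blocks); and the residual variance, whose near-degenerate
prior pins it at 1 as described above. Kernel random effects enter
through the eigen square root $T$ of $K$ ($K = TT'$), so they are
ridge blocks too, and line effects are recovered as $u = Tb$. Defaults
are 30,000 iterations with 20,000 burn-in; all draws use R's RNG, so
runs are bit-reproducible under a seed. Closed-form checks (pinned
variances vs the mixed-model equations, conjugate toy posteriors) are
part of the test suite.

## Cross-validation

`make_50cv()` assigns, per environment, a random half of the lines to
training, under the constraint that every tested line is observed in
at least one environment (violations are repaired by swapping).
`make_90cv()` keeps only 10% of a focal environment's lines in
training. `evaluate_cv()` compiles each model once and reuses the
identical partitions across models, so model comparisons are paired;
it reports the per-environment Pearson correlation between predicted
and observed yield BLUEs, averaged over partitions (APC), with
standard error sd/√(partitions). Note the evaluation target is the
second-stage BLUE, not the unobservable true genetic value.

## The synthetic generator

Generator defaults are the package's study conditions and deliberately
mirror a large wheat phenotyping experiment at desk scale: 3
environments, 10 trials per environment laid out as alpha-lattices of
3 replicates × 6 blocks × 5 plots (30 entries = 28 unique lines + 2
shared checks, hence 280 lines), 100 bands on 392–851 nm, one
time-point. `full_scale_config()` provides the full-scale version
(39 trials, 976 lines, 250 bands, 9 time-points; late trials partially
filled, since 39 × 28 = 1,092 slots hold the 976 genotyped lines).

Realism choices and limits:

* Markers arise by gene dropping through a simulated pedigree
  (40 founders), so genomic and pedigree relationships are mutually
  consistent; QC-failing markers (high missingness, near-monomorphic)
  are injected deliberately. Linkage disequilibrium is *not* modeled.
* Reflectance curves are a smooth mean (green peak, red-edge sigmoid)
  plus heritable line deviations whose basis coefficients have
  covariance proportional to the kinship, plus a small non-heritable
  per-cell wiggle; values are clipped to the unit interval. No
  radiative-transfer realism is attempted.
* Yield assembles environment means, kernel line effects, kernel
  line-by-environment effects, functional contributions
  $\int x\beta_1$ and $\int x\beta_2^{(i)}$ (with $\beta_2$ centered
  across environments), and replicate/trial/block/plot noise with the
  configured variances. The fixed $\beta$ shapes are rescaled so the
  realized functional contributions hit the configured target
  variances exactly.
* Because the curve deviations are heritable, spectra act as a
  fingerprint of line identity: band models retain a small genuine
  predictive edge even when $\beta \equiv 0$. A true "bands carry no
  signal" null therefore also requires `curve_sd = 0` (non-heritable
  curves); the acceptance suite uses exactly that.

`simulate_second_stage()` bypasses the plot level and generates the
adjusted cell means directly; it is used where the first-stage
adjustment is not itself under study.

## Evaluation scales and runtime

Model fits at desk scale take seconds per chain; the full catalogue
under 10-partition cross-validation runs in minutes. The full-scale
configuration is exercised structurally (dimensions, block sizes) but
not fit end-to-end in the test suite, to stay inside test-time
budgets. Stage one at full scale uses the shared-variance band mode.

## Known limitations

* Band-by-environment conventional models (M9, M10) carry
  $p(1 + I)$ coefficient columns (1,000 at 250 bands, 3 environments)
  and are the slowest of the catalogue; the functional counterparts
  exist precisely to avoid that cost.
* The sampler is single-chain; convergence is assessed through the
  package's closed-form validation tests rather than multi-chain
  diagnostics.
* Pedigrees with unknown parents treat founders as non-inbred and
  unrelated.
* First-stage weights are carried for yield only; band BLUEs enter the
  second stage unweighted, as covariates.
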