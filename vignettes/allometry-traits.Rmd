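---
title: "Hierarchical allometries and phylogenetically controlled trait correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical allometries and phylogenetically controlled trait correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`allotrait` links two classic objects of forest ecology: species-level
allometric equations relating tree height and crown radius to stem
diameter (DBH), and species functional traits interpreted along the
acquisitive-to-conservative strategy spectrum. This vignette is the
package's own account of the models it fits, the choices behind its
defaults, and what its synthetic experiments do and do not demonstrate.

## The hierarchical allometry model

For individual $i$ of species $j$ and either response (height or crown
radius, m), the linearized power law is

$$\log_{10} y_{ij} \sim \mathrm{N}\!\left(\alpha_j + \beta_j \log_{10}
\mathrm{DBH}_{ij},\; \sigma\right),\qquad
(\alpha_j, \beta_j) \sim \mathrm{N}_2\!\left((\mu_\alpha, \mu_\beta),\;
\Sigma(s_\alpha, s_\beta, \rho)\right).$$

The intercept $\alpha_j$ is deliberately defined at DBH = 1 cm (no
centering of $\log_{10}$ DBH): it is then directly interpretable as the
log10 dimension of a small-stemmed tree, the quantity ecological
hypotheses about shade tolerance and early-ontogeny architecture are
about. $\beta_j$ is the dimensionless scaling exponent. Partial pooling
matters here because realistic campaigns have as few as 10 trees for
some species; the bivariate hyperdistribution (with a free correlation
$\rho$, since intercepts and slopes of regression lines are rarely
independent) shrinks poorly informed species toward the community-level
allometry instead of letting them run away.

Priors, with defaults and rationale:

* $\mu_\beta \sim \mathrm{N}(0.75, 0.5^2)$ for height and
  $\mathrm{N}(0.70, 0.5^2)$ for crown radius — centred on the global
  angiosperm scaling exponents, with an SD wide enough that 14 species
  of data dominate; the point of the informative centre is faster, more
  reliable convergence for data-poor species, not constraint.
* $\mu_\alpha \sim \mathrm{N}(0, 1)$ on the log10 scale (heights of
  roughly 0.1–10 m at DBH = 1 cm within 1 SD).
* $s_\alpha, s_\beta, \sigma \sim$ half-normal(1) — weakly informative
  on log10-scale spreads.
* $\rho \sim \mathrm{U}(-1, 1)$.

A single residual SD $\sigma$ is shared across species: with 10–25
trees per species, species-specific residual variances would be poorly
identified and would leak into the intercept uncertainty the downstream
correlations depend on.

The saturating alternative, fit with the identical hierarchy and
compared by WAIC, is $\log_{10} y = a_j\,(1 - e^{-b_j \mathrm{DBH}})$,
with $a_j$ the log10 asymptotic dimension and $b_j > 0$ the approach
rate per cm; the hierarchy is placed on $(a_j, \log b_j)$ so the rate
stays positive. This is the most common two-parameter saturating family
for height–diameter curves; it represents the "asymptotic" class rather
than any one published equation.

### Sampling and numerics

Models are sampled with JAGS (4 chains; the production default of
20,000 iterations with 10,000 warmup mirrors a full analysis, while the
package's own experiments use 4 × 2,000/1,000 or 2 × 1,200/600 —
desk-scale profiles chosen because the posterior for this model is
effectively exact at that length, as the calibration experiments in the
test suite confirm). Two numerical choices are worth recording:

* The bivariate species-level normal is expressed as a marginal for
  $\alpha_j$ and a conditional for $\beta_j$ — algebraically the same
  joint distribution, but it avoids inverting a 2×2 covariance matrix
  inside the sampler, which fails when the hyper-SDs drift toward zero
  (exactly the near-common-slope regime this analysis lives in), and it
  keeps the species-level updates conjugate.
* Convergence is summarised by split R-hat (threshold 1.05) and
  effective sample size per parameter; a violation raises a warning and
  is flagged in the result and in the written convergence table, never
  silenced.

WAIC is computed from the pointwise log-likelihood matrix with a
log-sum-exp-stabilised lppd and the sample-variance penalty
$p_\mathrm{WAIC} = \sum_i \mathrm{var}_s\, \ell_{si}$; the pointwise
contributions sum to the total by construction.

## Contrasts and rank correlations

Species are not independent data points, so every correlation is
computed on phylogenetically independent contrasts (Felsenstein
pruning), standardized by the square root of the summed adjusted branch
lengths. Two implementation decisions:

* **Sign convention.** Each contrast's sign depends on which child is
  subtracted from which. Kendall's tau is *not* invariant to flipping a
  single node's sign in one variable only, so the package fixes a
  deterministic convention — the child whose smallest descendant tip
  label sorts first (C-locale radix order) supplies the minuend — and
  applies it identically to every variable on the same tree. Permuting
  the newick child order therefore cannot change any reported tau. The
  convention itself is arbitrary; results are convention-stable but a
  different convention could give numerically different (equally valid)
  tau values for the same data.
* **Tau-b.** Trait tables can contain ties, so the tie-corrected tau-b
  is used throughout (identical to tau-a without ties). All-tied input
  is an error, not a silent `NA`.

Polytomies are rejected rather than auto-resolved: silent resolution
changes the contrasts, and the user should decide how to date extra
nodes. Traits are contrasted as raw species means by default, with a
`log10_traits` flag for strongly right-skewed traits such as seed mass.
Because contrasts are a fixed linear map for a given tree, the map is
precomputed once and applied to thousands of posterior draws as a single
matrix product.

## Posterior propagation of the correlations

For each target (intercept, slope, or expected dimension at a reference
DBH of 1, 3, ..., 19 cm) the pipeline resamples posterior draws
uniformly with replacement (default 10,000; a `stream` mode uses each
retained draw at most once when enough are available), computes the
per-draw tau against each trait's contrasts, and summarises the tau
distribution by its median and equal-tailed 2.5/97.5 percentile
interval (linear interpolation). Traits enter as fixed species means —
no trait measurement uncertainty is propagated. For the height–crown
coupling the two posteriors come from independent fits, so their
pairing is arbitrary; draws are paired by resampled index by default,
with an `independent` option, and the choice is immaterial in practice
because the coupling statistic is dominated by the posterior medians.

One property deserves emphasis because it is easy to misread: the
interval is a *credible interval for the realized correlation between
traits and the true species parameters of this community*, propagating
estimation uncertainty only. It is **not** a null-hypothesis test
across hypothetical communities. When the intercepts are estimated very
precisely (low residual SD, many trees per species), the interval
legitimately collapses onto the tau of the realized parameters — and
for a finite community of 14 species the realized tau under zero
trait–parameter coupling is itself scattered (SD ≈ 0.23), so a narrow
interval can exclude zero even when no generative coupling exists. With
noisier data — as in typical field campaigns, where posterior intercept
uncertainty is comparable to the intercept spread — the interval widens
and "excludes zero" behaves much more like a conservative signal
detector. The package's simulation experiments show both regimes: the
weakly identified slopes are calibrated as a null detector (~98% of
null slope intervals contain 0), while the precisely identified
intercepts are not (~50% under the default low-noise conditions).
Interpreting an excluded zero therefore always requires asking how
sharp the parameter estimates are.

A structural consequence of near-common slopes, asserted exactly in the
tests: if all species share one slope within a posterior draw, the
expected dimensions at every reference diameter are a common positive
rescaling of each other, so the per-draw tau is *identical* across the
whole 1–19 cm grid. Variation of trait–architecture correlations across
size classes can only come from slope variation.

## The synthetic-data generator

The generator is the package's study-condition definition, not a test
dial. It emulates a campaign on 14 dominant species with 15 measured
trees each:

* **Phylogeny**: pure-birth (Yule) tree, unit birth rate, ultrametric —
  the minimal tree satisfying the Brownian-motion assumption behind
  contrasts. A user-supplied newick can replace it.
* **Traits**: six traits (leaf %N, leaf %P, wood density g/cm³, leaf
  area cm², SLA cm²/g, seed mass g) evolved by independent Brownian
  motion and analysed on that scale directly, keeping the contrast
  assumption exactly true. Root states are typical tropical-tree
  values; rates default to $(0.1 \times \mathrm{root})^2$ per unit
  depth so values stay positive with overwhelming probability.
* **Allometric parameters**: $(\alpha_j, \beta_j)$ from the bivariate
  hyperdistribution with $\mu_\alpha = 0.30$ (height; a ~2 m sapling at
  1 cm DBH) or $-0.35$ (crown; ~0.45 m radius), $\mu_\beta = 0.75$ /
  $0.70$, $s_\alpha = 0.1$ (clear intercept variation), $s_\beta =
  0.02$ (near-common slopes), $\rho = -0.3$. Default trait couplings
  act on intercepts only and encode the conservative-strategy syndrome
  the analysis is designed to detect — denser wood → shorter and
  wider-crowned at a given diameter, heavier seeds → wider crowns,
  higher leaf %P → narrower crowns — at moderate effect size (0.05–0.06
  log10 units per trait SD). Null and strong-coupling experiments
  construct their own configurations explicitly.
* **Observations**: one shared log-normal DBH per tree (log10 mean 0.9,
  SD 0.35, spanning ~1–30 cm and hence the 1–19 cm reference grid) and
  log10-normal residuals with SD 0.05.

What the generator does *not* emulate — and hence what passing
simulation experiments cannot show about real data: DBH measurement
error, within-species trait variation and trait–ontogeny drift,
non-Brownian trait evolution (no Ornstein–Uhlenbeck option),
non-ultrametric or misestimated phylogenies, crown asymmetry beyond the
two-radius average, and any disturbance-driven truncation of the size
distribution.

## Degenerate inputs and edge behaviour

Zero BM rate reproduces the root state at every tip; zero residual SD
reproduces the generating line exactly (the regression-recovery test);
zero hyper-SDs collapse species to the hyper-means. Records missing a
response are dropped for that model only, with a logged count; a model
needs at least two species, each with at least two usable records.
Single-radius crown records use the available radius. All percentile
summaries use the same interpolated quantile definition, so repeated
summaries of identical draws have zero-width intervals.

## Problem sizes

The test suite runs its replicate experiments at 14 species × 15 trees
with 2–4 chains of 700–2,000 iterations, 20 replicates per experiment,
and 200–600 tau resamples; the acceptance script uses 4 × 4,000 chains
and 10,000 tau resamples. These sizes were chosen so that Monte-Carlo
error is comfortably below every asserted tolerance while a full run
stays in the minutes range on a single core.

## Known limitations

* The asymptotic form is one representative of its class; WAIC margins
  against other saturating families may differ.
* A single shared residual SD; species-heteroscedastic versions are out
  of scope.
* No posterior-predictive simulation of new trees (expected values
  only) and no leave-one-out cross-validation.
* No multiple-testing adjustment across the trait × target grid — the
  interval semantics above are the user's guide instead.
* Kendall tau values depend on the documented contrast sign convention;
  comparisons with externally computed taus require aligning that
  convention.
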