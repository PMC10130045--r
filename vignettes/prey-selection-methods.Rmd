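---
title: "Methods: prey availability, isotope mixing models, and selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prey availability, isotope mixing models, and selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preyselect)
```

## The problem

Diet and prey selection of a rare, deep-foraging baleen whale cannot be
observed directly: there are no stomach contents, no surface feeding, and
very few individuals. What can be measured are (i) the prey field, via a
mid-water trawl survey of the core habitat; (ii) bulk stable isotopes
(δ¹³C, δ¹⁵N) of whale skin biopsies and prey muscle; and (iii) the
proximate composition (energy density, lipid, protein, moisture) of the
dominant forage species. `preyselect` chains these into a reproducible
pipeline: availability indices → Bayesian mixing model (with a geometric
validity check) → prey-quality comparisons → Chesson selectivity and
Pianka overlap. A seeded synthetic-data generator provides ground-truth
inputs so every stage has a parameter-recovery test.

## Prey availability

For species *i* over *N* hauls, the pipeline computes
%O = nᵢ/N × 100 (occurrence), %N = xᵢ/X × 100 (percent by number) and
%B = bᵢ/B × 100 (percent by biomass). Confidence intervals come from a
percentile bootstrap. Two decisions here were genuinely open:

* **Resampling unit.** The haul is the independent unit of the survey
  design, so hauls (not individuals) are resampled with replacement.
  Individual-level resampling would treat schooling fish as independent
  and produce implausibly tight intervals.
* **Quantile rule.** Intervals use inverse-ECDF quantiles
  (`quantile(type = 1)`), so a small-sample interval is always an
  attained resample value. This makes the bootstrap exactly checkable
  against exhaustive enumeration of resamples on two- and three-haul
  tables, which the test suite does. BCa corrections are deliberately
  not used.

Report rounding is two decimals for the indices; all internal
computation is full precision.

## The mixing model

Consumer tracer values are modelled as a mass-balance mixture of
TEF-corrected sources. For consumer *j* and tracer *t*:

$$X_{jt} \sim N\!\Big(\textstyle\sum_i p_i(\mu_{it} + \lambda_t),\; \sqrt{v_t}\Big)$$

with diet simplex *p* ~ Dirichlet(1, …, 1), source moments
(μᵢₜ, σᵢₜ), and trophic enrichment factor (TEF) λₜ ± τₜ — for whale skin,
1.29 ± 0.56 ‰ (δ¹³C) and 2.73 ± 0.58 ‰ (δ¹⁵N), the fin-whale surrogate
values.

### Error structure

The variance `v_t` is the consequential choice, and the package treats
it explicitly rather than hiding it:

* `error_structure = "residual_process"` (default):
  $v_t = \xi_t \sum_i p_i^2(\sigma_{it}^2 + \tau_t^2)$ with
  ξₜ ~ Uniform(0, 20), and—whenever the source table carries sample
  sizes—**hierarchical sources**: each source mean is sampled as
  N(mᵢₜ, sᵢₜ/√nᵢ) and each source variance from the scaled
  inverse-chi-squared sampling distribution of a sample variance with
  nᵢ − 1 degrees of freedom.
* `error_structure = "additive"`:
  $v_t = \sum_i p_i^2(\sigma_{it}^2 + \tau_t^2) + \epsilon_t^2$ with
  εₜ ~ half-normal(5 ‰), source moments fixed at their summaries.

The default is not arbitrary. Additive structures with fixed source
moments contain a quiet pathology: because the process term is weighted
by pᵢ², a spread-out diet shrinks `v_t` and is rewarded through the
−n/2·log vₜ term of the likelihood, dragging the posterior toward the
uniform simplex whenever the consumer data are tight. The multiplicative
factor ξₜ absorbs the overall variance scale per tracer, removing that
reward and letting the mean-balance carry the information. The
hierarchical source treatment propagates the finite prey sample sizes
(n = 3–23 here) instead of pretending the source moments are known. With
the bundled Gulf of Mexico inputs the two structures give posterior mean
contributions of roughly 67% and 39% for the dominant prey — the choice
matters, and the multiplicative/hierarchical form is the one consistent
with the published whale analysis and with standard mixing-model
practice for summary-statistic source data. The additive form is kept
because it is the exact forward model of `simulate_consumers()`, which
makes it the right structure for oracle and parameter-recovery testing
(and it is what `resid_sd_fixed` uses to make the posterior
one-dimensional for grid-integration cross-checks).

### Sampler and diagnostics

Sampling is blocked Metropolis-within-Gibbs on unconstrained scales: an
additive log-ratio transform for *p* and logs for ξ/ε (random-walk
block), a second random-walk block on the log source variances, and
exact conjugate normal Gibbs draws of the source means. Proposal scales
adapt toward ~25% acceptance during burn-in only, so the retained chain
is a valid time-homogeneous Markov chain. Defaults mirror the published
analysis (3 chains × 300 000 draws, 200 000 burn-in); tests and the
reproduction script run 3 × 30 000 / 20 000, which the test suite shows
is converged for this problem (all Gelman–Rubin R̂ ≤ 1.05, and an
independent JAGS implementation of the same model agrees with the
package sampler to well under the posterior's Monte Carlo error).
Non-convergence is never silent: any R̂ > 1.05 sets a flag on the fit
and raises a warning, and Geweke z-scores are reported per chain and
parameter. A constant parameter (e.g. the degenerate single-source
simplex) yields a degenerate-pass Geweke result rather than NaN noise.

Individual whale isotope values are unpublished; only means, SDs and
ranges are printed. `rescale_consumers_to_summary()` therefore maps any
seeded draw to a sample with *exactly* the printed mean and SD per
tracer (an affine transform, so z-scores are preserved). All summary
statistics entering the likelihood are then identical to the published
ones regardless of seed.

## Mixing-polygon validation

Before trusting a mixing model, each consumer must plausibly lie inside
the convex hull of the TEF-corrected sources. `simulate_mixing_region()`
repeats, 1500 times by default: draw each corrected source vertex, build
the convex hull (Andrew's monotone chain, counter-clockwise, collinear
points dropped), and test each consumer with ray casting, counting
on-edge points as inside. The retained criterion is an inside
probability of at least 0.05 (the 95% mixing region). Two details the
literature leaves open are exposed as arguments:

* `tef_shared` (default `TRUE`): one TEF deviate per tracer per
  iteration, shared by all sources — the enrichment belongs to the
  consumer, not to each prey independently. With independent draws
  (`FALSE`), inflating the TEF SD enlarges every vertex's spread and
  inside-probabilities rise monotonically; the shared form trades that
  monotonicity for the more defensible correlation structure.
* `se_scale`: draw source means with σ/√n instead of σ, for users who
  read the polygon as uncertainty in the source means rather than
  spread of source individuals.

Geometry primitives are tested against an O(n³) brute-force hull, the
base-R `chull()`, and a winding-number membership oracle. The optional
probability surface (`grid_n`) supports the conventional 5%-outermost /
10%-interval contour plot.

## Prey quality

Unit arithmetic is deliberately tiny and exact: wet = dry × (1 −
moisture/100) and protein = 6.25 × nitrogen. Between-species comparisons
use one-way ANOVA with Tukey HSD, or Kruskal–Wallis with Holm-adjusted
pairwise Wilcoxon tests when normality is unattainable.
`normality_gate()` encodes the usual decision chain — raw → log →
non-parametric — using a Shapiro–Wilk test on the pooled
within-species-centered residuals (the quantity ANOVA actually assumes
normal), which keeps its false-alarm rate at the nominal α instead of
compounding it across per-species tests. Pairwise "differences" are
reported as signed differences of species means (row minus column);
published tables of this kind are inconsistent about sign, so
reproduction checks compare absolute values.

## Selectivity and overlap

Chesson's index is implemented in the standard ratio form
αᵢ = (rᵢ/pᵢ) / Σⱼ(rⱼ/pⱼ), which is invariant to rescaling of the
availability vector and sums to one. The index equation as printed in
some reports (α ∝ rᵢpᵢ) does not reproduce their own tabulated values,
while the ratio form with percent-by-number availability reproduces all
of them to three decimals; the product form is nevertheless available
behind `formula = "product"` for compatibility. Classification supports
two rules: the conventional strict αᵢ > 1/m threshold (default) and
αᵢ > pᵢ ("taken in excess of availability"), which is the rule that
matches the published selection labels. Pianka's overlap
O = Σ pᵢApᵢB / √(Σ pᵢA² Σ pᵢB²) uses percent-by-biomass availability by
default. Recomputing it from the published biomass and diet tables gives
≈ 0.81; the published value of 0.333 cannot be reconstructed from any
combination of the printed tables (candidates ≈ 0.15, 0.75, 0.81), so
the package documents the recomputed value and treats the printed one as
irreproducible.

## The synthetic-data generator

`simulate_trawl_survey()` uses a zero-inflated negative binomial per
haul × species (presence Bernoulli × NB with dispersion k, variance
μ + μ²/k): demersal forage communities decouple occupancy from
abundance — in the motivating survey one species contributed ~88% of
individuals while 16 of 26 taxa occurred in fewer than 10% of hauls —
and a Poisson model cannot produce that. Body masses are lognormal
(strictly positive, right-skewed) and haul biomass is the sum of
individual masses, so biomass is zero exactly when the count is zero.
`default_survey_config()` encodes a 26-species community with that
patchiness structure. Conveniences: dispersion ∞ is Poisson, dispersion
0 is a point mass at the rounded mean (used by degenerate exactness
tests). All generators are pure functions of (config, seed); a single
integer seed is split into per-module streams by a counter-based hash,
so modules can be tested independently without RNG coupling.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real surveys: spatial haul placement and
station-selection bias, gear selectivity and escape behaviour,
length/size structure, and any correlation between count and body mass
within a haul.

## Numerical choices and degenerate inputs

* Simplex draws are checked to sum to 1 within 1e-9; the Dirichlet+ALR
  density collapses to Σ αᵢ log pᵢ, evaluated in logs throughout.
* Bootstrap and polygon runs, and every generator, are reproducible
  bit-for-bit under a fixed seed.
* Collinear point sets raise a degenerate-hull error rather than
  returning a 2-vertex "polygon"; membership uses an absolute tolerance
  of 1e-9 for the on-edge test.
* A single-source mixing model returns the exact degenerate simplex
  p = 1. Identical TEF-corrected sources are flagged as unidentifiable.
* Group comparisons refuse zero-variance data and species with fewer
  than two records; the normality gate needs three.
* Problem sizes used in the shipped tests (e.g. 2000-haul
  law-of-large-numbers checks, n = 10 000 isotope draws, 3 × 30 000
  MCMC draws, 20 recovery replicates at n = 50 consumers) were chosen
  as the smallest sizes at which the checked tolerances are comfortably
  dominated by the quantity being tested rather than by Monte Carlo
  noise.

## Known limitations

Two tracers bound the resolvable diet complexity: with four sources the
posterior is prior-sensitive where sources are isotopically similar (the
three low-δ¹⁵N fishes here). TEF choice is the dominant systematic
uncertainty and is a surrogate from a congener. The bundled survey
table is a totals table — haul-level structure is unpublished — so
occurrence and bootstrap intervals for the real survey cannot be
recomputed, only simulated. Tissue turnover time, covariates on the
diet, and informative priors are out of scope.
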