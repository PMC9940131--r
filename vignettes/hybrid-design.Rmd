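---
title: "Hybrid sample-size determination for PG and SW cluster-randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid sample-size determination for PG and SW cluster-randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridCRT)
```

## The problem

Cluster-randomized trials (CRTs) randomize groups — care homes, clinics,
villages — rather than individuals.  Their sample size depends critically on
the intra-cluster correlation (ICC) ρ, the fraction of outcome variance
attributable to between-cluster variation, and on the outcome SD σ.  Both
are notoriously hard to pin down at the design stage: trial reports often
carry a single "conservative" ICC with little justification, and a
misjudged ρ or σ translates directly into an under- or over-powered trial.

`hybridCRT` supports a hybrid Bayesian-frequentist response: keep the
frequentist analysis and error-rate control, but express design-stage
uncertainty about ρ (and optionally σ) as prior densities and size the
trial to control the *expected power* — frequentist power averaged over
those priors — instead of power at point guesses.  The same machinery then
answers a comparative question: when the ICC is uncertain, is a
parallel-group (PG) or a stepped-wedge (SW) design more efficient on a
common measurement budget?

## Model and power

Outcomes are modelled as normally distributed with a random cluster
intercept (variance σ_c² = ρσ²) and individual error (σ_e² = (1−ρ)σ²).
For a PG-CRT with C clusters of n measurements and 1:1 allocation, the
treatment-effect estimator has variance

$$\mathrm{Var}(\hat\mu) = \frac{4\{1 + (n-1)\rho\}\sigma^2}{Cn}.$$

For a cross-sectional SW-CRT the Hussey–Hughes model adds fixed period
effects; with the C×T treatment-indicator matrix X summarized by
U = ΣX_jk, W = Σ_k(Σ_j X_jk)², V = Σ_j(Σ_k X_jk)²,

$$\mathrm{Var}(\hat\mu) = \frac{C\sigma^2(1-\rho)\{1+\rho(nT-1)\}}
  {n[\{1+\rho(nT-1)\}(CU - W) + n\rho(U^2 - CV)]}.$$

One-sided power at target difference δ is
Φ(δ/√Var − z₁₋α) for the z-test of H₀: μ ≤ 0 at level α.  Design choices
worth noting:

- **Normal reference throughout.**  No small-sample t or Satterthwaite
  correction is applied — the closed forms above are z-based, and that is
  a documented limitation for trials with few clusters.  Two-sided tests
  are expressed by passing α/2.
- **ρ = 1 limit.**  The SW variance vanishes (the (1−ρ) factor), so
  `var_sw()` returns 0 and power 1 by continuity.  This matters because
  quadrature nodes of wide ICC priors can land arbitrarily close to 1.
- **Odd cluster counts.**  The PG formula assumes equal arms;
  `pg_design()` warns on odd C and `var_pg()` refuses unless the user
  forces the equal-split approximation (`allow_unequal = TRUE`).
- **Unequal wedges.**  When (T−1) does not divide C, remainder clusters
  are assigned one per step starting from the earliest step, with a
  warning.  This keeps the design as close to the standard equal wedge as
  possible while staying exact in C; it is a package choice, as no
  standard convention exists.
- **Fractional n.**  Both variances are continuous in n, and the design
  comparison needs n = N/T; constructors therefore accept non-integer
  sizes, while sample-size searches return integers.

Every closed form is cross-checked (in the test suite, to relative 1e−8
over random designs) against `gls_variance()`, an independent oracle that
builds the cluster-period-mean linear model and inverts its information
matrix.

## Priors

The ICC takes a prior on [0, 1]: truncated-normal TN(0, 1, m, s²)
(recommended: a mode at the design point estimate is easy to communicate),
or Beta(a, b).  The SD takes a Gamma(k, θ) prior in the *rate*
parametrization (density ∝ σ^{k−1}e^{−θσ}); constructors are labelled
explicitly to avoid the shape/scale ambiguity.  `prior_point()` recovers
the frequentist framework as a degenerate prior.  Beta shapes below 1
(density unbounded at an endpoint) are legitimate — a very small modal ICC
can motivate them — and are handled safely because all integration happens
through the quantile function, so the singular endpoint is never evaluated.

"Correctly specified" priors — mode equal to the frequentist point
estimate, SD expressing the uncertainty — are built with `match_mode()`:
closed-form for Gamma (quadratic in √k), root-finding on the
variance for Beta and TN, with infeasible mode/SD combinations rejected
with the attainable range.  The truncated-normal moments use the standard
formulas (mean m + s(φ(l)−φ(u))/Z, etc.), and the test suite makes
numerical integration the arbiter: every family's density must integrate
to 1 (1e−8) and its closed-form moments must match quadrature (1e−6).

One fixture deserves a note: the SW trial's SD prior Gamma(17.32, 40) has
mode 0.408 and mean 0.433, neither exactly the trial's point estimate
σ = 0.426.  The fixture stores those published parameters verbatim rather
than re-deriving them; the discrepancy is documented, not resolved.

## Expected power: integration scheme

`expected_power()` evaluates

$$EP = \int_0^\infty\!\!\int_0^1 P(\delta, n, X, \alpha, \sigma, \rho)\,
\psi_{SD}(\sigma)\,\psi_{ICC}(\rho)\,d\rho\,d\sigma$$

by transforming each prior to its probability scale: with Q the prior
quantile function, ∫P ψ dρ = ∫₀¹ P(Q(v)) dv, evaluated with Gauss–Legendre
nodes (default 129 per dimension, tensor product for the double integral).
The transform handles Beta endpoint singularities and the Gamma's
unbounded support uniformly, with no arbitrary σ cutoff.  Convergence is
verified by re-evaluating at roughly double the node count and doubling
until successive estimates agree to 1e−6 (the reported `est_error`); the
scheme and tolerance are package choices validated by oracle agreement,
not prescribed by the methodology.  `ep_monte_carlo()` provides the
independent stochastic estimate (prior draws, reported standard error);
the suite requires |quadrature − MC| < max(3·MCse, 1e−3) across random
specifications, and exact agreement (1e−10) with frequentist power under
point-mass priors.

A property worth knowing when reading expected-power curves: with an SD
prior centred on σ, the EP is *lower* than the ICC-only EP in the
high-power regime (power is concave in σ there, so averaging loses), but
*higher* at small C where power is low and convexity wins.  For the PG
worked example the curves cross near C ≈ 33; the familiar statement "SD
uncertainty slows the approach to full power" applies from roughly the
trial's own size upward.

## Sample-size search

Power and expected power are increasing in the cluster count, so
`min_clusters_freq()` / `min_clusters_hybrid()` bracket by geometric
doubling and refine by bisection, using O(log C) evaluations; minimality
of the result is confirmed directly.  Admissible counts keep the design in
standard form: steps of 2 for PG (exact 1:1 allocation), steps of T−1 for
SW (equal wedge), with `allow_unequal` unlocking step 1 plus the remainder
rule.  Rounding is always up.  `min_cluster_size()` solves the dual
problem at fixed C; for a PG design with ρ > 0 the power is bounded as
n → ∞ by Φ(δ√(C/(4ρσ²)) − z₁₋α), and a target above that asymptote fails
with the attainable supremum rather than searching forever.  Heavy-tailed
SD priors can likewise cap the expected power below 1; the cluster search
reports the supremum it observed when the target is unreachable.

## Comparing PG and SW designs under ICC uncertainty

`ep_comparison_grid()` fixes a common budget — C clusters, N measurements
per cluster, so n = N for PG and n = N/T for SW — and maps the EP of both
designs over a grid of TN ICC-prior parameters (m, s).  With the SD held
fixed, EP depends on (δ, σ) only through δ/σ (verified to 1e−10), so σ is
set to 1 and the standardized effect is the knob.  The default α is 0.025
one-sided.  `extract_contour()` returns the equal-EP level set via linear
interpolation on grid cells (`grDevices::contourLines`), so its error is
bounded by the grid resolution — 0.005 for replication runs, 0.025 in the
quick tests; `pg_region_summary()` reports the maximal m and s at which
the PG design is favoured.

At C = 50, N = 30, T = 3, scanning standardized effects 0.10–0.40, the
PG-favourable region is confined to small m and s, largest at effect 0.10
with maxima m = 0.105, s ≈ 0.17, and it shrinks as T grows at fixed
budget — the stepped wedge's within-cluster comparisons make it robust to
high-ICC prior mass.  The facet effect sizes of the published comparison
are not recoverable from its text, so the replication scans candidates and
reports extremes with grid-resolution tolerance.

## What the tests do and do not show

All empirical statements above are computed by the test suite or the
acceptance script at the stated sizes (power curves over C ≤ 100,
comparison grids at 0.005/0.025 resolution, Monte-Carlo oracles at 10⁵
draws).  The fixtures are published design parameters, not data: the
package evaluates design-stage formulas and never fits the mixed model to
outcomes.  Conclusions are accordingly about the design calculus — they
say nothing about closed-cohort stepped wedges, decaying within-cluster
correlation, binary outcomes, unequal cluster sizes, or priors on the
effect size, all of which are out of scope.
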