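---
title: "Neighborhood-wide association screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood-wide association screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwas)
```

## The screening problem

A neighborhood-wide association study (NWAS) treats every area-level census
variable as a candidate "locus" and screens all of them, agnostically,
against a binary health outcome — here the motivating phenotype is
aggressive prostate cancer (tumor stage 3–4 *and* Gleason grade ≥ 7),
observed case by case in a state cancer registry and linked to the census
tract of residence through the 11-character FIPS key (state + county +
tract; the county is the first five characters). The statistical obstacles
are the ones familiar from genome-wide screens, plus two of its own:

* **multiplicity** — tens of thousands of tests;
* **within-tract dependence** — cases in the same tract share all exposure
  values by construction;
* **spatial confounding** — disease risk and census variables are both
  spatially smooth, so county-scale risk gradients can masquerade as
  variable effects;
* **inter-variable correlation** — census variables come in large blocks of
  near-duplicates, the analogue of linkage disequilibrium.

The pipeline answers these with three successively more stringent phases,
each consuming only the significant set from the phase before.

## Preprocessing

The cohort is defined by an auditable exclusion cascade with
first-match-wins attribution (race restriction, P.O. Box address, missing
stage/grade, missing age, missing year of diagnosis), so per-rule counts
are disjoint and sum exactly — mirroring how registry exclusions are
reported in practice. Variables are filtered in two strict-inequality
stages: missing fraction > 10%, then (among survivors) a single modal value
covering > 95% of non-missing entries. Boundary values are retained.
Surviving variables are Z-scored *across tracts* (each tract weighted once,
sample SD with denominator n−1), so every downstream effect is a log odds
ratio per tract-level SD and comparable across variables. Z-scoring across
linked cases instead would let populous tracts dominate the scale; the
tract-level choice is the package default and the case-level alternative
can be had by passing a case-weighted table, but we regard the tract-level
version as the natural reading of a tract attribute.

## Phase 1 — GEE logistic screen

For each variable \(i\), with cases \(k\) clustered in tracts \(j\):

\[\operatorname{logit} p_{kj} = \alpha + \beta_{i0}\,\mathrm{age}_k +
\beta_{i1}\,\mathrm{year}_k + \beta_{i2}\, x_{ij}\]

fit by generalized estimating equations with an exchangeable working
correlation and the robust sandwich covariance
\(B^{-1} M B^{-1}\), \(B = \sum_j D_j' V_j^{-1} D_j\),
\(M = \sum_j D_j' V_j^{-1} r_j r_j' V_j^{-1} D_j\). The exchangeable inverse
is applied in closed form, so each fit is \(O(np^2)\) per Fisher-scoring
iteration; \(\alpha\) (working correlation) and \(\phi\) (dispersion) are
moment-updated from Pearson residuals each iteration. Convergence is
\(\max_k|\Delta\beta_k| < 10^{-8}\) within 100 iterations; a diverging
linear predictor (\(\max|\eta| > 30\), the signature of separation) flags
the fit as non-converged. Non-converged variables are reported in a skip
list and excluded from the multiplicity count \(m\).

Inference is a two-sided Wald test of \(\beta_{i2}\) against the robust SE
— the standard GEE test; p-values are Bonferroni-corrected
(\(\min(1, mp)\)) and judged at family-wise level 0.05. Per-variable
residual missingness (≤ 10% after filtering) is handled by complete cases,
the minimal assumption.

## Phase 2 — Bayesian spatial re-evaluation

Each Phase 1 hit is refit at county scale \(j\):

\[\operatorname{logit} p_{kj} = \alpha + \beta_0\,\mathrm{age}_k +
\beta_1\,\mathrm{year}_k + \beta_2 x_{kj} + V_j + U_j\]

with \(V_j \sim N(0, \sigma_v^2)\) exchangeable (global smoothing) and
\(U\) an intrinsic CAR (Besag) field over the county adjacency graph
(local smoothing): the improper Gaussian prior whose precision is
\(\sigma_u^{-2} Q\) with \(Q\) the graph Laplacian, made proper by a
sum-to-zero constraint per connected component; isolated counties are
pinned at zero. Every county must hold at least one case and one control —
checked, with offending counties named.

Priors (configurable): fixed effects \(N(0, 10^2)\); both precisions
\(\mathrm{Gamma}(1, 5\times 10^{-4})\), a common weakly-informative default
in disease mapping. Either SD may instead be pinned, which is how the test
suite compares the sampler against a numerical-integration oracle and
realizes the no-random-effect limit.

### Sampler

Inference is a native adaptive Metropolis-within-Gibbs:

* per-coordinate random-walk updates for fixed effects, proposal scales
  adapted during warmup toward 44% acceptance. Covariates are centered
  internally (the intercept prior applies to the centered intercept, and
  draws are transformed back) — without this, calendar year makes the
  intercept direction essentially unidentifiable to a coordinate sampler;
* single-site random-walk updates for \(V_j\) and \(U_j\); the ICAR full
  conditional contributes \(N(\bar U_{\partial j}, \sigma_u^2/n_j)\);
* after each sweep, \(U\) is recentered per connected component with the
  mean shift absorbed into the intercept (for a connected graph this is an
  exact reparameterization under the wide intercept prior; it is the
  centering-on-the-fly long used for Besag fields), so the sum-to-zero
  constraint holds in every retained draw;
* conjugate Gibbs draws for \(\sigma_v^2\) and \(\sigma_u^2\) (the latter
  with degrees of freedom equal to the rank of \(Q\));
* a joint rescale move \((V, \sigma_v^2) \to (cV, c^2\sigma_v^2)\) (and
  likewise for \(U\)) that walks along the prior-scale direction and breaks
  the mutual-shrinkage trap where a small variance pins its effects near
  zero and vice versa.

Every reported scalar carries an effective sample size (Geyer
initial-positive-sequence), its Monte Carlo SE, and a split-half
convergence statistic; the contract MCSE < 5% of posterior SD (equivalently
ESS ≥ 400) and \(\hat R < 1.01\) attaches a warning when unmet rather than
failing — the \(V/U\) variance *split* is only weakly likelihood-identified
and mixes slowly, which is intrinsic to the Besag-plus-exchangeable
parameterization, while their sum (what the residual-variability summary
uses) and the exposure effect mix well.

### Corrected credible intervals

With \(n\) variables entering Phase 2, significance is exclusion of zero
from the equal-tailed credible interval at level \(1 - 0.05/n\) — for the
published screen, \(n = 434\) gives level \(\approx 0.9998848\). Extreme
quantiles need draws: when (tail mass × draws) < 20 the interval is not
estimable and the package raises a precision error asking for more draws
instead of returning noise. The interval *length* on the log-odds scale is
the Phase 3 ranking statistic.

### Residual variability

The per-model summary is the latent-scale intraclass correlation
\((\sigma_v^2 + \operatorname{var}(U)) / (\sigma_v^2 +
\operatorname{var}(U) + \pi^2/3)\), averaged over draws, with
\(\operatorname{var}(U)\) the empirical variance of the field within each
draw. "Residual variability" has no single standard definition in the
disease-mapping literature; this latent-scale ICC is one principled
reading, and figures reported elsewhere under that name should be compared
with caution rather than treated as reproduction targets.

## Phase 3 — components and top hits

Phase 2 survivors are grouped by eigen-decomposition of their tract-level
Pearson correlation matrix (rows are tracts, not cases — the case-weighted
alternative would again let populous tracts dominate; this is configurable
by passing a different table). Residual missing cells are mean-imputed
(counted and reported). Component signs are fixed so each component's
largest-magnitude loading is positive. The smallest \(k\) components whose
cumulative variance reaches 90% are retained; each variable joins the
retained component where its absolute loading is maximal (ties to the lower
index), and each component is represented by its member with the shortest
Phase 2 credible interval — ties prefer the larger absolute posterior
effect, then the lexicographically smaller id. "Loaded on" has no published
loading threshold; maximal absolute loading is the operational choice.

## The synthetic-data generator

Real registry linkages are not redistributable, so the generator emulates
the data's *structure* with known truth: a rook-adjacency county grid
(default 6 × 5) containing 10 tracts per county; exposures built as
\(\sqrt\rho\) × block factor + spatial share × county ICAR field + iid
noise, unit variance by construction so a planted log-OR is per SD;
ages \(N(69.2, 9.4^2)\), diagnosis years uniform on 1995–2005, baseline
log-odds −2.4 (≈ 8% aggressive, matching the published cohort fraction),
county effect SDs \(\sigma_v = 0.3\), \(\sigma_u = 0.5\); stage and Gleason
back-filled so the labeling rule reproduces the simulated outcome exactly.
Counties violating the Phase 2 case/control precondition are redrawn.

What it does **not** emulate: real SF1/SF3 marginal distributions (census
variables are counts, percentages, medians — here everything is Gaussian),
real Pennsylvania geography, geocoding error, or informative missingness.
Passing tests therefore demonstrate the statistical machinery is correct
under the assumed generating model, not that the published substantive
findings replicate.

A separate deterministic fixture builder reproduces the published
preprocessing tallies exactly (80,575 → 77,086 cases through the cascade;
24,634 → 14,663 variables through the filters; 6,416/70,670 outcome
split), with every excluded record violating exactly one rule.

## Numerical choices and simulation sizes

* GEE: tol \(10^{-8}\), max 100 iterations, working correlation clamped to
  the positive-definite range.
* MCMC defaults: 1,500 warmup + 4,000 draws, seed-deterministic;
  per-variable seeds in the Phase 2 screen are derived from the base seed.
* Tie-breaks: documented above for membership and top hits; writers sort
  rows by key for diff-stable output.
* Test-suite simulation sizes are chosen to exercise the claimed operating
  characteristics at meaningful scale while keeping the default suite
  minutes-scale: family-wise error is checked over 200 replicates of a
  200-variable null screen with ~5,000 cases; spatial-model coverage over
  50 replicates of a 30-county lattice with ~4,000 cases at reduced MCMC
  sizes (1,000 warmup + 1,200 draws); the quadrature comparison uses a
  20-observation toy where dense integration is exact to plotting accuracy.
* Correlation-block recovery tests use unequal block sizes (6/5/4): with
  equal sizes and equal \(\rho\) the leading eigenvalues are degenerate and
  the component basis within the shared eigenspace is arbitrary, so "which
  block is which component" would be unidentifiable by construction, not by
  defect.

## Known limitations

* The GEE screen assumes the marginal model; it shares sandwich small-sample
  optimism when clusters are few (not the regime here).
* The Phase 2 sampler is single-chain by default with split-half \(\hat R\);
  for publication-grade runs, raise draws until the attached diagnostics
  clear the contract.
* Alternative working correlations (AR1, unstructured), BYM2
  reparameterization, factor rotation, and any substantive interpretation
  of components are out of scope.
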