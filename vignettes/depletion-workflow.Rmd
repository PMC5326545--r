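---
title: "Depletion fishing: models, estimation choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depletion fishing: models, estimation choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deplete)
```

`deplete` estimates how much dive effort is needed to reduce an invasive
reef-fish population by a chosen percentage. This vignette is the package's
account of the science behind each stage: the models and their assumptions,
the tunable parameters and their defaults, the numerical choices, what the
simulator does and does not emulate, and the known limitations.

## 1. Standardization

Raw dive records hold total hunting minutes summed over divers and the
number of fish caught. Because sites differ in area, both are expressed per
1,000 m² of reef:

* effort `h = (diver_minutes / 60) × 1000 / area`, diver-hours per 1,000 m²;
* catch `c = catch_count × 1000 / area`, fish per 1,000 m²;
* `CPUE = c / h`, fish per diver-hour.

Using summed diver-minutes assumes divers do not change each other's
efficiency (no gain or loss from communication); this is untestable from the
catch records themselves. A dive with zero effort has no defined CPUE and is
rejected outright rather than silently dropped, so a data error surfaces at
the standardization step with the site and dive named.

Removal campaigns commonly stop after two consecutive dives with no fish
caught. `build_series()` treats the first zero of such a pair as the last
depletion dive and drops the second (a confirmation dive carrying no
additional information about the removal process); an isolated zero between
positive catches is kept. Dives are ordered by their 1-based chronological
index and the regressor for dive `t` is the cumulative catch strictly before
it, `K_0 = 0`.

## 2. The Leslie depletion regression

The Leslie model assumes a closed population (no immigration, emigration,
birth or death over the few days of removals), constant catchability across
time and individuals, and removals large enough to move CPUE. Under
proportionality `CPUE_t = q N_t` with `N_t = N_0 − K_{t−1}`, ordinary least
squares of CPUE on `K_{t−1}` estimates slope `−q` and intercept `q N_0`.

Choices a user can change:

* **`level`** (default 0.95): confidence level for all intervals.
* **`n0_ci`** (default `"delta"`): the `N_0 = intercept/q` interval either by
  the delta method on the OLS coefficient covariance, or a seeded percentile
  residual bootstrap (`boot_reps`, default 2000). The delta method is the
  default because it is deterministic and matches the symmetric intervals
  conventionally reported for Leslie fits; with 4–7 points a case bootstrap
  would be degenerate, hence residual resampling.
* **Minimum dives**: three, with at least two distinct `K` values. Two points
  fit a line exactly and would report a meaningless `r² = 1`.

A non-negative slope means no depletion signal — CPUE did not decline — and
is an explicit failure naming the site, not a fit with `q ≤ 0`. When the `q`
interval includes zero the `N_0` interval is arithmetically near-unbounded;
it is reported but flagged `N0_ci_reliable = FALSE`.

The summed standardized catch (`total_catch_estimate()`) is also exposed: it
is a hard lower bound on `N_0` (every counted fish was removed) but the
regression estimate is the canonical one; the two agree only when removal
was complete.

Residual diagnostics (Shapiro–Wilk normality; Breusch–Pagan
homoscedasticity, studentized variant by default, matching common
statistical-software defaults; the classic variant is a flag) never abort
the pipeline — they attach warnings to the per-site report. Raw residuals
are used. The cross-site regression of `q` on `N_0` asks whether
catchability is density-dependent (e.g., handling time dominating search at
high density); over a narrow density range a flat slope is weak evidence,
which is why the slope, `r²` and p-value are all reported.

## 3. The exponential removal model

Cumulative percent removed at a site, `C_obs = 100 × K_t / N̂_0`, is related
to cumulative effort through

`C = 100 (1 − exp(−(α + b_i) x)) + ε`,

with `x = q t` (catchability-scaled effort) or `x = t` (raw), site effect
`b_i ~ N(0, σ_b²)`, and `ε ~ N(0, σ²)`. `C_obs` may exceed 100 when the
regression underestimates `N_0`; it is deliberately not clipped and the
Gaussian likelihood is unconstrained, so a site that overshoots pulls the
curve rather than being censored.

Estimation choices:

* **Maximum likelihood, not REML.** The model suite varies its fixed-effect
  structure, and only ML log-likelihoods make those variants comparable by
  information criteria. Parameter counts are `K = 2` (α, σ), `K = 3`
  (α, σ_b, σ), `K = 2` (μ, σ for the null model).
* **Adaptive Gauss–Hermite quadrature** (default 15 nodes) integrates the
  site random effect: the integrand's mode is located per site, its
  curvature estimated by finite differences, and the rule centered and
  scaled there; if the curvature estimate degenerates the prior curvature
  `1/σ_b²` stands in (a Laplace-style fallback). Fifteen nodes are far more
  than needed for these near-Gaussian integrands; the cost is negligible.
* **Optimization** runs on `(α, log σ_b, log σ)` with `nlminb`, multi-started
  from 5 seeded points plus a boundary start at `σ_b → 0`, tolerance 1e−8 on
  the log-likelihood. The fixed-α initial value comes from a profile fit in
  which `σ²` is closed-form; because the curve saturates at 100, its SSE is
  flat for large α and the profile minimum is first bracketed on a log grid
  rather than trusted to a golden-section search.
* **Degenerate data** (all observations exactly on one curve) make the mixed
  likelihood unbounded as `σ → 0`; the fit then returns the boundary limit
  (`σ_b = 0`, flagged `boundary = TRUE`) instead of chasing an arbitrary
  degenerate optimum. `σ_b` estimates at the lower bound are likewise
  flagged.

AICc uses `n` = the number of site-dive observations. Model ranking reports
ΔAICc and Akaike weights `∝ exp(−ΔAICc/2)`.

## 4. The planner

`predict_removal()` evaluates `C = 100(1 − e^{−αqt})`;
`effort_for_target()` inverts it, `t = −ln(1 − target/100)/(αq)`. A target
of 100% is rejected — the curve reaches complete removal only
asymptotically. Intervals propagate the t-distribution confidence limits of
`α` (df = n − K) through these monotone maps; random-effect and residual
variability are deliberately excluded, so the band describes uncertainty in
the *mean* curve, not a prediction interval for a new site. A parametric
alternative for new-site prediction would need `σ_b` and `σ` and is out of
scope. `effort_model_from_coefficients()` lets the planner run from a
published `(α, SE, n, K)` when no local depletion data exist — useful as a
reference calculation for comparable reef systems, with the caveat that
between-system transfer is untested.

## 5. What the simulator emulates

`simulation_config()` defaults describe a small Caribbean forereef study:
7 sites of 1,148–1,800 m², initial densities 11–29 fish per 1,000 m²,
catchability 0.43–0.91 per diver-hour per 1,000 m², dives of about one
diver-hour (sd 0.25, truncated at 15 min), at most 10 dives, stopping after
two consecutive zero catches. Two noise modes:

* **expectation** — each dive removes exactly `q·h·N`: continuous fish, the
  exact generative counterpart of the Leslie line, used for
  exact-recovery tests (a removal fraction above 1 is clipped with a
  warning);
* **binomial** — whole fish, each caught with probability `1 − (1−q)^h`, so
  `q` keeps its per-unit-effort meaning. With `h = 1` the expected CPUE is
  exactly `qN`; with `h ≠ 1` the Leslie estimand is `(1 − (1−q)^h)/h`, which
  inflates toward `−ln(1−q)` as per-area effort shrinks — the simulator
  recovers `q` approximately, not exactly, mirroring real standardized
  surveys.

Fish lengths (truncated normal, mean 25.9 cm, sd 5.9, range 12–41) and
masses (generic cube-law) are attached in binomial mode purely so that the
file interface can be exercised realistically; they play no role in
estimation. When `alpha_true` is set the simulator also emits observations
drawn directly from the effort model on each site's effort grid, for
effort-model recovery tests.

What it does **not** emulate: immigration or recolonization between dives,
size- or behavior-selective catchability (fish becoming wary of divers),
diver-to-diver skill differences, and boundary effects at site edges.
Passing recovery tests therefore show the estimators are correct *under the
closed-population removal model*, not that field data satisfy that model.

Test and validation problem sizes are chosen to exercise the estimators at
the study's own scale: recovery experiments use 200 replicates (the scale at
which Monte-Carlo standard errors are a few percent of the parameters), and
calibration checks use 500 simulated sites.

## 6. Known limitations

* **The `q` confidence interval undercovers under binomial removals.** The
  cumulative-catch regressor contains the same sampling noise as earlier
  responses, which the OLS t-interval ignores; at study-like catchabilities
  (0.43–0.91) measured coverage is about 0.79 rather than 0.95 (it improves
  toward nominal as `q` falls). The `N_0` delta-method interval is close to
  nominal (measured ≈ 0.97). Users needing calibrated `q` intervals at high
  catchability should treat the reported interval as optimistic.
* Catchability is assumed constant over dives within a site; adaptive fish
  behavior would bias `N_0` upward.
* The effort model treats per-site `q` as known when scaling effort,
  ignoring its estimation error (an errors-in-variables effect shared by the
  original analysis design).
* The planner's interval reflects mean-curve uncertainty only (see §4).
* With 4–7 dives per site, all per-site inference is small-sample; the
  p-values and `r²` reported per site should be read accordingly.
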