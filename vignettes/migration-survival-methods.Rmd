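---
title: "Models and methods for upstream migration survival under climate scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for upstream migration survival under climate scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `migsurv`, the choices
made where the design was genuinely open, and what the synthetic-data
generator does and does not emulate.

## The estimation problem

Adult sockeye and spring/summer Chinook salmon are detected by PIT-tag
antennas as they pass Bonneville (BON), McNary (MCN), Ice Harbor (ICH) and
Lower Granite (LGR) dams and terminal weirs. Apparent survival through a
reach — Columbia (BON to ICH), Snake (ICH to LGR), and the free-flowing
Salmon reach (LGR to the terminal site) — is the probability of re-detection
at or above the reach exit; detection efficiency at these sites is high
enough that apparent survival is close to true survival, and the package
treats the reach outcome as a Bernoulli trial per fish.

## Covariates

* **T, F (°C, m³/s)** — daily means on the day of first detection at the
  reach-entry dam. In the Salmon reach, where entry-dam conditions poorly
  represent the free-flowing river, they are arithmetic means over a window
  starting on the entry day: 7 days for Chinook and 14 for sockeye,
  matching each species' typical residence in the warmest stretch. The
  Salmon reach draws temperature and flow from separate gauges; the
  site-to-role mapping is an argument (`salmon_roles`), not hard-coded.
* **M (degree-days)** — cumulative thermal load from Bonneville to reach
  entry, summed over dam-to-dam legs as leg duration times the mean of the
  two dams' entry-day temperatures. This is exactly the trapezoid integral
  of an exposure that interpolates linearly between dam passages (the test
  suite checks this equivalence against fine-grid quadrature). M is
  modelled as ln(M + 1): the 1 degree-day offset keeps a same-day traversal
  (M = 0) finite and is negligible at typical loads of 100–300 degree-days.
  Fish with out-of-order detections are excluded at the I/O stage rather
  than clamped, preserving the leg-sum semantics.
* **C (fish/week)** — Zone 6 fishery harvest in the week containing the
  Bonneville detection, cube-root transformed. Weeks start on Monday by
  default (`week_start_day`); multi-week reports are disaggregated
  uniformly by days (`disaggregate_catch()`).
* **Categoricals** — population group P (Chinook only), ocean age A coded
  as an unordered factor {1, 2, 3+}, juvenile history J
  (transported/in-river), origin H (hatchery/wild; not used for sockeye,
  which are a single hatchery-dominated population), and migration year y.

Missing environmental days are filled by linear interpolation for gaps of
at most `max_interp_days` (default 3; the threshold is exposed because no
authoritative cutoff exists) and otherwise by regressing the gauge on a
neighbouring gauge over shared complete days — nearby gauges on this system
correlate at r ≈ 0.96, and `regression_fill_interval()` reports prediction
intervals for filled stretches. Observed values are never altered.

## Arrival-timing models

Arrival day at Bonneville is modelled as a single Gaussian (sockeye) or a
two-component Gaussian mixture (Chinook; the components are the spring and
summer runs), with each component's annual mean linear in one annual
covariate and component standard deviations constant over years. The
candidate covariates are all monthly and bimonthly means of temperature and
flow at Bonneville during March–June (bimonthly = two consecutive calendar
months); flow metrics are expressed per 1000 m³/s so temperature and flow
coefficients have comparable magnitudes. Candidates are compared by AICc;
for the mixture, one covariate per component over all ordered pairs.

Numerical choices: the single-Gaussian MLE is computed in closed form
(least squares plus the ML variance). The mixture is maximized by BFGS on
transformed parameters (log σ, logit p) with soft (marginal-likelihood)
component membership; run labels, when available, only initialize and
label. Initialization uses year-level least squares within each labelled
group, with 10 jittered restarts by default; convergence tolerance 1e-10 on
the relative likelihood. Components are ordered by implied mean arrival day
(spring = earlier) — ordering by raw intercept would be wrong when the two
components use different covariates. The mixing weight p is pooled across
years; a per-year weight was considered and rejected as unidentifiable in
short series. The covariance comes from the numerical information matrix
at the optimum; a covariate with no variation across years is flagged and
its slope pinned (not drawn) during uncertainty propagation. σ below 1e-3
days or a failed optimizer raises an error rather than returning a
degenerate fit.

## Survival models

Per species × reach, a penalized binomial regression:
smooth thin-plate terms for T and F (basis dimension 4) and for C or M
(basis dimension 3, reflecting presumed monotone effects), categorical
terms, and year as a Gaussian random intercept implemented as a ridge
penalty on year indicators (`bs = "re"`), with smoothing parameters chosen
by REML (a GCV alternative is exposed via `sp_method`). C is considered
only in the Columbia reach, M only in Snake/Salmon; P and H are never used
for sockeye. Continuous covariates are combined only when all pairwise
correlations are below 0.7. All-survived/all-died outcomes and diverging
coefficients (|β| > 50) are rejected as separation.

Model selection fits every subset of the global terms (smooths enter or
leave whole; year is always included; the null model is intercept + year),
ranks by AICc with k equal to the model's effective degrees of freedom,
and selects the simplest model within 2 AICc of the best (ties: fewest
effective df, then lexicographic term order). A known property of this
rule, visible in the selection-consistency simulations, is an irreducible
false-inclusion rate: a pure-noise term enters the ΔAICc < 2 window
whenever its deviance gain exceeds 4, which for one spare degree of freedom
happens with probability about 0.046 regardless of sample size; with three
noise candidates the exact-recovery probability is therefore about 0.85–0.87
rather than 1. This is a property of parsimony selection itself, not of the
implementation.

Projection-mode prediction zeroes the year random effect by dropping its
basis columns from the linear predictor, and flags predictions outside the
convex hull of the observed (T, F) pairs as extrapolation. AUC is the
Mann–Whitney concordance with ties counted one half.

## Travel-time stand-in

Moving simulated fish between dams requires a travel-time model. The
behavioural model used with the real data (hourly covariates, fast/slow
movement states) is not reimplemented; `travel_model()` is a documented
stand-in: per dam-to-dam leg and species, a fast/slow log-normal mixture
whose median responds log-linearly to temperature and flow at leg entry
relative to reference conditions. Its Salmon-reach defaults are calibrated
so simulated medians (and roughly the SDs) match the observed 19 d
(Chinook) and 39 d (sockeye); hydrosystem legs are a few days each.
Durations beyond 120 d are censored to bound the simulation horizon, and
censored fish count as deaths in cumulative survival — a conservative
choice affecting well under 1% of fish at the defaults. Its structural
adequacy relative to the original behavioural model is a stated limitation.

## The projection

Each loop draws one parameter vector per model from a multivariate normal
with the fitted covariance (arrival parameters on their transformed scale,
so σ > 0 and 0 ≤ p ≤ 1 are preserved; non-positive-semidefinite covariances
error, with an opt-in eigenvalue-clip repair). Each simulated year then:
(1) draws arrival days from the arrival model using that scenario-year's
annual covariates; (2) bootstraps one observation-year's catch, transport
rate, hatchery proportion and ocean-age mix — a bootstrap over years was
chosen to honour "interannual variability" without asserting a parametric
form; (3) simulates passage dates; (4) draws per-reach Bernoulli outcomes
with the year effect zeroed. Cumulative survival is the product of reach
indicators per fish. RNG streams are seeded hierarchically (master seed →
loop → scenario → species → year), so any cell is independently
reproducible and sensitivity grids can reuse the base run's seeds as common
random numbers — differences between grid points are then the signal, not
Monte-Carlo noise. Chinook are summarized as aggregate plus spring/summer
components.

Sensitivity operators: arrival days shifted earlier by 3–14 d; constant
temperature deltas of −0.8 to +2 °C added to scenario series; flow factors
0–1.4 applied to the daily scenario-minus-historical flow change with a
10 m³/s floor (factor 0 reproduces the historical series, 1 the scenario).
The exceedance analysis computes annual means of temperature and flow
within each species' run window (5th–95th percentile of observed
reach-entry day-of-year), fits a skew-normal per scenario (ML with a
method-of-moments start; a flagged moments fallback on optimizer failure;
the CDF uses Owen's T function by quadrature, reducing exactly to the
normal at shape 0), and reports both the empirical and fitted-tail
frequency of years at least as warm (temperature) or at least as dry
(flow) as the reference year — the intended reading of "as extreme as".

## The synthetic-data generator

The generator is the package's test bed: it emulates the statistical
structure the analysis assumes, with every truth recorded.

* **Environment** — per site, temperature is an annual sinusoid (means
  10.5–11.5 °C, amplitudes 9–11 °C, late-July peak, warmer summers moving
  upstream) plus centred annual offsets (SD 0.7 °C), centred
  month-specific anomalies (SD 0.8 °C, interpolated between month
  midpoints — these give each monthly covariate metric distinct
  interannual variation, without which all spring metrics would be nearly
  collinear), and daily noise (SD 0.6 °C). Flow is a baseflow plus a
  Gaussian spring-freshet pulse with a log-normal annual multiplier
  (log-SD 0.25) and daily noise. Scenario deltas share the noise
  realization, so zero deltas reproduce the historical series exactly:
  warming is summer-peaked and grows upstream (1.3–1.7 °C at Bonneville to
  2.6–3.4 °C in the Salmon reach between dry and wet), the freshet shifts
  12 d earlier and rescales, and summer baseflow drops. Centring the
  interannual effects makes long-run means equal the seasonal curves, so
  the cohort calibrations below are stable across seeds. One year (2015
  when in range) is pinned at +2 SD run-window temperature and −2 SD flow
  as the labelled extreme year.
* **Cohort** — composition follows the observation dataset: transported
  33% (Chinook) / 38% (sockeye), hatchery 74% / 99%, ocean-age-2 66% /
  89%, with small centred annual jitter. Arrival truth: sockeye
  −1.36 d/°C on April temperature (σ = 8 d around day ~183); Chinook a
  45:55 spring:summer mixture with −3.06 d/°C on April temperature and
  +0.02 d per 1000 m³/s April flow (σ = 8, 10 d). The printed flow unit
  for that slope (km³/s) would make the effect indistinguishable from zero
  at Columbia-scale flows, so the generator uses the 1000 m³/s reading.
* **Survival truth** — logistic, piecewise linear in the logit with a
  15 °C breakpoint and a steeper negative slope above it (an interpretable
  stand-in for a spline truth, since the reported feature is the
  threshold, not a functional form), reach-specific flow effects (negative
  freshet effect for Chinook in the Columbia, +0.9 per 200 m³/s for
  sockeye in the Salmon reach), negative log-M, catch and transport
  effects (sockeye transport −1.30 on the logit, calibrated so marginal
  Columbia survival is 0.30 transported vs 0.59 in-river), and a hatchery
  deficit. Intercepts were calibrated once, by simulation, to the observed
  per-reach survival rates and then frozen.

What the generator does **not** emulate: spatial correlation beyond the
configured upstream gradient, hydrologic routing (flows at adjacent sites
are generated, not routed), autocorrelated daily weather beyond the monthly
anomalies, fallback/re-ascension at dams, evolutionary change in run
timing, and detection failure (detection is perfect by construction).
Passing tests therefore demonstrate that the estimators recover the stated
structure when it holds — not that real data satisfy it.

## Problem sizes and tolerances in the test suite

The suite exercises cohorts of ~10,000 fish over 12 years (seconds to
generate), arrival recovery at 12 years × 2,000 fish, survival recovery at
n ≈ 6,000–10,000, selection-consistency simulations of 50–100 replicates at
n = 1,000–3,000, and projections of tens of thousands of fish — sizes at
which parameter-recovery checks are sharp while the full suite completes in
a few minutes. Stochastic assertions use binomial or CLT-scale tolerances
at fixed seeds; exact operators (flow factors, degree-day legs, AICc, AUC)
are checked against independent oracles (fine-grid quadrature, O(n²) pair
enumeration, closed forms) to near machine precision.

## Known limitations

Apparent survival conflates mortality with permanent cessation of upstream
movement; the travel-time stand-in is structural, not behavioural; the
year random effect absorbs, but cannot attribute, shared annual drivers
such as ocean condition carryover; and parsimony selection carries the
false-inclusion rate derived above. Projections inherit all of these, plus
the assumption that fitted covariate relationships extrapolate to scenario
conditions — predictions outside the observed (T, F) hull are flagged for
exactly this reason.
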