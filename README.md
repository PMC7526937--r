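# migsurv

Adult sockeye and spring/summer Chinook salmon returning to the Snake River
Basin migrate up to 1,450 km through eight dams, during the hottest part of
the year. `migsurv` is an R package for quantifying how river temperature,
flow, cumulative thermal exposure and anthropogenic factors (juvenile
barge/truck transportation, hatchery origin, fishery catch) shape their
upstream-migration survival — and for projecting that survival under
climate scenarios. It is aimed at quantitative fisheries ecologists working
with PIT-tag detection histories and daily gauge records.

## What it does

The workflow has five stages, each exposed as ordinary R functions:

1. **Covariates** — per-fish, per-reach design variables: entry-day
   temperature *T* and flow *F* (windowed means in the free-flowing Salmon
   reach), cumulative thermal load in degree-days accumulated between dams,

   *M*<sub>Snake</sub> = D₁·(T₍BON₎+T₍MCN₎)/2 + D₂·(T₍MCN₎+T₍ICH₎)/2,
   *M*<sub>Salmon</sub> = *M*<sub>Snake</sub> + D₃·(T₍ICH₎+T₍LGR₎)/2,

   and weekly fishery catch *C* aligned to the Bonneville passage week
   (modelled as ln(*M*+1) and *C*^⅓).
2. **Arrival timing** — maximum-likelihood models of arrival day at the
   first dam: a single Gaussian for sockeye, a two-component mixture for
   Chinook, Pr(x|θ) = Σₖ wₖ g(x|θₖ), with each component mean linear in an
   annual spring covariate, μₖₜ = β0ₖ + β1ₖ Eₖₜ, selected by AICc over all
   monthly/bimonthly March–June temperature and flow metrics
   (`fit_arrival()`, `select_arrival_model()`).
3. **Survival** — binomial spline models per species × reach,
   S ~ s(T) + s(F) + s(C) or s(M) + P + A + J + H + (year), thin-plate
   smoothers (basis dimension 4 for T and F, 3 for C and M), year as a
   Gaussian random intercept, a pairwise-correlation (< 0.7) collinearity
   screen, all-subsets AICc selection with the simplest-ΔAICc<2 rule, and
   AUC goodness of fit (`fit_survival()`, `dredge_select()`).
4. **Projection** — a Monte-Carlo simulator that, per loop, draws model
   parameters from the fitted covariances, then simulates arrival → travel
   (fast/slow log-normal mixture per dam-to-dam leg) → per-reach Bernoulli
   survival with the year effect zeroed, over years × scenarios
   (`run_projection()`; the published design is 100 fish × 70 years ×
   3 scenarios × 200 loops × 2 species = 8.4 million fish).
5. **Sensitivity & exceedance** — arrival-day shifts, additive temperature
   deltas, flow factors F₍t,s,x₎ = F₍t,hist₎ + ΔF₍t,s₎·Fx with a 10 m³/s
   floor (`run_sensitivity_grid()`), and run-window exceedance frequencies
   with skew-normal fits (`compare_scenarios()`).

A first-class synthetic-data generator (`make_env_scenarios()`,
`make_cohort()`) reproduces the statistical structure of the observation
data — bimodal Chinook and unimodal sockeye arrivals, seasonal temperature
curves and a spring freshet with scenario deltas, the observed cohort
composition, and logistic survival surfaces declining above 15 °C — with
all truths recorded, so every stage is testable end to end without access
to tag databases or gauge records.

## Worked example

```r
library(migsurv)

cfg    <- generator_config(seed = 1)          # 12 years, 2004-2015
env    <- make_env_scenarios(cfg)             # historical / dry / wet, 5 sites
catch  <- make_catch_series(cfg)
coh    <- make_cohort(cfg, env$historical, catch,
                      n_per_year = 500, species = "sockeye")

covs    <- annual_covariates(env$historical$BON)
days    <- as.integer(format(coh$date_BON, "%j"))
arrival <- fit_arrival(days, coh$migration_year, covs,
                       spec = "temp_Apr", k = 1)
arrival
#> <arrival_model> 1 component(s), n = 6000, AICc = 42045.36
#>   covariate(s): temp_Apr
#>       b0       b1    sigma        p
#> 194.4898  -1.2714   8.0393   1.0000
```

The fitted slope says sockeye arrive about 1.3 d earlier per °C of April
warmth at Bonneville (the generating value is −1.36); `sigma` is the
within-year spread in days.

```r
design <- attr(coh, "design")
m <- fit_survival(design[design$reach == "Columbia", ],
                  smooth_terms = c("T", "C"), factor_terms = c("A", "J"))
m
#> <survival_model> sockeye / Columbia reach, n = 6000
#>   terms: s(T) + s(C) + A + J + y
#>   edf = 15.1, AICc = 7566.18, AUC = 0.702
```

With per-reach models in hand, a small projection (5 loops here; raise to
the full design for production runs):

```r
models <- list(sockeye = list(arrival = arrival, survival = fits,
                              travel = travel_model("sockeye"),
                              obs_annual = empirical_annual(coh, catch)))
run <- run_projection(simulation_config(n_fish = 100, n_loops = 5,
                                        n_years = 12, species = "sockeye",
                                        seed = 1),
                      models, env)
run
#>  species   scenario   mean     sd pct_change
#>  sockeye        dry 0.0510 0.0382      -77.5
#>  sockeye historical 0.2272 0.0980         NA
#>  sockeye        wet 0.0328 0.0258      -85.5
```

`mean` is mean annual cumulative survival (Bonneville to the terminal
site); `pct_change` compares each future scenario with the historical one —
here projected sockeye survival collapses by roughly 80% under both
scenarios, driven by summer warming interacting with the steep decline in
survival above 15 °C.

`run_pipeline(pipeline_config())` runs all five stages end to end and
writes every artifact (fish and environment CSVs, model summaries,
projection and sensitivity tables, provenance JSON) to a directory.

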