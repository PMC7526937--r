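# Shared fixtures, generated once per test session and cached.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- make()
  .fx_cache[[name]]
}

gen_fixture <- function() fixture("gen", function() {
  cfg <- generator_config(seed = 1)
  list(cfg = cfg,
       env = make_env_scenarios(cfg),
       catch = make_catch_series(cfg))
})

sockeye_cohort <- function() fixture("sockeye", function() {
  g <- gen_fixture()
  make_cohort(g$cfg, g$env$historical, g$catch, n_per_year = 840,
              species = "sockeye", seed = 42)
})

chinook_cohort <- function() fixture("chinook", function() {
  g <- gen_fixture()
  make_cohort(g$cfg, g$env$historical, g$catch, n_per_year = 420,
              species = "chinook", seed = 42)
})

# a small fitted model set for projection tests (sockeye only)
sockeye_models <- function() fixture("sockeye_models", function() {
  g <- gen_fixture()
  coh <- sockeye_cohort()
  design <- attr(coh, "design")
  fits <- list()
  for (rn in c("Columbia", "Snake", "Salmon")) {
    d <- design[design$reach == rn, ]
    sm <- if (rn == "Columbia") c("T", "C") else c("T", "F", "M")
    fits[[rn]] <- fit_survival(d, smooth_terms = sm, factor_terms = c("A", "J"),
                               species = "sockeye", reach = rn)
  }
  covs <- annual_covariates(g$env$historical$BON)
  days <- as.integer(format(coh$date_BON, "%j"))
  arrival <- fit_arrival(days, coh$migration_year, covs, spec = "temp_Apr", k = 1)
  list(arrival = arrival, survival = fits, travel = travel_model("sockeye"),
       obs_annual = empirical_annual(coh, g$catch))
})

# brute-force O(n^2) AUC oracle (ties count one half)
auc_bruteforce <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
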