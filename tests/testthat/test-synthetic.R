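test_that("generation is fully deterministic under a fixed seed", {
  cfg <- generator_config(seed = 33, years = 4)
  e1 <- make_env_scenarios(cfg); e2 <- make_env_scenarios(cfg)
  expect_identical(e1, e2)
  c1 <- make_catch_series(cfg); c2 <- make_catch_series(cfg)
  expect_identical(c1, c2)
  f1 <- make_cohort(cfg, e1$historical, c1, n_per_year = 60, species = "sockeye")
  f2 <- make_cohort(cfg, e2$historical, c2, n_per_year = 60, species = "sockeye")
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("zero scenario deltas collapse the scenarios onto historical", {
  cfg <- generator_config(seed = 5, years = 3)
  cfg$temp_delta$dry[] <- 0
  cfg$flow_scenario$dry <- c(peak_shift = 0, peak_factor = 1, summer_factor = 1)
  env <- make_env_scenarios(cfg)
  expect_equal(env$dry$BON$temperature, env$historical$BON$temperature)
  expect_equal(env$dry$BON$flow, env$historical$BON$flow)
})

test_that("scenario deltas are summer-peaked and grow upstream", {
  g <- gen_fixture()
  summer <- function(env) {
    doy <- as.integer(format(env$date, "%j"))
    mean(env$temperature[doy >= 170 & doy <= 240])
  }
  winter <- function(env) {
    doy <- as.integer(format(env$date, "%j"))
    mean(env$temperature[doy <= 60])
  }
  d_bon <- summer(g$env$dry$BON) - summer(g$env$historical$BON)
  d_sal <- summer(g$env$dry$SALMON) - summer(g$env$historical$SALMON)
  expect_gt(d_sal, d_bon)                     # warming grows upstream
  expect_gt(d_bon, winter(g$env$dry$BON) - winter(g$env$historical$BON))
  # configured summer offset is realized at the BON gauge
  expect_equal(d_bon, mean(c(1.3 * 1, 1.3 * 0.5)), tolerance = 0.35)
  # summer flows decline in both future scenarios
  sflow <- function(env) {
    doy <- as.integer(format(env$date, "%j"))
    mean(env$flow[doy >= 180 & doy <= 260])
  }
  expect_lt(sflow(g$env$dry$SALMON), sflow(g$env$historical$SALMON))
  expect_lt(sflow(g$env$wet$SALMON), sflow(g$env$historical$SALMON))
})

test_that("high summer flows and high temperatures do not co-occur", {
  g <- gen_fixture()
  env <- g$env$historical$SALMON
  win <- structure(list(start = 160L, end = 250L), class = "run_window")
  am <- annual_window_means(env, win)
  expect_lt(cor(am$mean_temp, am$mean_flow), 0)
})

test_that("the extreme year is the warmest, driest run-window year", {
  g <- gen_fixture()
  win <- structure(list(start = 170L, end = 220L), class = "run_window")
  am <- annual_window_means(g$env$historical$BON, win)
  ex <- g$cfg$extreme_year
  expect_equal(ex, 2015L)
  z_t <- (am$mean_temp - mean(am$mean_temp)) / sd(am$mean_temp)
  z_f <- (am$mean_flow - mean(am$mean_flow)) / sd(am$mean_flow)
  expect_equal(am$year[which.max(am$mean_temp)], ex)  # warmest window
  expect_gt(z_t[am$year == ex], 1.5)
  expect_lte(rank(am$mean_flow)[am$year == ex], 2)    # among the driest
  expect_lt(z_f[am$year == ex], -1)
})

test_that("cohort composition matches the observation dataset's rates", {
  coh <- sockeye_cohort()
  expect_equal(mean(coh$juv_history == "transported"), 0.38, tolerance = 0.015)
  expect_equal(mean(coh$origin == "hatchery"), 0.99, tolerance = 0.01)
  expect_equal(mean(coh$ocean_age == 2), 0.89, tolerance = 0.02)
  chc <- chinook_cohort()
  expect_equal(mean(chc$juv_history == "transported"), 0.33, tolerance = 0.02)
  expect_equal(mean(chc$origin == "hatchery"), 0.74, tolerance = 0.02)
  expect_equal(mean(chc$ocean_age == 2), 0.66, tolerance = 0.02)
})

test_that("chinook arrivals are bimodal; sockeye unimodal", {
  chc <- chinook_cohort()
  days <- as.integer(format(chc$date_BON, "%j"))
  g <- gen_fixture()
  covs <- annual_covariates(g$env$historical$BON)
  m1 <- fit_arrival(days, chc$migration_year, covs, spec = "temp_Apr", k = 1)
  m2 <- fit_arrival(days, chc$migration_year, covs,
                    spec = c("temp_Apr", "flow_Apr"), k = 2, run = chc$run,
                    n_restarts = 2)
  expect_lt(m2$aicc, m1$aicc)      # mixture preferred: bimodal
  # the two fitted modes are well separated (mid-May vs early June peaks)
  mu <- predict(m2, type = "mean")
  expect_gt(mean(mu[, 2]) - mean(mu[, 1]), 10)
})

test_that("zeroed effect sizes reduce survival to the intercept logistic", {
  cfg <- generator_config(seed = 9, years = 4)
  for (sp in names(cfg$survival_truth))
    for (rn in names(cfg$survival_truth[[sp]])) {
      cf <- cfg$survival_truth[[sp]][[rn]]
      cf[c("bT_lo", "bT_hi", "bF", "bM", "bC", "bJ", "bH", "bA1", "bA3")] <- 0
      cfg$survival_truth[[sp]][[rn]] <- cf
    }
  env <- make_env_scenarios(cfg)
  catch <- make_catch_series(cfg)
  coh <- make_cohort(cfg, env$historical, catch, n_per_year = 1500,
                     species = "sockeye")
  p0 <- plogis(cfg$survival_truth$sockeye$Columbia["b0"])
  for (grp in c("transported", "in_river")) {
    sel <- coh$juv_history == grp
    expect_equal(mean(coh$surv_columbia[sel] == "survived"), unname(p0),
                 tolerance = 0.03)
  }
})

test_that("Bayes AUC matches enumeration and its degenerate limits", {
  set.seed(14)
  p <- runif(200); y <- rbinom(200, 1, p)
  expect_equal(bayes_auc(p, y), auc_bruteforce(p, y))
  # zero effects: no discrimination
  p0 <- rep(0.6, 500); y0 <- rbinom(500, 1, p0)
  expect_equal(bayes_auc(p0 + runif(500, -1e-9, 1e-9), y0), 0.5,
               tolerance = 0.05)
  # deterministic truth: perfect discrimination
  pd <- rep(c(0, 1), each = 50); yd <- pd
  expect_equal(bayes_auc(pd, yd), 1)
})

test_that("empirical annual table tracks per-year composition", {
  g <- gen_fixture()
  coh <- sockeye_cohort()
  oa <- empirical_annual(coh, g$catch)
  expect_equal(nrow(oa), 12)
  expect_true(all(abs(oa$transport_rate - 0.38) < 0.12))
  expect_true(all(oa$p_age1 + oa$p_age2 + oa$p_age3 > 0.999))
  expect_true(all(oa$mean_catch > 0))
})
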