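test_that("the default projection design enumerates 8.4 million fish", {
  expect_equal(n_simulated_fish(simulation_config()), 8.4e6)
  expect_equal(n_simulated_fish(simulation_config(n_fish = 10, n_loops = 1,
                                                  n_years = 1,
                                                  scenarios = "historical",
                                                  species = "sockeye")), 10)
  expect_error(simulation_config(n_loops = 0), ">= 1")
})

test_that("parameter draws honour the covariance and the seed contract", {
  mods <- sockeye_models()
  # zero covariance -> the point estimate
  a0 <- mods$arrival; a0$vcov <- diag(0, length(a0$par))
  m0 <- mods$survival$Snake
  m0v <- m0; m0v$fit$Vp <- m0$fit$Vp * 0
  d0 <- draw_parameter_set(a0, list(Snake = m0v), seed = 5)
  expect_equal(d0$arrival$par, a0$par)
  expect_equal(d0$betas$Snake, coef(m0), tolerance = 1e-12)
  # same seed -> identical draw; different seed -> different
  d1 <- draw_parameter_set(mods$arrival, mods$survival["Snake"], seed = 7)
  d2 <- draw_parameter_set(mods$arrival, mods$survival["Snake"], seed = 7)
  d3 <- draw_parameter_set(mods$arrival, mods$survival["Snake"], seed = 8)
  expect_identical(d1$arrival$par, d2$arrival$par)
  expect_identical(d1$betas, d2$betas)
  expect_false(identical(d1$betas, d3$betas))
  # sample covariance of many draws matches the input within MC error
  set.seed(9)
  draws <- t(replicate(4000, MASS::mvrnorm(1, mods$arrival$par,
                                           mods$arrival$vcov)))
  expect_equal(cov(draws), mods$arrival$vcov, tolerance = 0.1)
  # non-PSD covariance: error, or repaired when asked
  abad <- mods$arrival
  abad$vcov <- diag(c(1, 1, -0.5))
  expect_error(draw_parameter_set(abad, list(), seed = 1), "positive semidefinite")
  expect_message(draw_parameter_set(abad, list(), seed = 1, repair = TRUE),
                 "repair")
})

test_that("cohort survival follows the product law over reaches", {
  g <- gen_fixture()
  mods <- sockeye_models()
  force_beta <- function(m, value) {
    b <- coef(m); b[] <- 0; b[1] <- value; b
  }
  betas1 <- lapply(mods$survival, force_beta, value = 30)   # p ~ 1
  set.seed(41)
  coh1 <- simulate_cohort(2010, g$env$historical, "sockeye", mods$arrival,
                          mods$survival, mods$travel, mods$obs_annual,
                          n_fish = 300, betas = betas1)
  expect_true(all(coh1$cumulative[!coh1$censored] == 1))
  # p = 0.5 per reach, independent -> cumulative ~ 0.125
  betas5 <- lapply(mods$survival, force_beta, value = 0)
  set.seed(42)
  coh5 <- simulate_cohort(2010, g$env$historical, "sockeye", mods$arrival,
                          mods$survival, mods$travel, mods$obs_annual,
                          n_fish = 10000, betas = betas5)
  expect_lt(abs(mean(coh5$cumulative) - 0.125), 0.012)
  # cumulative equals the product of the reach indicators, exactly
  prod_law <- with(coh5, as.integer(
    !is.na(S_Columbia) & S_Columbia == 1 & !is.na(S_Snake) & S_Snake == 1 &
      !is.na(S_Salmon) & S_Salmon == 1))
  expect_identical(coh5$cumulative, prod_law)
})

test_that("projections are deterministic and summarize percent change", {
  g <- gen_fixture()
  mods <- sockeye_models()
  cfg <- simulation_config(n_fish = 30, n_loops = 2, n_years = 4,
                           scenarios = c("historical", "dry"),
                           species = "sockeye", seed = 3)
  run1 <- run_projection(cfg, list(sockeye = mods), g$env)
  run2 <- run_projection(cfg, list(sockeye = mods), g$env)
  expect_identical(run1$summary, run2$summary)
  expect_equal(nrow(run1$annual), 2 * 2 * 4)  # loops x scenarios x years
  # percent-change column is the documented arithmetic
  s <- run1$summary
  for (i in which(s$scenario == "dry")) {
    h <- s$mean[s$scenario == "historical" & s$reach == s$reach[i] &
                  s$component == s$component[i]]
    expect_equal(s$pct_change[i], 100 * (s$mean[i] - h) / h, tolerance = 1e-12)
  }
  expect_true(all(is.na(s$pct_change[s$scenario == "historical"])))
})

test_that("identical scenario series yield exchangeable summaries", {
  g <- gen_fixture()
  mods <- sockeye_models()
  env_same <- list(historical = g$env$historical, dry = g$env$historical,
                   wet = g$env$historical)
  cfg <- simulation_config(n_fish = 60, n_loops = 3, n_years = 8,
                           species = "sockeye", seed = 11)
  run <- run_projection(cfg, list(sockeye = mods), env_same,
                        draw_parameters = FALSE)
  cum <- run$summary[run$summary$reach == "cumulative", ]
  expect_lt(max(cum$mean) - min(cum$mean), 0.06)  # Monte-Carlo noise only
})
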