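test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-5, 2, 10), 14 + 12 / 7)
  # correction vanishes as n grows: AICc -> AIC
  expect_equal(aicc(-100, 5, 1e9), -2 * -100 + 2 * 5, tolerance = 1e-6)
  expect_error(aicc(-5, 9, 10), "n must exceed")
  # independent recomputation on random tuples
  set.seed(1)
  for (i in 1:20) {
    ll <- rnorm(1, -50, 20); k <- sample(1:6, 1); n <- sample(20:200, 1)
    ref <- -2 * ll + 2 * k * n / (n - k - 1)  # textbook equivalent form
    expect_equal(aicc(ll, k, n), ref, tolerance = 1e-12)
  }
})

test_that("annual covariates cover all monthly and bimonthly metrics", {
  g <- gen_fixture()
  covs <- annual_covariates(g$env$historical$BON)
  expect_equal(nrow(covs), 12)
  expect_setequal(setdiff(names(covs), "year"),
                  c(t(outer(c("temp_", "flow_"),
                            c("Mar", "Apr", "May", "Jun",
                              "MarApr", "AprMay", "MayJun"), paste0))))
  # bimonthly = mean over the two constituent months (weighted by days)
  env <- g$env$historical$BON
  mo <- as.integer(format(env$date, "%m"))
  yr <- as.integer(format(env$date, "%Y"))
  expect_equal(covs$temp_MarApr[1],
               mean(env$temperature[yr == covs$year[1] & mo %in% 3:4]))
})

test_that("single-Gaussian fit recovers a no-covariate year and flags b1", {
  set.seed(2)
  days <- rnorm(500, 160, 5)
  covs <- data.frame(year = 2010, temp_Apr = 9.0)
  m <- fit_arrival(days, rep(2010, 500), covs, spec = "temp_Apr", k = 1)
  expect_false(m$identifiable[["b1"]])
  expect_equal(unname(coef(m)["b0"]), 160, tolerance = 0.8)
  expect_equal(unname(coef(m)["sigma"]), 5, tolerance = 0.5)
})

test_that("two-component mixture recovers truth within confidence limits", {
  g <- gen_fixture()
  covs <- annual_covariates(g$env$historical$BON)
  truth <- true_arrival_model("chinook", g$cfg, covs)
  truth$par["qlogis_p"] <- qlogis(0.4)
  set.seed(101)
  arr <- simulate(truth, nsim = 2000, newdata = covs)
  m <- fit_arrival(arr$day, arr$year, covs, spec = c("temp_Apr", "flow_Apr"),
                   k = 2, run = arr$component, n_restarts = 2)
  cf <- coef(m); V <- vcov(m); se <- sqrt(pmax(diag(V), 0))
  expect_equal(unname(cf["p"]), 0.4, tolerance = 0.08)
  expect_equal(unname(cf["sigma_spring"]), 8, tolerance = 0.5)
  expect_equal(unname(cf["sigma_summer"]), 10, tolerance = 0.5)
  ci <- cf["b1_spring"] + c(-1.96, 1.96) * se["b1_spring"]
  expect_gt(-3.06, ci[1]); expect_lt(-3.06, ci[2])
  # component labels ordered: spring implies the earlier mean
  mu <- predict(m, type = "mean")
  expect_true(mean(mu[, 1]) < mean(mu[, 2]))
  # selected-model log-likelihood beats the nested no-slope special case
  m0 <- fit_arrival(arr$day, arr$year,
                    transform(covs, const = 1), spec = c("const", "const"),
                    k = 2, run = arr$component, n_restarts = 2)
  expect_gt(m$logLik, m0$logLik)
})

test_that("mixture density integrates to one", {
  g <- gen_fixture()
  covs <- annual_covariates(g$env$historical$BON)
  m <- true_arrival_model("chinook", g$cfg, covs)
  dens <- predict(m, type = "density", grid = seq(40, 320, by = 0.1))
  area <- sum(dens$density) * 0.1
  expect_equal(area, 1, tolerance = 1e-6)
})

test_that("simulated arrivals obey the model's moments and linearity", {
  covs <- data.frame(year = 2010, temp_Apr = 9)
  m <- structure(list(k = 1, par = c(b0 = 195.5, b1 = -1.36,
                                     lsigma = log(8)),
                      vcov = diag(1e-12, 3), logLik = NA, aicc = NA, n = 0,
                      n_params = 3, spec = "temp_Apr",
                      identifiable = c(b1 = TRUE), years = 2010,
                      covariates = covs), class = "arrival_model")
  mu <- 195.5 - 1.36 * 9
  set.seed(5)
  d <- simulate(m, nsim = 1e5, newdata = covs)
  expect_equal(mean(d$day), mu, tolerance = 3 * 8 / sqrt(1e5))
  # covariate +1 shifts the mean by b1
  d2 <- simulate(m, nsim = 1e5, seed = 5,
                 newdata = data.frame(year = 2010, temp_Apr = 10))
  expect_equal(mean(d2$day) - mean(d$day), -1.36, tolerance = 0.15)
  # sigma -> 0 collapses to the mean
  m0 <- m; m0$par["lsigma"] <- log(1e-12)
  d0 <- simulate(m0, nsim = 50, newdata = covs)
  expect_true(all(abs(d0$day - mu) < 1e-9))
})

test_that("covariate selection finds the generating metric", {
  g <- gen_fixture()
  covs <- annual_covariates(g$env$historical$BON)
  truth <- true_arrival_model("sockeye", g$cfg, covs)
  # single candidate -> returned
  set.seed(11)
  arr1 <- simulate(truth, nsim = 200, newdata = covs)
  s1 <- select_arrival_model(arr1$day, arr1$year, covs, k = 1,
                             candidates = "temp_Apr")
  expect_equal(s1$spec, "temp_Apr")
  # duplicated candidate columns: deterministic first-candidate tie-break
  covs2 <- covs; covs2$temp_Apr2 <- covs2$temp_Apr
  s2 <- select_arrival_model(arr1$day, arr1$year, covs2, k = 1,
                             candidates = c("temp_Apr", "temp_Apr2"))
  expect_equal(s2$spec, "temp_Apr")
  # selection consistency: the generating covariate wins in >= 95% of
  # replicates against the full candidate set
  wins <- 0L
  for (r in 1:100) {
    set.seed(1000 + r)
    arr <- simulate(truth, nsim = 1000, newdata = covs)
    s <- select_arrival_model(arr$day, arr$year, covs, k = 1)
    wins <- wins + (s$spec == "temp_Apr")
  }
  expect_gte(wins, 95)
})

test_that("refit model reproduces arrival-day quantiles on clean data", {
  g <- gen_fixture()
  covs <- annual_covariates(g$env$historical$BON)
  truth <- true_arrival_model("sockeye", g$cfg, covs)
  set.seed(21)
  arr <- simulate(truth, nsim = 800, newdata = covs)
  m <- fit_arrival(arr$day, arr$year, covs, spec = "temp_Apr", k = 1)
  expect_gte(arrival_qq_correlation(m, arr$day, arr$year), 0.97)
})
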