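make_const_env <- function(temp, flow = 100, site = "BON", n = 400,
                           start = "2010-01-01") {
  dates <- seq(as.Date(start), by = "day", length.out = n)
  env_series(dates, rep(temp, n), rep(flow, n), site = site)
}

test_that("reach-entry conditions use entry-day values and species windows", {
  env <- make_const_env(15)
  r1 <- reach_def("Columbia", "BON", "ICH", 1L)
  expect_equal(reach_conditions(as.Date("2010-06-01"), env, env, r1)[["T"]], 15)

  # sockeye Salmon reach: 14-day mean of 7 days at 10 then 7 at 20 -> 15
  dates <- seq(as.Date("2010-06-01"), by = "day", length.out = 14)
  env2 <- env_series(dates, c(rep(10, 7), rep(20, 7)), rep(100, 14), "SALMON")
  r14 <- reach_def("Salmon", "LGR", "TERM", 14L)
  expect_equal(reach_conditions(dates[1], env2, env2, r14)[["T"]], 15)

  # chinook Salmon reach: mean of 7 linearly rising values 10..16 -> 13
  dates7 <- seq(as.Date("2010-06-01"), by = "day", length.out = 7)
  env3 <- env_series(dates7, seq(10, 16, by = 1), rep(100, 7), "SALMON")
  r7 <- reach_def("Salmon", "LGR", "TERM", 7L)
  expect_equal(reach_conditions(dates7[1], env3, env3, r7)[["T"]], 13)

  # window exceeding coverage -> error
  expect_error(reach_conditions(dates7[5], env3, env3, r7), "cover")

  # translation equivariance: adding delta to every day adds delta to T
  env4 <- env3; env4$temperature <- env3$temperature + 2.5
  expect_equal(reach_conditions(dates7[1], env4, env4, r7)[["T"]], 15.5)
})

test_that("cumulative thermal load follows the leg-trapezoid formula", {
  d0 <- as.Date("2010-06-01")
  mk <- function(site, temp) make_const_env(temp, site = site,
                                            start = "2010-05-01", n = 60)
  env_list <- list(BON = mk("BON", 12), MCN = mk("MCN", 14),
                   ICH = mk("ICH", 16), LGR = mk("LGR", 18))
  dates <- list(BON = d0, MCN = d0 + 2, ICH = d0 + 3, LGR = d0 + 3)
  # D1=2, D2=1: M = 2*(12+14)/2 + 1*(14+16)/2 = 41 degree-days
  expect_equal(cumulative_temp(dates, env_list, "Snake"), 41)
  # D3 = 0: Salmon load equals Snake load
  expect_equal(cumulative_temp(dates, env_list, "Salmon"), 41)
  # missing intermediate detection -> error
  expect_error(cumulative_temp(list(BON = d0, MCN = NA, ICH = d0 + 3),
                               env_list, "Snake"), "MCN")
  expect_error(cumulative_temp(list(BON = d0 + 5, MCN = d0, ICH = d0 + 6),
                               env_list, "Snake"), "out-of-order")
})

test_that("leg formula equals a day-by-day trapezoid oracle", {
  # oracle: integrate the linear interpolation of temperature between
  # dam-passage snapshots on a fine grid
  set.seed(3)
  g <- gen_fixture()
  env_list <- g$env$historical
  for (rep in 1:20) {
    d0 <- as.Date("2010-05-01") + sample(0:60, 1)
    D <- sample(0:9, 3, replace = TRUE)
    dates <- list(BON = d0, MCN = d0 + D[1], ICH = d0 + D[1] + D[2],
                  LGR = d0 + D[1] + D[2] + D[3])
    temps <- c(env_list$BON$temperature[match(dates$BON, env_list$BON$date)],
               env_list$MCN$temperature[match(dates$MCN, env_list$MCN$date)],
               env_list$ICH$temperature[match(dates$ICH, env_list$ICH$date)],
               env_list$LGR$temperature[match(dates$LGR, env_list$LGR$date)])
    # fine-grid quadrature of each leg's linearly interpolated exposure
    leg_integral <- function(D, T1, T2) {
      if (D == 0) return(0)
      grid <- seq(0, D, length.out = 2001)
      vals <- T1 + (T2 - T1) * grid / D
      sum((vals[-1] + vals[-length(vals)]) / 2) * (grid[2] - grid[1])
    }
    oracle <- function(upto) {
      sum(vapply(seq_len(upto - 1), function(l)
        leg_integral(D[l], temps[l], temps[l + 1]), numeric(1)))
    }
    expect_equal(cumulative_temp(dates, env_list, "Snake"), oracle(3),
                 tolerance = 1e-6)
    expect_equal(cumulative_temp(dates, env_list, "Salmon"), oracle(4),
                 tolerance = 1e-6)
  }
})

test_that("catch aligns to the Bonneville passage week", {
  cs <- catch_series(seq(as.Date("2010-05-03"), by = "week", length.out = 6),
                     c(50, 125, 300, 80, 60, 40))
  expect_equal(align_catch(as.Date("2010-05-12"), cs), 125)
  # week-boundary day goes to the week containing it under the convention
  expect_equal(align_catch(as.Date("2010-05-10"), cs), 125)  # Monday
  expect_equal(align_catch(as.Date("2010-05-16"), cs), 125)  # Sunday
  expect_error(align_catch(as.Date("2011-01-01"), cs), "cover")
})

test_that("modelling transforms are exact and guard domains", {
  expect_equal(transform_C(27), 3)
  expect_equal(transform_C(0), 0)
  expect_equal(transform_M(41, m0 = 1), log(42))
  expect_error(transform_M(-1), ">= 0")
  expect_error(transform_C(-1), ">= 0")
})

test_that("design table invariants hold on a generated cohort", {
  coh <- sockeye_cohort()
  d <- attr(coh, "design")
  # Salmon cumulative load >= Snake load for the same fish
  ms <- d$M[d$reach == "Snake"]
  msa <- d$M[d$reach == "Salmon"]
  sn <- d$fish_id[d$reach == "Snake"]; sa <- d$fish_id[d$reach == "Salmon"]
  shared <- intersect(sn, sa)
  expect_true(all(msa[match(shared, sa)] >= ms[match(shared, sn)]))
  expect_true(all(d$M >= 0, na.rm = TRUE))
  # transformed columns are deterministic functions of the raw ones
  expect_equal(d$logM, log(d$M + 1))
  expect_equal(d$crC, d$C^(1 / 3))
  # correlation screen is symmetric with entries in [-1, 1]
  cm <- covariate_correlations(d[d$reach == "Columbia", ], c("T", "F", "crC"))
  expect_equal(cm, t(cm))
  expect_true(all(abs(cm) <= 1 + 1e-12))
})
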