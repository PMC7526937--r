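## Prospective Monte-Carlo projection: simulate arrivals -> travel ->
## survival over years x scenarios x loops, drawing model parameters per
## loop from the retrospective fits' covariance to propagate uncertainty.

#' Simulation configuration
#'
#' Defaults follow the published design: 100 fish per year/scenario/loop/
#' species, 70 years per scenario, 3 scenarios, 200 loops — 8.4 million
#' fish in total.
#'
#' @param n_fish fish per year/scenario/loop/species.
#' @param n_loops parameter-draw loops.
#' @param n_years years per scenario.
#' @param scenarios scenario names.
#' @param species species simulated.
#' @param seed master seed; every stream is derived from it.
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(n_fish = 100, n_loops = 200, n_years = 70,
                              scenarios = c("historical", "dry", "wet"),
                              species = c("chinook", "sockeye"), seed = 1) {
  for (v in c(n_fish, n_loops, n_years))
    if (v < 1) stop("all simulation counts must be >= 1")
  structure(list(n_fish = n_fish, n_loops = n_loops, n_years = n_years,
                 scenarios = scenarios, species = species, seed = seed),
            class = "simulation_config")
}

#' Total number of simulated fish (closed form)
#'
#' `n_fish x n_years x scenarios x loops x species`; the default
#' configuration enumerates 8.4 million fish.
#'
#' @param config a [simulation_config()].
#' @return Integer-valued count.
#' @export
n_simulated_fish <- function(config) {
  config$n_fish * config$n_years * length(config$scenarios) *
    config$n_loops * length(config$species)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d fish x %d years x %d scenarios x %d loops x %d species = %s fish\n",
    x$n_fish, x$n_years, length(x$scenarios), x$n_loops, length(x$species),
    format(n_simulated_fish(x), big.mark = ",")))
  invisible(x)
}

#' Percent change of future vs historical survival
#'
#' @param future,historical mean survival values.
#' @return `100 * (future - historical) / historical`.
#' @export
percent_change <- function(future, historical) {
  100 * (future - historical) / historical
}

.derive_seed <- function(master, ...) {
  idx <- c(...)
  primes <- c(1000003, 10007, 101, 7919, 31, 13)[seq_along(idx)]
  as.integer((master + sum(idx * primes)) %% 2147483647L)
}

.nearest_psd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, 0), nrow(V)) %*% t(e$vectors)
}

.check_psd <- function(V, what, repair) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) < -1e-8 * max(abs(e))) {
    if (!repair) stop(what, " covariance is not positive semidefinite")
    message("repairing non-PSD ", what, " covariance (eigenvalue clip)")
    return(.nearest_psd(V))
  }
  (V + t(V)) / 2
}

#' Draw one parameter set from the fitted models' covariances
#'
#' One multivariate-normal draw per model: the arrival model's transformed
#' parameter vector and each survival model's coefficient vector, using the
#' covariance matrices from the retrospective fits. Draws are reproducible
#' from (master seed, loop index).
#'
#' @param arrival an `"arrival_model"`.
#' @param survival_models named list of `"survival_model"` objects (per
#'   reach).
#' @param seed RNG seed for this draw (derive from master seed + loop).
#' @param repair if `TRUE`, repair a non-PSD covariance by eigenvalue
#'   clipping (logged) instead of erroring.
#' @return List: `arrival` (an `"arrival_model"` with the drawn parameters)
#'   and `betas` (named list of drawn coefficient vectors).
#' @export
draw_parameter_set <- function(arrival, survival_models, seed = NULL,
                               repair = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  Va <- .check_psd(arrival$vcov, "arrival", repair)
  a2 <- arrival
  a2$par <- stats::setNames(
    drop(MASS::mvrnorm(1, arrival$par, Va)), names(arrival$par))
  ## unidentifiable slopes stay pinned at their point value
  if (!all(arrival$identifiable)) {
    pin <- names(arrival$identifiable)[!arrival$identifiable]
    pin <- intersect(if (arrival$k == 1) "b1" else pin, names(a2$par))
    a2$par[pin] <- arrival$par[pin]
  }
  betas <- lapply(survival_models, function(m) {
    Vb <- .check_psd(stats::vcov(m), paste("survival", m$reach), repair)
    drop(MASS::mvrnorm(1, stats::coef(m), Vb))
  })
  list(arrival = a2, betas = betas)
}

## vectorized reach-entry conditions (NA where env does not cover)
.reach_TF <- function(entry_dates, temp_env, flow_env, window) {
  n <- length(entry_dates)
  Tm <- matrix(NA_real_, n, window); Fm <- matrix(NA_real_, n, window)
  for (k in seq_len(window)) {
    i_t <- match(entry_dates + (k - 1L), temp_env$date)
    i_f <- match(entry_dates + (k - 1L), flow_env$date)
    Tm[, k] <- temp_env$temperature[i_t]
    Fm[, k] <- flow_env$flow[i_f]
  }
  list(T = rowMeans(Tm), F = rowMeans(Fm))
}

.temp_at <- function(env, dates) env$temperature[match(dates, env$date)]

#' Simulate one projected cohort
#'
#' The projection's per-year core: (1) arrival days at Bonneville are drawn
#' from the arrival model using the year's annual covariates from the
#' scenario series; (2) catch, juvenile-transport rate, hatchery proportion
#' and ocean-age mix are bootstrapped from the empirical annual table; (3)
#' passage dates come from the travel model; (4) each reach survival is
#' Bernoulli with probability from the survival model (year effect zero,
#' optionally at drawn coefficients). Censored fish count as deaths in
#' cumulative survival.
#'
#' @param year calendar year to simulate.
#' @param scenario_env named list of [env_series()] per site for one
#'   scenario.
#' @param species `"chinook"` or `"sockeye"`.
#' @param arrival `"arrival_model"` (possibly a parameter draw).
#' @param survival_models named list per reach (`Columbia`, `Snake`,
#'   `Salmon`).
#' @param travel a [travel_model()].
#' @param obs_annual empirical annual table (see [empirical_annual()]).
#' @param n_fish cohort size.
#' @param arrival_shift_days sensitivity shift, days earlier.
#' @param betas optional coefficient draws per reach model.
#' @param covs precomputed [annual_covariates()] table for the scenario
#'   (computed from `scenario_env$BON` when `NULL`).
#' @return Data frame, one row per fish: arrival day, component, covariate
#'   draws, per-reach outcomes (`NA` where the reach was never entered) and
#'   `cumulative`.
#' @export
simulate_cohort <- function(year, scenario_env, species, arrival,
                            survival_models, travel, obs_annual,
                            n_fish = 100, arrival_shift_days = 0,
                            betas = NULL, covs = NULL) {
  if (is.null(covs)) covs <- annual_covariates(scenario_env$BON)
  cov_row <- covs[covs$year == year, , drop = FALSE]
  if (nrow(cov_row) == 0) stop("scenario series does not cover year ", year)
  arr <- simulate.arrival_model(arrival, nsim = n_fish, newdata = cov_row)
  day <- shift_arrivals(arr$day, arrival_shift_days)
  day_int <- pmax(round(day), 32L)
  bon <- as.Date(paste0(year, "-01-01")) - 1L + day_int
  ## interannual covariate draws: bootstrap a year from the observation data
  brow <- obs_annual[sample.int(nrow(obs_annual), 1L), ]
  J <- ifelse(stats::runif(n_fish) < brow$transport_rate, "transported", "in_river")
  H <- ifelse(stats::runif(n_fish) < brow$hatchery_prop, "hatchery", "wild")
  A <- sample(c(1L, 2L, 3L), n_fish, TRUE,
              prob = c(brow$p_age1, brow$p_age2, brow$p_age3))
  crC <- transform_C(max(brow$mean_catch, 0))
  trav <- simulate_travel(bon, scenario_env, travel)
  reaches <- default_reaches(species)
  entry_col <- c(Columbia = "date_BON", Snake = "date_ICH", Salmon = "date_LGR")
  temp_site <- c(Columbia = "BON", Snake = "ICH", Salmon = "SALMON")
  flow_site <- c(Columbia = "BON", Snake = "ICH", Salmon = "SALMON")
  out <- data.frame(year = year, species = species, component = arr$component,
                    day = day, J = J, H = H, A = A,
                    S_Columbia = NA_integer_, S_Snake = NA_integer_,
                    S_Salmon = NA_integer_, censored = trav$censored)
  ## cumulative thermal load at dam-passage snapshots
  T_bon <- .temp_at(scenario_env$BON, trav$date_BON)
  T_mcn <- .temp_at(scenario_env$MCN, trav$date_MCN)
  T_ich <- .temp_at(scenario_env$ICH, trav$date_ICH)
  T_lgr <- .temp_at(scenario_env$LGR, trav$date_LGR)
  D1 <- as.numeric(trav$date_MCN - trav$date_BON)
  D2 <- as.numeric(trav$date_ICH - trav$date_MCN)
  D3 <- as.numeric(trav$date_LGR - trav$date_ICH)
  M_snake <- D1 * (T_bon + T_mcn) / 2 + D2 * (T_mcn + T_ich) / 2
  M_salmon <- M_snake + D3 * (T_ich + T_lgr) / 2
  alive <- rep(TRUE, n_fish)
  for (rn in REACH_NAMES) {
    entry <- trav[[entry_col[rn]]]
    enter <- alive & !is.na(entry)
    if (!any(enter)) break
    tf <- .reach_TF(entry[enter], scenario_env[[temp_site[rn]]],
                    scenario_env[[flow_site[rn]]], reaches[[rn]]$window_days)
    nd <- data.frame(T = tf$T, F = tf$F,
                     logM = if (rn == "Snake") transform_M(pmax(M_snake[enter], 0))
                            else if (rn == "Salmon") transform_M(pmax(M_salmon[enter], 0))
                            else NA_real_,
                     crC = crC, J = J[enter], H = H[enter], A = A[enter])
    covered <- stats::complete.cases(nd[c("T", "F")])
    m <- survival_models[[rn]]
    p <- rep(NA_real_, sum(enter))
    if (any(covered))
      p[covered] <- predict_survival(m, nd[covered, , drop = FALSE],
                                     beta = if (is.null(betas)) NULL else betas[[rn]])
    s <- as.integer(stats::runif(sum(enter)) < p)
    s[is.na(p)] <- 0L                     # env coverage exhausted: censored
    out[[paste0("S_", rn)]][enter] <- s
    alive[enter] <- s == 1L
    alive[!enter] <- FALSE
  }
  out$cumulative <- as.integer(!is.na(out$S_Salmon) & out$S_Salmon == 1L &
                                 out$S_Snake == 1L & out$S_Columbia == 1L)
  out
}

#' Run the full prospective projection
#'
#' Iterates loops x scenarios x years x species. Each loop draws one
#' parameter set per species from the fitted models' covariances; each
#' year/scenario simulates a cohort. Emits annual survival summaries per
#' reach and cumulative, and mean (SD) per scenario with percent change of
#' future vs historical means. Chinook are reported as aggregate plus
#' spring/summer run components.
#'
#' @param config a [simulation_config()].
#' @param models per-species list: `models[[sp]]$arrival`,
#'   `models[[sp]]$survival` (named per reach), `models[[sp]]$travel`,
#'   `models[[sp]]$obs_annual`.
#' @param env_scenarios nested list scenario -> site -> [env_series()].
#' @param obs_annual default empirical annual table when a species does not
#'   carry its own.
#' @param arrival_shift_days sensitivity shift passed through to cohorts.
#' @param draw_parameters draw per-loop parameter sets (default `TRUE`;
#'   `FALSE` uses the point estimates in every loop).
#' @return Object of class `"scenario_run"`: `$annual` (per
#'   loop/scenario/species/year/component survival) and `$summary`
#'   (mean, SD, percent change vs historical).
#' @export
run_projection <- function(config, models, env_scenarios, obs_annual = NULL,
                           arrival_shift_days = 0, draw_parameters = TRUE) {
  annual <- list()
  covs_cache <- list()
  scen_avail <- intersect(config$scenarios, names(env_scenarios))
  if (!length(scen_avail)) stop("no requested scenario present in env_scenarios")
  for (loop in seq_len(config$n_loops)) {
    draws <- list()
    for (si in seq_along(config$species)) {
      sp <- config$species[si]
      draws[[sp]] <- if (draw_parameters)
        draw_parameter_set(models[[sp]]$arrival, models[[sp]]$survival,
                           seed = .derive_seed(config$seed, loop, si))
      else list(arrival = models[[sp]]$arrival, betas = NULL)
    }
    for (ci in seq_along(scen_avail)) {
      sc <- scen_avail[ci]
      env <- env_scenarios[[sc]]
      if (loop == 1L && is.null(covs_cache[[sc]]))
        covs_cache[[sc]] <- annual_covariates(env$BON)
      yrs_avail <- covs_cache[[sc]]$year
      yrs <- utils::head(yrs_avail, config$n_years)
      for (si in seq_along(config$species)) {
        sp <- config$species[si]
        oa <- models[[sp]]$obs_annual %||% obs_annual
        for (yi in seq_along(yrs)) {
          set.seed(.derive_seed(config$seed, loop, ci, si, yi))
          coh <- simulate_cohort(yrs[yi], env, sp, draws[[sp]]$arrival,
                                 models[[sp]]$survival, models[[sp]]$travel,
                                 oa, n_fish = config$n_fish,
                                 arrival_shift_days = arrival_shift_days,
                                 betas = draws[[sp]]$betas,
                                 covs = covs_cache[[sc]])
          comps <- if (sp == "chinook")
            c("aggregate", "spring", "summer") else "aggregate"
          for (cmp in comps) {
            sel <- if (cmp == "aggregate") rep(TRUE, nrow(coh))
                   else coh$component == cmp
            if (!any(sel)) next
            annual[[length(annual) + 1L]] <- data.frame(
              loop = loop, scenario = sc, species = sp, component = cmp,
              year = yrs[yi],
              Columbia = mean(coh$S_Columbia[sel], na.rm = TRUE),
              Snake = mean(coh$S_Snake[sel], na.rm = TRUE),
              Salmon = mean(coh$S_Salmon[sel], na.rm = TRUE),
              cumulative = mean(coh$cumulative[sel]))
          }
        }
      }
    }
  }
  annual <- do.call(rbind, annual)
  ## summarize: mean (SD) of annual survival per scenario/species/component
  long <- stats::reshape(
    annual, direction = "long",
    varying = c("Columbia", "Snake", "Salmon", "cumulative"),
    v.names = "survival", timevar = "reach",
    times = c("Columbia", "Snake", "Salmon", "cumulative"))
  agg <- stats::aggregate(survival ~ scenario + species + component + reach,
                          data = long, FUN = function(v)
                            c(mean = mean(v, na.rm = TRUE),
                              sd = stats::sd(v, na.rm = TRUE)))
  summary_df <- data.frame(agg[1:4], mean = agg$survival[, "mean"],
                           sd = agg$survival[, "sd"])
  hist_key <- summary_df$scenario == "historical"
  hk <- paste(summary_df$species, summary_df$component, summary_df$reach)
  hist_mean <- stats::setNames(summary_df$mean[hist_key], hk[hist_key])
  summary_df$pct_change <- ifelse(
    hist_key, NA_real_,
    percent_change(summary_df$mean, hist_mean[hk]))
  out <- list(annual = annual, summary = summary_df, config = config)
  class(out) <- "scenario_run"
  out
}

#' @export
print.scenario_run <- function(x, ...) {
  cat("<scenario_run>\n")
  print(x$config)
  cum <- x$summary[x$summary$reach == "cumulative" &
                     x$summary$component == "aggregate", ]
  print(cum[order(cum$species, cum$scenario),
            c("species", "scenario", "mean", "sd", "pct_change")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
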