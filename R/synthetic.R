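## Synthetic-data generator: daily environmental scenarios with seasonal
## temperature curves and a spring freshet, tagged-fish cohorts with the
## observation dataset's composition, arrival/travel/survival generated from
## known truth surfaces, and generator-truth utilities (true coefficients,
## Bayes AUC) for recovery tests.

GEN_SITES <- c("BON", "MCN", "ICH", "LGR", "SALMON")

#' Synthetic-data generator configuration
#'
#' Defaults encode the statistical structure of the observation data: annual
#' sinusoidal temperature curves per site (warming as fish move upstream), a
#' spring-freshet flow curve per site, scenario deltas with the largest
#' warming in summer and an earlier, smaller freshet with reduced summer
#' flows, cohort composition (transported 33% Chinook / 38% sockeye,
#' hatchery 74% / 99%, ocean-age-2 66% / 89%), arrival-timing truth
#' (sockeye: April temperature slope -1.36 d per deg C; spring Chinook:
#' -3.06 d per deg C; summer Chinook: +0.02 d per 1000 m^3/s April flow),
#' and logistic survival surfaces that decline steeply above a 15 deg C
#' breakpoint, with reach-specific flow effects (negative freshet effect for
#' Chinook in the Columbia, a strong positive flow effect for sockeye in the
#' Salmon reach), negative cumulative-temperature, transport and catch
#' effects, and a hatchery deficit. Interannual effects (temperature
#' offsets, flow multipliers, composition jitter) are centred across the
#' generated years so long-run means equal the stated curves.
#'
#' @param seed master seed.
#' @param years number of calendar years to generate.
#' @param start_year first calendar year (default 2004).
#' @param extreme_year calendar year flagged as the "2015-like" extreme
#'   (+2 SD run-window temperature, -2 SD flow); default 2015 when in range,
#'   else the last year.
#' @param temp_year_sd SD of annual temperature offsets, deg C.
#' @param temp_month_sd SD of month-specific temperature anomalies, deg C
#'   (gives each calendar month distinct interannual variation, as weather
#'   does; anomalies are centred per month across years).
#' @param flow_year_lsd log-SD of annual flow multipliers.
#' @param comp_jitter_sd logit-scale SD of annual composition jitter.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1, years = 12, start_year = 2004,
                             extreme_year = NULL, temp_year_sd = 0.7,
                             temp_month_sd = 0.8, flow_year_lsd = 0.25,
                             comp_jitter_sd = 0.1) {
  yrs <- start_year + seq_len(years) - 1L
  if (is.null(extreme_year))
    extreme_year <- if (2015 %in% yrs) 2015L else yrs[length(yrs)]
  cfg <- list(
    seed = seed, years = years, start_year = start_year,
    calendar_years = yrs, extreme_year = extreme_year,
    temp_year_sd = temp_year_sd, temp_month_sd = temp_month_sd,
    flow_year_lsd = flow_year_lsd,
    comp_jitter_sd = comp_jitter_sd, temp_daily_sd = 0.6, flow_daily_lsd = 0.08,
    ## seasonal temperature: mean + amp * cos(2*pi*(doy - peak_doy)/365)
    temp_curve = list(
      BON    = c(mean = 11.5, amp = 9.0, peak_doy = 210),
      MCN    = c(mean = 11.3, amp = 9.3, peak_doy = 210),
      ICH    = c(mean = 11.5, amp = 9.8, peak_doy = 212),
      LGR    = c(mean = 11.0, amp = 9.5, peak_doy = 212),
      SALMON = c(mean = 10.5, amp = 11.0, peak_doy = 212)),
    ## freshet flow: base + peak * exp(-((doy - peak_day)/width)^2 / 2)
    flow_curve = list(
      BON    = c(base = 3000, peak = 5000, peak_day = 140, width = 30),
      MCN    = c(base = 2800, peak = 4800, peak_day = 140, width = 30),
      ICH    = c(base = 900, peak = 1900, peak_day = 135, width = 28),
      LGR    = c(base = 850, peak = 1800, peak_day = 135, width = 28),
      SALMON = c(base = 150, peak = 900, peak_day = 150, width = 25)),
    ## scenario temperature deltas (deg C at the summer peak of the seasonal
    ## shape); warming grows moving upstream, wet > dry
    temp_delta = list(
      dry = c(BON = 1.3, MCN = 1.7, ICH = 2.3, LGR = 2.4, SALMON = 2.6),
      wet = c(BON = 1.7, MCN = 2.1, ICH = 2.8, LGR = 2.9, SALMON = 3.4)),
    ## seasonal shape of warming: 0.5 + 0.5 * exp(-((doy-200)/60)^2/2)
    temp_delta_shape = c(floor = 0.5, peak_doy = 200, width = 60),
    ## scenario flow: freshet shifts earlier and shrinks; summer flows drop
    flow_scenario = list(
      dry = c(peak_shift = -12, peak_factor = 0.80, summer_factor = 0.62),
      wet = c(peak_shift = -12, peak_factor = 1.15, summer_factor = 0.75)),
    flow_summer = c(start_doy = 160, ramp_days = 30),
    ## cohort composition
    composition = list(
      chinook = list(transported = 0.33, hatchery = 0.74,
                     age_probs = c(`1` = 0.20, `2` = 0.66, `3` = 0.14)),
      sockeye = list(transported = 0.38, hatchery = 0.99,
                     age_probs = c(`1` = 0.06, `2` = 0.89, `3` = 0.05))),
    ## arrival-timing truth
    arrival_truth = list(
      sockeye = list(k = 1, spec = "temp_Apr", b0 = 195.5, b1 = -1.36, sigma = 8),
      chinook = list(k = 2, spec = c("temp_Apr", "flow_Apr"),
                     b0 = c(161.5, 156.8), b1 = c(-3.06, 0.02),
                     sigma = c(8, 10), p = 0.45)),
    ## survival truth (see true_survival_coefs)
    survival_truth = default_survival_truth(),
    catch = c(base = 400, lsd = 0.45, peak_doy = 150, width = 35)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Generator-truth survival coefficients
#'
#' Logistic survival surfaces on the logit scale:
#' `b0 + bT_lo*min(T-15,0) + bT_hi*max(T-15,0) + bF*(F-f_ref)/f_scale +`
#' `bM*(logM-m_ref) + bC*(crC-c_ref) + bJ*[transported] + bH*[hatchery] +`
#' `bA1*[age 1] + bA3*[age 3+]`. The temperature effect is piecewise linear
#' in the logit with a 15 deg C breakpoint (survival declines steeply above
#' 15 deg C). Intercepts are calibrated so marginal observed survival in a
#' default cohort matches the observation dataset's stylized rates (notably
#' sockeye Columbia 0.59 in-river vs 0.30 transported).
#'
#' @return Nested list species -> reach -> named coefficient vector.
#' @export
default_survival_truth <- function() {
  list(
    chinook = list(
      Columbia = c(b0 = 2.53, bT_lo = 0.03, bT_hi = -0.25, bF = -0.35,
                   bM = 0, bC = -0.08, bJ = -0.15, bH = -0.25,
                   bA1 = 0.30, bA3 = -0.15,
                   f_ref = 5000, f_scale = 2000, m_ref = 4.5, c_ref = 8),
      Snake = c(b0 = 4.53, bT_lo = 0, bT_hi = -0.30, bF = -0.15,
                bM = -0.50, bC = 0, bJ = -0.10, bH = -0.10,
                bA1 = 0.30, bA3 = -0.10,
                f_ref = 1500, f_scale = 800, m_ref = 4.5, c_ref = 0),
      Salmon = c(b0 = 3.58, bT_lo = 0, bT_hi = -0.35, bF = -0.20,
                 bM = -0.60, bC = 0, bJ = -0.05, bH = -0.05,
                 bA1 = 0.20, bA3 = -0.10,
                 f_ref = 500, f_scale = 300, m_ref = 4.8, c_ref = 0)),
    sockeye = list(
      Columbia = c(b0 = 2.40, bT_lo = 0.02, bT_hi = -0.45, bF = -0.10,
                   bM = 0, bC = -0.10, bJ = -1.30, bH = 0,
                   bA1 = 0.40, bA3 = -0.20,
                   f_ref = 3500, f_scale = 2000, m_ref = 0, c_ref = 8),
      Snake = c(b0 = 4.66, bT_lo = 0, bT_hi = -0.50, bF = -0.10,
                bM = -0.60, bC = 0, bJ = -0.30, bH = 0,
                bA1 = 0.30, bA3 = -0.10,
                f_ref = 1000, f_scale = 800, m_ref = 5.0, c_ref = 0),
      Salmon = c(b0 = 2.79, bT_lo = 0, bT_hi = -0.40, bF = 0.90,
                 bM = -0.80, bC = 0, bJ = -0.20, bH = 0,
                 bA1 = 0.20, bA3 = -0.10,
                 f_ref = 250, f_scale = 200, m_ref = 5.2, c_ref = 0))
  )
}

#' True survival probability from the generator surfaces
#'
#' @param species,reach which surface.
#' @param data data frame with columns `T`, `F`, `logM`, `crC`, `J`, `H`,
#'   `A` (missing continuous covariates may be NA when their coefficient
#'   is 0).
#' @param truth coefficient list (default [default_survival_truth()]).
#' @return Vector of survival probabilities.
#' @export
true_survival_prob <- function(species, reach, data,
                               truth = default_survival_truth()) {
  cf <- truth[[species]][[reach]]
  z <- function(x) ifelse(is.na(x), 0, x)
  eta <- cf["b0"] +
    cf["bT_lo"] * pmin(data$T - 15, 0) +
    cf["bT_hi"] * pmax(data$T - 15, 0) +
    cf["bF"] * (data$F - cf["f_ref"]) / cf["f_scale"] +
    cf["bM"] * z(data$logM - cf["m_ref"]) +
    cf["bC"] * z(data$crC - cf["c_ref"]) +
    cf["bJ"] * (data$J == "transported") +
    cf["bH"] * (data$H == "hatchery") +
    cf["bA1"] * (as.numeric(data$A) == 1) +
    cf["bA3"] * (as.numeric(data$A) >= 3)
  stats::plogis(unname(eta))
}

.centered_norm <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  x - mean(x)
}

.doy <- function(dates) as.integer(format(dates, "%j"))

#' Generate daily environmental scenarios
#'
#' Produces historical, dry and wet daily series for every site. All
#' scenarios share the same annual offsets and daily noise, so with zero
#' deltas the scenarios are identical and differences between scenarios are
#' exactly the configured climate signal: summer-peaked warming that grows
#' upstream, an earlier and rescaled freshet, and reduced summer flows. The
#' configured extreme year gets a +2 SD temperature offset and a -2 SD flow
#' multiplier ("2015-like").
#'
#' @param config a [generator_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return Nested list scenario -> site -> [env_series()], with attribute
#'   `"extreme_year"`.
#' @export
make_env_scenarios <- function(config, seed = config$seed) {
  set.seed(seed)
  yrs <- config$calendar_years
  dates <- seq(as.Date(paste0(yrs[1], "-01-01")),
               as.Date(paste0(yrs[length(yrs)], "-12-31")), by = "day")
  doy <- .doy(dates)
  year_of <- as.integer(format(dates, "%Y"))
  yi <- match(year_of, yrs)
  ## shared interannual effects, centred; extreme year pinned at +/- 2 SD
  t_off <- .centered_norm(length(yrs), config$temp_year_sd)
  f_mul <- exp(.centered_norm(length(yrs), config$flow_year_lsd))
  ei <- match(config$extreme_year, yrs)
  if (!is.na(ei)) {
    t_off[ei] <- 2 * config$temp_year_sd
    f_mul[ei] <- exp(-2 * config$flow_year_lsd)
  }
  ## month-specific anomalies, shared across sites and scenarios, centred
  ## per calendar month across years; interpolated smoothly between month
  ## midpoints so monthly covariate metrics vary independently across years
  anom_m <- matrix(stats::rnorm(length(yrs) * 12, 0, config$temp_month_sd),
                   length(yrs), 12)
  anom_m <- sweep(anom_m, 2, colMeans(anom_m))
  month_mid <- c(15.5, 45, 74.5, 105, 135.5, 166, 196.5, 227.5, 258, 288.5,
                 319, 349.5)
  anom_day <- numeric(length(dates))
  for (j in seq_along(yrs)) {
    sel <- yi == j
    anom_day[sel] <- stats::approx(month_mid, anom_m[j, ], xout = doy[sel],
                                   rule = 2)$y
  }
  shape <- config$temp_delta_shape
  dshape <- shape["floor"] + (1 - shape["floor"]) *
    exp(-((doy - shape["peak_doy"]) / shape["width"])^2 / 2)
  fs <- config$flow_summer
  summer_w <- stats::plogis((doy - fs["start_doy"]) / (fs["ramp_days"] / 4))
  out <- list()
  for (sc in c("historical", "dry", "wet")) out[[sc]] <- list()
  for (site in GEN_SITES) {
    tc <- config$temp_curve[[site]]
    fc <- config$flow_curve[[site]]
    t_noise <- stats::rnorm(length(dates), 0, config$temp_daily_sd)
    f_noise <- exp(stats::rnorm(length(dates), 0, config$flow_daily_lsd))
    t_det <- tc["mean"] + tc["amp"] * cos(2 * pi * (doy - tc["peak_doy"]) / 365)
    t_hist <- t_det + t_off[yi] + anom_day + t_noise
    freshet <- function(shift, pf) fc["peak"] * pf *
      exp(-((doy - (fc["peak_day"] + shift)) / fc["width"])^2 / 2)
    f_base_hist <- fc["base"] + freshet(0, 1)
    for (sc in c("historical", "dry", "wet")) {
      if (sc == "historical") {
        tt <- t_hist
        ff <- f_base_hist
      } else {
        tt <- t_hist + config$temp_delta[[sc]][site] * dshape
        fsc <- config$flow_scenario[[sc]]
        base_sc <- fc["base"] * (1 - (1 - fsc["summer_factor"]) * summer_w)
        ff <- base_sc + freshet(fsc["peak_shift"], fsc["peak_factor"])
      }
      ff <- pmax(ff * f_mul[yi] * f_noise, 1)
      out[[sc]][[site]] <- env_series(dates, as.numeric(tt), as.numeric(ff),
                                      site = site, scenario = sc)
    }
  }
  attr(out, "extreme_year") <- config$extreme_year
  out
}

#' Build the generator-truth arrival model
#'
#' Packages the configured true arrival coefficients as an
#' `"arrival_model"` object so simulation and recovery tests can use the
#' same machinery as fitted models.
#'
#' @param species `"chinook"` or `"sockeye"`.
#' @param config a [generator_config()].
#' @param covariates annual covariate table (from [annual_covariates()] of
#'   the generated first-dam series).
#' @return An `"arrival_model"` whose parameters are the generator truth.
#' @export
true_arrival_model <- function(species, config, covariates) {
  tr <- config$arrival_truth[[species]]
  if (tr$k == 1) {
    par <- c(b0 = tr$b0, b1 = tr$b1, lsigma = log(tr$sigma))
    ident <- c(b1 = TRUE)
  } else {
    par <- c(b0_spring = tr$b0[1], b1_spring = tr$b1[1],
             b0_summer = tr$b0[2], b1_summer = tr$b1[2],
             lsigma_spring = log(tr$sigma[1]), lsigma_summer = log(tr$sigma[2]),
             qlogis_p = stats::qlogis(tr$p))
    ident <- c(b1_spring = TRUE, b1_summer = TRUE)
  }
  out <- list(k = tr$k, par = par, vcov = diag(1e-12, length(par)),
              logLik = NA_real_, aicc = NA_real_, n = 0L,
              n_params = length(par), spec = tr$spec, identifiable = ident,
              years = covariates$year, covariates = covariates)
  class(out) <- "arrival_model"
  out
}

#' Generate a weekly fishery-catch series
#'
#' Log-normal weekly harvest with a spring-summer seasonal peak, covering
#' every week of the configured years.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed (default `config$seed + 1`).
#' @return A [catch_series()].
#' @export
make_catch_series <- function(config, seed = config$seed + 1) {
  set.seed(seed)
  yrs <- config$calendar_years
  all_days <- seq(as.Date(paste0(yrs[1], "-01-01")),
                  as.Date(paste0(yrs[length(yrs)], "-12-31")), by = "day")
  weeks <- sort(unique(week_of(all_days)))
  cc <- config$catch
  doy <- .doy(weeks + 3L)
  season <- 0.15 + exp(-((doy - cc["peak_doy"]) / cc["width"])^2 / 2)
  catch <- round(cc["base"] * season *
                   exp(stats::rnorm(length(weeks), 0, cc["lsd"])))
  catch_series(weeks, pmax(catch, 0))
}

#' Generate a tagged-fish cohort with known truth
#'
#' Draws a cohort for one species over the configured years: covariates per
#' the composition (with centred annual jitter), arrival days from the true
#' arrival model driven by the generated annual covariates, passage dates
#' from the true travel model, and per-reach survival Bernoulli outcomes
#' from the true logistic surfaces. Fish that die in a reach have their
#' upstream detections removed and upstream reaches marked not applicable;
#' travel-censored fish count as deaths. All truths are recorded alongside.
#'
#' @param config a [generator_config()].
#' @param env_list named list of historical [env_series()] per site (from
#'   [make_env_scenarios()]`$historical`).
#' @param catch a [catch_series()] (from [make_catch_series()]).
#' @param n_per_year fish per migration year.
#' @param species `"chinook"` or `"sockeye"`.
#' @param seed RNG seed (default `config$seed + 2`).
#' @return A `"fish_table"` with attributes `"true_probs"` (per fish x reach
#'   true survival probability), `"design"` (the latent design rows),
#'   `"truth"` (the coefficient lists) and `"annual"` (per-year composition
#'   rates actually used).
#' @export
make_cohort <- function(config, env_list, catch, n_per_year = 500,
                        species = c("chinook", "sockeye"),
                        seed = config$seed + 2) {
  species <- match.arg(species)
  set.seed(seed)
  yrs <- config$calendar_years
  comp <- config$composition[[species]]
  covs <- annual_covariates(env_list$BON)
  amod <- true_arrival_model(species, config, covs)
  tmod <- travel_model(species)
  ny <- length(yrs)
  jit <- function(p) stats::plogis(stats::qlogis(p) +
                                     .centered_norm(ny, config$comp_jitter_sd))
  tr_rate <- jit(comp$transported)
  hat_rate <- jit(comp$hatchery)
  arr <- simulate.arrival_model(amod, nsim = n_per_year,
                                newdata = covs[covs$year %in% yrs, ])
  n <- nrow(arr)
  yi <- match(arr$year, yrs)
  J <- ifelse(stats::runif(n) < tr_rate[yi], "transported", "in_river")
  H <- ifelse(stats::runif(n) < hat_rate[yi], "hatchery", "wild")
  A <- as.integer(sample(names(comp$age_probs), n, TRUE, comp$age_probs))
  pop <- if (species == "sockeye") "SawtoothValley" else
    sample(c("GrandeRonde", "MiddleForkSalmon", "UpperSalmon",
             "SouthForkSalmon", "Imnaha", "Pahsimeroi"), n, TRUE)
  run <- if (species == "sockeye") NA_character_ else arr$component
  day0 <- as.Date(paste0(arr$year, "-01-01")) - 1L
  bon <- day0 + pmax(arr$day_int, 32L)
  trav <- simulate_travel(bon, env_list, tmod)
  fish <- data.frame(
    fish_id = sprintf("%s%06d", toupper(substr(species, 1, 2)), seq_len(n)),
    species = species, population = pop, run = run, ocean_age = A,
    origin = H, juv_history = J, migration_year = arr$year,
    trav[c("date_BON", "date_MCN", "date_ICH", "date_LGR", "date_terminal")],
    surv_columbia = "died", surv_snake = "died",
    surv_salmon = "died", stringsAsFactors = FALSE)
  ## latent design covariates for every reach the fish reached in travel
  design <- build_design_table(fish, env_list, catch,
                               salmon_roles = c(temperature = "SALMON",
                                                flow = "SALMON"))
  truth <- config$survival_truth
  design$p_true <- NA_real_
  for (rn in REACH_NAMES) {
    sel <- design$reach == rn
    design$p_true[sel] <- true_survival_prob(species, rn, design[sel, ], truth)
  }
  ## sequential Bernoulli outcomes; death truncates the migration record
  surv_col <- c(Columbia = "surv_columbia", Snake = "surv_snake",
                Salmon = "surv_salmon")
  up_dates <- list(Columbia = c("date_ICH", "date_LGR", "date_terminal"),
                   Snake = c("date_LGR", "date_terminal"),
                   Salmon = "date_terminal")
  alive <- !trav$censored & !is.na(trav$date_terminal)
  ## fish censored in travel or missing coverage: treated as dead where lost
  for (rn in REACH_NAMES) {
    rows <- which(design$reach == rn)
    ids <- match(design$fish_id[rows], fish$fish_id)
    ok <- alive[ids]
    s <- stats::runif(length(rows)) < design$p_true[rows]
    s[!ok] <- FALSE
    design$S[rows] <- as.integer(s)
    fish[[surv_col[rn]]][ids] <- ifelse(s, "survived", "died")
    died <- ids[!s]
    for (dc in up_dates[[rn]]) fish[[dc]][died] <- NA
    if (rn != "Salmon") {
      nxt <- surv_col[match(rn, REACH_NAMES) + 1L]
      fish[[nxt]][ids[s]] <- "died"      # provisional; overwritten if reached
    }
    alive[ids[!s]] <- FALSE
  }
  ## drop latent design rows for reaches never entered (death downstream)
  keep <- rep(TRUE, nrow(design))
  for (rn in c("Snake", "Salmon")) {
    rows <- which(design$reach == rn)
    ids <- match(design$fish_id[rows], fish$fish_id)
    prev <- surv_col[match(rn, REACH_NAMES) - 1L]
    keep[rows] <- fish[[prev]][ids] == "survived"
  }
  ## reaches never entered are not applicable
  for (rn in c("Snake", "Salmon")) {
    prev <- surv_col[match(rn, REACH_NAMES) - 1L]
    never <- fish[[prev]] != "survived"
    fish[[surv_col[rn]]][never] <- "not_applicable"
  }
  design <- design[keep, ]
  fish <- validate_fish_table(fish)
  annual <- data.frame(year = yrs, transport_rate = tr_rate,
                       hatchery_prop = hat_rate)
  attr(fish, "true_probs") <- design[c("fish_id", "reach", "p_true")]
  attr(fish, "design") <- design
  attr(fish, "truth") <- truth
  attr(fish, "annual") <- annual
  attr(fish, "arrival_model") <- amod
  fish
}

#' AUC of the generator's true probabilities
#'
#' The Bayes-optimal AUC on a generated cohort: concordance of the true
#' survival probabilities with the realized Bernoulli outcomes. Serves as
#' the oracle ceiling for fitted-model AUC.
#'
#' @param true_probs vector of true probabilities.
#' @param outcomes realized 0/1 outcomes.
#' @return AUC value.
#' @export
bayes_auc <- function(true_probs, outcomes) auc(true_probs, outcomes)

#' Empirical annual covariate rates from a cohort
#'
#' Per-year transported and hatchery proportions, ocean-age distribution and
#' mean weekly catch during the run — the quantities the projection
#' bootstraps over years to reflect interannual variability.
#'
#' @param fish a `"fish_table"`.
#' @param catch a [catch_series()].
#' @return Data frame, one row per migration year.
#' @export
empirical_annual <- function(fish, catch) {
  yrs <- sort(unique(fish$migration_year))
  rows <- lapply(yrs, function(y) {
    f <- fish[fish$migration_year == y, ]
    wk <- week_of(f$date_BON[!is.na(f$date_BON)])
    cval <- mean(catch$catch[catch$week_start %in% unique(wk)])
    data.frame(year = y,
               transport_rate = mean(f$juv_history == "transported"),
               hatchery_prop = mean(f$origin == "hatchery"),
               p_age1 = mean(f$ocean_age == 1),
               p_age2 = mean(f$ocean_age == 2),
               p_age3 = mean(f$ocean_age >= 3),
               mean_catch = cval)
  })
  do.call(rbind, rows)
}
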