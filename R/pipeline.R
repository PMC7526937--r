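## End-to-end pipeline: synthetic data -> retrospective fits (arrival,
## survival) -> projection -> sensitivity -> scenario comparison, with
## structured configuration, validation and provenance capture.

#' Default pipeline configuration
#'
#' A declarative configuration for the five pipeline stages. Defaults are
#' scaled for a desk-size end-to-end run on synthetic data; the projection
#' dimensions can be raised to the published design (100 fish, 70 years,
#' 200 loops).
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed, recorded in provenance.
#' @param years generated calendar years.
#' @param n_per_year cohort size per year for the retrospective fits.
#' @param species species to run.
#' @param n_fish,n_years,n_loops projection dimensions.
#' @param sensitivity_axes sensitivity axes to run (subset of
#'   `c("arrival","temp","flow")`).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("migsurv_run_"), seed = 1,
                            years = 12, n_per_year = 400,
                            species = c("chinook", "sockeye"),
                            n_fish = 50, n_years = 8, n_loops = 3,
                            sensitivity_axes = "temp") {
  structure(list(out_dir = out_dir, seed = seed, years = years,
                 n_per_year = n_per_year, species = species,
                 n_fish = n_fish, n_years = n_years, n_loops = n_loops,
                 sensitivity_axes = sensitivity_axes,
                 knots = SMOOTH_KNOTS, flow_floor = 10,
                 max_interp_days = 3),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema and constraint checks: positive counts, knot dimensions in
#' \{3, 4\}, positive flow floor, known species.
#'
#' @param config a [pipeline_config()] (or plain list).
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed must be a number")
  for (f in c("years", "n_per_year", "n_fish", "n_years", "n_loops"))
    chk(is.numeric(config[[f]]) && config[[f]] >= 1,
        paste(f, "must be a positive count"))
  chk(all(config$species %in% SPECIES_LEVELS),
      "species must be chinook and/or sockeye")
  chk(all(config$knots %in% c(3L, 4L)), "knots must be 3 or 4")
  chk(is.numeric(config$flow_floor) && config$flow_floor > 0,
      "flow_floor must be positive")
  chk(all(config$sensitivity_axes %in% c("arrival", "temp", "flow")),
      "unknown sensitivity axis")
  v
}

#' Run the full pipeline on synthetic data
#'
#' Executes, in order: (1) synthetic-data generation (environmental
#' scenarios, catch, cohorts); (2) retrospective fits — arrival-timing model
#' selection and per-reach survival models; (3) the Monte-Carlo projection
#' over climate scenarios; (4) sensitivity grids; (5) the run-window
#' exceedance comparison against the extreme ("2015-like") year. Every
#' stage writes its artifact into `config$out_dir`, plus a provenance JSON
#' with the seed and configuration.
#'
#' @param config a [pipeline_config()].
#' @return Invisible list with all stage outputs (`env`, `cohorts`,
#'   `arrival`, `survival`, `projection`, `sensitivity`, `comparison`,
#'   `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  bad <- validate_config(config)
  if (length(bad)) stop("invalid configuration:\n", paste(bad, collapse = "\n"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("stage %-12s done in %.1fs", name, proc.time()[3] - t0))
    res
  }
  gen <- generator_config(seed = config$seed, years = config$years)
  env <- stage("synthetic", {
    e <- make_env_scenarios(gen)
    for (site in names(e$historical))
      write_env_series(e$historical[[site]],
                       file.path(config$out_dir, paste0("env_", site, ".csv")))
    e
  })
  catch <- make_catch_series(gen)
  write_catch_series(catch, file.path(config$out_dir, "catch.csv"))
  cohorts <- list(); arrivals <- list(); survivals <- list(); models <- list()
  for (sp in config$species) {
    coh <- stage(paste0("cohort_", sp),
                 make_cohort(gen, env$historical, catch,
                             n_per_year = config$n_per_year, species = sp))
    write_fish_table(coh, file.path(config$out_dir, paste0("fish_", sp, ".csv")))
    cohorts[[sp]] <- coh
    design <- attr(coh, "design")
    covs <- annual_covariates(env$historical$BON)
    arrivals[[sp]] <- stage(paste0("arrival_", sp), {
      days <- as.integer(format(coh$date_BON, "%j"))
      fit_arrival(days, coh$migration_year, covs,
                  spec = gen$arrival_truth[[sp]]$spec,
                  k = gen$arrival_truth[[sp]]$k,
                  run = if (sp == "chinook") coh$run else NULL)
    })
    survivals[[sp]] <- stage(paste0("survival_", sp), {
      fits <- list()
      for (rn in REACH_NAMES) {
        d <- design[design$reach == rn, ]
        sm <- if (rn == "Columbia") c("T", "F", "C") else c("T", "F", "M")
        fa <- if (sp == "sockeye") c("A", "J") else c("A", "J", "H")
        fits[[rn]] <- fit_survival(d, smooth_terms = sm, factor_terms = fa,
                                   species = sp, reach = rn)
      }
      fits
    })
    models[[sp]] <- list(arrival = arrivals[[sp]], survival = survivals[[sp]],
                         travel = travel_model(sp),
                         obs_annual = empirical_annual(coh, catch))
  }
  sim_cfg <- simulation_config(n_fish = config$n_fish, n_loops = config$n_loops,
                               n_years = config$n_years,
                               species = config$species, seed = config$seed)
  projection <- stage("projection",
                      run_projection(sim_cfg, models, env))
  utils::write.csv(projection$summary,
                   file.path(config$out_dir, "projection_summary.csv"),
                   row.names = FALSE)
  sens <- list()
  for (ax in config$sensitivity_axes) {
    vals <- switch(ax, arrival = c(6), temp = c(1), flow = c(0.5))
    sens[[ax]] <- stage(paste0("sensitivity_", ax),
                        run_sensitivity_grid(ax, values = vals,
                                             config = sim_cfg, models = models,
                                             env_scenarios = env,
                                             obs_annual = NULL))
  }
  if (length(sens)) {
    sens_df <- do.call(rbind, sens)
    utils::write.csv(sens_df, file.path(config$out_dir, "sensitivity.csv"),
                     row.names = FALSE)
  }
  comparison <- stage("comparison", {
    rows <- list()
    for (sp in config$species) {
      coh <- cohorts[[sp]]
      win <- run_window(coh$date_BON[!is.na(coh$date_BON)])
      ref <- annual_window_means(env$historical$BON, win)
      refy <- ref[ref$year == gen$extreme_year, ]
      cmp <- compare_scenarios(lapply(env, `[[`, "BON"), win,
                               ref_temp = refy$mean_temp,
                               ref_flow = refy$mean_flow)
      cmp$species <- sp
      rows[[sp]] <- cmp
    }
    do.call(rbind, rows)
  })
  utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                   row.names = FALSE)
  prov <- list(seed = config$seed,
               config = unclass(config)[c("years", "n_per_year", "n_fish",
                                          "n_years", "n_loops", "species")],
               package_version = as.character(utils::packageVersion("migsurv")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(env = env, cohorts = cohorts, arrival = arrivals,
                 survival = survivals, projection = projection,
                 sensitivity = sens, comparison = comparison,
                 out_dir = config$out_dir))
}
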