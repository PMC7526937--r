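## Sensitivity grids: arrival-day shifts, additive temperature deltas, and
## flow factors interpolating/extrapolating the scenario-minus-historical
## flow change (with a minimum-flow floor).

#' Sensitivity analysis specification
#'
#' Default grids: arrival shifts of 3, 6, 9, 12, 14 days earlier;
#' temperature deltas of -0.8, -0.4, 0.4, 0.8, 1.2, 1.6, 2 deg C; flow
#' factors of 0, 0.2, 0.4, 0.6, 0.8, 1.2, 1.4 with a 10 m^3/s floor.
#'
#' @param arrival_shifts_days days earlier than the modelled arrival.
#' @param temp_deltas_C additive daily temperature changes.
#' @param flow_factors multipliers on the scenario flow change.
#' @param flow_floor minimum flow after the factor is applied, m^3/s (> 0).
#' @return List of class `"sensitivity_spec"`.
#' @export
sensitivity_spec <- function(arrival_shifts_days = c(3, 6, 9, 12, 14),
                             temp_deltas_C = c(-0.8, -0.4, 0.4, 0.8, 1.2, 1.6, 2),
                             flow_factors = c(0, 0.2, 0.4, 0.6, 0.8, 1.2, 1.4),
                             flow_floor = 10) {
  if (flow_floor <= 0) stop("flow_floor must be positive")
  structure(list(arrival_shifts_days = arrival_shifts_days,
                 temp_deltas_C = temp_deltas_C,
                 flow_factors = flow_factors,
                 flow_floor = flow_floor),
            class = "sensitivity_spec")
}

#' Shift arrival days earlier
#'
#' @param days arrival day-of-year values.
#' @param delta days earlier (>= 0).
#' @return `days - delta`.
#' @export
shift_arrivals <- function(days, delta) {
  if (delta < 0) stop("delta must be >= 0 (days earlier)")
  days - delta
}

#' Add a constant temperature delta to a daily series
#'
#' @param env an [env_series()].
#' @param dT additive change, deg C. Flow is untouched.
#' @return Modified [env_series()].
#' @export
add_delta_temperature <- function(env, dT) {
  env$temperature <- env$temperature + dT
  env
}

#' Apply a flow factor to a climate-scenario series
#'
#' \deqn{F_{t,s,x} = F_{t,hist} + \Delta F_{t,s} \cdot F_x}
#' where \eqn{\Delta F_{t,s}} is the scenario-minus-historical flow change on
#' day t. A factor of 0 reproduces the historical series, 1 the scenario
#' series; values below `floor` are raised to `floor` (flow cannot be
#' negative and a minimum of 10 m^3/s is imposed).
#'
#' @param hist historical [env_series()].
#' @param scen scenario [env_series()] on the same dates.
#' @param Fx flow factor (multiplier on the daily change).
#' @param floor minimum flow, m^3/s.
#' @return [env_series()] with scenario temperature and factored flow.
#' @export
apply_flow_factor <- function(hist, scen, Fx, floor = 10) {
  if (nrow(hist) != nrow(scen) || !all(hist$date == scen$date))
    stop("historical and scenario series must share dates")
  scen$flow <- pmax(hist$flow + (scen$flow - hist$flow) * Fx, floor)
  scen
}

#' Run a one-axis sensitivity grid of survival projections
#'
#' Re-runs the projection at each grid value of one sensitivity axis, using
#' common random numbers (the same master seed as the base run) so that
#' differences between grid points are not Monte-Carlo noise. The unmodified
#' base point is always included (value 0 for the arrival and temperature
#' axes, 1 for the flow axis).
#'
#' @param axis `"arrival"`, `"temp"` or `"flow"`.
#' @param values grid values; defaults taken from `spec`.
#' @param spec a [sensitivity_spec()].
#' @param config a [simulation_config()].
#' @param models per-species model list as in [run_projection()].
#' @param env_scenarios scenario environmental series as in [run_projection()].
#' @param obs_annual empirical annual covariate table as in [run_projection()].
#' @return Long data frame keyed by `axis`, `value`, `scenario`, `species`,
#'   `reach` (reaches plus `"cumulative"`) with mean and SD of annual
#'   survival, of class `"sensitivity_grid"`.
#' @export
run_sensitivity_grid <- function(axis = c("arrival", "temp", "flow"),
                                 values = NULL, spec = sensitivity_spec(),
                                 config, models, env_scenarios, obs_annual) {
  axis <- match.arg(axis)
  base_value <- if (axis == "flow") 1 else 0
  if (is.null(values))
    values <- switch(axis,
                     arrival = spec$arrival_shifts_days,
                     temp = spec$temp_deltas_C,
                     flow = spec$flow_factors)
  values <- unique(c(base_value, values))
  out <- list()
  for (v in values) {
    env_v <- env_scenarios
    shift <- 0
    if (axis == "arrival") {
      shift <- v
    } else if (axis == "temp" && v != 0) {
      for (sc in setdiff(names(env_v), "historical"))
        env_v[[sc]] <- lapply(env_v[[sc]], add_delta_temperature, dT = v)
    } else if (axis == "flow" && v != 1) {
      for (sc in setdiff(names(env_v), "historical"))
        env_v[[sc]] <- Map(function(s, h) apply_flow_factor(h, s, v, spec$flow_floor),
                           env_v[[sc]], env_scenarios$historical[names(env_v[[sc]])])
    }
    run <- run_projection(config, models, env_v, obs_annual,
                          arrival_shift_days = shift)
    sm <- run$summary
    sm$axis <- axis
    sm$value <- v
    out[[length(out) + 1L]] <- sm
  }
  res <- do.call(rbind, out)
  class(res) <- c("sensitivity_grid", "data.frame")
  res
}
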