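## Core domain types and tabular I/O shared by every stage of the pipeline.

SPECIES_LEVELS <- c("chinook", "sockeye")
RUN_LEVELS <- c("spring", "summer")
ORIGIN_LEVELS <- c("hatchery", "wild")
JUV_LEVELS <- c("transported", "in_river")
SURV_LEVELS <- c("survived", "died", "not_applicable")
SCENARIO_LEVELS <- c("historical", "dry", "wet", "observed")
DAM_SITES <- c("BON", "MCN", "ICH", "LGR", "TERM")
REACH_NAMES <- c("Columbia", "Snake", "Salmon")

FISH_COLS <- c("fish_id", "species", "population", "run", "ocean_age",
               "origin", "juv_history", "migration_year",
               "date_BON", "date_MCN", "date_ICH", "date_LGR", "date_terminal",
               "surv_columbia", "surv_snake", "surv_salmon")

#' Daily environmental series for one site and scenario
#'
#' Construct a date-indexed daily series of mean water temperature and flow,
#' the environmental unit consumed by the covariate builder, the projection
#' simulator and the sensitivity operators.
#'
#' @param dates vector of `Date`, contiguous daily after construction.
#' @param temperature daily mean temperature, degrees C. `NA` marks a gap.
#' @param flow daily mean flow, m^3/s, non-negative. `NA` marks a gap.
#' @param site site code (e.g. `"BON"`, `"ICH"`, `"SALMON"`).
#' @param scenario one of `"historical"`, `"dry"`, `"wet"`, `"observed"`.
#'
#' @return A data frame of class `"env_series"` with columns `date`,
#'   `temperature`, `flow` and attributes `site` and `scenario`.
#' @export
env_series <- function(dates, temperature, flow, site = "BON",
                       scenario = "historical") {
  dates <- as.Date(dates)
  if (anyDuplicated(dates)) stop("duplicate dates in environmental series")
  if (length(temperature) != length(dates) || length(flow) != length(dates))
    stop("dates, temperature and flow must have equal length")
  scenario <- match.arg(scenario, SCENARIO_LEVELS)
  ord <- order(dates)
  dates <- dates[ord]; temperature <- temperature[ord]; flow <- flow[ord]
  if (any(flow < 0, na.rm = TRUE)) stop("negative flow in environmental series")
  ## expand to contiguous daily coverage; inserted days are gaps (NA)
  full <- seq(dates[1L], dates[length(dates)], by = "day")
  idx <- match(full, dates)
  out <- data.frame(date = full,
                    temperature = temperature[idx],
                    flow = flow[idx])
  attr(out, "site") <- as.character(site)
  attr(out, "scenario") <- scenario
  class(out) <- c("env_series", "data.frame")
  out
}

#' @export
print.env_series <- function(x, ...) {
  ng <- sum(!stats::complete.cases(x[c("temperature", "flow")]))
  cat(sprintf("<env_series> site=%s scenario=%s  %d days (%s..%s), %d gap day(s)\n",
              attr(x, "site"), attr(x, "scenario"), nrow(x),
              format(x$date[1L]), format(x$date[nrow(x)]), ng))
  invisible(x)
}

#' Report gap days in an environmental series
#'
#' @param env an [env_series()].
#' @return Data frame of runs of consecutive missing days with columns
#'   `start`, `end`, `length`.
#' @export
env_gaps <- function(env) {
  miss <- !stats::complete.cases(env[c("temperature", "flow")])
  if (!any(miss)) {
    return(data.frame(start = as.Date(character()), end = as.Date(character()),
                      length = integer()))
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = env$date[starts[keep]], end = env$date[ends[keep]],
             length = r$lengths[keep])
}

#' Read / write a daily environmental series
#'
#' CSV schema: `date,site,scenario,temp_C,flow_m3s` with ISO-8601 dates.
#' Missing days are flagged as gaps (see [env_gaps()]); duplicate dates and
#' negative flows are rejected.
#'
#' @param path CSV file path.
#' @return An [env_series()].
#' @export
read_env_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "site", "scenario", "temp_C", "flow_m3s")
  if (!all(need %in% names(d)))
    stop("env CSV must have columns: ", paste(need, collapse = ","))
  dates <- as.Date(d$date)
  if (anyNA(dates)) stop("malformed date in env CSV: ",
                         paste(utils::head(d$date[is.na(dates)], 3), collapse = ", "))
  env_series(dates, d$temp_C, d$flow_m3s,
             site = d$site[1L], scenario = d$scenario[1L])
}

#' @rdname read_env_series
#' @param env an [env_series()] to write.
#' @export
write_env_series <- function(env, path) {
  out <- data.frame(date = format(env$date),
                    site = attr(env, "site"),
                    scenario = attr(env, "scenario"),
                    temp_C = env$temperature,
                    flow_m3s = env$flow)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Fill gaps in an environmental series
#'
#' Short gaps (at most `max_interp_days` consecutive missing days) are filled
#' by linear interpolation between the flanking observed values. Longer gaps
#' are filled by regressing the target series on a neighbouring site's series
#' over their shared complete days and predicting over the gap (nearby gauges
#' on this river system are strongly correlated, r around 0.96). All
#' originally observed values are preserved exactly.
#'
#' @param target [env_series()] with gaps.
#' @param neighbor optional [env_series()] covering the target's long gaps.
#' @param max_interp_days longest gap filled by interpolation (default 3).
#' @return A gap-free [env_series()].
#' @export
fill_missing_env <- function(target, neighbor = NULL, max_interp_days = 3) {
  gaps <- env_gaps(target)
  if (nrow(gaps) == 0L) return(target)
  for (v in c("temperature", "flow")) {
    x <- target[[v]]
    if (!anyNA(x)) next
    r <- rle(is.na(x))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]; len <- i1 - i0 + 1L
      if (len <= max_interp_days && i0 > 1L && i1 < length(x)) {
        x[i0:i1] <- stats::approx(x = c(i0 - 1L, i1 + 1L),
                                  y = x[c(i0 - 1L, i1 + 1L)],
                                  xout = i0:i1)$y
      } else {
        x[i0:i1] <- .regress_gap(target, neighbor, v, i0, i1)
      }
    }
    target[[v]] <- x
  }
  if (any(target$flow < 0, na.rm = TRUE)) target$flow <- pmax(target$flow, 0)
  target
}

.regress_gap <- function(target, neighbor, v, i0, i1) {
  rng <- paste(format(target$date[i0]), "to", format(target$date[i1]))
  if (is.null(neighbor))
    stop("gap ", rng, " in ", v, " needs a neighbor series for regression fill")
  nb <- neighbor[[v]][match(target$date, neighbor$date)]
  shared <- !is.na(target[[v]]) & !is.na(nb)
  if (sum(shared) < 3L || anyNA(nb[i0:i1]))
    stop("gap ", rng, " in ", v, " not coverable: neighbor lacks overlap")
  fit <- stats::lm(y ~ x, data = data.frame(y = target[[v]][shared], x = nb[shared]))
  as.numeric(stats::predict(fit, newdata = data.frame(x = nb[i0:i1])))
}

#' Prediction interval for regression-filled values
#'
#' Refits the neighbour regression used by [fill_missing_env()] and returns
#' the filled values with pointwise prediction intervals, for checking the
#' coverage of long-gap fills.
#'
#' @inheritParams fill_missing_env
#' @param level interval level (default 0.95).
#' @param variable `"temperature"` or `"flow"`.
#' @return Data frame `date`, `fit`, `lwr`, `upr` for all gap days.
#' @export
regression_fill_interval <- function(target, neighbor, variable = "temperature",
                                     level = 0.95) {
  nb <- neighbor[[variable]][match(target$date, neighbor$date)]
  y <- target[[variable]]
  shared <- !is.na(y) & !is.na(nb)
  gap <- is.na(y)
  fit <- stats::lm(y ~ x, data = data.frame(y = y[shared], x = nb[shared]))
  pr <- stats::predict(fit, newdata = data.frame(x = nb[gap]),
                       interval = "prediction", level = level)
  data.frame(date = target$date[gap], fit = pr[, "fit"],
             lwr = pr[, "lwr"], upr = pr[, "upr"])
}

#' Reach definition
#'
#' A reach is a river segment between detection sites. The three modelled
#' reaches are Columbia (Bonneville to Ice Harbor), Snake (Ice Harbor to
#' Lower Granite) and the free-flowing Salmon reach (Lower Granite to the
#' terminal site). In the hydrosystem reaches, entry-day conditions represent
#' the reach; in the Salmon reach conditions are averaged over a species-
#' specific window (1 week Chinook, 2 weeks sockeye) reflecting travel time.
#'
#' @param name one of `"Columbia"`, `"Snake"`, `"Salmon"`.
#' @param entry_dam,exit_site site codes.
#' @param window_days averaging window length, days, at least 1.
#' @return A list of class `"reach_def"`.
#' @export
reach_def <- function(name, entry_dam, exit_site, window_days = 1L) {
  name <- match.arg(name, REACH_NAMES)
  window_days <- as.integer(window_days)
  if (window_days < 1L) stop("window_days must be >= 1")
  structure(list(name = name, entry_dam = entry_dam, exit_site = exit_site,
                 window_days = window_days), class = "reach_def")
}

#' Default reach definitions per species
#'
#' @param species `"chinook"` or `"sockeye"`.
#' @return Named list of three [reach_def()] objects.
#' @export
default_reaches <- function(species = c("chinook", "sockeye")) {
  species <- match.arg(species)
  salmon_window <- if (species == "chinook") 7L else 14L
  list(
    Columbia = reach_def("Columbia", "BON", "ICH", 1L),
    Snake    = reach_def("Snake", "ICH", "LGR", 1L),
    Salmon   = reach_def("Salmon", "LGR", "TERM", salmon_window)
  )
}

#' Read / write the tagged-fish detection table
#'
#' One row per PIT-tagged adult. CSV schema:
#' `fish_id,species,population,run,ocean_age,origin,juv_history,migration_year,`
#' `date_BON,date_MCN,date_ICH,date_LGR,date_terminal,surv_columbia,surv_snake,surv_salmon`
#' with ISO-8601 dates; missing detections left blank. Rows violating the
#' record invariants (unknown categorical level, malformed date, detection
#' dates not weakly increasing along the route, ocean age < 1) are rejected
#' with their line numbers and fish ids.
#'
#' @param path CSV file path.
#' @return Validated data frame of class `"fish_table"`.
#' @export
read_fish_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(fish_id = "character"))
  if (!all(FISH_COLS %in% names(d)))
    stop("fish CSV must have columns: ", paste(FISH_COLS, collapse = ","))
  d <- d[FISH_COLS]
  for (dc in c("date_BON", "date_MCN", "date_ICH", "date_LGR", "date_terminal")) {
    raw <- d[[dc]]
    parsed <- as.Date(ifelse(is.na(raw) | raw == "", NA, raw))
    bad_parse <- !is.na(raw) & raw != "" & is.na(parsed)
    if (any(bad_parse))
      stop("malformed ", dc, " at line(s) ",
           paste(which(bad_parse) + 1L, collapse = ", "))
    d[[dc]] <- parsed
  }
  validate_fish_table(d)
}

#' Validate a fish table against the record invariants
#'
#' @param d data frame with the fish-table columns.
#' @return `d` with class `"fish_table"`, or an error listing every bad row.
#' @export
validate_fish_table <- function(d) {
  problems <- character()
  bad <- function(rows, what) {
    if (any(rows))
      problems <<- c(problems, sprintf("line %d (fish %s): %s",
                                       which(rows) + 1L, d$fish_id[rows], what))
  }
  bad(!d$species %in% SPECIES_LEVELS, "unknown species")
  bad(!(is.na(d$run) | d$run %in% RUN_LEVELS), "unknown run")
  bad(!d$origin %in% ORIGIN_LEVELS, "unknown origin")
  bad(!d$juv_history %in% JUV_LEVELS, "unknown juv_history")
  bad(!is.na(d$ocean_age) & d$ocean_age < 1, "ocean_age < 1")
  for (sc in c("surv_columbia", "surv_snake", "surv_salmon"))
    bad(!d[[sc]] %in% SURV_LEVELS, paste("unknown", sc, "level"))
  ## detection dates weakly increasing along the route (NAs skipped)
  dmat <- cbind(as.numeric(d$date_BON), as.numeric(d$date_MCN),
                as.numeric(d$date_ICH), as.numeric(d$date_LGR),
                as.numeric(d$date_terminal))
  mono <- apply(dmat, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) < 2L || !is.unsorted(r)
  })
  bad(!mono, "detection dates not weakly increasing along route")
  ## upstream detection implies survival of the reach below it
  up_of <- list(surv_columbia = c("date_LGR", "date_terminal"),
                surv_snake = "date_terminal")
  for (sc in names(up_of)) {
    has_up <- Reduce(`|`, lapply(up_of[[sc]], function(cc) !is.na(d[[cc]])))
    bad(has_up & d[[sc]] != "survived" & d[[sc]] %in% SURV_LEVELS,
        paste("upstream detection contradicts", sc))
  }
  if (length(problems))
    stop("invalid fish rows:\n", paste(problems, collapse = "\n"))
  class(d) <- c("fish_table", "data.frame")
  d
}

#' @rdname read_fish_table
#' @param fish a `"fish_table"` data frame to write.
#' @export
write_fish_table <- function(fish, path) {
  out <- as.data.frame(fish)
  for (dc in c("date_BON", "date_MCN", "date_ICH", "date_LGR", "date_terminal"))
    out[[dc]] <- ifelse(is.na(out[[dc]]), "", format(out[[dc]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a weekly fishery-catch series
#'
#' CSV schema: `week_start,catch` (fish harvested per week, non-negative).
#' Longer reporting periods must be disaggregated to weekly first
#' (see [disaggregate_catch()]).
#'
#' @param path CSV file path.
#' @return Data frame of class `"catch_series"` with `week_start` (`Date`)
#'   and `catch`.
#' @export
read_catch_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("week_start", "catch") %in% names(d)))
    stop("catch CSV must have columns week_start,catch")
  catch_series(as.Date(d$week_start), d$catch)
}

#' @rdname read_catch_series
#' @param week_start vector of week-start `Date`s, 7 days apart.
#' @param catch non-negative weekly harvest counts.
#' @export
catch_series <- function(week_start, catch) {
  week_start <- as.Date(week_start)
  if (any(catch < 0)) stop("negative catch")
  ord <- order(week_start)
  week_start <- week_start[ord]; catch <- catch[ord]
  if (length(week_start) > 1L &&
      any(diff(as.numeric(week_start)) != 7))
    stop("catch series must be weekly (week starts 7 days apart)")
  structure(data.frame(week_start = week_start, catch = catch),
            class = c("catch_series", "data.frame"))
}

#' @rdname read_catch_series
#' @param cs a `"catch_series"`.
#' @export
write_catch_series <- function(cs, path) {
  out <- data.frame(week_start = format(cs$week_start), catch = cs$catch)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Disaggregate multi-week catch reports into weekly estimates
#'
#' Reports covering more than one week (e.g. biweekly hook-and-line totals)
#' are spread across their constituent weeks by linear interpolation, i.e.
#' proportionally to the number of report days falling in each week.
#'
#' @param period_start,period_end report period boundaries (`Date`;
#'   `period_end` is the exclusive end, a week-start-aligned date).
#' @param total fish harvested over each period.
#' @param week_start_day weekday the week starts on (default `"Monday"`).
#' @return A [catch_series()] at weekly resolution.
#' @export
disaggregate_catch <- function(period_start, period_end, total,
                               week_start_day = "Monday") {
  period_start <- as.Date(period_start); period_end <- as.Date(period_end)
  weeks <- list(); vals <- list()
  for (i in seq_along(total)) {
    days <- seq(period_start[i], period_end[i] - 1L, by = "day")
    wk <- week_of(days, week_start_day)
    per_day <- total[i] / length(days)
    agg <- tapply(rep(per_day, length(days)), as.character(wk), sum)
    weeks[[i]] <- as.Date(names(agg)); vals[[i]] <- as.numeric(agg)
  }
  wk_all <- do.call(c, weeks); v_all <- unlist(vals)
  agg <- tapply(v_all, as.character(wk_all), sum)
  catch_series(as.Date(names(agg)), as.numeric(agg))
}

#' Week containing a date
#'
#' @param dates vector of `Date`.
#' @param week_start_day weekday the week starts on (default `"Monday"`).
#' @return `Date` vector of week-start days.
#' @export
week_of <- function(dates, week_start_day = "Monday") {
  dates <- as.Date(dates)
  start_idx <- match(week_start_day,
                     c("Monday", "Tuesday", "Wednesday", "Thursday",
                       "Friday", "Saturday", "Sunday"))
  if (is.na(start_idx)) stop("unknown week_start_day: ", week_start_day)
  ## POSIXlt wday: 0 = Sunday
  wday <- as.POSIXlt(dates)$wday             # 0..6, Sun..Sat
  offset <- (wday - start_idx) %% 7L
  dates - offset
}
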