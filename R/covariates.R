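## Per-fish model covariates: reach-entry conditions, cumulative thermal
## load (degree-days), fishery-catch alignment, and the modelling transforms.

#' Reach-entry temperature and flow for one fish
#'
#' Hydrosystem reaches (Columbia, Snake) use the single daily mean on the day
#' of first detection at the entry dam. The Salmon reach uses the arithmetic
#' mean over `window_days` starting on the entry day (1 week for Chinook,
#' 2 weeks for sockeye), reflecting the longer exposure in the free-flowing
#' river.
#'
#' @param entry_date `Date` of first detection at the reach entry dam.
#' @param temp_env [env_series()] supplying temperature for the reach.
#' @param flow_env [env_series()] supplying flow (defaults to `temp_env`;
#'   the Salmon reach uses different gauges for the two variables).
#' @param reach a [reach_def()].
#' @return Named numeric vector `c(T = , F = )` (deg C, m^3/s).
#' @export
reach_conditions <- function(entry_date, temp_env, flow_env = temp_env, reach) {
  entry_date <- as.Date(entry_date)
  w <- reach$window_days
  days <- seq(entry_date, by = "day", length.out = w)
  ti <- match(days, temp_env$date)
  fi <- match(days, flow_env$date)
  if (anyNA(ti) || anyNA(temp_env$temperature[ti]))
    stop("temperature series does not cover ", format(entry_date), " + ",
         w - 1L, " days for reach ", reach$name)
  if (anyNA(fi) || anyNA(flow_env$flow[fi]))
    stop("flow series does not cover ", format(entry_date), " + ",
         w - 1L, " days for reach ", reach$name)
  c(T = mean(temp_env$temperature[ti]), F = mean(flow_env$flow[fi]))
}

.temp_on <- function(env, date) {
  i <- match(as.Date(date), env$date)
  if (is.na(i) || is.na(env$temperature[i]))
    stop("no temperature at ", attr(env, "site"), " on ", format(date))
  env$temperature[i]
}

#' Cumulative migration temperature (degree-days)
#'
#' Thermal load accumulated from Bonneville Dam to reach entry, computed as
#' the sum over dam-to-dam legs of leg duration times the mean of the entry
#' and exit dams' daily temperatures on their detection dates:
#' \deqn{M_{Snake} = D_1 (T_{BON}+T_{MCN})/2 + D_2 (T_{MCN}+T_{ICH})/2}
#' \deqn{M_{Salmon} = M_{Snake} + D_3 (T_{ICH}+T_{LGR})/2}
#' where \eqn{D_1, D_2, D_3} are the day counts between first detections at
#' consecutive dams. This is the exact trapezoid integral of a temperature
#' exposure that interpolates linearly between dam passages.
#'
#' @param dates named list/vector of detection `Date`s with elements `BON`,
#'   `MCN`, `ICH` (and `LGR` for the Salmon target).
#' @param env_list named list of [env_series()] keyed by site code.
#' @param target_reach `"Snake"` or `"Salmon"` — which reach entry the load
#'   is accumulated to.
#' @return Degree-days (numeric, >= 0).
#' @export
cumulative_temp <- function(dates, env_list, target_reach = c("Snake", "Salmon")) {
  target_reach <- match.arg(target_reach)
  need <- c("BON", "MCN", "ICH", if (target_reach == "Salmon") "LGR")
  miss <- need[!need %in% names(dates) |
                 vapply(need, function(s) is.na(dates[[s]]), logical(1))]
  if (length(miss))
    stop("missing intermediate detection at ", paste(miss, collapse = ", "))
  dts <- lapply(need, function(s) as.Date(dates[[s]]))
  names(dts) <- need
  D <- diff(as.numeric(do.call(c, dts)))
  if (any(D < 0)) stop("out-of-order detections (negative leg duration)")
  temps <- vapply(need, function(s) .temp_on(env_list[[s]], dts[[s]]), numeric(1))
  legs <- D * (temps[-length(temps)] + temps[-1L]) / 2
  sum(legs)
}

#' Align weekly fishery catch to a fish's Bonneville passage
#'
#' Returns the Zone 6 weekly harvest for the week containing the fish's
#' first detection at Bonneville Dam, indexing vulnerability to the fishery
#' immediately after passage.
#'
#' @param bon_date `Date` of Bonneville detection.
#' @param catch a [catch_series()].
#' @param week_start_day weekday the week starts on (default `"Monday"`;
#'   must match the convention of the series).
#' @return Weekly catch (numeric).
#' @export
align_catch <- function(bon_date, catch, week_start_day = "Monday") {
  wk <- week_of(bon_date, week_start_day)
  i <- match(wk, catch$week_start)
  if (anyNA(i))
    stop("catch series does not cover week of ",
         paste(format(wk[is.na(i)]), collapse = ", "))
  catch$catch[i]
}

#' Modelling transforms for cumulative temperature and catch
#'
#' Cumulative temperature is log-transformed (with a 1 degree-day offset so a
#' same-day traversal with M = 0 stays finite) to limit the leverage of
#' especially slow fish; weekly catch is cube-root transformed to limit the
#' leverage of a few large openings. Raw values are retained alongside.
#'
#' @param M degree-days, >= 0.
#' @param m0 log offset in degree-days (default 1).
#' @return `log(M + m0)`.
#' @export
transform_M <- function(M, m0 = 1) {
  if (any(M < 0, na.rm = TRUE)) stop("M must be >= 0")
  log(M + m0)
}

#' @rdname transform_M
#' @param C weekly catch, >= 0.
#' @return `C^(1/3)`.
#' @export
transform_C <- function(C) {
  if (any(C < 0, na.rm = TRUE)) stop("C must be >= 0")
  C^(1 / 3)
}

#' Build the per-fish, per-reach survival design table
#'
#' Joins each fish's detections against the environmental series, the catch
#' series and its categorical covariates, producing one row per fish x reach
#' with raw and transformed model covariates and the binary outcome.
#'
#' @param fish a `"fish_table"` (see [read_fish_table()]).
#' @param env_list named list of [env_series()] keyed by site; the Salmon
#'   reach's sites are given by `salmon_roles`.
#' @param catch a [catch_series()] (Columbia reach only; may be `NULL` if the
#'   Columbia reach is excluded).
#' @param salmon_roles mapping of the Salmon reach variables to sites,
#'   default `c(temperature = "SALMON", flow = "SALMON")`.
#' @param reaches which reaches to build (default all three).
#' @param week_start_day catch week convention.
#' @param m0 log offset for the M transform.
#' @return Data frame of class `"design_table"` with columns `fish_id`,
#'   `reach`, `T`, `F`, `M`, `logM`, `C`, `crC`, `P`, `run`, `A`, `H`, `J`,
#'   `y`, `S` (0/1). Fish lacking the needed detections for a reach are
#'   skipped for that reach (counted in attribute `"dropped"`).
#' @export
build_design_table <- function(fish, env_list, catch = NULL,
                               salmon_roles = c(temperature = "SALMON",
                                                flow = "SALMON"),
                               reaches = REACH_NAMES,
                               week_start_day = "Monday", m0 = 1) {
  stopifnot(inherits(fish, "data.frame"))
  entry_col <- c(Columbia = "date_BON", Snake = "date_ICH", Salmon = "date_LGR")
  surv_col <- c(Columbia = "surv_columbia", Snake = "surv_snake",
                Salmon = "surv_salmon")
  dropped <- 0L
  blocks <- list()
  for (sp in unique(fish$species)) {
    rdefs <- default_reaches(sp)
    fsp <- fish[fish$species == sp, , drop = FALSE]
    for (rn in reaches) {
      sel <- !is.na(fsp[[entry_col[rn]]]) &
        fsp[[surv_col[rn]]] != "not_applicable"
      f <- fsp[sel, , drop = FALSE]
      if (!nrow(f)) next
      entry <- f[[entry_col[rn]]]
      if (rn == "Salmon") {
        tf <- .reach_TF(entry, env_list[[salmon_roles["temperature"]]],
                        env_list[[salmon_roles["flow"]]],
                        rdefs[[rn]]$window_days)
      } else {
        e <- env_list[[rdefs[[rn]]$entry_dam]]
        tf <- .reach_TF(entry, e, e, 1L)
      }
      ## cumulative thermal load from dam-passage snapshots (Snake/Salmon)
      M <- rep(NA_real_, nrow(f))
      if (rn != "Columbia") {
        Tb <- .temp_at(env_list$BON, f$date_BON)
        Tm <- .temp_at(env_list$MCN, f$date_MCN)
        Ti <- .temp_at(env_list$ICH, f$date_ICH)
        D1 <- as.numeric(f$date_MCN - f$date_BON)
        D2 <- as.numeric(f$date_ICH - f$date_MCN)
        M <- D1 * (Tb + Tm) / 2 + D2 * (Tm + Ti) / 2
        if (rn == "Salmon") {
          Tl <- .temp_at(env_list$LGR, f$date_LGR)
          D3 <- as.numeric(f$date_LGR - f$date_ICH)
          M <- M + D3 * (Ti + Tl) / 2
        }
        M[!is.na(M) & M < 0] <- NA        # out-of-order detections: exclude
      }
      C <- rep(NA_real_, nrow(f))
      if (rn == "Columbia" && !is.null(catch)) {
        wk <- week_of(f$date_BON, week_start_day)
        C <- catch$catch[match(wk, catch$week_start)]
      }
      ok <- !is.na(tf$T) & !is.na(tf$F)
      if (rn != "Columbia") ok <- ok & !is.na(M)
      if (rn == "Columbia" && !is.null(catch)) ok <- ok & !is.na(C)
      dropped <- dropped + sum(!ok)
      f <- f[ok, , drop = FALSE]
      if (!nrow(f)) next
      blocks[[length(blocks) + 1L]] <- data.frame(
        fish_id = f$fish_id, reach = rn,
        T = tf$T[ok], F = tf$F[ok],
        M = M[ok],
        logM = ifelse(is.na(M[ok]), NA_real_, transform_M(pmax(M[ok], 0), m0)),
        C = C[ok],
        crC = ifelse(is.na(C[ok]), NA_real_, transform_C(pmax(C[ok], 0))),
        P = f$population, run = f$run, A = f$ocean_age,
        H = f$origin, J = f$juv_history, y = f$migration_year,
        S = as.integer(f[[surv_col[rn]]] == "survived"),
        species = sp, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  attr(out, "dropped") <- dropped
  attr(out, "m0") <- m0
  class(out) <- c("design_table", "data.frame")
  out
}

#' Write a design table to CSV
#'
#' @param design a `"design_table"`.
#' @param path output CSV path.
#' @export
write_design_table <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pairwise correlations of continuous design covariates
#'
#' Used as the collinearity screen before model fitting: only covariates
#' with all pairwise correlations below the threshold (0.7 in the survival
#' models) are combined.
#'
#' @param design a `"design_table"` (or any data frame).
#' @param vars continuous covariate columns to screen.
#' @return Symmetric correlation matrix (pairwise complete observations).
#' @export
covariate_correlations <- function(design, vars = c("T", "F", "logM", "crC")) {
  vars <- vars[vars %in% names(design)]
  keep <- vars[vapply(vars, function(v) sum(!is.na(design[[v]])) > 2 &&
                        stats::sd(design[[v]], na.rm = TRUE) > 0, logical(1))]
  stats::cor(design[keep], use = "pairwise.complete.obs")
}
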