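## "New normal" comparison: run-window annual means of temperature and flow,
## skew-normal fits to their interannual distribution, and the frequency of
## years at least as extreme as a reference (e.g. 2015) per scenario.

#' Run window from observed reach-entry dates
#'
#' The migration window for a species/reach: the 5th to 95th percentile of
#' observed reach-entry day-of-year.
#'
#' @param entry_dates `Date` (or day-of-year numeric) reach-entry dates.
#' @param probs quantile pair (default `c(0.05, 0.95)`).
#' @return List of class `"run_window"` with integer `start` and `end`
#'   day-of-year.
#' @export
run_window <- function(entry_dates, probs = c(0.05, 0.95)) {
  doy <- if (inherits(entry_dates, "Date"))
    as.integer(format(entry_dates, "%j")) else as.numeric(entry_dates)
  q <- stats::quantile(doy, probs = probs, names = FALSE)
  out <- list(start = as.integer(floor(q[1])), end = as.integer(ceiling(q[2])))
  if (out$start >= out$end) stop("degenerate run window")
  class(out) <- "run_window"
  out
}

#' Annual run-window means of temperature and flow
#'
#' Arithmetic mean of the daily values inside the run window, per calendar
#' year. Years without complete window coverage are dropped (and named in
#' attribute `"dropped_years"`).
#'
#' @param env an [env_series()].
#' @param window a [run_window()].
#' @return Data frame `year`, `mean_temp`, `mean_flow`.
#' @export
annual_window_means <- function(env, window) {
  yr <- as.integer(format(env$date, "%Y"))
  doy <- as.integer(format(env$date, "%j"))
  sel <- doy >= window$start & doy <= window$end
  years <- sort(unique(yr))
  need <- window$end - window$start + 1L
  rows <- lapply(years, function(y) {
    s <- sel & yr == y
    if (sum(s) < need || anyNA(env$temperature[s]) || anyNA(env$flow[s]))
      return(NULL)
    data.frame(year = y, mean_temp = mean(env$temperature[s]),
               mean_flow = mean(env$flow[s]))
  })
  ok <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[ok])
  attr(out, "dropped_years") <- years[!ok]
  out
}

#' Skew-normal density, distribution and fitting
#'
#' The skew-normal family with location `xi`, scale `omega` and shape
#' `alpha`: density `2/omega * dnorm(z) * pnorm(alpha z)`, `z = (x-xi)/omega`.
#' Shape 0 reduces exactly to the normal distribution. The CDF uses Owen's T
#' function evaluated by numerical quadrature.
#'
#' @param x,q evaluation points.
#' @param xi location.
#' @param omega scale (> 0).
#' @param alpha shape.
#' @return Density / probability values.
#' @export
dskewnorm <- function(x, xi = 0, omega = 1, alpha = 0) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

.owen_t <- function(h, a) {
  ## T(h, a) = 1/(2*pi) * int_0^a exp(-h^2(1+x^2)/2)/(1+x^2) dx
  vapply(seq_along(h), function(i) {
    if (a == 0) return(0)
    f <- function(x) exp(-h[i]^2 * (1 + x^2) / 2) / (1 + x^2)
    sign(a) * stats::integrate(f, 0, abs(a), rel.tol = 1e-10)$value / (2 * pi)
  }, numeric(1))
}

#' @rdname dskewnorm
#' @export
pskewnorm <- function(q, xi = 0, omega = 1, alpha = 0) {
  z <- (q - xi) / omega
  stats::pnorm(z) - 2 * .owen_t(z, alpha)
}

#' @rdname dskewnorm
#' @param values sample to fit (at least 10 values).
#' @return For `fit_skew_normal()`: list of class `"skew_normal_fit"` with
#'   `xi`, `omega`, `alpha`, `logLik`, `method` (`"ML"` or, on optimizer
#'   failure, the flagged `"moments"` fallback).
#' @export
fit_skew_normal <- function(values) {
  if (length(values) < 10) stop("need at least 10 values")
  mom <- .sn_moments(values)
  nll <- function(p) {
    d <- dskewnorm(values, p[1], exp(p[2]), p[3])
    -sum(log(pmax(d, 1e-300)))
  }
  fit <- tryCatch(
    stats::optim(c(mom$xi, log(mom$omega), mom$alpha), nll, method = "BFGS",
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    out <- list(xi = mom$xi, omega = mom$omega, alpha = mom$alpha,
                logLik = -nll(c(mom$xi, log(mom$omega), mom$alpha)),
                method = "moments")
  } else {
    out <- list(xi = fit$par[1], omega = exp(fit$par[2]), alpha = fit$par[3],
                logLik = -fit$value, method = "ML")
  }
  class(out) <- "skew_normal_fit"
  out
}

## method-of-moments start: solve sample skewness for delta
.sn_moments <- function(values) {
  m <- mean(values); s <- stats::sd(values)
  g1 <- mean((values - m)^3) / (mean((values - m)^2))^1.5
  g1 <- max(min(g1, 0.99), -0.99)          # attainable skewness < 0.9953
  skew_of <- function(d) {
    mz <- d * sqrt(2 / pi)
    (4 - pi) / 2 * mz^3 / (1 - mz^2)^1.5
  }
  dmax <- 0.9952
  d <- if (abs(g1) < 1e-8) 0 else {
    f <- function(d) skew_of(d) - abs(g1)
    if (f(dmax) < 0) dmax else stats::uniroot(f, c(1e-6, dmax))$root
  }
  d <- d * sign(g1)
  omega <- s / sqrt(max(1 - 2 * d^2 / pi, 1e-6))
  xi <- m - omega * d * sqrt(2 / pi)
  alpha <- d / sqrt(max(1 - d^2, 1e-6))
  list(xi = xi, omega = omega, alpha = alpha)
}

#' @export
print.skew_normal_fit <- function(x, ...) {
  cat(sprintf("<skew_normal_fit> xi=%.3f omega=%.3f alpha=%.3f (%s)\n",
              x$xi, x$omega, x$alpha, x$method))
  invisible(x)
}

#' Frequency of years at least as extreme as a reference
#'
#' Empirical proportion of annual values meeting the condition (at least as
#' warm: `direction = "ge"`; at least as dry: `direction = "le"`), together
#' with the corresponding tail probability of a fitted skew-normal
#' distribution when supplied.
#'
#' @param values annual window means.
#' @param reference reference value (e.g. the 2015 window mean).
#' @param direction `"ge"` (temperature) or `"le"` (flow).
#' @param fit optional `"skew_normal_fit"`.
#' @return List `empirical` and (if `fit` given) `fitted`, both in \[0, 1\].
#' @export
exceedance_frequency <- function(values, reference,
                                 direction = c("ge", "le"), fit = NULL) {
  direction <- match.arg(direction)
  emp <- if (direction == "ge") mean(values >= reference)
         else mean(values <= reference)
  out <- list(empirical = emp)
  if (!is.null(fit)) {
    p <- pskewnorm(reference, fit$xi, fit$omega, fit$alpha)
    out$fitted <- if (direction == "ge") 1 - p else p
  }
  out
}

#' Exceedance comparison across scenarios
#'
#' For each scenario's environmental series, computes annual run-window
#' means, fits a skew-normal to each variable, and reports the empirical and
#' fitted frequency of years at least as warm (temperature) or at least as
#' dry (flow) as the reference year.
#'
#' @param env_by_scenario named list of [env_series()] (one per scenario,
#'   same site).
#' @param window a [run_window()].
#' @param ref_temp,ref_flow reference window means (inputs; e.g. the
#'   2015-like year's values).
#' @return Data frame: scenario, variable, empirical and fitted frequency,
#'   skew-normal parameters.
#' @export
compare_scenarios <- function(env_by_scenario, window, ref_temp, ref_flow) {
  rows <- list()
  for (sc in names(env_by_scenario)) {
    am <- annual_window_means(env_by_scenario[[sc]], window)
    for (v in c("temp", "flow")) {
      vals <- if (v == "temp") am$mean_temp else am$mean_flow
      ref <- if (v == "temp") ref_temp else ref_flow
      dir <- if (v == "temp") "ge" else "le"
      fit <- fit_skew_normal(vals)
      ex <- exceedance_frequency(vals, ref, dir, fit)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, variable = v, n_years = nrow(am),
        reference = ref, direction = dir,
        empirical = ex$empirical, fitted = ex$fitted,
        xi = fit$xi, omega = fit$omega, alpha = fit$alpha,
        fit_method = fit$method)
    }
  }
  do.call(rbind, rows)
}
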