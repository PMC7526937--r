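## Arrival-day models at the first dam: single Gaussian (sockeye) or a
## two-component Gaussian mixture (spring/summer Chinook), with component
## means driven by annual spring covariates, fit by maximum likelihood and
## selected by AICc over all candidate covariates.

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)}
#'
#' @param loglik maximized log-likelihood.
#' @param k_params number of estimated parameters.
#' @param n sample size; must exceed `k_params + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k_params, n) {
  if (any(n <= k_params + 1))
    stop("AICc undefined: n must exceed k_params + 1")
  -2 * loglik + 2 * k_params + 2 * k_params * (k_params + 1) / (n - k_params - 1)
}

#' Annual spring covariate metrics at the first dam
#'
#' Candidate predictors of arrival timing: all monthly and bimonthly means of
#' temperature and flow during March-June. Bimonthly metrics are means over
#' two consecutive calendar months (Mar-Apr, Apr-May, May-Jun). Flow metrics
#' are expressed in units of 1000 m^3/s so that regression coefficients for
#' temperature (per deg C) and flow are on comparable scales.
#'
#' @param env [env_series()] at the first dam, covering the years of interest
#'   (any scenario).
#' @return Data frame, one row per calendar year, columns `year` plus
#'   `temp_Mar`, ..., `temp_MayJun`, `flow_Mar`, ..., `flow_MayJun`.
#' @export
annual_covariates <- function(env) {
  yr <- as.integer(format(env$date, "%Y"))
  mo <- as.integer(format(env$date, "%m"))
  years <- sort(unique(yr))
  singles <- list(Mar = 3L, Apr = 4L, May = 5L, Jun = 6L)
  pairs <- list(MarApr = c(3L, 4L), AprMay = c(4L, 5L), MayJun = c(5L, 6L))
  windows <- c(singles, pairs)
  out <- data.frame(year = years)
  for (w in names(windows)) {
    sel <- mo %in% windows[[w]]
    out[[paste0("temp_", w)]] <- vapply(years, function(y)
      mean(env$temperature[sel & yr == y]), numeric(1))
    out[[paste0("flow_", w)]] <- vapply(years, function(y)
      mean(env$flow[sel & yr == y]) / 1000, numeric(1))
  }
  out
}

.mix_negll <- function(par, day, E1, E2) {
  ## par: b01, b11, b02, b12, ls1, ls2, lp  (transformed scale)
  mu1 <- par[1] + par[2] * E1
  mu2 <- par[3] + par[4] * E2
  s1 <- exp(par[5]); s2 <- exp(par[6]); p <- stats::plogis(par[7])
  d <- p * stats::dnorm(day, mu1, s1) + (1 - p) * stats::dnorm(day, mu2, s2)
  -sum(log(pmax(d, 1e-300)))
}

#' Fit an arrival-day model
#'
#' Maximum-likelihood fit of arrival day-of-year at the first dam. For
#' `k = 1` (sockeye) the model is a single Gaussian whose annual mean is
#' linear in one covariate, `mu_t = b0 + b1 E_t`, with constant sd. For
#' `k = 2` (Chinook) it is a two-component mixture: each component (spring,
#' summer run) has its own covariate, intercept, slope and sd, plus a pooled
#' mixing weight `p` (proportion spring run). Component membership during
#' fitting is marginal (soft); run labels, if supplied, only initialize and
#' label the components. Components are ordered so that component 1 (spring)
#' has the earlier intercept.
#'
#' @param day numeric day-of-year of arrival per fish.
#' @param year migration year per fish.
#' @param covariates data frame from [annual_covariates()] (or any data frame
#'   with a `year` column and metric columns).
#' @param spec character: metric name for `k = 1`, or length-2 vector
#'   (spring, summer metric) for `k = 2`.
#' @param k number of mixture components, 1 or 2.
#' @param run optional per-fish run labels (`"spring"`/`"summer"`) used to
#'   initialize the `k = 2` fit.
#' @param n_restarts random restarts for the `k = 2` optimizer (default 10).
#' @return Object of class `"arrival_model"`: transformed-scale parameters
#'   `par` with covariance `vcov` (from the numerical information matrix),
#'   natural-scale coefficients via [coef.arrival_model()], `logLik`, `aicc`,
#'   `n`, and the covariate spec. Slopes for covariates with no variation
#'   across years are flagged unidentifiable.
#' @export
fit_arrival <- function(day, year, covariates, spec, k = 1, run = NULL,
                        n_restarts = 10) {
  stopifnot(k %in% c(1, 2), length(day) == length(year))
  spec <- as.character(spec)
  if (length(spec) != k) stop("spec must name ", k, " covariate metric(s)")
  missing_cov <- spec[!spec %in% names(covariates)]
  if (length(missing_cov)) stop("unknown covariate metric: ", missing_cov[1])
  yi <- match(year, covariates$year)
  if (anyNA(yi)) stop("covariates missing for year(s) ",
                      paste(unique(year[is.na(yi)]), collapse = ", "))
  n <- length(day)
  if (k == 1) {
    E <- covariates[[spec]][yi]
    ident <- stats::sd(E) > 0
    X <- if (ident) cbind(1, E) else cbind(rep(1, n))
    qr_ <- qr(X)
    beta <- qr.coef(qr_, day)
    resid <- day - X %*% beta
    sigma <- sqrt(sum(resid^2) / n)          # ML estimate
    if (sigma < 1e-6) stop("degenerate fit: sigma -> 0")
    ll <- sum(stats::dnorm(day, X %*% beta, sigma, log = TRUE))
    b0 <- beta[1]; b1 <- if (ident) beta[2] else NA_real_
    par <- c(b0 = unname(b0), b1 = if (ident) unname(b1) else 0, lsigma = log(sigma))
    ## information-matrix covariance: beta block sigma^2 (X'X)^-1,
    ## var(log sigma) = 1/(2n), asymptotically independent
    XtXi <- chol2inv(qr.R(qr_))
    V <- matrix(0, 3, 3, dimnames = list(names(par), names(par)))
    if (ident) V[1:2, 1:2] <- sigma^2 * XtXi else V[1, 1] <- sigma^2 * XtXi[1, 1]
    V[3, 3] <- 1 / (2 * n)
    npar <- if (ident) 3 else 2
    out <- list(k = 1, par = par, vcov = V, logLik = ll,
                aicc = aicc(ll, npar, n), n = n, n_params = npar,
                spec = spec, identifiable = c(b1 = ident),
                years = sort(unique(year)), covariates = covariates)
    class(out) <- "arrival_model"
    return(out)
  }
  ## k = 2 mixture
  E1 <- covariates[[spec[1]]][yi]
  E2 <- covariates[[spec[2]]][yi]
  ident <- c(stats::sd(E1) > 0, stats::sd(E2) > 0)
  ## initialization: run labels if given, else early/late split at the
  ## median; within each group, year-level OLS on the group's covariate
  lab <- if (!is.null(run)) run == "spring" else day <= stats::median(day)
  grp_init <- function(g, E) {
    if (stats::sd(E[g]) > 0) {
      cf <- stats::coef(stats::lm(day[g] ~ E[g]))
      c(cf[1], cf[2])
    } else c(mean(day[g]), 0)
  }
  init <- function(jit = 0) {
    i1 <- grp_init(lab, E1); i2 <- grp_init(!lab, E2)
    c(i1[1] + stats::rnorm(1, 0, jit), i1[2] * (1 + stats::rnorm(1, 0, jit / 10)),
      i2[1] + stats::rnorm(1, 0, jit), i2[2] * (1 + stats::rnorm(1, 0, jit / 10)),
      log(stats::sd(day[lab]) + 1) + stats::rnorm(1, 0, jit / 20),
      log(stats::sd(day[!lab]) + 1) + stats::rnorm(1, 0, jit / 20),
      stats::qlogis(min(max(mean(lab), 0.05), 0.95)))
  }
  best <- NULL; diagnostics <- character()
  for (r in seq_len(max(1, n_restarts))) {
    p0 <- init(jit = if (r == 1) 0 else 5)
    fit <- tryCatch(
      stats::optim(p0, .mix_negll, day = day, E1 = E1, E2 = E2,
                   method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) { diagnostics <- c(diagnostics, "optim error"); next }
    if (fit$convergence != 0)
      diagnostics <- c(diagnostics, paste("convergence code", fit$convergence))
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best))
    stop("arrival-model optimizer failed to converge: ",
         paste(unique(diagnostics), collapse = "; "))
  par <- best$par
  if (any(exp(par[5:6]) < 1e-3)) stop("degenerate fit: sigma -> 0")
  ## order components by implied mean arrival day: spring = earlier
  mu1_bar <- par[1] + par[2] * mean(E1)
  mu2_bar <- par[3] + par[4] * mean(E2)
  if (mu1_bar > mu2_bar) {
    par <- c(par[3:4], par[1:2], par[6], par[5], -par[7])
    spec <- rev(spec); ident <- rev(ident)
  }
  names(par) <- c("b0_spring", "b1_spring", "b0_summer", "b1_summer",
                  "lsigma_spring", "lsigma_summer", "qlogis_p")
  H <- tryCatch(stats::optimHess(par, .mix_negll, day = day, E1 = E1, E2 = E2),
                error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(V)) V <- diag(1e-6, length(par))
  dimnames(V) <- list(names(par), names(par))
  ll <- -best$value
  npar <- 5 + sum(ident)  # 2 intercepts + 2 sds + weight + identifiable slopes
  out <- list(k = 2, par = par, vcov = V, logLik = ll,
              aicc = aicc(ll, npar, n), n = n, n_params = npar,
              spec = spec, identifiable = stats::setNames(ident, c("b1_spring", "b1_summer")),
              years = sort(unique(year)), covariates = covariates)
  class(out) <- "arrival_model"
  out
}

#' @export
coef.arrival_model <- function(object, ...) {
  p <- object$par
  if (object$k == 1) {
    c(b0 = unname(p["b0"]), b1 = unname(p["b1"]), sigma = unname(exp(p["lsigma"])),
      p = 1)
  } else {
    c(b0_spring = unname(p["b0_spring"]), b1_spring = unname(p["b1_spring"]),
      b0_summer = unname(p["b0_summer"]), b1_summer = unname(p["b1_summer"]),
      sigma_spring = unname(exp(p["lsigma_spring"])),
      sigma_summer = unname(exp(p["lsigma_summer"])),
      p = unname(stats::plogis(p["qlogis_p"])))
  }
}

#' @export
vcov.arrival_model <- function(object, ...) object$vcov

#' @export
logLik.arrival_model <- function(object, ...) {
  structure(object$logLik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
print.arrival_model <- function(x, ...) {
  cat(sprintf("<arrival_model> %d component(s), n = %d, AICc = %.2f\n",
              x$k, x$n, x$aicc))
  cat("  covariate(s):", paste(x$spec, collapse = ", "), "\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.arrival_model <- function(object, ...) {
  se_tr <- sqrt(pmax(diag(object$vcov), 0))
  cat(sprintf("Arrival-day model: %d component(s), n = %d\n", object$k, object$n))
  cat(sprintf("logLik = %.3f,  AICc = %.3f,  params = %d\n",
              object$logLik, object$aicc, object$n_params))
  tab <- data.frame(estimate = object$par, se = se_tr)
  print(round(tab, 4))
  invisible(object)
}

## component means for given covariate values; cov_values is a data frame
## with the spec metric columns (one row per year to predict)
.arrival_means <- function(model, cov_values) {
  cf <- coef(model)
  if (model$k == 1) {
    cbind(mu = cf["b0"] + cf["b1"] * cov_values[[model$spec]])
  } else {
    cbind(mu_spring = cf["b0_spring"] + cf["b1_spring"] * cov_values[[model$spec[1]]],
          mu_summer = cf["b0_summer"] + cf["b1_summer"] * cov_values[[model$spec[2]]])
  }
}

#' Mixture density, CDF and quantiles of predicted arrival days
#'
#' `predict()` on an arrival model returns, for the supplied annual covariate
#' values, the per-year component means (`type = "mean"`), the pooled mixture
#' density over a day grid (`type = "density"`), or pooled quantiles obtained
#' by numerically inverting the average-over-years mixture CDF
#' (`type = "quantile"`).
#'
#' @param object an `"arrival_model"`.
#' @param newdata data frame with the model's covariate metric columns (one
#'   row per year). Defaults to the fitting covariate table restricted to
#'   the fitted years.
#' @param type `"mean"`, `"density"` or `"quantile"`.
#' @param probs quantile probabilities (for `type = "quantile"`).
#' @param grid day grid (for `type = "density"`).
#' @param ... unused.
#' @return Matrix of means, data frame `day`/`density`, or named quantile
#'   vector.
#' @export
predict.arrival_model <- function(object, newdata = NULL,
                                  type = c("mean", "density", "quantile"),
                                  probs = (1:99) / 100,
                                  grid = seq(60, 300, by = 0.25), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    newdata <- object$covariates[object$covariates$year %in% object$years, ,
                                 drop = FALSE]
  mu <- .arrival_means(object, newdata)
  cf <- coef(object)
  mix_cdf <- function(q) {
    if (object$k == 1) {
      rowMeans(outer(q, mu[, 1], function(a, b) stats::pnorm(a, b, cf["sigma"])))
    } else {
      p <- cf["p"]
      rowMeans(outer(q, seq_len(nrow(mu)), function(a, j)
        p * stats::pnorm(a, mu[j, 1], cf["sigma_spring"]) +
          (1 - p) * stats::pnorm(a, mu[j, 2], cf["sigma_summer"])))
    }
  }
  if (type == "mean") return(mu)
  if (type == "density") {
    dd <- if (object$k == 1) {
      rowMeans(outer(grid, mu[, 1], function(a, b) stats::dnorm(a, b, cf["sigma"])))
    } else {
      p <- cf["p"]
      rowMeans(outer(grid, seq_len(nrow(mu)), function(a, j)
        p * stats::dnorm(a, mu[j, 1], cf["sigma_spring"]) +
          (1 - p) * stats::dnorm(a, mu[j, 2], cf["sigma_summer"])))
    }
    return(data.frame(day = grid, density = dd))
  }
  ## quantiles: invert the pooled CDF on a fine grid
  cdf <- mix_cdf(grid)
  q <- stats::approx(cdf, grid, xout = probs, ties = "ordered", rule = 2)$y
  stats::setNames(q, paste0(probs * 100, "%"))
}

#' Simulate arrival days from a fitted (or truth) arrival model
#'
#' For each fish, a component is drawn Bernoulli(p) and a day drawn from
#' `N(mu_{k,t}, sigma_k)`; real-valued days are returned with a rounded
#' integer copy.
#'
#' @param object an `"arrival_model"`.
#' @param nsim fish per year.
#' @param seed optional RNG seed.
#' @param newdata data frame of annual covariate values, one row per year
#'   (with a `year` column, otherwise years are numbered).
#' @param ... unused.
#' @return Data frame `year`, `day` (real), `day_int`, `component`
#'   (`"spring"`/`"summer"`, `"single"` for k = 1).
#' @export
simulate.arrival_model <- function(object, nsim = 1, seed = NULL,
                                   newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata))
    newdata <- object$covariates[object$covariates$year %in% object$years, ,
                                 drop = FALSE]
  mu <- .arrival_means(object, newdata)
  cf <- coef(object)
  yrs <- if ("year" %in% names(newdata)) newdata$year else seq_len(nrow(newdata))
  out <- lapply(seq_len(nrow(mu)), function(j) {
    if (object$k == 1) {
      d <- stats::rnorm(nsim, mu[j, 1], cf["sigma"])
      comp <- rep("single", nsim)
    } else {
      spring <- stats::runif(nsim) < cf["p"]
      d <- ifelse(spring,
                  stats::rnorm(nsim, mu[j, 1], cf["sigma_spring"]),
                  stats::rnorm(nsim, mu[j, 2], cf["sigma_summer"]))
      comp <- ifelse(spring, "spring", "summer")
    }
    data.frame(year = yrs[j], day = d, day_int = round(d), component = comp)
  })
  do.call(rbind, out)
}

#' Select the best-supported arrival model by AICc
#'
#' Fits one model per candidate covariate metric (`k = 1`) or per ordered
#' pair of metrics (`k = 2`: one covariate for the spring component, one for
#' the summer component) and returns the lowest-AICc fit together with the
#' full ranking table. Ties are broken by candidate order (stable minimum).
#'
#' @inheritParams fit_arrival
#' @param candidates metric names to consider; defaults to every non-`year`
#'   column of `covariates`.
#' @return The winning `"arrival_model"`, with the ranking table (data frame
#'   of spec, logLik, AICc, dAICc) attached as `$ranking`.
#' @export
select_arrival_model <- function(day, year, covariates, k = 1, run = NULL,
                                 candidates = setdiff(names(covariates), "year"),
                                 n_restarts = 10) {
  specs <- if (k == 1) as.list(candidates) else {
    g <- expand.grid(spring = candidates, summer = candidates,
                     stringsAsFactors = FALSE)
    split(as.matrix(g), seq_len(nrow(g)))
  }
  fits <- lapply(specs, function(sp)
    tryCatch(fit_arrival(day, year, covariates, spec = as.character(sp), k = k,
                         run = run, n_restarts = n_restarts),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all arrival-model candidate fits failed")
  aiccs <- vapply(fits[ok], function(f) f$aicc, numeric(1))
  ranking <- data.frame(
    spec = vapply(specs[ok], function(sp) paste(sp, collapse = "+"), character(1)),
    logLik = vapply(fits[ok], function(f) f$logLik, numeric(1)),
    AICc = aiccs)
  ranking$dAICc <- ranking$AICc - min(ranking$AICc)
  ord <- order(ranking$AICc)
  best <- fits[ok][[which.min(aiccs)]]     # stable: first minimum in candidate order
  best$ranking <- ranking[ord, ]
  rownames(best$ranking) <- NULL
  best
}

#' Quantile-quantile correlation of predicted vs observed arrivals
#'
#' Pearson correlation between model-predicted pooled arrival-day quantiles
#' and the empirical quantiles of observed arrival days (percentiles 1-99,
#' pooled across years) — the adequacy statistic reported for the arrival
#' models (0.97 sockeye, 0.93 Chinook on the observation data).
#'
#' @param model an `"arrival_model"`.
#' @param day,year observed arrival days with year labels.
#' @param newdata optional covariate table (defaults to the fitted years).
#' @param probs percentile grid.
#' @return Pearson correlation (numeric).
#' @export
arrival_qq_correlation <- function(model, day, year, newdata = NULL,
                                   probs = (1:99) / 100) {
  pred_q <- predict(model, newdata = newdata, type = "quantile", probs = probs)
  obs_q <- stats::quantile(day, probs = probs, names = FALSE)
  stats::cor(pred_q, obs_q)
}
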