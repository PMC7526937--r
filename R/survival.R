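## Binomial spline-smoother survival models per species/reach, with
## all-subsets AICc selection, prediction with the year effect zeroed, and
## AUC goodness of fit. Spline machinery is delegated to mgcv; the reach
## rules, collinearity prefilter, dredge and hull flagging live here.

## design-table column carrying each model term (C and M enter on their
## transformed scales)
SMOOTH_COLS <- c(T = "T", F = "F", C = "crC", M = "logM")
SMOOTH_KNOTS <- c(T = 4L, F = 4L, C = 3L, M = 3L)
FACTOR_COLS <- c(P = "P", A = "A", J = "J", H = "H")

#' Thin-plate regression spline basis
#'
#' Low-rank penalized spline basis of the stated dimension with the
#' sum-to-zero identifiability constraint absorbed. The penalty is positive
#' semidefinite with null space spanned by linear functions, so an infinitely
#' penalized smooth is a straight line.
#'
#' @param x covariate values (at least `dim` distinct values).
#' @param dim basis dimension (number of knots in the model's vocabulary;
#'   4 for temperature and flow, 3 for catch and cumulative temperature).
#' @return List with the model matrix `X` (n x (dim-1) after constraint),
#'   penalty matrix `S`, and the mgcv smooth object `smooth` for reuse.
#' @export
spline_basis <- function(x, dim) {
  if (dim < 3) stop("basis dimension must be at least 3")
  if (length(unique(x)) < dim)
    stop("need at least ", dim, " distinct covariate values")
  sm <- mgcv::smoothCon(mgcv::s(x, k = dim, bs = "tp"),
                        data = data.frame(x = x), absorb.cons = TRUE)[[1]]
  list(X = sm$X, S = sm$S[[1]], smooth = sm)
}

#' Mann-Whitney AUC
#'
#' Probability that a randomly chosen survivor received a higher predicted
#' survival probability than a randomly chosen fish that died; ties count
#' one half (midrank form of the Mann-Whitney statistic).
#'
#' @param predicted predicted probabilities (any monotone score works).
#' @param observed binary outcomes (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(predicted, observed) {
  observed <- as.integer(observed)
  n1 <- sum(observed == 1); n0 <- sum(observed == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both outcome classes required")
  r <- rank(predicted)            # midranks handle ties as 1/2
  (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.resolve_terms <- function(terms, table) {
  unknown <- setdiff(terms, names(table))
  if (length(unknown)) stop("unknown model term(s): ",
                            paste(unknown, collapse = ", "))
  table[terms]
}

.check_reach_rules <- function(species, reach, smooth_terms, factor_terms) {
  if ("C" %in% smooth_terms && reach != "Columbia")
    stop("catch (C) is considered only in the Columbia reach")
  if ("M" %in% smooth_terms && reach == "Columbia")
    stop("cumulative temperature (M) is considered only in Snake/Salmon reaches")
  if (species == "sockeye" && any(c("P", "H") %in% factor_terms))
    stop("P and H are not considered for sockeye (single hatchery population)")
}

#' Fit a binomial spline survival model for one species/reach
#'
#' Penalized binomial GAMM of per-fish reach survival: thin-plate smooths of
#' the continuous covariates (knots 4 for T and F, 3 for C and M, the latter
#' two entering on cube-root and log scales respectively), categorical
#' factors, and migration year as a Gaussian random intercept (penalized
#' factor smooth, `bs = "re"`), with smoothing parameters selected by REML.
#' Continuous covariates may only be combined when all pairwise correlations
#' are below 0.7.
#'
#' @param design a `"design_table"` (rows for one species and reach).
#' @param smooth_terms subset of `c("T","F","C","M")`.
#' @param factor_terms subset of `c("P","A","J","H")`.
#' @param species,reach used to enforce the reach rules; taken from the
#'   design rows when omitted.
#' @param knots named basis dimensions (defaults: T=4, F=4, C=3, M=3).
#' @param cor_threshold collinearity limit for combined smooths (0.7).
#' @param sp_method smoothing-parameter criterion, `"REML"` (default) or
#'   `"GCV.Cp"`.
#' @return Object of class `"survival_model"` wrapping the mgcv fit, with
#'   the term set, effective degrees of freedom, AICc, AUC on the fitting
#'   data, the observed (T, F) convex hull for extrapolation flagging, and
#'   coefficient covariance.
#' @export
fit_survival <- function(design, smooth_terms = c("T", "F"),
                         factor_terms = character(), species = NULL,
                         reach = NULL, knots = SMOOTH_KNOTS,
                         cor_threshold = 0.7, sp_method = "REML") {
  species <- species %||% unique(design$species)[1]
  reach <- reach %||% unique(design$reach)[1]
  .check_reach_rules(species, reach, smooth_terms, factor_terms)
  scols <- .resolve_terms(smooth_terms, SMOOTH_COLS)
  fcols <- .resolve_terms(factor_terms, FACTOR_COLS)
  S <- design$S
  if (any(!S %in% c(0, 1))) stop("outcome S must be binary")
  if (length(unique(S)) < 2)
    stop("separation: all fish share one outcome; model unidentifiable")
  ## collinearity prefilter among included continuous covariates
  if (length(scols) > 1) {
    cm <- stats::cor(design[unname(scols)], use = "pairwise.complete.obs")
    cm[upper.tri(cm, diag = TRUE)] <- 0
    bad <- which(abs(cm) >= cor_threshold, arr.ind = TRUE)
    if (nrow(bad))
      stop("correlation rule violated (|r| >= ", cor_threshold, "): ",
           rownames(cm)[bad[1, 1]], " ~ ", colnames(cm)[bad[1, 2]],
           sprintf(" (r = %.2f)", cm[bad[1, , drop = FALSE]]))
  }
  dat <- as.data.frame(design)
  dat$year_f <- factor(dat$y)
  for (fc in fcols) dat[[fc]] <- .code_factor(fc, dat[[fc]])
  sm_bits <- sprintf("s(%s, k = %d)", scols, knots[smooth_terms])
  fa_bits <- unname(fcols)
  rhs <- paste(c(sm_bits, fa_bits, "s(year_f, bs = \"re\")"), collapse = " + ")
  form <- stats::as.formula(paste("S ~", rhs))
  fit <- mgcv::gam(form, family = stats::binomial(), data = dat,
                   method = sp_method, select = FALSE)
  beta <- stats::coef(fit)
  if (max(abs(beta[!grepl("year_f", names(beta))])) > 50)
    stop("separation: diverging coefficients (|beta| > 50)")
  ll <- stats::logLik(fit)
  k_eff <- attr(ll, "df")                        # effective df incl. random effect
  n <- stats::nobs(fit)
  hull <- if (all(c("T", "F") %in% smooth_terms)) .hull_tf(dat$T, dat$F) else NULL
  out <- list(fit = fit, species = species, reach = reach,
              smooth_terms = smooth_terms, factor_terms = factor_terms,
              knots = knots[smooth_terms], formula = form,
              edf = k_eff, n = n, logLik = as.numeric(ll),
              aicc = aicc(as.numeric(ll), k_eff, n),
              auc = auc(stats::fitted(fit), dat$S),
              hull = hull, xlevels = lapply(dat[unname(fcols)], levels),
              year_levels = levels(dat$year_f))
  class(out) <- "survival_model"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ocean age coded as unordered factor 1 / 2 / 3+
.code_factor <- function(name, x) {
  if (name == "A") {
    lv <- ifelse(as.numeric(x) >= 3, "3+", as.character(x))
    factor(lv, levels = intersect(c("1", "2", "3+"), unique(lv)))
  } else factor(x)
}

.hull_tf <- function(T, F) {
  pts <- cbind(T, F)
  h <- grDevices::chull(pts)
  rbind(pts[h, , drop = FALSE], pts[h[1], , drop = FALSE])  # closed loop
}

#' @export
print.survival_model <- function(x, ...) {
  cat(sprintf("<survival_model> %s / %s reach, n = %d\n", x$species, x$reach, x$n))
  cat("  terms: ",
      paste(c(sprintf("s(%s)", x$smooth_terms), x$factor_terms, "y"),
            collapse = " + "), "\n", sep = "")
  cat(sprintf("  edf = %.1f, AICc = %.2f, AUC = %.3f\n", x$edf, x$aicc, x$auc))
  invisible(x)
}

#' @export
summary.survival_model <- function(object, ...) summary(object$fit, ...)

#' @export
coef.survival_model <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.survival_model <- function(object, ...) stats::vcov(object$fit)

#' @export
logLik.survival_model <- function(object, ...) stats::logLik(object$fit)

## linear-predictor matrix with the year random-effect columns zeroed
.lpmatrix_yearzero <- function(model, newdata) {
  nd <- as.data.frame(newdata)
  for (fc in names(model$xlevels)) {
    if (!fc %in% names(nd)) stop("missing factor column ", fc, " in newdata")
    if (fc == "A") {                       # apply the 3+ age pooling
      v <- as.character(nd[[fc]])
      num <- suppressWarnings(as.numeric(v))
      v[!is.na(num) & num >= 3] <- "3+"
      nd[[fc]] <- v
    }
    bad <- setdiff(unique(as.character(nd[[fc]])), model$xlevels[[fc]])
    if (length(bad)) stop("unknown factor level for ", fc, ": ",
                          paste(bad, collapse = ", "))
    nd[[fc]] <- factor(nd[[fc]], levels = model$xlevels[[fc]])
  }
  nd$year_f <- factor(model$year_levels[1], levels = model$year_levels)
  X <- stats::predict(model$fit, newdata = nd, type = "lpmatrix")
  yr_cols <- grep("s\\(year_f\\)", colnames(X))
  X[, yr_cols] <- 0
  X
}

#' Predict survival probability with the year effect zeroed
#'
#' Projection-mode prediction: the Gaussian year random intercept is set to
#' zero (its basis columns are dropped from the linear predictor), so
#' predictions reflect average-year conditions. Predictions outside the
#' convex hull of the observed (T, F) pairs are flagged as extrapolation.
#'
#' @param model a `"survival_model"`.
#' @param newdata data frame with the model's covariate columns (design-table
#'   naming: `T`, `F`, `crC`, `logM`, factors as fitted).
#' @param year_effect additive year offset on the logit scale (default 0).
#' @param beta optional coefficient vector overriding the fitted one (used by
#'   the projection's parameter-uncertainty draws).
#' @return Numeric vector of probabilities in \[0, 1\], with logical
#'   attribute `"outside_hull"` when the model tracks a (T, F) hull.
#' @export
predict_survival <- function(model, newdata, year_effect = 0, beta = NULL) {
  X <- .lpmatrix_yearzero(model, newdata)
  b <- beta %||% stats::coef(model$fit)
  eta <- drop(X %*% b) + year_effect
  p <- stats::plogis(eta)
  if (!is.null(model$hull) && all(c("T", "F") %in% names(newdata))) {
    inside <- mgcv::in.out(model$hull, cbind(newdata$T, newdata$F))
    attr(p, "outside_hull") <- !inside
  }
  p
}

#' All-subsets AICc selection of survival-model terms
#'
#' Fits every subset of the global term set (smooths enter or leave whole;
#' the year random intercept is always included; the null model is the
#' intercept-plus-year model), ranks by AICc with k equal to the model's
#' effective degrees of freedom, and — following the parsimony rule — selects
#' among all models with dAICc < 2 the one with fewest terms, breaking ties
#' by fewest effective df and then by lexicographic term order.
#'
#' @inheritParams fit_survival
#' @param smooth_terms,factor_terms the global term sets.
#' @return Object of class `"survival_selection"`: `$model` (the selected
#'   `"survival_model"`) and `$ranking` (terms, n_terms, edf, logLik, AICc,
#'   dAICc, AUC, with the null model included).
#' @export
dredge_select <- function(design, smooth_terms = c("T", "F"),
                          factor_terms = character(), species = NULL,
                          reach = NULL, ...) {
  all_terms <- c(smooth_terms, factor_terms)
  n_all <- length(all_terms)
  subsets <- lapply(0:(2^n_all - 1), function(m)
    all_terms[bitwAnd(m, bitwShiftL(1, seq_len(n_all) - 1)) > 0])
  fits <- vector("list", length(subsets))
  labels <- character(length(subsets))
  for (i in seq_along(subsets)) {
    st <- intersect(subsets[[i]], smooth_terms)
    ft <- intersect(subsets[[i]], factor_terms)
    labels[i] <- if (length(subsets[[i]]) == 0) "null" else
      paste(c(sprintf("s(%s)", st), ft, "y"), collapse = " + ")
    fits[[i]] <- tryCatch(
      fit_survival(design, smooth_terms = st, factor_terms = ft,
                   species = species, reach = reach, ...),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no survival-model subset converged")
  fits <- fits[ok]; subsets <- subsets[ok]; labels <- labels[ok]
  ranking <- data.frame(
    terms = labels,
    n_terms = lengths(subsets),
    edf = vapply(fits, function(f) f$edf, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    AUC = vapply(fits, function(f) f$auc, numeric(1)))
  ranking$dAICc <- ranking$AICc - min(ranking$AICc)
  cand <- which(ranking$dAICc < 2)
  cand <- cand[order(ranking$n_terms[cand], ranking$edf[cand],
                     ranking$terms[cand])]
  best_i <- cand[1]
  ord <- order(ranking$AICc)
  out <- list(model = fits[[best_i]],
              ranking = ranking[ord, c("terms", "n_terms", "edf", "logLik",
                                       "AICc", "dAICc", "AUC")])
  rownames(out$ranking) <- NULL
  class(out) <- "survival_selection"
  out
}

#' @export
print.survival_selection <- function(x, ...) {
  cat("<survival_selection> selected:\n")
  print(x$model)
  cat("top of ranking:\n")
  print(utils::head(x$ranking, 5), digits = 4)
  invisible(x)
}

#' Write a model-selection ranking table to CSV
#'
#' @param selection a `"survival_selection"`.
#' @param path output CSV path.
#' @export
write_ranking <- function(selection, path) {
  utils::write.csv(selection$ranking, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
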