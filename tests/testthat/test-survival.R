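test_that("thin-plate basis has PSD penalty with a linear null space", {
  set.seed(1)
  x <- runif(200, 0, 10)
  b <- spline_basis(x, 4)
  expect_equal(ncol(b$X), 3)            # dim - 1 after sum-to-zero constraint
  S <- b$S
  expect_equal(S, t(S), tolerance = 1e-10)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  expect_equal(sum(ev < 1e-8 * max(ev)), 1)  # one unpenalized (linear) direction
  # the unpenalized direction reproduces a straight line in x
  null_vec <- eigen(S, symmetric = TRUE)$vectors[, which.min(ev)]
  line <- b$X %*% null_vec
  expect_gt(abs(cor(line, x)), 0.999)
  expect_error(spline_basis(rep(1:3, 10), 4), "distinct")
})

test_that("dense-knot basis reproduces a cubic; low-rank error is bounded", {
  x <- seq(0, 1, length.out = 400)
  f <- 1 - 3 * x + 2 * x^3
  fit_err <- function(dim) {
    B <- spline_basis(x, dim)$X
    X <- cbind(1, B)
    max(abs(f - X %*% qr.coef(qr(X), f)))
  }
  expect_lt(fit_err(20), 5e-3)          # dense-knot oracle: near-exact
  expect_lt(fit_err(4), 0.1)            # the survival models' resolution
  expect_gt(fit_err(4), fit_err(20))
})

test_that("AUC equals the Mann-Whitney concordance with half ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  p <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9)
  y <- c(0, 0, 1, 1, 0, 1)
  expect_equal(auc(p, y), auc_bruteforce(p, y))
  set.seed(4)
  for (i in 1:5) {
    p <- round(runif(40), 1); y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(p, y), auc_bruteforce(p, y))
  }
  expect_error(auc(runif(5), rep(1, 5)), "both outcome classes")
})

test_that("binomial spline fit recovers a logistic-linear truth", {
  set.seed(9)
  n <- 5000
  d <- data.frame(T = runif(n, 8, 22), F = rnorm(n, 3000, 600),
                  A = sample(1:3, n, TRUE),
                  J = sample(c("transported", "in_river"), n, TRUE),
                  H = "hatchery", y = sample(2004:2009, n, TRUE),
                  species = "sockeye", reach = "Columbia")
  eta <- 2.2 - 0.25 * (d$T - 15) - 0.8 * (d$J == "transported")
  d$S <- rbinom(n, 1, plogis(eta))
  m <- fit_survival(d, smooth_terms = c("T", "F"), factor_terms = "J",
                    species = "sockeye", reach = "Columbia")
  nd <- data.frame(T = seq(10, 20, 0.5), F = 3000, J = "in_river")
  p <- predict_survival(m, nd)
  eta_hat <- qlogis(as.numeric(p))
  slope <- coef(lm(eta_hat ~ nd$T))[2]
  expect_equal(unname(slope), -0.25, tolerance = 0.05)
  # transport coefficient recovered
  expect_equal(unname(coef(m)["Jtransported"]), -0.8, tolerance = 0.2)
})

test_that("degenerate outcomes and collinear covariates are rejected", {
  coh <- sockeye_cohort()
  d <- attr(coh, "design")
  dc <- d[d$reach == "Columbia", ][1:500, ]
  dc$S <- 1L
  expect_error(fit_survival(dc, smooth_terms = "T", species = "sockeye",
                            reach = "Columbia"), "separation")
  dup <- d[d$reach == "Snake", ]
  dup$F <- dup$T * 3 + rnorm(nrow(dup), 0, 0.01)  # engineered collinearity
  expect_error(fit_survival(dup, smooth_terms = c("T", "F"),
                            species = "sockeye", reach = "Snake"),
               "correlation rule")
})

test_that("reach rules restrict catch, thermal load and sockeye factors", {
  coh <- sockeye_cohort()
  d <- attr(coh, "design")
  expect_error(fit_survival(d[d$reach == "Snake", ], smooth_terms = c("T", "C"),
                            species = "sockeye", reach = "Snake"),
               "Columbia")
  expect_error(fit_survival(d[d$reach == "Columbia", ], smooth_terms = c("T", "M"),
                            species = "sockeye", reach = "Columbia"),
               "Snake/Salmon")
  expect_error(fit_survival(d[d$reach == "Columbia", ], smooth_terms = "T",
                            factor_terms = "H", species = "sockeye",
                            reach = "Columbia"), "sockeye")
})

test_that("projection-mode prediction zeroes the year effect and flags hull", {
  set.seed(10)
  n <- 2000
  d <- data.frame(T = runif(n, 10, 20), F = runif(n, 1000, 5000),
                  J = "in_river", H = "hatchery", A = 2,
                  y = sample(2004:2008, n, TRUE),
                  species = "sockeye", reach = "Columbia")
  d$S <- rbinom(n, 1, 0.5)
  m <- fit_survival(d, smooth_terms = c("T", "F"), species = "sockeye",
                    reach = "Columbia")
  ## intercept-only signal: probability near 0.5 everywhere
  p <- predict_survival(m, data.frame(T = 15, F = 3000))
  expect_equal(as.numeric(p), 0.5, tolerance = 0.05)
  ## equals the mgcv route that excludes the year smooth (oracle cross-check)
  nd <- data.frame(T = c(12, 18), F = c(2000, 4000),
                   year_f = factor(2004, levels = 2004:2008))
  p_pkg <- predict_survival(m, nd)
  p_mgcv <- as.numeric(predict(m$fit, newdata = nd, type = "response",
                               exclude = "s(year_f)"))
  expect_equal(as.numeric(p_pkg), p_mgcv, tolerance = 1e-9)
  ## hull flag agrees with an independent ray-casting point-in-polygon test
  nd2 <- data.frame(T = c(15, 40, 9, 25), F = c(3000, 3000, 6000, 10))
  flag <- attr(predict_survival(m, nd2), "outside_hull")
  ray_cast <- function(pt, poly) {
    j <- nrow(poly); inside <- FALSE
    for (i in seq_len(nrow(poly))) {
      if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
          pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
            (poly[j, 2] - poly[i, 2]) + poly[i, 1])
        inside <- !inside
      j <- i
    }
    inside
  }
  poly <- m$hull[-nrow(m$hull), ]
  oracle <- !apply(as.matrix(nd2), 1, ray_cast, poly = poly)
  expect_equal(unname(flag), unname(oracle))
  ## unknown factor level -> error
  d$J <- sample(c("transported", "in_river"), nrow(d), TRUE)
  m2 <- fit_survival(d, smooth_terms = "T", factor_terms = "J",
                     species = "sockeye", reach = "Columbia")
  expect_error(predict_survival(m2, data.frame(T = 15, J = "flown")),
               "unknown factor level")
})

test_that("all-subsets AICc selection ranks and picks parsimoniously", {
  coh <- sockeye_cohort()
  d <- attr(coh, "design")
  dc <- d[d$reach == "Columbia", ]
  dc <- dc[sample.int(nrow(dc), 2500), ]
  sel <- dredge_select(dc, smooth_terms = c("T", "C"), factor_terms = "J",
                       species = "sockeye", reach = "Columbia")
  rk <- sel$ranking
  expect_true("null" %in% rk$terms)                  # null always ranked
  expect_equal(nrow(rk), 8)                          # 2^3 subsets
  expect_lte(sel$model$aicc, min(rk$AICc) + 2)
  expect_lte(sel$model$aicc, rk$AICc[rk$terms == "null"])
  # parsimony rule: no model with fewer terms within 2 AICc of the best
  cand <- rk[rk$dAICc < 2, ]
  expect_equal(length(sel$model$smooth_terms) + length(sel$model$factor_terms),
               min(cand$n_terms))
  # single-term candidate space: that term vs null only
  sel1 <- dredge_select(dc, smooth_terms = "T", species = "sockeye",
                        reach = "Columbia")
  expect_equal(nrow(sel1$ranking), 2)
})

test_that("fitted-model AUC approaches the generator's Bayes AUC", {
  coh <- sockeye_cohort()
  d <- attr(coh, "design")
  dc <- d[d$reach == "Columbia", ]
  m <- fit_survival(dc, smooth_terms = c("T", "C"), factor_terms = c("A", "J"),
                    species = "sockeye", reach = "Columbia")
  b_auc <- bayes_auc(dc$p_true, dc$S)
  expect_equal(m$auc, b_auc, tolerance = 0.02)
})
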