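# simulated PROMIS-like covariates shared across the fitting tests
gamlss_testdata <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(ph_t = rnorm(n, 45, 8), mh_t = rnorm(n, 47, 8),
                 pi_t = rnorm(n, 55, 8))
}

test_that("constant-parameter data are recovered with linear smooths", {
  dat <- gamlss_testdata(500, 61)
  mu0 <- 30; sig0 <- 0.15; nu0 <- 0.5
  dat$y <- rbccg(nrow(dat), mu0, sig0, nu0)
  fit <- fit_gamlss_bccg(dat, "y", spline = pb_spec(lambda = Inf))
  expect_lt(abs(fit$mu$intercept - mu0), 3 * fit$mu$intercept_se)
  expect_lt(abs(fit$sigma$intercept - log(sig0)),
            3 * fit$sigma$intercept_se)
  expect_lt(abs(fit$nu$estimate - nu0), 3 * fit$nu$se)
  expect_true(all(diff(fit$trace) <= 1e-6))
  expect_true(fit$converged)
})

test_that("the fit matches a direct-optimization oracle for linear predictors", {
  dat <- gamlss_testdata(400, 62)
  dat$y <- rbccg(nrow(dat), 25 + 0.2 * (dat$ph_t - 45), 0.2, 0)
  fit <- fit_gamlss_bccg(dat, "y", spline = pb_spec(lambda = Inf))
  # oracle: generic numerical maximization of the same likelihood over the
  # linear-predictor parameterization the infinite penalty enforces
  xs <- scale(cbind(dat$ph_t, dat$mh_t, dat$pi_t), scale = FALSE)
  nll <- function(p) {
    mu <- p[1] + xs %*% p[2:4]
    if (any(mu <= 0)) return(1e10)
    -sum(dbccg(dat$y, mu, exp(p[5] + xs[, 3] * p[6]), p[7], log = TRUE))
  }
  o <- optim(c(mean(dat$y), 0, 0, 0, log(0.2), 0, 0), nll,
             method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(abs(2 * o$value - fit$deviance), 1e-3)
  # nu of lognormal data sits near 0
  expect_lt(abs(fit$nu$estimate), 3 * fit$nu$se)
})

test_that("an auto-smoothed fit recovers a sinusoidal location effect", {
  dat <- gamlss_testdata(1000, 63)
  ftrue <- function(x) 30 + 5 * sin(x / 5)
  dat$y <- rbccg(nrow(dat), ftrue(dat$pi_t), 0.08, 1)
  fit <- fit_gamlss_bccg(dat, "y", spline = pb_spec(lambda = "auto"))
  grid <- tibble::tibble(
    pi_t = seq(quantile(dat$pi_t, 0.02), quantile(dat$pi_t, 0.98),
               length.out = 60),
    ph_t = mean(dat$ph_t), mh_t = mean(dat$mh_t))
  pr <- predict(fit, grid)
  expect_gt(cor(pr$mu, ftrue(grid$pi_t)), 0.95)
  expect_true(all(diff(fit$trace) <= 1e-6))
  # edf bounded by basis size, at least the penalty null space
  expect_true(all(fit$mu$edf <= 24 + 1e-6))
  expect_true(all(fit$mu$edf >= 1 - 1e-6))
})

test_that("prediction reproduces training fits, keeps sigma positive, refuses far extrapolation", {
  dat <- gamlss_testdata(200, 64)
  dat$y <- rbccg(nrow(dat), 30, 0.1, 1)
  fit <- fit_gamlss_bccg(dat, "y", spline = pb_spec(lambda = 1))
  pr <- predict(fit, dat)
  expect_equal(pr$mu, fit$fitted$mu, tolerance = 1e-8)
  expect_equal(pr$sigma, fit$fitted$sigma, tolerance = 1e-8)
  expect_true(all(pr$sigma > 0))
  far <- dat[1, ]
  far$pi_t <- max(dat$pi_t) + 0.2 * diff(range(dat$pi_t))
  expect_error(predict(fit, far), "extrapolation")
})

test_that("predicted centiles are calibrated on simulated data", {
  dat <- gamlss_testdata(2000, 65)
  dat$y <- rbccg(nrow(dat), 28 + 0.3 * (dat$pi_t - 55), 0.12, 0.8)
  fit <- fit_gamlss_bccg(dat, "y", spline = pb_spec(lambda = Inf))
  q10 <- predict_centile(fit, dat, p = 0.1)
  expect_lt(abs(mean(dat$y < q10) - 0.10), 0.02)
})

test_that("recovery error of the location intercept shrinks with sample size", {
  err_at <- function(n, reps, seed0) {
    vapply(seq_len(reps), function(r) {
      dat <- gamlss_testdata(n, seed0 + r)
      dat$y <- rbccg(n, 30, 0.15, 0.5)
      f <- fit_gamlss_bccg(dat, "y", spline = pb_spec(lambda = Inf))
      abs(f$mu$intercept - 30)
    }, numeric(1))
  }
  e_small <- median(err_at(150, 12, 660))
  e_large <- median(err_at(1200, 12, 760))
  expect_lt(e_large, e_small)
})

test_that("degenerate inputs are rejected with informative errors", {
  dat <- gamlss_testdata(30, 67)
  dat$y <- rbccg(30, 20, 0.1, 0)
  dat$y[5] <- -1
  expect_error(fit_gamlss_bccg(dat, "y"), "positive gait values")
  expect_error(fit_gamlss_bccg(dat[1:10, ], "y"), "at least 20")
  expect_error(fit_gamlss_bccg(dat, "nope"), "not found")
})

test_that("tidy and glance expose the report quantities", {
  dat <- gamlss_testdata(200, 68)
  dat$y <- rbccg(200, 25, 0.15, 0.5)
  fit <- fit_gamlss_bccg(dat, "y", spline = pb_spec(lambda = Inf))
  td <- tidy(fit)
  expect_setequal(unique(td$parameter), c("mu", "sigma", "nu"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  # mu block: intercept + 3 smooth slopes; sigma: intercept + 1; nu: 1
  expect_identical(nrow(td), 3L + 3L + 1L)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_identical(gl$n, 200L)
  rep <- gamlss_report(list(a = fit, b = fit))
  expect_setequal(unique(rep$outcome), c("a", "b"))
})
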