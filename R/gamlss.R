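#' Fit the location-scale-shape gait model (BCCG GAMLSS)
#'
#' Fits a generalized additive model for location, scale and shape with a
#' Box-Cox Cole-Green response to a positive gait parameter, with the
#' structure used throughout the package:
#' \deqn{\mu = a_\mu + pb(PH) + pb(MH) + pb(PI)}
#' \deqn{\log\sigma = a_\sigma + pb(PI)}
#' \deqn{\nu = a_\nu}
#' where `pb()` are penalized B-spline smooths of the PROMIS T scores,
#' `mu` uses an identity link (with a positivity screen on fitted values),
#' `sigma` a log link and `nu` (the Box-Cox power) a single identity-link
#' intercept.
#'
#' Estimation is penalized maximum likelihood: outer cycling over the three
#' distribution parameters with, for each, an iteratively reweighted
#' penalized least-squares step on the working response. The score and
#' curvature of the BCCG log-likelihood with respect to each predictor are
#' obtained by central finite differences (relative step 1e-5). Every
#' update is gated by step halving so the global deviance (-2 log-lik) is
#' non-increasing across outer iterations by construction; the fit stops
#' when the deviance changes by less than `dev_tol`.
#'
#' Smoothing weights follow the spline spec: a number, `Inf` (forces the
#' term onto the penalty null space, a straight line for the default
#' order-2 penalty), or `"auto"` for a local maximum-likelihood update of
#' each smooth's lambda every outer cycle. Alternatively `edf_target` fixes
#' each smooth's effective degrees of freedom.
#'
#' @param data data frame holding the outcome and the PROMIS T scores.
#' @param outcome name of the positive gait-parameter column.
#' @param mu_smooth covariates smoothed in the location predictor
#'   (default the three PROMIS T scores).
#' @param sigma_smooth covariates smoothed in the log-scale predictor
#'   (default Pain Interference).
#' @param spline a [pb_spec()] shared by all smooth terms.
#' @param edf_target if non-`NULL`, each smooth's lambda is chosen so its
#'   effective degrees of freedom match this value (e.g. 3).
#' @param max_outer maximum outer iterations.
#' @param dev_tol convergence tolerance on the global deviance change.
#' @return object of class `gp_gamlss`; see [tidy.gp_gamlss()],
#'   [glance.gp_gamlss()], [predict.gp_gamlss()].
#' @export
fit_gamlss_bccg <- function(data, outcome,
                            mu_smooth = c("ph_t", "mh_t", "pi_t"),
                            sigma_smooth = "pi_t",
                            spline = pb_spec(),
                            edf_target = NULL,
                            max_outer = 100, dev_tol = 1e-4) {
  y <- data[[outcome]]
  if (is.null(y)) abort(paste0("outcome `", outcome, "` not found."))
  keep <- complete.cases(data[, c(outcome, union(mu_smooth, sigma_smooth))])
  data <- data[keep, ]
  y <- data[[outcome]]
  n <- length(y)
  if (n < 20) abort("need at least 20 complete rows to fit the model.")
  if (any(y <= 0)) {
    abort("the BCCG response requires positive gait values; screen them first.")
  }

  blk_mu <- build_block(data, mu_smooth, spline)
  blk_sg <- build_block(data, sigma_smooth, spline)

  # state: coefficient vectors; eta always lies in the design column space
  beta_mu <- c(mean(y), numeric(ncol(blk_mu$X) - 1))
  beta_sg <- c(log(max(sd(y) / mean(y), 1e-3)),
               numeric(ncol(blk_sg$X) - 1))
  a_nu <- 0

  devfun <- function(eta_mu, eta_sg, anu) {
    if (any(eta_mu <= 0)) return(Inf)
    -2 * sum(dbccg(y, mu = eta_mu, sigma = exp(eta_sg), nu = anu,
                   log = TRUE))
  }
  eta_mu <- as.vector(blk_mu$X %*% beta_mu)
  eta_sg <- as.vector(blk_sg$X %*% beta_sg)
  dev <- devfun(eta_mu, eta_sg, a_nu)
  trace <- dev
  w_mu <- w_sg <- rep(1, n); w_nu <- 1

  converged <- FALSE
  for (it in seq_len(max_outer)) {
    dev_prev <- dev

    # --- mu (identity link) ---
    up <- irls_step(
      beta_mu, blk_mu$X, block_penalty(blk_mu), dev,
      lfun = function(eta) safe_logpdf(y, pmax(eta, 1e-8), exp(eta_sg), a_nu),
      dev_of = function(eta) devfun(eta, eta_sg, a_nu))
    beta_mu <- up$beta; dev <- up$dev; w_mu <- up$w
    eta_mu <- as.vector(blk_mu$X %*% beta_mu)
    blk_mu <- update_lambdas(blk_mu, beta_mu, w_mu, up$z, eta_mu,
                             edf_target)

    # --- sigma (log link) ---
    up <- irls_step(
      beta_sg, blk_sg$X, block_penalty(blk_sg), dev,
      lfun = function(eta) safe_logpdf(y, eta_mu, exp(eta), a_nu),
      dev_of = function(eta) devfun(eta_mu, eta, a_nu))
    beta_sg <- up$beta; dev <- up$dev; w_sg <- up$w
    eta_sg <- as.vector(blk_sg$X %*% beta_sg)
    blk_sg <- update_lambdas(blk_sg, beta_sg, w_sg, up$z, eta_sg,
                             edf_target)

    # --- nu (identity link, intercept only) ---
    up <- irls_step(
      a_nu, matrix(1, n, 1), matrix(0, 1, 1), dev,
      lfun = function(eta) safe_logpdf(y, eta_mu, exp(eta_sg), eta),
      dev_of = function(eta) devfun(eta_mu, eta_sg, eta[1]))
    a_nu <- up$beta[1]; dev <- up$dev; w_nu <- up$w

    trace <- c(trace, dev)
    if (abs(dev_prev - dev) < dev_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(paste0("no convergence after ", max_outer, " outer iterations ",
                 "(last deviance ", signif(dev, 8), ")."),
          class = "gp_gamlss_no_convergence", trace_deviance = trace)
  }
  if (any(eta_mu <= 0)) {
    warn("identity-link mu produced nonpositive fitted values; interpret with care.")
  }

  # intercept standard errors from the joint observed information over
  # (beta_mu, beta_sigma, a_nu): the conditional per-block SEs understate
  # the uncertainty because sigma and nu are strongly correlated in
  # Box-Cox families
  jse <- joint_intercept_se(y, blk_mu, blk_sg, eta_mu, eta_sg, a_nu)

  res <- list(
    outcome = outcome, n = n, deviance = dev, trace = trace,
    iterations = length(trace) - 1, converged = converged,
    mu = finalize_block(blk_mu, beta_mu, w_mu, se_intercept = jse[1]),
    sigma = finalize_block(blk_sg, beta_sg, w_sg, se_intercept = jse[2]),
    nu = list(estimate = a_nu,
              se = if (is.finite(jse[3])) jse[3]
                   else sqrt(1 / max(sum(w_nu), 1e-12))),
    fitted = tibble(mu = eta_mu, sigma = exp(eta_sg), nu = a_nu),
    data = data[, union(c(outcome), union(mu_smooth, sigma_smooth))]
  )
  class(res) <- "gp_gamlss"
  res
}

# per-observation BCCG log-likelihood, -Inf-safe for the finite-difference
# machinery
safe_logpdf <- function(y, mu, sigma, nu) {
  out <- rep(-1e10, length(y))
  ok <- mu > 0 & sigma > 0
  if (any(ok)) {
    out[ok] <- dbccg(y[ok], mu = mu[ok],
                     sigma = rep_len(sigma, length(y))[ok],
                     nu = rep_len(nu, length(y))[ok], log = TRUE)
  }
  out
}

# design + penalty bookkeeping for one predictor's smooth terms.
# A term with infinite lambda is replaced by the exact limit: the penalty
# null space, i.e. centered polynomials of degree < penalty_order (a
# straight line for the default order-2 penalty), with zero penalty.
build_block <- function(data, vars, spline) {
  lam0 <- spline$lambda
  lam_of <- function(j) {
    if (identical(lam0, "auto")) 10 else rep_len(lam0, length(vars))[j]
  }
  bases <- lapply(seq_along(vars), function(j) {
    v <- vars[j]
    x <- data[[v]]
    if (is.null(x)) abort(paste0("covariate `", v, "` not found."))
    if (!identical(lam0, "auto") && is.infinite(lam_of(j))) {
      powers <- seq_len(spline$penalty_order - 1)
      Braw <- outer(x, powers, "^")
      cm <- colMeans(Braw)
      list(var = v, type = "poly", powers = powers, cm = cm,
           Bc = sweep(Braw, 2, cm), P = matrix(0, length(powers),
                                               length(powers)),
           x = x, range = range(x), penalty_order = spline$penalty_order)
    } else {
      b <- pb_basis(x, spline)
      cm <- colMeans(b$B)
      list(var = v, type = "spline", basis = b, cm = cm,
           Bc = sweep(b$B, 2, cm), P = b$P,
           x = x, range = b$range, penalty_order = b$penalty_order)
    }
  })
  X <- cbind(1, do.call(cbind, lapply(bases, function(b) b$Bc)))
  sizes <- vapply(bases, function(b) ncol(b$Bc), integer(1))
  ends <- 1 + cumsum(sizes)
  starts <- c(2, utils::head(ends, -1) + 1)
  cols <- purrr::map2(starts, ends, seq)
  lambda <- vapply(seq_along(bases), function(j) {
    if (bases[[j]]$type == "poly") 0 else lam_of(j)
  }, numeric(1))
  list(X = X, bases = bases, cols = cols, lambda = lambda,
       auto = identical(lam0, "auto"), spline = spline)
}

block_penalty <- function(blk) {
  p <- ncol(blk$X)
  S <- matrix(0, p, p)
  for (j in seq_along(blk$bases)) {
    S[blk$cols[[j]], blk$cols[[j]]] <- blk$lambda[j] * blk$bases[[j]]$P
  }
  S
}

# solve with a relative ridge retry for near-singular systems
safe_solve <- function(A, b) {
  tryCatch(solve(A, b), error = function(e) {
    solve(A + diag(1e-8 * mean(abs(diag(A))) + 1e-12, nrow(A)), b)
  })
}

# one penalized IRLS step with deviance-gated step halving; the global
# deviance never increases
irls_step <- function(beta_old, X, S, cur_dev, lfun, dev_of) {
  eta_old <- as.vector(X %*% beta_old)
  d <- num_derivs(lfun, eta_old)
  z <- eta_old + d$u / d$w
  beta_prop <- tryCatch(
    safe_solve(crossprod(X, X * d$w) + S, crossprod(X, d$w * z)),
    error = function(e) NULL)
  if (!is.null(beta_prop)) {
    beta_prop <- as.vector(beta_prop)
    for (a in 2^-(0:10)) {
      beta_try <- (1 - a) * beta_old + a * beta_prop
      dv <- dev_of(as.vector(X %*% beta_try))
      if (is.finite(dv) && dv <= cur_dev + 1e-8) {
        return(list(beta = beta_try, dev = dv, w = d$w, z = z))
      }
    }
  }
  list(beta = beta_old, dev = cur_dev, w = d$w, z = z)
}

# central finite differences of the per-observation log-likelihood in eta
num_derivs <- function(lfun, eta) {
  h <- 1e-5 * pmax(abs(eta), 1)
  lp <- lfun(eta + h); lm <- lfun(eta - h); l0 <- lfun(eta)
  u <- (lp - lm) / (2 * h)
  w <- -(lp - 2 * l0 + lm) / h^2
  bad <- !is.finite(w) | w <= 1e-10
  w[bad] <- pmax(u[bad]^2, 1e-4)
  u[!is.finite(u)] <- 0
  list(u = u, w = w)
}

edf_by_term <- function(blk, w) {
  XtWX <- crossprod(blk$X, blk$X * w)
  A <- tryCatch(safe_solve(XtWX + block_penalty(blk), diag(nrow(XtWX))),
                error = function(e) NULL)
  if (is.null(A)) return(rep(NA_real_, length(blk$bases)))
  hd <- diag(A %*% XtWX)
  vapply(seq_along(blk$bases),
         function(j) sum(hd[blk$cols[[j]]]), numeric(1))
}

# local ML lambda update (Schall-type) or edf-matching, per smooth
update_lambdas <- function(blk, beta, w, z, eta, edf_target) {
  if (!is.null(edf_target)) {
    for (j in seq_along(blk$bases)) {
      if (blk$bases[[j]]$type == "poly") next
      blk$lambda[j] <- lambda_for_edf(blk, w, j, edf_target)
    }
    return(blk)
  }
  if (!blk$auto) return(blk)
  if (all(vapply(blk$bases, function(b) b$type, "") == "poly")) return(blk)
  edf <- edf_by_term(blk, w)
  if (any(!is.finite(edf))) return(blk)
  rss <- sum(w * (z - eta)^2)
  sig2e <- rss / max(length(z) - (1 + sum(edf)), 1)
  for (j in seq_along(blk$bases)) {
    if (blk$bases[[j]]$type == "poly") next
    bj <- beta[blk$cols[[j]]]
    pen <- as.numeric(t(bj) %*% blk$bases[[j]]$P %*% bj)
    d <- blk$bases[[j]]$penalty_order
    sig2b <- pen / max(edf[j] - d, 0.1)
    if (sig2b <= 1e-12) next
    lam_new <- sig2e / sig2b
    # damp: at most a factor 10 per cycle
    lam_new <- min(max(lam_new, blk$lambda[j] / 10), blk$lambda[j] * 10)
    blk$lambda[j] <- min(max(lam_new, 1e-4), 1e9)
  }
  blk
}

lambda_for_edf <- function(blk, w, j, target) {
  f <- function(loglam) {
    blk$lambda[j] <- exp(loglam)
    edf_by_term(blk, w)[j] - target
  }
  lo <- log(1e-6); hi <- log(1e10)
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    return(blk$lambda[j])
  }
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-3)$root)
}

# joint observed information over the three predictors, reduced to the
# standard errors of the mu, sigma and nu intercepts. Second derivatives
# (including the cross-parameter blocks) by central finite differences of
# the per-observation log-likelihood.
joint_intercept_se <- function(y, blk_mu, blk_sg, eta_mu, eta_sg, a_nu) {
  n <- length(y)
  l3 <- function(em, es, en) safe_logpdf(y, em, exp(es), en)
  h_m <- 1e-5 * pmax(abs(eta_mu), 1)
  h_s <- 1e-5 * pmax(abs(eta_sg), 1)
  h_n <- 1e-5 * max(abs(a_nu), 1)
  en <- rep(a_nu, n)
  l0 <- l3(eta_mu, eta_sg, en)
  # diagonal curvatures
  wmm <- -(l3(eta_mu + h_m, eta_sg, en) - 2 * l0 +
             l3(eta_mu - h_m, eta_sg, en)) / h_m^2
  wss <- -(l3(eta_mu, eta_sg + h_s, en) - 2 * l0 +
             l3(eta_mu, eta_sg - h_s, en)) / h_s^2
  wnn <- -(l3(eta_mu, eta_sg, en + h_n) - 2 * l0 +
             l3(eta_mu, eta_sg, en - h_n)) / h_n^2
  # mixed curvatures via the four-point stencil
  wms <- -(l3(eta_mu + h_m, eta_sg + h_s, en) -
             l3(eta_mu + h_m, eta_sg - h_s, en) -
             l3(eta_mu - h_m, eta_sg + h_s, en) +
             l3(eta_mu - h_m, eta_sg - h_s, en)) / (4 * h_m * h_s)
  wmn <- -(l3(eta_mu + h_m, eta_sg, en + h_n) -
             l3(eta_mu + h_m, eta_sg, en - h_n) -
             l3(eta_mu - h_m, eta_sg, en + h_n) +
             l3(eta_mu - h_m, eta_sg, en - h_n)) / (4 * h_m * h_n)
  wsn <- -(l3(eta_mu, eta_sg + h_s, en + h_n) -
             l3(eta_mu, eta_sg + h_s, en - h_n) -
             l3(eta_mu, eta_sg - h_s, en + h_n) +
             l3(eta_mu, eta_sg - h_s, en - h_n)) / (4 * h_s * h_n)
  Xm <- blk_mu$X; Xs <- blk_sg$X
  one <- matrix(1, n, 1)
  H <- rbind(
    cbind(crossprod(Xm, Xm * wmm) + block_penalty(blk_mu),
          crossprod(Xm, Xs * wms), crossprod(Xm, one * wmn)),
    cbind(crossprod(Xs, Xm * wms), crossprod(Xs, Xs * wss) +
            block_penalty(blk_sg), crossprod(Xs, one * wsn)),
    cbind(crossprod(one, Xm * wmn), crossprod(one, Xs * wsn),
          sum(wnn))
  )
  V <- tryCatch(safe_solve(H, diag(nrow(H))), error = function(e) NULL)
  idx <- c(1, ncol(Xm) + 1, ncol(Xm) + ncol(Xs) + 1)
  if (is.null(V) || any(diag(V)[idx] <= 0)) {
    # fall back to the conditional block SEs
    return(c(NA_real_, NA_real_, NA_real_))
  }
  sqrt(diag(V)[idx])
}

# intercept SE, per-term edf and linearized slope summaries for one block
finalize_block <- function(blk, beta, w, se_intercept = NA_real_) {
  XtWX <- crossprod(blk$X, blk$X * w)
  A <- safe_solve(XtWX + block_penalty(blk), diag(nrow(XtWX)))
  hd <- diag(A %*% XtWX)
  edf <- vapply(seq_along(blk$bases),
                function(j) sum(hd[blk$cols[[j]]]), numeric(1))
  slopes <- purrr::imap(blk$bases, function(b, j) {
    idx <- blk$cols[[j]]
    f <- as.vector(b$Bc %*% beta[idx])
    xc <- b$x - mean(b$x)
    cvec <- xc / sum(xc^2)
    slope <- sum(cvec * f)
    cov_f <- b$Bc %*% A[idx, idx, drop = FALSE] %*% t(b$Bc)
    se <- sqrt(max(as.numeric(t(cvec) %*% cov_f %*% cvec), 0))
    tibble(term = b$var, estimate = slope, std.error = se,
           p.value = 2 * pnorm(-abs(slope / max(se, 1e-12))),
           edf = edf[j], lambda = blk$lambda[j])
  }) %>% purrr::list_rbind()
  list(intercept = beta[1],
       intercept_se = if (is.finite(se_intercept)) se_intercept
                      else sqrt(A[1, 1]),
       beta = beta, cov = A, edf = edf, lambda = blk$lambda,
       slopes = slopes,
       bases = lapply(blk$bases, function(b) {
         b$Bc <- NULL
         b
       }))
}

#' Predict conditional BCCG parameters at new PROMIS scores
#'
#' Evaluates the fitted predictors at new covariate values and inverts the
#' links, returning the full conditional distribution `(mu, sigma, nu)` per
#' row, from which centile curves follow via [qbccg()]. Inputs more than 5%
#' of the training span outside the training range are refused.
#'
#' @param object a [fit_gamlss_bccg()] fit.
#' @param newdata data frame holding the model's covariate columns.
#' @param ... unused.
#' @return tibble with columns `mu`, `sigma`, `nu`.
#' @export
predict.gp_gamlss <- function(object, newdata, ...) {
  eta_of <- function(block) {
    eta <- rep(block$intercept, nrow(newdata))
    for (b in block$bases) {
      x <- newdata[[b$var]]
      if (is.null(x)) abort(paste0("column `", b$var, "` missing."))
      span <- diff(b$range)
      if (any(x < b$range[1] - 0.05 * span | x > b$range[2] + 0.05 * span)) {
        abort(paste0("`", b$var, "` is beyond 5% extrapolation of the ",
                     "training range [", signif(b$range[1], 4), ", ",
                     signif(b$range[2], 4), "]."))
      }
      Bn <- if (b$type == "poly") {
        sweep(outer(x, b$powers, "^"), 2, b$cm)
      } else {
        sweep(pb_eval(b$basis, pmin(pmax(x, b$range[1]), b$range[2])),
              2, b$cm)
      }
      eta <- eta + as.vector(Bn %*% block_beta(block, b$var))
    }
    eta
  }
  mu <- eta_of(object$mu)
  sigma <- exp(eta_of(object$sigma))
  tibble(mu = mu, sigma = sigma, nu = object$nu$estimate)
}

# coefficients of one smooth term inside a finalized block
block_beta <- function(block, var) {
  sizes <- vapply(block$bases, function(b) length(b$cm), integer(1))
  ends <- 1 + cumsum(sizes)
  starts <- c(2, utils::head(ends, -1) + 1)
  j <- which(vapply(block$bases, function(b) b$var == var, logical(1)))[1]
  block$beta[starts[j]:ends[j]]
}

#' Predicted centile of the conditional gait distribution
#'
#' @inheritParams predict.gp_gamlss
#' @param fit a [fit_gamlss_bccg()] fit.
#' @param p centile probability (e.g. 0.1 for the 10th centile).
#' @return numeric vector of gait-parameter centiles.
#' @export
predict_centile <- function(fit, newdata, p = 0.5) {
  pars <- predict(fit, newdata)
  qbccg(p, mu = pars$mu, sigma = pars$sigma, nu = pars$nu)
}

#' @exportS3Method generics::tidy
tidy.gp_gamlss <- function(x, ...) {
  ints <- tibble(
    parameter = c("mu", "sigma", "nu"),
    term = "(Intercept)",
    estimate = c(x$mu$intercept, x$sigma$intercept, x$nu$estimate),
    std.error = c(x$mu$intercept_se, x$sigma$intercept_se, x$nu$se),
    edf = NA_real_, lambda = NA_real_)
  ints$p.value <- 2 * pnorm(-abs(ints$estimate / ints$std.error))
  sl <- dplyr::bind_rows(
    mutate(x$mu$slopes, parameter = "mu"),
    mutate(x$sigma$slopes, parameter = "sigma"))
  dplyr::bind_rows(ints, sl) %>%
    select("parameter", "term", "estimate", "std.error", "p.value",
           "edf", "lambda")
}

#' @exportS3Method generics::glance
glance.gp_gamlss <- function(x, ...) {
  tibble(outcome = x$outcome, n = x$n, deviance = x$deviance,
         iterations = x$iterations, converged = x$converged,
         edf_mu = sum(x$mu$edf), edf_sigma = sum(x$sigma$edf))
}

#' @export
print.gp_gamlss <- function(x, ...) {
  cat("BCCG GAMLSS fit for", x$outcome, " (n =", x$n, ")\n")
  cat("global deviance", round(x$deviance, 3), "after", x$iterations,
      "outer iterations\n\n")
  print(tidy(x))
  invisible(x)
}

#' Stack per-outcome GAMLSS fits into a report table
#'
#' Combines a named list of fits (one per gait parameter) into the wide
#' mu/sigma/nu-block report shape: one row per parameter block and term,
#' one estimate/SE/p triple per outcome.
#'
#' @param fits named list of [fit_gamlss_bccg()] objects.
#' @return tidy tibble with columns `parameter`, `term`, `outcome`,
#'   `estimate`, `std.error`, `p.value`.
#' @export
gamlss_report <- function(fits) {
  purrr::imap(fits, function(f, nm) {
    mutate(tidy(f), outcome = nm)
  }) %>%
    purrr::list_rbind() %>%
    select("parameter", "term", "outcome", "estimate", "std.error",
           "p.value")
}
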