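# Unobserved-components state-space model for the Box-Cox-transformed binned
# interarrival series:
#
#   y_t = mu_t + gamma_t + x_t' beta + eps_t
#
# with a random-walk local level mu, a trigonometric seasonal gamma of period
# s truncated at kappa harmonics (deterministic when its disturbance
# variances are zero), optional campaign-dummy regressors, and an AR(1)
# irregular eps. Estimation is Gaussian maximum likelihood via the Kalman
# filter with approximate diffuse initialisation; component extraction uses
# the fixed-interval smoother.

#' Specify an unobserved-components model
#'
#' @param kappa harmonic cutoff, `1 <= kappa <= s/2`; `NULL` selects the
#'   cutoff with the lowest corrected Akaike information criterion.
#' @param s seasonal period in bins (12 two-hour bins = one day).
#' @param stochastic_seasonal estimate a common disturbance variance for the
#'   seasonal harmonics (default `FALSE`: deterministic seasonal).
#' @param ar_irregular model the irregular as AR(1) (default) rather than
#'   white noise.
#' @return An object of class `ucm_spec`.
#' @export
ucm_spec <- function(kappa = NULL, s = 12, stochastic_seasonal = FALSE,
                     ar_irregular = TRUE) {
  if (!is.null(kappa) && (kappa < 1 || kappa > s / 2)) {
    stop_domain("kappa must lie in [1, s/2]")
  }
  structure(list(kappa = kappa, s = s,
                 stochastic_seasonal = stochastic_seasonal,
                 ar_irregular = ar_irregular),
            class = "ucm_spec")
}

# System matrices for given structural parameters.
ucm_system <- function(spec, kappa, pars, n_reg, scale_y) {
  s <- spec$s
  nyq <- kappa == s / 2
  n_seas <- 2 * kappa - nyq
  m <- 1 + n_seas + 1 + n_reg
  Tm <- matrix(0, m, m)
  Tm[1, 1] <- 1
  idx <- 2
  seas_obs <- integer(0)
  for (j in seq_len(kappa)) {
    lam <- 2 * pi * j / s
    if (j < s / 2) {
      Tm[idx, idx] <- cos(lam); Tm[idx, idx + 1] <- sin(lam)
      Tm[idx + 1, idx] <- -sin(lam); Tm[idx + 1, idx + 1] <- cos(lam)
      seas_obs <- c(seas_obs, idx)
      idx <- idx + 2
    } else {
      Tm[idx, idx] <- -1
      seas_obs <- c(seas_obs, idx)
      idx <- idx + 1
    }
  }
  ar_idx <- idx
  Tm[ar_idx, ar_idx] <- pars$phi
  if (n_reg > 0) {
    for (r in seq_len(n_reg)) Tm[ar_idx + r, ar_idx + r] <- 1
  }
  Q <- matrix(0, m, m)
  Q[1, 1] <- pars$q_level
  if (n_seas > 0) diag(Q)[2:(1 + n_seas)] <- pars$q_seas
  Q[ar_idx, ar_idx] <- pars$q_ar
  z_base <- numeric(m)
  z_base[1] <- 1
  z_base[seas_obs] <- 1
  z_base[ar_idx] <- 1
  # diffuse prior for level, seasonal and regression states; stationary for AR
  P0 <- diag(1e7 * scale_y, m)
  P0[ar_idx, ar_idx] <- if (abs(pars$phi) < 1) {
    max(pars$q_ar / (1 - pars$phi^2), 1e-12 * scale_y)
  } else 1e7 * scale_y
  list(T = Tm, Q = Q, z_base = z_base, P0 = P0, m = m, ar_idx = ar_idx,
       seas_obs = seas_obs, n_diffuse = m - 1,
       reg_idx = if (n_reg > 0) ar_idx + seq_len(n_reg) else integer(0))
}

# Kalman filter (predicted-state form) with optional smoothing pass.
# `skip` overrides the number of initial prediction-error terms dropped from
# the likelihood (default: the model's own diffuse-state count); cutoff
# selection passes a common value so likelihoods are comparable across kappa.
ucm_kalman <- function(y, X, sys, scale_y, smooth = FALSE, skip = NULL) {
  n <- length(y)
  m <- sys$m
  Tm <- sys$T
  Q <- sys$Q
  jitter <- 1e-8 * scale_y
  a <- numeric(m)
  P <- sys$P0
  v_all <- rep(NA_real_, n)
  F_all <- rep(NA_real_, n)
  yhat <- rep(NA_real_, n)
  if (smooth) {
    A <- matrix(0, m, n)
    Parr <- array(0, c(m, m, n))
    Karr <- matrix(0, m, n)
  }
  ll <- 0
  n_used <- 0
  n_skip <- skip %||% sys$n_diffuse
  seen <- 0
  for (t in seq_len(n)) {
    z <- sys$z_base
    if (length(sys$reg_idx)) z[sys$reg_idx] <- X[t, ]
    if (smooth) { A[, t] <- a; Parr[, , t] <- P }
    if (is.na(y[t])) {
      a <- Tm %*% a
      P <- Tm %*% P %*% t(Tm) + Q
      next
    }
    Pz <- P %*% z
    Fv <- drop(crossprod(z, Pz)) + jitter
    if (!is.finite(Fv) || Fv <= 0) Fv <- jitter  # numerical PSD loss guard
    v <- y[t] - drop(crossprod(z, a))
    yhat[t] <- drop(crossprod(z, a))
    v_all[t] <- v
    F_all[t] <- Fv
    K <- (Tm %*% Pz) / Fv
    if (smooth) Karr[, t] <- K
    seen <- seen + 1
    if (seen > n_skip) {
      ll <- ll - 0.5 * (log(2 * pi) + log(Fv) + v^2 / Fv)
      n_used <- n_used + 1
    }
    L <- Tm - K %*% t(z)
    a <- Tm %*% a + K * v
    P <- Tm %*% P %*% t(L) + Q
    P <- (P + t(P)) / 2
  }
  out <- list(loglik = ll, n_used = n_used, v = v_all, F = F_all, yhat = yhat,
              a_final = a, P_final = P)
  if (smooth) {
    alpha <- matrix(0, m, n)
    r <- numeric(m)
    for (t in rev(seq_len(n))) {
      z <- sys$z_base
      if (length(sys$reg_idx)) z[sys$reg_idx] <- X[t, ]
      if (is.na(y[t])) {
        r <- t(Tm) %*% r
      } else {
        L <- Tm - Karr[, t] %*% t(z)
        r <- z * (v_all[t] / F_all[t]) + t(L) %*% r
      }
      alpha[, t] <- A[, t] + Parr[, , t] %*% r
    }
    out$alpha <- alpha
  }
  out
}

ucm_unpack <- function(theta, spec, scale_y) {
  i <- 1
  q_level <- scale_y * exp(theta[i]); i <- i + 1
  q_seas <- if (spec$stochastic_seasonal) {
    v <- scale_y * exp(theta[i]); i <- i + 1; v
  } else 0
  phi <- if (spec$ar_irregular) {
    v <- tanh(theta[i]); i <- i + 1; v
  } else 0
  q_ar <- scale_y * exp(theta[i])
  list(q_level = q_level, q_seas = q_seas, phi = phi, q_ar = q_ar)
}

#' Fit the unobserved-components model
#'
#' Maximum-likelihood estimation of the disturbance variances and AR
#' coefficient via Kalman filtering with approximate diffuse initialisation,
#' followed by fixed-interval smoothing for component extraction. When the
#' harmonic cutoff is unspecified, every cutoff `1..s/2` is fitted and the
#' one with the lowest AICc is kept. Missing bins are handled natively by
#' the filter (no imputation).
#'
#' @param series a `rate_series` from [aggregate_interarrivals()] (the
#'   Box-Cox-transformed mean interarrivals are modelled), or a plain numeric
#'   vector treated as an already-transformed series.
#' @param spec a [ucm_spec()].
#' @param lambda Box-Cox parameter; default: the profile-ML estimate stored
#'   on the series (`NA` for plain numeric input: no transform).
#' @param regressors optional `n x k` matrix of campaign dummy indicators.
#' @return An object of class `ucm_fit`: parameter estimates with standard
#'   errors, log-likelihood, AICc, smoothed components (`level`, `seasonal`,
#'   `regression`, `irregular`), one-step residuals and fitted values.
#' @export
fit_ucm <- function(series, spec = ucm_spec(), lambda = NULL,
                    regressors = NULL) {
  if (inherits(series, "rate_series")) {
    lambda <- lambda %||% attr(series, "boxcox_lambda")
    y <- boxcox(series$mean_interarrival, lambda)
    bin_width <- attr(series, "bin_width")
    bin_start <- series$bin_start
  } else {
    y <- as.numeric(series)
    lambda <- lambda %||% NA_real_
    if (!is.na(lambda)) y <- boxcox(y, lambda)
    bin_width <- 1
    bin_start <- seq_along(y) - 1
  }
  n <- length(y)
  if (sum(!is.na(y)) < 4 * spec$s) {
    stop_domain("series too short: need at least 4 seasonal cycles of bins")
  }
  X <- regressors
  n_reg <- if (is.null(X)) 0L else ncol(X)
  if (n_reg > 0 && nrow(X) != n) stop_domain("regressors must have one row per bin")
  # scale free variances by the differenced-series variance: unlike var(y) it
  # is not inflated by the wandering level, so optimizer starts are sane
  yd <- diff(y[!is.na(y)])
  scale_y <- max(if (length(yd) > 1) stats::var(yd) else stats::var(y, na.rm = TRUE),
                 1e-10)

  fit_one <- function(kappa) {
    nll <- function(theta) {
      pars <- ucm_unpack(theta, spec, scale_y)
      sys <- ucm_system(spec, kappa, pars, n_reg, scale_y)
      -ucm_kalman(y, X, sys, scale_y)$loglik
    }
    starts <- list(
      c(log(0.2), if (spec$stochastic_seasonal) log(0.01),
        if (spec$ar_irregular) atanh(0.3), log(0.5)),
      c(log(0.02), if (spec$stochastic_seasonal) log(0.001),
        if (spec$ar_irregular) atanh(0), log(1))
    )
    n_par <- length(starts[[1]])
    lower <- rep(-25, n_par)
    upper <- rep(8, n_par)
    if (spec$ar_irregular) {
      k <- 1 + spec$stochastic_seasonal + 1
      lower[k] <- atanh(-0.995); upper[k] <- atanh(0.995)
    }
    # Nelder-Mead from two starts explores the (possibly ridged) likelihood
    # surface; a quasi-Newton polish sharpens the optimum and supplies the
    # Hessian.
    nms <- lapply(starts, function(th0) {
      stats::optim(th0, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000))
    })
    opt_nm <- nms[[which.min(vapply(nms, `[[`, numeric(1), "value"))]]
    start <- pmin(pmax(opt_nm$par, lower), upper)
    opt <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, hessian = TRUE,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value) || opt$value > opt_nm$value + 1e-6) {
      opt <- opt_nm
      opt$hessian <- tryCatch(stats::optimHess(opt$par, nll),
                              error = function(e) NULL)
    }
    if (!is.finite(opt$value)) {
      stop("UCM estimation did not converge: ",
           paste(utils::capture.output(utils::str(opt)), collapse = "\n"))
    }
    pars <- ucm_unpack(opt$par, spec, scale_y)
    sys <- ucm_system(spec, kappa, pars, n_reg, scale_y)
    kf <- ucm_kalman(y, X, sys, scale_y, smooth = TRUE)
    # selection criterion on a burn-in common to every candidate cutoff, so
    # the compared likelihoods cover the same observations
    kf_sel <- ucm_kalman(y, X, sys, scale_y, skip = common_skip)
    k_par <- length(opt$par) + sys$n_diffuse
    n_eff <- kf_sel$n_used
    aicc <- -2 * kf_sel$loglik + 2 * k_par +
      if (n_eff - k_par - 1 > 0) 2 * k_par * (k_par + 1) / (n_eff - k_par - 1) else Inf
    list(opt = opt, pars = pars, sys = sys, kf = kf, kappa = kappa, aicc = aicc)
  }

  kappas <- if (is.null(spec$kappa)) seq_len(spec$s / 2) else spec$kappa
  nyq_max <- max(kappas) == spec$s / 2
  common_skip <- 1 + (2 * max(kappas) - nyq_max) + n_reg  # largest diffuse set
  fits <- lapply(kappas, fit_one)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aicc"))]]

  # delta-method standard errors on the natural scale
  se_theta <- tryCatch({
    h <- best$opt$hessian
    if (is.null(h)) stop("no hessian")
    sqrt(pmax(diag(solve(h)), 0))
  }, error = function(e) rep(NA_real_, length(best$opt$par)))
  pars <- best$pars
  nm <- c("q_level",
          if (spec$stochastic_seasonal) "q_seas",
          if (spec$ar_irregular) "phi",
          "q_ar")
  est <- unlist(pars)[nm]
  jac <- ifelse(nm == "phi", 1 - pars$phi^2, est)  # d(natural)/d(theta)
  se <- abs(jac) * se_theta

  sys <- best$sys
  kf <- best$kf
  alpha <- kf$alpha
  seasonal <- if (length(sys$seas_obs)) colSums(alpha[sys$seas_obs, , drop = FALSE]) else rep(0, n)
  regression <- if (n_reg > 0) {
    rowSums(X * t(alpha[sys$reg_idx, , drop = FALSE]))
  } else rep(0, n)
  components <- data.frame(
    bin_start = bin_start,
    level = alpha[1, ],
    seasonal = seasonal,
    regression = regression,
    irregular = alpha[sys$ar_idx, ]
  )
  structure(
    list(spec = spec, kappa = best$kappa, lambda = lambda,
         estimates = stats::setNames(est, nm), se = stats::setNames(se, nm),
         loglik = -best$opt$value, aicc = best$aicc,
         components = components, y = y, X = X,
         residuals = kf$v, F = kf$F, fitted = kf$yhat,
         a_final = kf$a_final, P_final = kf$P_final, sys = sys,
         scale_y = scale_y, bin_width = bin_width,
         bin_start = bin_start),
    class = "ucm_fit"
  )
}

#' @export
print.ucm_fit <- function(x, ...) {
  cat(sprintf("<ucm_fit> kappa=%d, lambda=%s, loglik=%.2f, AICc=%.2f\n",
              x$kappa, format(x$lambda, digits = 4), x$loglik, x$aicc))
  print(round(rbind(estimate = x$estimates, se = x$se), 6))
  invisible(x)
}

#' Multistep forecast of the arrival rate
#'
#' Propagates the state-space forecast `horizon_bins` ahead, producing point
#' forecasts with 95% prediction intervals on the transformed scale, the
#' bias-adjusted expected mean interarrival on the original scale, and the
#' implied arrival rate per minute. One-step residual diagnostics (Ljung-Box
#' and White) are attached.
#'
#' @param fit a [fit_ucm()] object.
#' @param horizon_bins number of bins ahead, `>= 1`.
#' @param newreg optional future regressor matrix (`horizon_bins x k`);
#'   defaults to all-zero (campaigns off).
#' @return An object of class `rate_forecast`: data frame `forecast` with
#'   `bin`, `point`, `lower95`, `upper95`, `interarrival_min`, `rate_per_min`,
#'   plus `diagnostics` (`ljung_box`, `white`).
#' @export
forecast_rate <- function(fit, horizon_bins, newreg = NULL) {
  stopifnot(inherits(fit, "ucm_fit"))
  if (horizon_bins < 1) stop_domain("horizon_bins must be >= 1")
  sys <- fit$sys
  Tm <- sys$T
  Q <- sys$Q
  a <- fit$a_final
  P <- fit$P_final
  n_reg <- length(sys$reg_idx)
  if (n_reg > 0 && is.null(newreg)) newreg <- matrix(0, horizon_bins, n_reg)
  point <- varf <- numeric(horizon_bins)
  jitter <- 1e-8 * fit$scale_y
  for (h in seq_len(horizon_bins)) {
    z <- sys$z_base
    if (n_reg > 0) z[sys$reg_idx] <- newreg[h, ]
    point[h] <- drop(crossprod(z, a))
    varf[h] <- max(drop(crossprod(z, P %*% z)) + jitter, jitter)
    if (!all(is.finite(c(point[h], varf[h])))) {
      stop("forecast variance overflowed at horizon ", h)
    }
    a <- Tm %*% a
    P <- Tm %*% P %*% t(Tm) + Q
  }
  lower <- point - 1.96 * sqrt(varf)
  upper <- point + 1.96 * sqrt(varf)
  if (!is.na(fit$lambda)) {
    ia <- inverse_boxcox_bias_adjusted(point, varf, fit$lambda)
    rate <- 1 / ia
  } else {
    ia <- rep(NA_real_, horizon_bins)
    rate <- rep(NA_real_, horizon_bins)
  }
  res <- fit$residuals / sqrt(fit$F)
  ok <- which(!is.na(res))
  ok <- ok[-seq_len(min(sys$n_diffuse, length(ok)))]
  r <- res[ok]
  lb <- stats::Box.test(r, lag = min(10, max(2, floor(length(r) / 5))),
                        type = "Ljung-Box")
  wt <- tryCatch(white_test(r, fit$fitted[ok]),
                 error = function(e) list(H = NA_real_, p_value = NA_real_))
  fc <- data.frame(bin = seq_len(horizon_bins), point = point,
                   lower95 = lower, upper95 = upper,
                   interarrival_min = ia, rate_per_min = rate)
  structure(
    list(forecast = fc,
         diagnostics = list(
           ljung_box = list(Q = unname(lb$statistic), p_value = unname(lb$p.value)),
           white = wt
         ),
         lambda = fit$lambda, bin_width = fit$bin_width,
         last_bin_start = fit$bin_start[length(fit$bin_start)]),
    class = "rate_forecast"
  )
}

#' White heteroskedasticity test
#'
#' Auxiliary-regression test: squared residuals are regressed on the fitted
#' values and their squares; under homoskedasticity `H = n R^2` is
#' chi-squared with 2 degrees of freedom.
#'
#' @param residuals model residuals (at least 5).
#' @param fitted corresponding fitted values.
#' @return List with `H` and `p_value`.
#' @export
white_test <- function(residuals, fitted) {
  n <- length(residuals)
  if (n < 5) stop_domain("need at least 5 residuals")
  if (length(fitted) != n) stop_domain("residuals and fitted lengths differ")
  if (stats::sd(residuals) == 0 || stats::sd(fitted) == 0) {
    stop_domain("degenerate (constant) residuals or fitted values")
  }
  e2 <- residuals^2
  aux <- stats::lm(e2 ~ fitted + I(fitted^2))
  r2 <- summary(aux)$r.squared
  H <- n * r2
  list(H = H, p_value = stats::pchisq(H, df = 2, lower.tail = FALSE))
}

#' Build a continuous rate function from binned rates
#'
#' Interpolates `(bin midpoint, rate)` knots with a monotone piecewise-cubic
#' Hermite polynomial, clipped at zero -- the downsampled intensity used by
#' the thinning sampler.
#'
#' @param x a `rate_forecast` (uses `rate_per_min`) or a `rate_series` (uses
#'   `1/mean_interarrival`).
#' @param t_max evaluation horizon in minutes; default spans the bins.
#' @return A [rate_function()].
#' @export
build_rate_function <- function(x, t_max = NULL) {
  if (inherits(x, "rate_forecast")) {
    bw <- x$bin_width
    t0 <- x$last_bin_start + bw
    mid <- t0 + (x$forecast$bin - 1) * bw + bw / 2
    rate <- x$forecast$rate_per_min
  } else if (inherits(x, "rate_series")) {
    bw <- attr(x, "bin_width")
    mid <- x$bin_start + bw / 2
    rate <- 1 / x$mean_interarrival
  } else {
    stop_domain("x must be a rate_forecast or rate_series")
  }
  if (any(!is.finite(rate))) stop_domain("nonfinite rate; cannot interpolate")
  if (length(mid) < 2) stop_domain("need at least 2 bins")
  rate_function(mid, rate, t_max = t_max %||% max(mid))
}
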