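#' Construct a relaxation-time series
#'
#' Temperature dependence of the structural relaxation time
#' \eqn{\tau_\alpha(T)} at one pressure and composition, as obtained from
#' HN fits of loss spectra collected above Tg.
#'
#' @param temperature Temperatures in K (distinct).
#' @param tau_alpha Relaxation times in s, > 0.
#' @param pressure Pressure in MPa.
#' @param composition_label Free-text composition label.
#' @param onset_flag Optional logical vector marking points recorded at or
#'   after the crystallization onset; flagged points are excluded from VFT
#'   fitting.
#' @return Object of class `relaxation_series`.
#' @export
relaxation_series <- function(temperature, tau_alpha, pressure = 0.1,
                              composition_label = "", onset_flag = NULL) {
  if (length(temperature) != length(tau_alpha))
    stopf("'temperature' and 'tau_alpha' must have equal length")
  if (anyDuplicated(temperature)) stopf("temperatures must be distinct")
  if (any(tau_alpha <= 0)) stopf("'tau_alpha' must be > 0")
  if (is.null(onset_flag)) onset_flag <- rep(FALSE, length(temperature))
  structure(list(temperature = as.numeric(temperature),
                 tau_alpha = as.numeric(tau_alpha),
                 pressure = pressure,
                 composition_label = as.character(composition_label),
                 onset_flag = as.logical(onset_flag)),
            class = "relaxation_series")
}

#' Evaluate the VFT equation
#'
#' \deqn{\tau(T) = \tau_\infty \exp\!\left(\frac{B}{T - T_0}\right)}
#'
#' @param temperature Temperatures in K; all must exceed `t0`.
#' @param tau_inf Pre-exponential time \eqn{\tau_\infty} in s, > 0.
#' @param b_vft Activation parameter B in K, > 0.
#' @param t0 Vogel temperature in K, >= 0.
#' @return Relaxation times in s.
#' @export
vft_tau <- function(temperature, tau_inf, b_vft, t0) {
  check_number(tau_inf, "tau_inf", positive = TRUE)
  check_number(b_vft, "b_vft", positive = TRUE)
  check_number(t0, "t0")
  if (t0 < 0) stopf("'t0' must be >= 0")
  if (any(temperature <= t0))
    stopf("all temperatures must exceed T0 = %g K", t0)
  tau_inf * exp(b_vft / (temperature - t0))
}

#' Construct a VFT fit object
#'
#' @inheritParams vft_tau
#' @param tau_ref Reference relaxation time defining Tg (default 100 s).
#' @param covariance Optional parameter covariance matrix (in the internal
#'   parameterization log10 tau_inf, B, T0).
#' @param fit_quality Optional residual summary list.
#' @return Object of class `vft_fit` with derived `tg` (K) at
#'   `tau = tau_ref`.
#' @export
vft_fit <- function(tau_inf, b_vft, t0, tau_ref = 100, covariance = NULL,
                    fit_quality = NULL) {
  out <- structure(list(tau_inf = tau_inf, b_vft = b_vft, t0 = t0,
                        tau_ref = tau_ref, covariance = covariance,
                        fit_quality = fit_quality, tg = NA_real_),
                   class = "vft_fit")
  # validate by evaluating once
  vft_tau(t0 + b_vft, tau_inf, b_vft, t0)
  out$tg <- extrapolate_tg(out, tau_ref)
  out
}

#' @export
print.vft_fit <- function(x, ...) {
  cat(sprintf("<vft_fit> tau_inf = %.4g s, B = %.2f K, T0 = %.2f K, Tg(tau=%g s) = %.2f K\n",
              x$tau_inf, x$b_vft, x$t0, x$tau_ref, x$tg))
  invisible(x)
}

#' Fit the VFT equation to a relaxation-time series
#'
#' Levenberg-Marquardt fit of `log10 tau` versus temperature: fitting in
#' the log domain equalizes leverage across the 8+ decades a relaxation
#' map spans.  Points flagged as crystallization onset are excluded.
#' Initialization scans candidate Vogel temperatures and picks the one
#' whose linearized fit (log10 tau vs 1/(T - T0)) has the smallest residual.
#'
#' @param series A [relaxation_series()], or a data.frame with columns
#'   `temperature_K` and `tau_s`.
#' @param tau_ref Reference time defining Tg (default 100 s).
#' @return A [vft_fit()] with covariance and fit_quality populated.
#' @export
fit_vft <- function(series, tau_ref = 100) {
  if (is.data.frame(series))
    series <- relaxation_series(series$temperature_K, series$tau_s)
  stopifnot(inherits(series, "relaxation_series"))
  keep <- !series$onset_flag
  temp <- series$temperature[keep]
  tau <- series$tau_alpha[keep]
  if (length(temp) < 3L)
    stopf("VFT fit needs at least 3 usable points (got %d); consider horizontal_shift_tg()",
          length(temp))
  y <- log10(tau)

  # initialization: profile T0 on a grid, linear in 1/(T - T0)
  t0_grid <- seq(0, min(temp) - 1, length.out = 60)
  best <- NULL
  for (t0c in t0_grid) {
    x <- 1 / (temp - t0c)
    cf <- stats::lm.fit(cbind(1, x), y)
    rss <- sum(cf$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, t0 = t0c, lt = cf$coefficients[1],
                   b = cf$coefficients[2] * log(10))
  }
  p0 <- c(best$lt, max(best$b, 1), best$t0)

  resid_fn <- function(p)
    p[1] + p[2] / (log(10) * (temp - p[3])) - y
  fit <- minpack.lm::nls.lm(par = p0,
                            lower = c(-30, 1e-6, 0),
                            upper = c(10, 1e5, min(temp) - 1e-3),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15, maxiter = 1000))
  if (fit$info < 1 || fit$info > 4)
    stopf("VFT fit did not converge (info = %d)", fit$info)
  p <- unname(fit$par)
  if (p[3] >= min(temp))
    stopf("fitted T0 = %.2f K is not below the lowest data temperature", p[3])
  covar <- tryCatch(vcov(fit), error = function(e) NULL)
  vft_fit(tau_inf = 10^p[1], b_vft = p[2], t0 = p[3], tau_ref = tau_ref,
          covariance = covar,
          fit_quality = list(sigma = sd(fit$fvec), rss = sum(fit$fvec^2),
                             n = length(temp), converged = TRUE))
}

#' Glass-transition temperature from a VFT fit
#'
#' Inverts the VFT equation at a reference relaxation time, by convention
#' \eqn{T_g = T(\tau_\alpha = 100\,\mathrm{s})}:
#' \deqn{T_g = T_0 + \frac{B}{\ln(\tau_{ref}/\tau_\infty)}.}
#'
#' @param fit A [vft_fit()].
#' @param tau_ref Reference time in s; must exceed `fit$tau_inf`.
#' @return Temperature in K.
#' @export
extrapolate_tg <- function(fit, tau_ref = 100) {
  stopifnot(inherits(fit, "vft_fit"))
  check_number(tau_ref, "tau_ref", positive = TRUE)
  if (tau_ref <= fit$tau_inf)
    stopf("tau_ref (%g s) must exceed tau_inf (%g s)", tau_ref, fit$tau_inf)
  fit$t0 + fit$b_vft / log(tau_ref / fit$tau_inf)
}

#' Temperature at which a VFT fit reaches a target relaxation time
#'
#' Same closed form as [extrapolate_tg()]; used to locate isochronal
#' (equal-\eqn{\tau_\alpha}) conditions across pressures.
#'
#' @param fit A [vft_fit()].
#' @param tau_target Target relaxation time in s, > `fit$tau_inf`.
#' @return Temperature in K.
#' @export
isochrone_temperature <- function(fit, tau_target) {
  extrapolate_tg(fit, tau_target)
}

#' Tg via horizontal displacement of a reference VFT curve
#'
#' For sparse data sets where too few relaxation times are available to
#' fit the VFT equation, the fit of a closely related composition is
#' shifted horizontally (in temperature) until it passes through a single
#' anchor point \eqn{(T_a, \tau_a)}; the shifted curve's 100 s
#' extrapolation then supplies Tg.  The displacement \eqn{\delta} solves
#' \eqn{\tau_{ref}(T_a - \delta) = \tau_a} by 1-D bracketing (tolerance
#' 1e-6 K) and the returned value is `reference$tg + delta`.
#'
#' @param reference A fitted [vft_fit()] for the neighbouring composition.
#' @param anchor_temperature Temperature of the single usable point, K.
#' @param anchor_tau Relaxation time of that point, s (> `reference$tau_inf`).
#' @return Tg in K of the shifted curve.
#' @export
horizontal_shift_tg <- function(reference, anchor_temperature, anchor_tau) {
  stopifnot(inherits(reference, "vft_fit"))
  check_number(anchor_temperature, "anchor_temperature", positive = TRUE)
  check_number(anchor_tau, "anchor_tau", positive = TRUE)
  if (anchor_tau <= reference$tau_inf)
    stopf("anchor_tau (%g s) must exceed the reference tau_inf (%g s)",
          anchor_tau, reference$tau_inf)
  g <- function(delta)
    log10(vft_tau(anchor_temperature - delta, reference$tau_inf,
                  reference$b_vft, reference$t0)) - log10(anchor_tau)
  # delta must keep anchor_temperature - delta > t0
  hi <- anchor_temperature - reference$t0 - 1e-9
  lo <- hi - 2000
  if (g(hi - 1e-6) < 0 || g(lo) > 0)
    stopf("anchor point cannot be reached by horizontally shifting the reference curve")
  delta <- uniroot(g, c(lo, hi - 1e-6), tol = 1e-6)$root
  reference$tg + delta
}
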