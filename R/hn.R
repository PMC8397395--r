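#' Construct a dielectric loss spectrum
#'
#' Bundles one isothermal/isobaric dielectric loss curve \eqn{\varepsilon''(f)}
#' with its measurement condition.  This is the raw unit of spectral fitting.
#'
#' @param frequency Frequencies in Hz, strictly increasing, all > 0.
#' @param loss Dimensionless dielectric loss \eqn{\varepsilon''}, same length
#'   as `frequency`, all > 0.
#' @param temperature Temperature in K.
#' @param pressure Pressure in MPa (default 0.1, ambient).
#' @param label Free-text label (e.g. composition).
#' @return An object of class `loss_spectrum`: a list with the fields above.
#' @examples
#' sp <- loss_spectrum(10^seq(-1, 6, 0.5), hn_loss(10^seq(-1, 6, 0.5),
#'   delta_eps = 2, tau_hn = 1e-3, a = 0.8, b = 0.6), temperature = 350)
#' @export
loss_spectrum <- function(frequency, loss, temperature, pressure = 0.1,
                          label = "") {
  if (length(frequency) != length(loss))
    stopf("'frequency' and 'loss' must have equal length")
  if (length(frequency) < 8L)
    stopf("a loss spectrum needs at least 8 points (got %d)", length(frequency))
  if (any(frequency <= 0)) stopf("'frequency' must be > 0")
  check_increasing(frequency, "frequency")
  if (any(loss <= 0)) stopf("'loss' values must be > 0")
  check_number(temperature, "temperature", positive = TRUE)
  structure(list(frequency = as.numeric(frequency), loss = as.numeric(loss),
                 temperature = temperature, pressure = pressure,
                 label = as.character(label)),
            class = "loss_spectrum")
}

#' @export
print.loss_spectrum <- function(x, ...) {
  cat(sprintf("<loss_spectrum> %d points, %.3g-%.3g Hz, T = %.2f K, P = %.3g MPa%s\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              x$temperature, x$pressure,
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}

check_hn_params <- function(delta_eps, tau_hn, a, b) {
  check_number(delta_eps, "delta_eps", positive = TRUE)
  check_number(tau_hn, "tau_hn", positive = TRUE)
  check_number(a, "a"); check_number(b, "b")
  if (a <= 0 || a > 1) stopf("'a' (symmetric broadening) must satisfy 0 < a <= 1 (got %g)", a)
  if (b <= 0 || b > 1) stopf("'b' (asymmetric broadening) must satisfy 0 < b <= 1 (got %g)", b)
  invisible(NULL)
}

#' Havriliak-Negami dielectric loss
#'
#' Imaginary part of the HN complex permittivity,
#' \deqn{\varepsilon''(\omega) = -\mathrm{Im}\!\left[\frac{\Delta\varepsilon}
#'   {(1 + (i\omega\tau_{HN})^a)^b}\right] + \frac{\sigma_{dc}}
#'   {\varepsilon_0\,\omega},}
#' with \eqn{\omega = 2\pi f}.  The symmetric (`a`) and asymmetric (`b`)
#' broadening parameters recover the Debye loss for `a = b = 1`.  The
#' dc-conductivity term (default off) adds a `1/omega` contribution at low
#' frequency; the high-frequency permittivity \eqn{\varepsilon_\infty}
#' affects only the real part and so does not appear here.
#'
#' @param frequency Frequency in Hz (vectorized), must be > 0.
#' @param delta_eps Dielectric strength \eqn{\Delta\varepsilon} > 0.
#' @param tau_hn HN relaxation time \eqn{\tau_{HN}} in s, > 0.
#' @param a,b Broadening exponents in (0, 1].
#' @param sigma_dc Optional dc conductivity coefficient (S/m); 0 disables
#'   the conductivity term.
#' @return Dimensionless loss values, one per frequency.
#' @examples
#' hn_loss(1 / (2 * pi), delta_eps = 1, tau_hn = 1, a = 1, b = 1)  # 0.5
#' @export
hn_loss <- function(frequency, delta_eps, tau_hn, a, b, sigma_dc = 0) {
  check_hn_params(delta_eps, tau_hn, a, b)
  if (any(frequency <= 0)) stopf("'frequency' must be > 0")
  omega <- 2 * pi * frequency
  eps <- delta_eps / (1 + (1i * omega * tau_hn)^a)^b
  out <- -Im(eps)
  if (sigma_dc != 0) out <- out + sigma_dc / (.EPS0 * omega)
  out
}

#' Alpha-relaxation time from HN parameters
#'
#' Converts the HN relaxation time to the model-free relaxation time
#' \eqn{\tau_\alpha} defined by the loss-peak position
#' (\eqn{2\pi f_{max}\tau_\alpha = 1}):
#' \deqn{\tau_\alpha = \tau_{HN}\,
#'   \left[\sin\frac{a\pi}{2(1+b)}\right]^{-1/a}
#'   \left[\sin\frac{ab\pi}{2(1+b)}\right]^{1/a}.}
#' For the Debye case (`a = b = 1`) this reduces to \eqn{\tau_\alpha =
#' \tau_{HN}}.
#'
#' @inheritParams hn_loss
#' @return \eqn{\tau_\alpha} in seconds.
#' @export
tau_alpha_from_hn <- function(tau_hn, a, b) {
  check_hn_params(1, tau_hn, a, b)
  tau_hn * sin(a * pi / (2 * (1 + b)))^(-1 / a) *
    sin(a * b * pi / (2 * (1 + b)))^(1 / a)
}

#' Construct an HN fit result
#'
#' Low-level constructor; usually produced by [fit_hn()].
#'
#' @param delta_eps,tau_hn,a,b,sigma_dc HN parameters (see [hn_loss()]).
#' @param eps_inf High-frequency limit permittivity (recorded, not used by
#'   the loss model).
#' @param fit_quality Optional list with residual summaries.
#' @param peak_outside_window Logical flag: the fitted peak lies more than a
#'   decade outside the measured frequency window.
#' @return Object of class `hn_fit` with derived `tau_alpha`.
#' @export
hn_fit <- function(delta_eps, tau_hn, a, b, eps_inf = NA_real_, sigma_dc = 0,
                   fit_quality = NULL, peak_outside_window = FALSE) {
  check_hn_params(delta_eps, tau_hn, a, b)
  structure(list(delta_eps = delta_eps, tau_hn = tau_hn, a = a, b = b,
                 eps_inf = eps_inf, sigma_dc = sigma_dc,
                 tau_alpha = tau_alpha_from_hn(tau_hn, a, b),
                 fit_quality = fit_quality,
                 peak_outside_window = peak_outside_window),
            class = "hn_fit")
}

#' @export
print.hn_fit <- function(x, ...) {
  cat(sprintf(paste0("<hn_fit> delta_eps = %.4g, tau_HN = %.4g s, a = %.4f, ",
                     "b = %.4f, tau_alpha = %.4g s%s\n"),
              x$delta_eps, x$tau_hn, x$a, x$b, x$tau_alpha,
              if (isTRUE(x$peak_outside_window)) " [peak outside window]" else ""))
  if (!is.null(x$fit_quality))
    cat(sprintf("  residual sd (log10 loss): %.3g\n", x$fit_quality$sigma))
  invisible(x)
}

#' Fit the Havriliak-Negami function to a loss spectrum
#'
#' Least-squares fit of [hn_loss()] to a single-peak loss spectrum.
#' Residuals are computed on `log10(loss)` so that the decades-spanning
#' wings of the peak carry weight comparable to its maximum.  Optimization
#' uses the Levenberg-Marquardt algorithm ([minpack.lm::nls.lm()]) with
#' box constraints keeping `a`, `b` in (0, 1].
#'
#' The default initialization places \eqn{\tau_{HN} = 1/(2\pi f_{argmax})},
#' \eqn{\Delta\varepsilon = 2\,\varepsilon''_{max}}, `a = 0.9`, `b = 0.7`,
#' which converges for single-peak spectra.  If the fitted loss peak lies
#' more than one decade outside the measured frequency window the result is
#' flagged (`peak_outside_window`), not rejected.
#'
#' @param spectrum A [loss_spectrum()].
#' @param init Optional `hn_fit` (or named list with `delta_eps`, `tau_hn`,
#'   `a`, `b`) supplying the starting point.
#' @param fit_sigma_dc If `TRUE`, a dc-conductivity term is co-fitted;
#'   default `FALSE` (whether measured spectra contained one is recorded in
#'   the result's `sigma_dc` field either way).
#' @return An [hn_fit()] with `fit_quality` populated (`sigma`: residual sd
#'   in log10 units; `rss`: residual sum of squares; `converged`).
#' @export
fit_hn <- function(spectrum, init = NULL, fit_sigma_dc = FALSE) {
  stopifnot(inherits(spectrum, "loss_spectrum"))
  f <- spectrum$frequency
  y <- log10(spectrum$loss)

  if (is.null(init)) {
    imax <- which.max(spectrum$loss)
    init <- list(delta_eps = 2 * spectrum$loss[imax],
                 tau_hn = 1 / (2 * pi * f[imax]), a = 0.9, b = 0.7)
  }
  p0 <- c(log10(init$delta_eps), log10(init$tau_hn), init$a, init$b)
  lower <- c(-12, -18, 1e-3, 1e-3)
  upper <- c(12, 12, 1, 1)
  if (fit_sigma_dc) {
    p0 <- c(p0, -20)            # log10 sigma_dc
    lower <- c(lower, -30); upper <- c(upper, 5)
  }

  resid_fn <- function(p) {
    mod <- hn_loss(f, 10^p[1], 10^p[2], p[3], p[4],
                   sigma_dc = if (fit_sigma_dc) 10^p[5] else 0)
    log10(pmax(mod, 1e-300)) - y
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15, maxiter = 500))
  if (fit$info < 1 || fit$info > 4)
    stopf("HN fit did not converge (info = %d, last delta_eps = %g, tau_hn = %g)",
          fit$info, 10^fit$par[1], 10^fit$par[2])
  p <- fit$par
  res <- hn_fit(delta_eps = 10^p[1], tau_hn = 10^p[2], a = p[3], b = p[4],
                sigma_dc = if (fit_sigma_dc) 10^p[5] else 0,
                fit_quality = list(sigma = sd(fit$fvec),
                                   rss = sum(fit$fvec^2),
                                   converged = TRUE,
                                   residual_scale = "log10(loss)"))
  fpeak <- 1 / (2 * pi * res$tau_alpha)
  res$peak_outside_window <- fpeak < min(f) / 10 || fpeak > max(f) * 10
  res
}

#' Construct a dielectric-strength decay trace
#'
#' Time evolution of the dielectric strength \eqn{\Delta\varepsilon(t)}
#' during isothermal annealing.  A sudden drop marks the onset of
#' recrystallization of the amorphous drug; a plateau marks its cessation.
#'
#' @param time Annealing times in s, strictly increasing.
#' @param delta_eps Dielectric strengths, all >= 0.
#' @param temperature Temperature in K.
#' @param pressure Pressure in MPa.
#' @return Object of class `delta_eps_trace`.
#' @export
delta_eps_trace <- function(time, delta_eps, temperature = NA_real_,
                            pressure = 0.1) {
  if (length(time) != length(delta_eps))
    stopf("'time' and 'delta_eps' must have equal length")
  if (length(time) == 0L) stopf("empty trace")
  check_increasing(time, "time")
  if (any(delta_eps < 0)) stopf("'delta_eps' must be >= 0")
  structure(list(time = as.numeric(time), delta_eps = as.numeric(delta_eps),
                 temperature = temperature, pressure = pressure),
            class = "delta_eps_trace")
}

#' Detect recrystallization onset and cessation in a dielectric-strength trace
#'
#' Onset is the first time at which \eqn{\Delta\varepsilon} falls below
#' `(1 - drop_threshold)` times the initial baseline (the first recorded
#' value).  Cessation is the start of the first run of `plateau_window`
#' consecutive points after onset whose relative range is below
#' `plateau_tol`.  Either can be `NA` when the criterion is never met
#' (e.g. a trace that drops but never plateaus within the record).
#'
#' @param trace A [delta_eps_trace()].
#' @param drop_threshold Relative drop defining onset (default 0.1 = 10%).
#' @param plateau_window Number of consecutive points defining a plateau
#'   (default 5).
#' @param plateau_tol Relative range below which those points count as flat
#'   (default 0.02).
#' @return List with `onset_time` and `cessation_time` (s, or `NA`).
#' @export
detect_recrystallization <- function(trace, drop_threshold = 0.1,
                                     plateau_window = 5L, plateau_tol = 0.02) {
  stopifnot(inherits(trace, "delta_eps_trace"))
  n <- length(trace$time)
  if (n < plateau_window + 2L)
    stopf("trace too short: need at least plateau_window + 2 = %d points, got %d",
          plateau_window + 2L, n)
  de <- trace$delta_eps
  baseline <- de[1L]
  below <- which(de < (1 - drop_threshold) * baseline)
  onset <- if (length(below)) trace$time[below[1L]] else NA_real_
  cessation <- NA_real_
  if (!is.na(onset)) {
    i0 <- below[1L]
    for (i in seq(i0, n - plateau_window + 1L)) {
      win <- de[i:(i + plateau_window - 1L)]
      centre <- mean(win)
      rel_range <- if (centre > 0) diff(range(win)) / centre else 0
      if (rel_range < plateau_tol) { cessation <- trace$time[i]; break }
    }
  }
  list(onset_time = onset, cessation_time = cessation)
}
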