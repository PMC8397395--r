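#' Gordon-Taylor parameter set
#'
#' Parameterizes the composition dependence of the glass-transition
#' temperature of a binary drug-polymer mixture,
#' \deqn{T_g = \frac{W_1 T_{g1} + K\,W_2 T_{g2}}{W_1 + K\,W_2},}
#' with \eqn{W_1, W_2} the weight fractions of drug and polymer.  `K` can
#' either be fitted to measured mixtures or computed from the
#' heat-capacity increments at Tg of the pure components,
#' \eqn{K = \Delta C_{p2} / \Delta C_{p1}} (the adopted convention is
#' recorded in the `source` field, since more than one convention exists
#' in the literature).
#'
#' @param tg_drug Pure amorphous drug Tg (K), \eqn{T_{g1}}.
#' @param tg_poly Pure polymer Tg (K), \eqn{T_{g2}}; must exceed `tg_drug`
#'   for this system class.
#' @param k Dimensionless Gordon-Taylor constant > 0; may be omitted when
#'   both `delta_cp_*` are supplied.
#' @param delta_cp_drug,delta_cp_poly Optional heat-capacity increments at
#'   Tg, J/(g K).
#' @param source One of `"fitted"` or `"from_delta_cp"`.
#' @return Object of class `gt_params`.
#' @export
gt_params <- function(tg_drug, tg_poly, k = NULL,
                      delta_cp_drug = NULL, delta_cp_poly = NULL,
                      source = NULL) {
  if (is.null(source)) source <- if (is.null(k)) "from_delta_cp" else "fitted"
  check_number(tg_drug, "tg_drug", positive = TRUE)
  check_number(tg_poly, "tg_poly", positive = TRUE)
  if (tg_drug >= tg_poly)
    stopf("expected tg_drug < tg_poly (got %g >= %g)", tg_drug, tg_poly)
  if (is.null(k)) {
    if (is.null(delta_cp_drug) || is.null(delta_cp_poly))
      stopf("supply either 'k' or both heat-capacity increments")
    check_number(delta_cp_drug, "delta_cp_drug", positive = TRUE)
    check_number(delta_cp_poly, "delta_cp_poly", positive = TRUE)
    k <- delta_cp_poly / delta_cp_drug
  }
  check_number(k, "k", positive = TRUE)
  structure(list(tg_drug = tg_drug, tg_poly = tg_poly, k = k,
                 delta_cp_drug = delta_cp_drug, delta_cp_poly = delta_cp_poly,
                 source = source, k_convention = "delta_cp_poly / delta_cp_drug"),
            class = "gt_params")
}

#' @export
print.gt_params <- function(x, ...) {
  cat(sprintf("<gt_params> Tg(drug) = %.2f K, Tg(poly) = %.2f K, K = %.4f (%s)\n",
              x$tg_drug, x$tg_poly, x$k, x$source))
  invisible(x)
}

#' Predict the mixture Tg from composition
#'
#' @param params A [gt_params()].
#' @param w_poly Weight fraction of polymer \eqn{W_2} in \[0, 1\]
#'   (vectorized).
#' @return Tg in K.
#' @examples
#' p <- gt_params(294, 377, k = 0.7)
#' gt_predict(p, c(0, 0.5, 1))
#' @export
gt_predict <- function(params, w_poly) {
  stopifnot(inherits(params, "gt_params"))
  check_fraction(w_poly, "w_poly")
  w1 <- 1 - w_poly
  (w1 * params$tg_drug + params$k * w_poly * params$tg_poly) /
    (w1 + params$k * w_poly)
}

#' Fit the Gordon-Taylor constant to composition-Tg data
#'
#' Least-squares fit of the Gordon-Taylor curve to measured
#' (composition, Tg) points by Levenberg-Marquardt.  By default the pure
#' component Tg values are fixed to the measured endpoints (taken from the
#' supplied points at `w_poly = 0` and `w_poly = 1`, or given explicitly)
#' and only `K` is free; with `fix_endpoints = FALSE` all three parameters
#' are fitted.
#'
#' @param points Data frame with columns `w_poly` (weight fraction of
#'   polymer) and `tg_K`, or columns `wtpct_drug` and `tg_K`.
#' @param fix_endpoints Fix the pure-component Tg values (default `TRUE`).
#' @param tg_drug,tg_poly Optional explicit endpoint values (K); defaults
#'   are read from the endpoint rows of `points`.
#' @return A [gt_params()] with attribute `"fit"` holding residual
#'   diagnostics (rss, sigma, n).
#' @export
fit_gordon_taylor <- function(points, fix_endpoints = TRUE,
                              tg_drug = NULL, tg_poly = NULL) {
  points <- as.data.frame(points)
  if (!"w_poly" %in% names(points)) {
    if (!"wtpct_drug" %in% names(points))
      stopf("'points' needs a 'w_poly' or 'wtpct_drug' column")
    points$w_poly <- 1 - points$wtpct_drug / 100
  }
  if (!"tg_K" %in% names(points)) stopf("'points' needs a 'tg_K' column")
  w2 <- points$w_poly
  tg <- points$tg_K
  check_fraction(w2, "w_poly")
  if (length(unique(w2)) < 2L)
    stopf("degenerate input: all points at the same composition")

  if (is.null(tg_drug)) {
    i <- which(w2 == 0)
    tg_drug <- if (length(i)) mean(tg[i]) else min(tg)
  }
  if (is.null(tg_poly)) {
    i <- which(w2 == 1)
    tg_poly <- if (length(i)) mean(tg[i]) else max(tg)
  }

  if (fix_endpoints) {
    resid_fn <- function(p) {
      pr <- gt_params(tg_drug, tg_poly, k = p[1])
      gt_predict(pr, w2) - tg
    }
    fit <- minpack.lm::nls.lm(par = c(k = 0.5), lower = 1e-6, upper = 100,
                              fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-15, ptol = 1e-15))
    out <- gt_params(tg_drug, tg_poly, k = fit$par[[1]])
  } else {
    if (length(w2) < 3L) stopf("free-endpoint fit needs at least 3 points")
    resid_fn <- function(p) {
      pr <- gt_params(p[2], p[3], k = p[1])
      gt_predict(pr, w2) - tg
    }
    fit <- minpack.lm::nls.lm(par = c(0.5, tg_drug, tg_poly),
                              lower = c(1e-6, 1, 1), upper = c(100, 2000, 2000),
                              fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-15, ptol = 1e-15))
    out <- gt_params(fit$par[[2]], fit$par[[3]], k = fit$par[[1]])
  }
  if (fit$info < 1 || fit$info > 4) stopf("Gordon-Taylor fit did not converge")
  attr(out, "fit") <- list(rss = sum(fit$fvec^2), sigma = sd(fit$fvec),
                           n = length(w2))
  out
}

#' Invert the Gordon-Taylor curve: Tg to drug weight fraction
#'
#' The core of the annealing protocol: the Tg measured after excess drug
#' has recrystallized is compared with the composition dependence of Tg to
#' read off the remaining (equilibrium) drug content.  The closed-form
#' inverse of the Gordon-Taylor equation is
#' \deqn{W_1 = \frac{K (T_{g2} - T_g)}{(T_g - T_{g1}) + K (T_{g2} - T_g)}.}
#' `gt_predict` is strictly monotone in composition for `K > 0`, so the
#' inverse is unique.
#'
#' @param params A [gt_params()].
#' @param tg_observed Measured Tg in K; must lie in
#'   \[`tg_drug`, `tg_poly`\].
#' @return Weight fraction of drug \eqn{W_1} in \[0, 1\].
#' @export
gt_invert <- function(params, tg_observed) {
  stopifnot(inherits(params, "gt_params"))
  if (any(tg_observed < params$tg_drug) || any(tg_observed > params$tg_poly))
    stopf("tg_observed must lie within [Tg(drug) = %g, Tg(poly) = %g] K",
          params$tg_drug, params$tg_poly)
  k <- params$k
  num <- k * (params$tg_poly - tg_observed)
  num / ((tg_observed - params$tg_drug) + num)
}

#' Construct a calorimetric step trace
#'
#' A heat-flow-like signal versus temperature containing (at most) one
#' sigmoidal heat-capacity step at the glass transition.
#'
#' @param temperature Temperatures in K, strictly increasing.
#' @param signal Heat-flow-like trace, arbitrary units.
#' @param scan_rate Heating rate in K/min (metadata).
#' @return Object of class `thermogram`.
#' @export
thermogram <- function(temperature, signal, scan_rate = 10) {
  if (length(temperature) != length(signal))
    stopf("'temperature' and 'signal' must have equal length")
  check_increasing(temperature, "temperature")
  structure(list(temperature = as.numeric(temperature),
                 signal = as.numeric(signal), scan_rate = scan_rate),
            class = "thermogram")
}

#' Glass-transition temperature from a calorimetric step trace
#'
#' Fits the trace with linear pre/post baselines joined by a logistic
#' step, and reports Tg as the midpoint of the heat-capacity increment
#' (the temperature at half step height).  The fit fails with a detection
#' error when no step rises above the noise floor (fitted height below
#' `min_snr` times the residual scatter).
#'
#' @param trace A [thermogram()].
#' @param min_snr Minimum ratio of fitted step height to residual sd for a
#'   step to count as detected (default 5).
#' @return Tg in K.
#' @export
tg_from_thermogram <- function(trace, min_snr = 5) {
  stopifnot(inherits(trace, "thermogram"))
  temp <- trace$temperature
  y <- trace$signal
  n <- length(temp)
  if (n < 10L) stopf("thermogram too short to locate a step")

  # initialization from the smoothed derivative
  dy <- diff(y) / diff(temp)
  i0 <- which.max(abs(stats::filter(dy, rep(1 / 3, 3), sides = 2))[-c(1, length(dy))]) + 1L
  tg0 <- temp[i0 + 1L]
  h0 <- mean(tail(y, n %/% 5)) - mean(head(y, n %/% 5))
  w0 <- max(diff(range(temp)) / 20, 1e-3)
  slope0 <- (y[n %/% 5] - y[1]) / (temp[n %/% 5] - temp[1] + 1e-9)

  resid_fn <- function(p)
    p[1] + p[2] * (temp - p[4]) + p[3] * plogis((temp - p[4]) / p[5]) - y
  fit <- minpack.lm::nls.lm(par = c(mean(head(y, n %/% 5)), slope0, h0, tg0, w0),
                            lower = c(-Inf, -Inf, -Inf, min(temp), 1e-4),
                            upper = c(Inf, Inf, Inf, max(temp), diff(range(temp))),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15, maxiter = 500))
  h <- fit$par[3]
  noise <- sd(fit$fvec)
  if (!is.finite(h) || abs(h) <= min_snr * max(noise, 1e-12))
    stopf("no heat-capacity step detected (height %.3g vs noise %.3g)", h, noise)
  fit$par[[4]]
}
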