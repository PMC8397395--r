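#' Configuration for the synthetic-data generators
#'
#' Fixes the random seed, frequency grid and noise magnitudes used by
#' every generator, so that a complete synthetic study is reproducible
#' bit-for-bit from one configuration object.
#'
#' Noise models (see the methods vignette for rationale): dielectric loss
#' receives multiplicative lognormal noise (loss spans decades and must
#' stay positive); relaxation times receive additive Gaussian noise in
#' log10 units (they span 8+ decades); Tg and solubility points receive
#' additive Gaussian noise in K and weight percent.  The default
#' magnitudes (2% on loss, 0.05 decades on tau, 0.5 K on Tg, 0.5 wt% on
#' solubility) are assumptions chosen to be typical of careful broadband
#' dielectric and calorimetric work; instrument noise levels are rarely
#' published and these defaults are configurable.
#'
#' @param seed Integer seed; fixes all randomness of a generator call.
#' @param frequency_grid Frequencies in Hz, strictly increasing, > 0.
#'   Default: 10 points per decade from 1e-1 to 1e6 Hz (the usual
#'   broadband instrument range).
#' @param eps_rel_sd Relative sd of the multiplicative lognormal noise on
#'   dielectric loss (0 = noiseless).
#' @param tau_log10_sd Additive sd on log10(tau).
#' @param tg_sd_K Additive sd on Tg, K.
#' @param sol_wtpct_sd Additive sd on solubility points, wt%.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             frequency_grid = 10^seq(-1, 6, by = 0.1),
                             eps_rel_sd = 0.02, tau_log10_sd = 0.05,
                             tg_sd_K = 0.5, sol_wtpct_sd = 0.5) {
  if (any(frequency_grid <= 0)) stopf("'frequency_grid' must be > 0")
  check_increasing(frequency_grid, "frequency_grid")
  for (nm in c("eps_rel_sd", "tau_log10_sd", "tg_sd_K", "sol_wtpct_sd")) {
    check_number(get(nm), nm)
    if (get(nm) < 0) stopf("'%s' must be >= 0", nm)
  }
  structure(list(seed = as.integer(seed),
                 frequency_grid = as.numeric(frequency_grid),
                 eps_rel_sd = eps_rel_sd, tau_log10_sd = tau_log10_sd,
                 tg_sd_K = tg_sd_K, sol_wtpct_sd = sol_wtpct_sd),
            class = "synthetic_config")
}

noiseless <- function(config) {
  config$eps_rel_sd <- 0; config$tau_log10_sd <- 0
  config$tg_sd_K <- 0; config$sol_wtpct_sd <- 0
  config
}

with_config_seed <- function(config, expr) {
  set.seed(config$seed)
  expr
}

#' Generate a synthetic HN loss spectrum
#'
#' Evaluates [hn_loss()] on the configured frequency grid and applies
#' multiplicative lognormal noise: `loss * exp(rnorm(n, 0, sd))` with
#' `sd = log(1 + eps_rel_sd)`.  With all noise sds zero the model loss is
#' returned exactly.
#'
#' @inheritParams hn_loss
#' @param config A [synthetic_config()].
#' @param temperature,pressure,label Condition metadata for the returned
#'   spectrum.
#' @return A [loss_spectrum()].
#' @export
generate_hn_spectrum <- function(delta_eps, tau_hn, a, b, config,
                                 sigma_dc = 0, temperature = 300,
                                 pressure = 0.1, label = "") {
  stopifnot(inherits(config, "synthetic_config"))
  check_hn_params(delta_eps, tau_hn, a, b)
  f <- config$frequency_grid
  y <- hn_loss(f, delta_eps, tau_hn, a, b, sigma_dc = sigma_dc)
  if (config$eps_rel_sd > 0)
    y <- with_config_seed(config,
      y * exp(rnorm(length(y), 0, log(1 + config$eps_rel_sd))))
  loss_spectrum(f, y, temperature = temperature, pressure = pressure,
                label = label)
}

#' Generate a synthetic VFT relaxation-time series
#'
#' \eqn{\tau(T) = \tau_\infty \exp(B/(T - T_0))} with optional Gaussian
#' noise in log10(tau).
#'
#' @inheritParams vft_tau
#' @param temperatures Temperatures in K; all must exceed `t0`.
#' @param config A [synthetic_config()].
#' @param pressure,composition_label Metadata for the returned series.
#' @return A [relaxation_series()].
#' @export
generate_vft_series <- function(tau_inf, b_vft, t0, temperatures, config,
                                pressure = 0.1, composition_label = "") {
  stopifnot(inherits(config, "synthetic_config"))
  tau <- vft_tau(temperatures, tau_inf, b_vft, t0)
  if (config$tau_log10_sd > 0)
    tau <- with_config_seed(config,
      10^(log10(tau) + rnorm(length(tau), 0, config$tau_log10_sd)))
  relaxation_series(temperatures, tau, pressure = pressure,
                    composition_label = composition_label)
}

#' Generate synthetic Gordon-Taylor composition-Tg points
#'
#' @param tg_drug,tg_poly Pure-component Tg values, K.
#' @param k_gt Gordon-Taylor constant > 0.
#' @param fractions Polymer weight fractions in \[0, 1\].
#' @param config A [synthetic_config()].
#' @return Data frame with columns `w_poly`, `wtpct_drug`, `tg_K`.
#' @export
generate_gt_curve <- function(tg_drug, tg_poly, k_gt, fractions, config) {
  stopifnot(inherits(config, "synthetic_config"))
  check_fraction(fractions, "fractions")
  params <- gt_params(tg_drug, tg_poly, k = k_gt)
  tg <- gt_predict(params, fractions)
  if (config$tg_sd_K > 0)
    tg <- with_config_seed(config, tg + rnorm(length(tg), 0, config$tg_sd_K))
  data.frame(w_poly = fractions, wtpct_drug = 100 * (1 - fractions),
             tg_K = tg)
}

#' Generate synthetic Flory-Huggins solubility points
#'
#' Solves the liquidus of `model` at each annealing temperature, converts
#' to weight percent, and adds Gaussian noise clipped to (0, 100).
#'
#' @param model An [fh_model()].
#' @param temperatures Annealing temperatures in K, all below the model's
#'   Tm0.
#' @param config A [synthetic_config()].
#' @param pressure Pressure metadata, MPa.
#' @return Data frame with columns `temperature_K`, `wtpct_drug`,
#'   `pressure_MPa`.
#' @export
generate_fh_solubility_points <- function(model, temperatures, config,
                                          pressure = 0.1) {
  stopifnot(inherits(model, "fh_model"), inherits(config, "synthetic_config"))
  if (any(temperatures >= model$constants$tm0))
    stopf("all temperatures must be below Tm0 = %g K (liquidus undefined above)",
          model$constants$tm0)
  w <- vapply(temperatures, solve_liquidus_wtpct, numeric(1), model = model)
  if (config$sol_wtpct_sd > 0)
    w <- with_config_seed(config,
      pmin(pmax(w + rnorm(length(w), 0, config$sol_wtpct_sd), 1e-6), 100 - 1e-6))
  data.frame(temperature_K = temperatures, wtpct_drug = w,
             pressure_MPa = pressure)
}

#' Generate a synthetic dielectric-strength decay trace
#'
#' Logistic-in-time decay of the dielectric strength from an initial to a
#' final plateau, emulating recrystallization of the excess amorphous
#' drug.  Only the onset/cessation structure matters downstream; no
#' crystallization-kinetics model is implied.
#'
#' @param initial_delta_eps,final_delta_eps Initial and final plateau
#'   values; `initial > final >= 0`.
#' @param rate Decay rate in 1/s, > 0.
#' @param times Times in s, ordered increasing.
#' @param config A [synthetic_config()].
#' @param midpoint Time of the inflection, s (default: centre of `times`).
#' @return A [delta_eps_trace()].
#' @export
generate_recrystallization_trace <- function(initial_delta_eps,
                                             final_delta_eps, rate, times,
                                             config,
                                             midpoint = mean(range(times))) {
  stopifnot(inherits(config, "synthetic_config"))
  check_number(initial_delta_eps, "initial_delta_eps", positive = TRUE)
  check_number(final_delta_eps, "final_delta_eps")
  if (final_delta_eps < 0 || final_delta_eps >= initial_delta_eps)
    stopf("need initial_delta_eps > final_delta_eps >= 0")
  check_number(rate, "rate", positive = TRUE)
  check_increasing(times, "times")
  de <- final_delta_eps + (initial_delta_eps - final_delta_eps) *
    plogis(-(times - midpoint) * rate)
  if (config$eps_rel_sd > 0)
    de <- with_config_seed(config,
      de * exp(rnorm(length(de), 0, log(1 + config$eps_rel_sd))))
  delta_eps_trace(times, de)
}

#' Generate a synthetic calorimetric step trace
#'
#' Sigmoidal heat-capacity step of height `step_height` centred at `tg`;
#' `width` is the temperature interval over which the step rises from 12%
#' to 88% of its height (4 logistic scale units).
#'
#' @param tg Glass-transition temperature, K.
#' @param step_height Step height, arbitrary heat-flow units (0 gives a
#'   flat trace; downstream midpoint extraction then errors).
#' @param width Transition width in K, > 0.
#' @param temperatures Temperatures in K, ordered increasing.
#' @param config A [synthetic_config()].
#' @param baseline_slope Linear baseline slope, units/K (default 0).
#' @param noise_sd Additive Gaussian noise sd in signal units (default:
#'   `step_height/200`, i.e. 0.5% of the step; 0 when `step_height = 0`).
#' @return A [thermogram()].
#' @export
generate_thermogram <- function(tg, step_height, width, temperatures, config,
                                baseline_slope = 0,
                                noise_sd = abs(step_height) / 200) {
  stopifnot(inherits(config, "synthetic_config"))
  check_number(tg, "tg", positive = TRUE)
  check_number(width, "width", positive = TRUE)
  check_increasing(temperatures, "temperatures")
  y <- baseline_slope * (temperatures - tg) +
    step_height * plogis((temperatures - tg) / (width / 4))
  if (noise_sd > 0)
    y <- with_config_seed(config, y + rnorm(length(y), 0, noise_sd))
  thermogram(temperatures, y)
}
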