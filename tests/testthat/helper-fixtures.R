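# Shared fixtures: configs and ground-truth models used across test files.

quiet_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, eps_rel_sd = 0, tau_log10_sd = 0,
                   tg_sd_K = 0, sol_wtpct_sd = 0, ...)
}

# A VFT parameter set with Tg(100 s) = 250 + 2000/ln(1e16) ~ 304.29 K
ref_vft <- function() vft_fit(tau_inf = 1e-14, b_vft = 2000, t0 = 250)

ref_gt <- function() gt_params(tg_drug = 294, tg_poly = 377, k = 0.7)

ref_fh <- function(chi = chi_model("linear_in_invT", a_chi = 6.7, b_chi = -3000))
  fh_model(nms_kva_constants(), chi)

# Brute-force liquidus root: sign-change scan + bisection, independent of
# solve_liquidus_phi's internals (coarser grid, plain bisection loop).
scan_liquidus_phi <- function(temperature, model, n = 4000L) {
  grid <- exp(seq(log(1e-6), log(1 - 1e-10), length.out = n))
  v <- liquidus_residual(temperature, grid, model)
  s <- which(diff(sign(v)) != 0)
  stopifnot(length(s) > 0)
  lo <- grid[max(s)]; hi <- grid[max(s) + 1L]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(liquidus_residual(temperature, mid, model)) ==
        sign(liquidus_residual(temperature, lo, model))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Numerical loss-peak frequency: discrete argmax on a log grid refined by
# parabolic interpolation of log-loss over the three bracketing points.
argmax_peak_frequency <- function(loss_fn, lg_from = -2, lg_to = 8,
                                  per_decade = 1000) {
  lg <- seq(lg_from, lg_to, by = 1 / per_decade)
  y <- log(loss_fn(10^lg))
  i <- which.max(y)
  if (i == 1L || i == length(lg)) return(10^lg[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  shift <- if (denom < 0) 0.5 * (y[i - 1L] - y[i + 1L]) / denom else 0
  10^(lg[i] + shift / per_decade)
}
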