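test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(seed = 7)
  expect_identical(generate_hn_spectrum(2, 1e-4, 0.8, 0.6, cfg)$loss,
                   generate_hn_spectrum(2, 1e-4, 0.8, 0.6, cfg)$loss)
  expect_identical(generate_vft_series(1e-14, 2000, 250, 300:310, cfg)$tau_alpha,
                   generate_vft_series(1e-14, 2000, 250, 300:310, cfg)$tau_alpha)
  mod <- ref_fh()
  expect_identical(generate_fh_solubility_points(mod, c(370, 390), cfg),
                   generate_fh_solubility_points(mod, c(370, 390), cfg))
  expect_identical(generate_thermogram(321, 1, 5, seq(300, 340, 0.2), cfg)$signal,
                   generate_thermogram(321, 1, 5, seq(300, 340, 0.2), cfg)$signal)
  cfg2 <- synthetic_config(seed = 8)
  expect_false(identical(generate_hn_spectrum(2, 1e-4, 0.8, 0.6, cfg)$loss,
                         generate_hn_spectrum(2, 1e-4, 0.8, 0.6, cfg2)$loss))
})

test_that("noiseless spectrum generator reproduces the model loss exactly", {
  z <- quiet_config()
  # Debye limit: peak at 1/(2 pi) Hz with height delta_eps / 2
  sp <- generate_hn_spectrum(1, 1, 1, 1, z)
  f_peak <- sp$frequency[which.max(sp$loss)]
  expect_equal(f_peak, 1 / (2 * pi), tolerance = 10^0.1 - 1)
  expect_equal(max(sp$loss), 0.5, tolerance = 1e-3)
  # general HN: generated curve equals hn_loss on the grid
  sp2 <- generate_hn_spectrum(2, 1e-4, 0.8, 0.6, z)
  expect_identical(sp2$loss, hn_loss(sp2$frequency, 2, 1e-4, 0.8, 0.6))
  # peak location matches dense-grid argmax of the model
  dense <- 10^seq(0, 6, by = 1e-3)
  f_arg <- dense[which.max(hn_loss(dense, 2, 1e-4, 0.8, 0.6))]
  expect_equal(sp2$frequency[which.max(sp2$loss)], f_arg, tolerance = 10^0.1 - 1)
})

test_that("generator input validation names the offending parameter", {
  z <- quiet_config()
  expect_error(generate_hn_spectrum(2, 1e-4, 1.2, 0.6, z), "'a'")
  expect_error(generate_hn_spectrum(2, 1e-4, 0.8, 0, z), "'b'")
  expect_error(generate_hn_spectrum(-1, 1e-4, 0.8, 0.6, z), "delta_eps")
  expect_error(generate_vft_series(1e-14, 2000, 250, c(240, 300), z), "T0")
  expect_error(generate_gt_curve(294, 377, 0.7, c(0.2, 1.4), z), "fractions")
  expect_error(generate_fh_solubility_points(ref_fh(), c(400, 425), z), "Tm0")
  expect_error(generate_recrystallization_trace(1, 0.2, 0.1, c(3, 2, 1), z),
               "increasing")
  expect_error(synthetic_config(eps_rel_sd = -0.1), ">= 0")
  expect_error(synthetic_config(frequency_grid = c(1, 1, 2)), "increasing")
})

test_that("VFT series generator matches the analytic curve and its limits", {
  z <- quiet_config()
  s <- generate_vft_series(1e-14, 2000, 250, 304.2868, z)
  expect_equal(s$tau_alpha, 100, tolerance = 1e-4)
  # tau decreases to tau_inf from above as T grows
  s2 <- generate_vft_series(1e-14, 2000, 250, c(300, 400, 700, 1500, 5000), z)
  expect_true(all(diff(s2$tau_alpha) < 0))
  expect_true(all(s2$tau_alpha > 1e-14))
  expect_equal(s2$tau_alpha[5], 1e-14, tolerance = 0.7)
})

test_that("Gordon-Taylor generator hits the pure-component endpoints", {
  z <- quiet_config()
  g <- generate_gt_curve(294, 377, 0.7, c(0, 0.5, 1), z)
  expect_equal(g$tg_K[1], 294)
  expect_equal(g$tg_K[3], 377)
  expect_true(g$tg_K[2] > 294 && g$tg_K[2] < 377)
})

test_that("FH solubility generator approaches pure drug just below Tm0", {
  z <- quiet_config()
  mod <- ref_fh()
  pts <- generate_fh_solubility_points(mod, 421 - 1e-4, z)
  expect_gt(pts$wtpct_drug, 99.9)
})

test_that("recrystallization trace spans its plateaus and is detectable", {
  z <- quiet_config()
  tr <- generate_recrystallization_trace(2, 0.4, 0.01, seq(0, 3000, 25), z,
                                         midpoint = 1200)
  expect_equal(tr$delta_eps[1], 2, tolerance = 1e-3)
  expect_equal(tail(tr$delta_eps, 1), 0.4, tolerance = 1e-3)
  det <- detect_recrystallization(tr)
  expect_false(is.na(det$onset_time))
  expect_false(is.na(det$cessation_time))
  expect_gt(det$cessation_time, det$onset_time)
  # cessation is flagged only once the final plateau is reached
  expect_gt(det$cessation_time, 1200)
})

test_that("thermogram generator centres the step at tg", {
  z <- quiet_config()
  th <- generate_thermogram(321, 1, 4, seq(300, 345, 0.1), z, noise_sd = 0)
  expect_equal(tg_from_thermogram(th), 321, tolerance = 0.1)
  flat <- generate_thermogram(321, 0, 4, seq(300, 345, 0.1), z, noise_sd = 0)
  expect_error(tg_from_thermogram(flat), "step")
})

test_that("noisy generator/fit pairs recover parameters within 3x standard errors", {
  # Gordon-Taylor K under 0.5 K Tg noise, 50 replicates
  fr <- seq(0, 1, by = 0.125)
  # asymptotic SE of K: sigma_Tg / ||dTg/dK|| (linearization at the truth)
  eps <- 1e-6
  dTg <- (gt_predict(gt_params(294, 377, k = 0.7 + eps), fr) -
            gt_predict(gt_params(294, 377, k = 0.7 - eps), fr)) / (2 * eps)
  k_se <- 0.5 / sqrt(sum(dTg^2))
  cover <- vapply(1:50, function(i) {
    cfg <- synthetic_config(seed = i, tg_sd_K = 0.5)
    pts <- generate_gt_curve(294, 377, 0.7, fr, cfg)
    fit <- fit_gordon_taylor(pts, tg_drug = 294, tg_poly = 377)
    abs(fit$k - 0.7) < 3 * k_se
  }, logical(1))
  expect_gt(mean(cover), 0.9)
  # FH constant chi under 0.5 wt% noise
  cc <- nms_kva_constants()
  truth <- fh_model(cc, chi_model("constant", chi = -1.5))
  err <- vapply(1:50, function(i) {
    cfg <- synthetic_config(seed = i, sol_wtpct_sd = 0.5)
    pts <- generate_fh_solubility_points(truth, seq(365, 400, 5), cfg)
    fit <- fit_fh_chi_constant(pts, cc)
    c(fit$chi$chi - -1.5, fit$chi$uncertainties[["chi"]])
  }, numeric(2))
  expect_gt(mean(abs(err[1, ]) < 3 * err[2, ]), 0.9)
})
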