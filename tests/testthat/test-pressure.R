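test_that("vertical Tg-curve transposition is an exact shift with exact inversion", {
  gt <- ref_gt()
  id <- transpose_tg_curve(gt, pressure_condition(50, 435, delta_tg = 0))
  expect_equal(gt_predict_shifted(id, c(0, 0.4, 1)), gt_predict(gt, c(0, 0.4, 1)))
  up <- transpose_tg_curve(gt, pressure_condition(50, 435, delta_tg = 12))
  # shifted pure-drug endpoint: ambient 294 K -> 306 K at pressure
  expect_equal(gt_predict_shifted(up, 0), 306)
  w <- seq(0, 1, 0.1)
  expect_equal(gt_predict_shifted(up, w), gt_predict(gt, w) + 12)
  # shift equivariance of the inverse
  tg0 <- gt_predict(gt, 0.55)
  expect_equal(gt_invert_shifted(up, tg0 + 12), gt_invert(gt, tg0),
               tolerance = 1e-12)
})

test_that("estimate_delta_tg recovers constant offsets and flags varying ones", {
  amb <- data.frame(wtpct_drug = c(80, 60, 45), tg_K = c(302, 320, 334))
  hp <- data.frame(wtpct_drug = c(80, 60, 45), tg_K = c(302, 320, 334) + 12)
  est <- estimate_delta_tg(amb, hp)
  expect_equal(est$delta_tg, 12)
  expect_equal(est$spread, 0)
  expect_true(est$constant)
  # the in-package dielectric Tg tables at both pressures give 12 K
  d <- nms_kva_data()
  est2 <- estimate_delta_tg(d$composition_tg_bds, d$composition_tg_bds_50mpa)
  expect_equal(est2$delta_tg, 12)
  expect_true(est2$constant)
  # non-constant offsets are reported with nonzero spread
  hp3 <- data.frame(wtpct_drug = c(80, 60, 45), tg_K = c(302, 320, 334) + c(8, 12, 16))
  est3 <- estimate_delta_tg(amb, hp3)
  expect_equal(est3$delta_tg, 12)
  expect_gt(est3$spread, 0)
  expect_error(estimate_delta_tg(amb, data.frame(wtpct_drug = 30, tg_K = 350)),
               "matched")
})

test_that("melting-point-referenced transposition shifts temperatures only", {
  pts <- data.frame(temperature_K = c(368, 378, 388, 398),
                    wtpct_drug = c(29, 31, 32, 36), pressure_MPa = 50)
  same <- transpose_solubility_points(pts, 421, 421)
  expect_equal(same$temperature_K, pts$temperature_K)
  down <- transpose_solubility_points(pts, 421, 435)
  expect_equal(down$temperature_K, pts$temperature_K - 14)
  expect_equal(down$wtpct_drug, pts$wtpct_drug)   # compositions untouched
  expect_equal(unique(down$temperature_shift_K), -14)
  # a 50 MPa point at 398 K lands at 384 K on the ambient reference
  expect_equal(down$temperature_K[down$wtpct_drug == 36], 384)
  # opposite shifts compose to the identity
  back <- transpose_solubility_points(down, 435, 421)
  expect_equal(back$temperature_K, pts$temperature_K)
})

test_that("combined_fh_fit degenerates to the ambient fit and recovers shifted truth", {
  z <- quiet_config()
  cc <- nms_kva_constants()
  d <- nms_kva_data()
  cond <- pressure_condition(50, 435, delta_tg = 12)
  alone <- fit_fh_chi_constant(d$solubility_bds_ambient, cc)
  empty <- combined_fh_fit(d$solubility_bds_ambient,
                           d$solubility_bds_50mpa[0, ], cond, cc, "chi_constant")
  expect_equal(empty$chi$chi, alone$chi$chi, tolerance = 1e-12)
  # end-to-end: high-pressure points generated from one FH model with a pure
  # vertical offset are pooled back onto the generating liquidus
  truth <- fh_model(cc, chi_model("linear_in_invT", a_chi = 6.7, b_chi = -3000))
  amb <- generate_fh_solubility_points(truth, seq(360, 400, 10), z)
  hp <- generate_fh_solubility_points(truth, seq(340, 370, 10), z)
  hp$temperature_K <- hp$temperature_K + 14    # what 50 MPa does to the data
  comb <- combined_fh_fit(amb, hp, cond, cc, "chi_temperature")
  expect_equal(comb$chi$a_chi, 6.7, tolerance = 1e-5)
  expect_equal(comb$chi$b_chi, -3000, tolerance = 1e-5)
  fx <- combined_fh_fit(amb, hp, cond, cc, "fixed_b", fixed_b_chi = -3000)
  expect_equal(fx$chi$a_chi, 6.7, tolerance = 1e-6)
})

test_that("isochronal pairing aligns temperatures and solubilities across pressures", {
  fit_a <- ref_vft()
  fit_p <- vft_fit(1e-14, 2000, 265)
  sol_a <- data.frame(temperature_K = seq(360, 400, 10),
                      wtpct_drug = c(30, 35, 41, 46, 52))
  fits <- list(ambient = fit_a, p50 = fit_a)
  sols <- list(ambient = sol_a, p50 = sol_a)
  same <- isochronal_solubility_pairs(fits, sols, tau_targets = c(1e-6, 1e-4))
  for (tau in unique(same$tau_s)) {
    sub <- same[same$tau_s == tau, ]
    expect_equal(sub$temperature_K[1], sub$temperature_K[2])
    expect_equal(sub$wtpct_drug[1], sub$wtpct_drug[2])
  }
  # construction with equal generating solubility at equal tau: shift the
  # solubility table by the same 15 K that separates the VFT curves
  sol_p <- sol_a; sol_p$temperature_K <- sol_p$temperature_K + 15
  pairs <- isochronal_solubility_pairs(list(ambient = fit_a, p50 = fit_p),
                                       list(ambient = sol_a, p50 = sol_p),
                                       tau_targets = c(1.07e-6, 4.92e-6))
  for (tau in unique(pairs$tau_s)) {
    sub <- pairs[pairs$tau_s == tau, ]
    expect_equal(sub$wtpct_drug[sub$condition == "ambient"],
                 sub$wtpct_drug[sub$condition == "p50"], tolerance = 1e-9)
  }
  # larger tau target -> lower temperature at every pressure
  t_small <- pairs$temperature_K[pairs$tau_s == 1.07e-6]
  t_large <- pairs$temperature_K[pairs$tau_s == 4.92e-6]
  expect_true(all(t_large < t_small))
  expect_error(isochronal_solubility_pairs(list(a = fit_a), list(a = sol_a), 1e-6),
               "2 pressure")
})
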