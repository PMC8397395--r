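test_that("volume ratio follows the molar-volume arithmetic", {
  cc <- nms_kva_constants()
  expect_equal(volume_ratio(cc), (46000 / 1.20) / (308.3 / 1.41),
               tolerance = 1e-12)
  expect_equal(volume_ratio(cc), 175.32, tolerance = 1e-4)
  same <- component_constants(400, 30000, 1.2, 1.2, 300, 300)
  expect_equal(volume_ratio(same), 1)
  double <- component_constants(421, 32988, 1.41, 1.20, 308.3, 92000)
  expect_equal(volume_ratio(double), 2 * volume_ratio(cc))
})

test_that("weight/volume fraction conversion round-trips exactly", {
  cc <- nms_kva_constants()
  expect_equal(wt_to_volfrac(0, cc), 0)
  expect_equal(wt_to_volfrac(100, cc), 1)
  w <- seq(1, 99, 7)
  expect_equal(volfrac_to_wt(wt_to_volfrac(w, cc), cc), w, tolerance = 1e-12)
  eq <- component_constants(400, 30000, 1.3, 1.3, 300, 40000)
  expect_equal(wt_to_volfrac(w, eq), w / 100)
})

test_that("the liquidus passes through the pure-drug melting point for any chi", {
  for (chi in list(chi_model("constant", chi = -1.17),
                   chi_model("constant", chi = 2),
                   chi_model("linear_in_invT", a_chi = 6.7, b_chi = -3000))) {
    mod <- fh_model(nms_kva_constants(), chi)
    expect_equal(liquidus_residual(421, 1, mod), 0)
    expect_equal(liquidus_temperature(1, mod), 421)
  }
  # continuity of the anchor for miscible (chi < 0) systems: the solubility
  # tends to 100 wt% just below Tm0 (strongly positive chi instead shows the
  # retrograde detachment typical of immiscible lattice solutions)
  for (chi in list(chi_model("constant", chi = -1.17),
                   chi_model("linear_in_invT", a_chi = 6.7, b_chi = -3000))) {
    mod <- fh_model(nms_kva_constants(), chi)
    expect_gt(solve_liquidus_wtpct(421 - 1e-3, mod), 99.5)
  }
  mod <- ref_fh()
  expect_error(liquidus_residual(370, 0, mod), "phi")
  expect_error(solve_liquidus_phi(425, mod), "Tm0")
  # affine in 1/T at fixed phi: residual differences scale with 1/T differences
  r <- liquidus_residual(c(350, 370, 390), 0.3, fh_model(nms_kva_constants(),
                                                         chi_model("constant", chi = -1)))
  expect_equal((r[2] - r[1]) / (1 / 370 - 1 / 350),
               (r[3] - r[2]) / (1 / 390 - 1 / 370), tolerance = 1e-9)
})

test_that("solve_liquidus_phi agrees with an independent scan-and-bisect oracle", {
  for (mod in list(fh_model(nms_kva_constants(), chi_model("constant", chi = -1.17)),
                   ref_fh())) {
    for (temp in c(320, 360, 400)) {
      expect_equal(solve_liquidus_phi(temp, mod),
                   scan_liquidus_phi(temp, mod), tolerance = 1e-8)
    }
  }
})

test_that("predicted solubility increases with temperature over the data range", {
  d <- nms_kva_data()
  mod <- fit_fh_chi_temperature(d$solubility_bds_ambient, nms_kva_constants())
  curve <- liquidus_curve(mod, seq(300, 415, 5))
  expect_true(all(diff(curve$wtpct_drug) > 0))
})

test_that("constant-chi fitting recovers a generating chi and interpolates one point", {
  z <- quiet_config()
  cc <- nms_kva_constants()
  truth <- fh_model(cc, chi_model("constant", chi = -1.5))
  pts <- generate_fh_solubility_points(truth, seq(360, 400, 10), z)
  fit <- fit_fh_chi_constant(pts, cc)
  expect_equal(fit$chi$chi, -1.5, tolerance = 1e-6)
  expect_false(is.null(fit$fit_report$r_squared))
  # two points exactly on a chi* liquidus pin chi = chi* by interpolation
  two <- generate_fh_solubility_points(truth, c(370, 395), z)
  expect_equal(fit_fh_chi_constant(two, cc)$chi$chi, -1.5, tolerance = 1e-6)
})

test_that("chi(T) fitting recovers (A, B) and degenerates correctly", {
  z <- quiet_config()
  cc <- nms_kva_constants()
  truth <- fh_model(cc, chi_model("linear_in_invT", a_chi = 6.7, b_chi = -3000))
  pts <- generate_fh_solubility_points(truth, seq(355, 400, 5), z)
  fit <- fit_fh_chi_temperature(pts, cc)
  expect_equal(fit$chi$a_chi, 6.7, tolerance = 1e-4)
  expect_equal(fit$chi$b_chi, -3000, tolerance = 1e-4)
  # fixing B at the jointly fitted value returns the same A
  fixed <- fit_fh_chi_temperature(pts, cc, fixed_b_chi = fit$chi$b_chi)
  expect_equal(fixed$chi$a_chi, fit$chi$a_chi, tolerance = 1e-6)
  # B fixed to 0 collapses to the constant-chi solution
  ptsc <- generate_fh_solubility_points(fh_model(cc, chi_model("constant", chi = -1.5)),
                                        seq(360, 400, 10), z)
  b0 <- fit_fh_chi_temperature(ptsc, cc, fixed_b_chi = 0)
  expect_equal(b0$chi$a_chi, fit_fh_chi_constant(ptsc, cc)$chi$chi,
               tolerance = 1e-8)
  expect_error(fit_fh_chi_temperature(pts[1:2, ], cc), "at least 3")
  same_t <- data.frame(temperature_K = c(370, 370 + 1e-9), wtpct_drug = c(30, 31))
  expect_error(fit_fh_chi_temperature(same_t, cc), "collinear")
})

test_that("every fitted model reports R-squared on temperature residuals", {
  d <- nms_kva_data()
  cc <- nms_kva_constants()
  for (mod in list(fit_fh_chi_constant(d$solubility_bds_ambient, cc),
                   fit_fh_chi_temperature(d$solubility_bds_ambient, cc))) {
    r2 <- mod$fit_report$r_squared
    expect_true(is.numeric(r2) && r2 <= 1)
    expect_identical(mod$fit_report$residual, "temperature_K")
    expect_identical(mod$fit_report$weighting, "none")
  }
})
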