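#' Pure-component constants for Flory-Huggins liquidus modelling
#'
#' @param tm0 Melting point of the neat drug at the working pressure, K.
#' @param dhfus Enthalpy of fusion of the neat drug, J/mol.
#' @param d_drug,d_poly True densities of drug and polymer, g/cm^3.
#' @param mw_drug,mw_poly Molecular weights, g/mol.
#' @return Object of class `component_constants` (also carries the gas
#'   constant R = 8.314 J/(mol K)).
#' @examples
#' nms_kva_constants()
#' @export
component_constants <- function(tm0, dhfus, d_drug, d_poly, mw_drug, mw_poly) {
  for (nm in c("tm0", "dhfus", "d_drug", "d_poly", "mw_drug", "mw_poly"))
    check_number(get(nm), nm, positive = TRUE)
  structure(list(tm0 = tm0, dhfus = dhfus, d_drug = d_drug, d_poly = d_poly,
                 mw_drug = mw_drug, mw_poly = mw_poly, r_gas = .R_GAS),
            class = "component_constants")
}

#' Constants of the nimesulide + Kollidon VA64 system
#'
#' Convenience constructor with the literature constants of the NMS + KVA
#' system at ambient pressure: Tm0 = 421 K, dHfus = 32,988 J/mol, densities
#' 1.41 / 1.20 g/cm^3, molecular weights 308.3 / 46,000 g/mol.
#'
#' @param tm0 Melting point override, K (435 K is the literature value at
#'   50 MPa).
#' @return A [component_constants()].
#' @export
nms_kva_constants <- function(tm0 = 421) {
  component_constants(tm0 = tm0, dhfus = 32988, d_drug = 1.41, d_poly = 1.20,
                      mw_drug = 308.3, mw_poly = 46000)
}

#' Polymer-to-drug molar volume ratio
#'
#' \deqn{m = \frac{M_{w,poly}/d_{poly}}{M_{w,drug}/d_{drug}}}
#'
#' @param constants A [component_constants()].
#' @return Dimensionless ratio (about 175 for NMS + KVA).
#' @export
volume_ratio <- function(constants) {
  stopifnot(inherits(constants, "component_constants"))
  (constants$mw_poly / constants$d_poly) /
    (constants$mw_drug / constants$d_drug)
}

#' Convert drug weight percent to volume fraction (and back)
#'
#' \deqn{\phi = \frac{w/d_{drug}}{w/d_{drug} + (1-w)/d_{poly}}, \quad
#'   w = \mathrm{wtpct}/100.}
#'
#' @param wtpct_drug Drug content in weight percent, in \[0, 100\]
#'   (vectorized).
#' @param constants A [component_constants()].
#' @return Volume fraction of drug in \[0, 1\].
#' @export
wt_to_volfrac <- function(wtpct_drug, constants) {
  stopifnot(inherits(constants, "component_constants"))
  if (any(wtpct_drug < 0 | wtpct_drug > 100))
    stopf("'wtpct_drug' must lie in [0, 100]")
  w <- wtpct_drug / 100
  vd <- w / constants$d_drug
  vd / (vd + (1 - w) / constants$d_poly)
}

#' @rdname wt_to_volfrac
#' @param phi Volume fraction of drug in \[0, 1\] (vectorized).
#' @export
volfrac_to_wt <- function(phi, constants) {
  stopifnot(inherits(constants, "component_constants"))
  check_fraction(phi, "phi")
  md <- phi * constants$d_drug
  100 * md / (md + (1 - phi) * constants$d_poly)
}

#' Interaction-parameter model
#'
#' Either a constant \eqn{\chi} or the linear-in-inverse-temperature form
#' \eqn{\chi(T) = A + B/T}, where A and B are related to entropic and
#' enthalpic contributions to mixing.
#'
#' @param kind `"constant"` or `"linear_in_invT"`.
#' @param chi Constant interaction parameter (for `kind = "constant"`).
#' @param a_chi,b_chi A (dimensionless) and B (K) of \eqn{\chi(T) = A + B/T}.
#' @param uncertainties Optional named numeric vector of standard errors.
#' @return Object of class `chi_model`.
#' @export
chi_model <- function(kind = c("constant", "linear_in_invT"), chi = NULL,
                      a_chi = NULL, b_chi = NULL, uncertainties = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    check_number(chi, "chi")
    a_chi <- b_chi <- NULL
  } else {
    check_number(a_chi, "a_chi"); check_number(b_chi, "b_chi")
    chi <- NULL
  }
  structure(list(kind = kind, chi = chi, a_chi = a_chi, b_chi = b_chi,
                 uncertainties = uncertainties),
            class = "chi_model")
}

#' Evaluate the interaction parameter at a temperature
#'
#' @param model A [chi_model()].
#' @param temperature Temperature(s) in K.
#' @return \eqn{\chi} value(s).
#' @export
chi_at <- function(model, temperature) {
  stopifnot(inherits(model, "chi_model"))
  if (model$kind == "constant") rep_len(model$chi, length(temperature))
  else model$a_chi + model$b_chi / temperature
}

#' Flory-Huggins liquidus model
#'
#' Couples component constants with an interaction-parameter model.  The
#' solid-liquid line (liquidus) is the locus of melting-point depression,
#' \deqn{\frac{1}{T_m} - \frac{1}{T_m^0} = -\frac{R}{\Delta H_{fus}}
#'   \left[\ln\phi + \left(1 - \frac{1}{m}\right)(1-\phi) +
#'   \chi(T)\,(1-\phi)^2\right],}
#' which passes through \eqn{(\phi = 1, T_m^0)} exactly for any \eqn{\chi}
#' (the pure-drug anchor is enforced by construction, not fitted).
#'
#' @param constants A [component_constants()].
#' @param chi A [chi_model()].
#' @param fit_report Optional list of fit diagnostics (populated by the
#'   fitting functions).
#' @return Object of class `fh_model` with derived volume ratio `m`.
#' @export
fh_model <- function(constants, chi, fit_report = NULL) {
  stopifnot(inherits(constants, "component_constants"),
            inherits(chi, "chi_model"))
  structure(list(constants = constants, chi = chi, m = volume_ratio(constants),
                 fit_report = fit_report),
            class = "fh_model")
}

#' @export
print.fh_model <- function(x, ...) {
  chi_desc <- if (x$chi$kind == "constant")
    sprintf("chi = %.4g", x$chi$chi)
  else sprintf("chi(T) = %.4g + (%.4g K)/T", x$chi$a_chi, x$chi$b_chi)
  cat(sprintf("<fh_model> Tm0 = %.1f K, m = %.2f, %s\n",
              x$constants$tm0, x$m, chi_desc))
  if (!is.null(x$fit_report))
    cat(sprintf("  fit: n = %d, R^2 = %.4f (temperature residuals)\n",
                x$fit_report$n, x$fit_report$r_squared))
  invisible(x)
}

#' Residual of the Flory-Huggins melting-depression relation
#'
#' Evaluates
#' \deqn{\left(\frac{1}{T} - \frac{1}{T_m^0}\right) +
#'   \frac{R}{\Delta H_{fus}}\left[\ln\phi + (1 - 1/m)(1-\phi) +
#'   \chi(T)(1-\phi)^2\right],}
#' which is zero exactly on the liquidus.
#'
#' @param temperature Temperature in K, > 0.
#' @param phi Volume fraction of drug in (0, 1\].
#' @param model An [fh_model()].
#' @return Dimensionless residual (units of 1/K times K; affine in 1/T at
#'   fixed phi).
#' @export
liquidus_residual <- function(temperature, phi, model) {
  stopifnot(inherits(model, "fh_model"))
  if (any(temperature <= 0)) stopf("'temperature' must be > 0")
  if (any(phi <= 0)) stopf("'phi' must be > 0 (ln phi undefined at 0)")
  if (any(phi > 1)) stopf("'phi' must be <= 1")
  cc <- model$constants
  (1 / temperature - 1 / cc$tm0) + (cc$r_gas / cc$dhfus) *
    (log(phi) + (1 - 1 / model$m) * (1 - phi) +
       chi_at(model$chi, temperature) * (1 - phi)^2)
}

#' Liquidus temperature at a given composition
#'
#' Because the melting-depression relation is affine in 1/T at fixed
#' composition (also when \eqn{\chi = A + B/T}), the liquidus temperature
#' has the closed form
#' \deqn{T_m(\phi) = \frac{1 + (R/\Delta H_{fus})\,B\,(1-\phi)^2}
#'   {1/T_m^0 - (R/\Delta H_{fus})\left[\ln\phi + (1-1/m)(1-\phi) +
#'   A(1-\phi)^2\right]},}
#' with \eqn{A = \chi, B = 0} for the constant model.
#'
#' @param phi Volume fraction(s) of drug in (0, 1\].
#' @param model An [fh_model()].
#' @return Temperature(s) in K.
#' @export
liquidus_temperature <- function(phi, model) {
  stopifnot(inherits(model, "fh_model"))
  if (any(phi <= 0 | phi > 1)) stopf("'phi' must lie in (0, 1]")
  cc <- model$constants
  if (model$chi$kind == "constant") { A <- model$chi$chi; B <- 0 }
  else { A <- model$chi$a_chi; B <- model$chi$b_chi }
  rh <- cc$r_gas / cc$dhfus
  denom <- 1 / cc$tm0 - rh * (log(phi) + (1 - 1 / model$m) * (1 - phi) +
                                A * (1 - phi)^2)
  (1 + rh * B * (1 - phi)^2) / denom
}

#' Solve the liquidus for composition at a given temperature
#'
#' Finds the largest root \eqn{\phi \in (0, 1)} of
#' [liquidus_residual()] at fixed temperature -- the drug-rich solubility
#' branch that annealing experiments report.  Roots are located by a sign
#' -change scan over a log-spaced grid of 10^4 compositions followed by
#' bisection refinement ([stats::uniroot()], tolerance 1e-12).
#'
#' @param temperature Temperature in K; must be below the model's Tm0
#'   (above it the liquidus is undefined).
#' @param model An [fh_model()].
#' @return Volume fraction of drug.
#' @seealso [solve_liquidus_wtpct()] for the weight-percent equivalent.
#' @export
solve_liquidus_phi <- function(temperature, model) {
  stopifnot(inherits(model, "fh_model"))
  check_number(temperature, "temperature", positive = TRUE)
  if (temperature >= model$constants$tm0)
    stopf("temperature (%g K) must be below Tm0 (%g K): liquidus undefined above the pure melting point",
          temperature, model$constants$tm0)
  # log-spaced in phi for the dilute side plus log-spaced in (1 - phi) for
  # the drug-rich side, where the root sits arbitrarily close to 1 near Tm0
  grid <- sort(unique(c(exp(seq(log(1e-6), log(1 - 1e-6), length.out = 5e3)),
                        1 - exp(seq(log(1e-12), log(0.5), length.out = 5e3)))))
  v <- liquidus_residual(temperature, grid, model)
  sgn <- which(diff(sign(v)) != 0)
  if (!length(sgn))
    stopf("no liquidus root in (0,1) at T = %g K (residual range [%.3g, %.3g])",
          temperature, min(v), max(v))
  i <- max(sgn)
  uniroot(function(p) liquidus_residual(temperature, p, model),
          c(grid[i], grid[i + 1]), tol = 1e-12)$root
}

#' @rdname solve_liquidus_phi
#' @return For `solve_liquidus_wtpct`, the equilibrium drug content in
#'   weight percent.
#' @export
solve_liquidus_wtpct <- function(temperature, model) {
  volfrac_to_wt(solve_liquidus_phi(temperature, model), model$constants)
}

# Shared LM machinery: minimize (predicted liquidus T at observed phi -
# observed T), unweighted, ftol = 1e-9 (the stated chi-square tolerance).
fh_lm_fit <- function(points, constants, make_chi, par0, lower, upper) {
  points <- as.data.frame(points)
  if (!"wtpct_drug" %in% names(points) || !"temperature_K" %in% names(points))
    stopf("'points' needs 'temperature_K' and 'wtpct_drug' columns")
  if (any(points$wtpct_drug <= 0 | points$wtpct_drug >= 100))
    stopf("solubility points must have 0 < wtpct_drug < 100")
  if (any(points$temperature_K >= constants$tm0))
    stopf("solubility points must lie below Tm0 = %g K", constants$tm0)
  phi <- wt_to_volfrac(points$wtpct_drug, constants)
  tobs <- points$temperature_K
  resid_fn <- function(p)
    liquidus_temperature(phi, fh_model(constants, make_chi(p))) - tobs
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-9, ptol = 1e-12, maxiter = 1000))
  if (fit$info < 1 || fit$info > 4)
    stopf("Flory-Huggins fit did not converge (info = %d)", fit$info)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(par0)))
  r2 <- 1 - sum(fit$fvec^2) / sum((tobs - mean(tobs))^2)
  list(par = fit$par, se = se,
       report = list(n = length(tobs), rss = sum(fit$fvec^2),
                     sigma = sd(fit$fvec), r_squared = r2,
                     residual = "temperature_K", weighting = "none",
                     converged = TRUE))
}

#' Fit a constant interaction parameter to solubility points (approach I)
#'
#' Fits a single \eqn{\chi} so that the liquidus temperatures predicted at
#' the observed compositions match the observed annealing temperatures in
#' the least-squares sense (unweighted Levenberg-Marquardt, temperature
#' residuals).  The fit report includes R^2 on the temperature residuals.
#'
#' @param points Data frame of solubility points with columns
#'   `temperature_K` and `wtpct_drug` (and optionally `pressure_MPa`).
#'   At least 2 points.
#' @param constants A [component_constants()].
#' @return An [fh_model()] with a constant [chi_model()] and populated
#'   `fit_report`.
#' @export
fit_fh_chi_constant <- function(points, constants) {
  stopifnot(inherits(constants, "component_constants"))
  if (nrow(as.data.frame(points)) < 2L)
    stopf("constant-chi fit needs at least 2 points")
  res <- fh_lm_fit(points, constants,
                   make_chi = function(p) chi_model("constant", chi = p[1]),
                   par0 = c(chi = 0), lower = -50, upper = 50)
  fh_model(constants,
           chi_model("constant", chi = res$par[[1]],
                     uncertainties = c(chi = res$se[[1]])),
           fit_report = res$report)
}

#' Fit a temperature-dependent interaction parameter (approach II)
#'
#' As [fit_fh_chi_constant()] but with \eqn{\chi(T) = A + B/T}; A and B
#' are fitted jointly, or A alone when `fixed_b_chi` supplies B (the
#' enthalpic contribution is then assumed pressure-independent).
#'
#' @inheritParams fit_fh_chi_constant
#' @param fixed_b_chi Optional fixed value of B (K); when given only A is
#'   fitted and at least 2 points are required (otherwise 3).
#' @return An [fh_model()] with a `linear_in_invT` [chi_model()].
#' @export
fit_fh_chi_temperature <- function(points, constants, fixed_b_chi = NULL) {
  stopifnot(inherits(constants, "component_constants"))
  points <- as.data.frame(points)
  need <- if (is.null(fixed_b_chi)) 3L else 2L
  if (nrow(points) >= 2L && diff(range(points$temperature_K)) < 1e-6)
    stopf("collinear input: all points at (nearly) one temperature")
  if (nrow(points) < need)
    stopf("temperature-dependent chi fit needs at least %d points", need)
  if (is.null(fixed_b_chi)) {
    res <- fh_lm_fit(points, constants,
                     make_chi = function(p) chi_model("linear_in_invT",
                                                      a_chi = p[1], b_chi = p[2]),
                     par0 = c(A = 0, B = 0), lower = c(-1e3, -1e6),
                     upper = c(1e3, 1e6))
    chi <- chi_model("linear_in_invT", a_chi = res$par[[1]], b_chi = res$par[[2]],
                     uncertainties = c(a_chi = res$se[[1]], b_chi = res$se[[2]]))
  } else {
    check_number(fixed_b_chi, "fixed_b_chi")
    res <- fh_lm_fit(points, constants,
                     make_chi = function(p) chi_model("linear_in_invT",
                                                      a_chi = p[1],
                                                      b_chi = fixed_b_chi),
                     par0 = c(A = 0), lower = -1e3, upper = 1e3)
    chi <- chi_model("linear_in_invT", a_chi = res$par[[1]], b_chi = fixed_b_chi,
                     uncertainties = c(a_chi = res$se[[1]], b_chi = 0))
    res$report$b_chi_fixed <- TRUE
  }
  fh_model(constants, chi, fit_report = res$report)
}

#' Liquidus curve on a temperature grid
#'
#' @param model An [fh_model()].
#' @param temperatures Temperatures in K, all below Tm0.
#' @return Data frame with columns `temperature_K` and `wtpct_drug`.
#' @export
liquidus_curve <- function(model, temperatures) {
  stopifnot(inherits(model, "fh_model"))
  data.frame(temperature_K = temperatures,
             wtpct_drug = vapply(temperatures, solve_liquidus_wtpct,
                                 numeric(1), model = model))
}
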