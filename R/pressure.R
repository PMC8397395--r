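#' Elevated-pressure condition
#'
#' Bundles the quantities needed to refer high-pressure measurements back
#' to ambient pressure: the pure-drug melting point at that pressure and
#' the (nearly composition-independent) Tg offset versus ambient.
#'
#' @param pressure Pressure in MPa.
#' @param tm0_at_p Pure-drug melting point at this pressure, K.
#' @param delta_tg Constant Tg increase versus ambient, K (>= 0).
#' @return Object of class `pressure_condition`.
#' @export
pressure_condition <- function(pressure, tm0_at_p, delta_tg = 0) {
  check_number(pressure, "pressure", positive = TRUE)
  check_number(tm0_at_p, "tm0_at_p", positive = TRUE)
  check_number(delta_tg, "delta_tg")
  if (delta_tg < 0) stopf("'delta_tg' must be >= 0")
  structure(list(pressure = pressure, tm0_at_p = tm0_at_p,
                 delta_tg = delta_tg),
            class = "pressure_condition")
}

#' Vertically transpose a composition-Tg curve to elevated pressure
#'
#' Pressure raises Tg by a nearly composition-independent amount, so the
#' ambient Gordon-Taylor curve is displaced vertically:
#' \eqn{T_g^P(w) = T_g^{ambient}(w) + \Delta T_g}.  Inversion at pressure
#' uses the shifted curve, which is equivalent to inverting the ambient
#' curve at `tg - delta_tg`.
#'
#' @param ambient A [gt_params()] fitted at ambient pressure.
#' @param condition A [pressure_condition()] supplying `delta_tg`.
#' @return A `gt_params` object with both endpoint Tg values shifted by
#'   `delta_tg` (the Gordon-Taylor K is shift-invariant only approximately;
#'   the shifted-endpoint curve differs from a pure vertical shift by
#'   O(K-nonlinearity), so prediction and inversion are implemented as an
#'   exact vertical offset -- see `gt_predict_shifted`).
#' @export
transpose_tg_curve <- function(ambient, condition) {
  stopifnot(inherits(ambient, "gt_params"),
            inherits(condition, "pressure_condition"))
  out <- ambient
  out$delta_tg <- condition$delta_tg
  class(out) <- c("gt_params_shifted", "gt_params")
  out
}

#' @export
print.gt_params_shifted <- function(x, ...) {
  cat(sprintf("<gt_params, vertically shifted by +%.2f K>\n", x$delta_tg))
  NextMethod()
}

#' @rdname transpose_tg_curve
#' @param params A shifted curve from [transpose_tg_curve()].
#' @param w_poly Weight fraction of polymer.
#' @export
gt_predict_shifted <- function(params, w_poly) {
  delta <- if (!is.null(params$delta_tg)) params$delta_tg else 0
  unshifted <- params; class(unshifted) <- "gt_params"
  gt_predict(unshifted, w_poly) + delta
}

#' @rdname transpose_tg_curve
#' @param tg_observed Tg measured at elevated pressure, K.
#' @export
gt_invert_shifted <- function(params, tg_observed) {
  delta <- if (!is.null(params$delta_tg)) params$delta_tg else 0
  unshifted <- params; class(unshifted) <- "gt_params"
  gt_invert(unshifted, tg_observed - delta)
}

#' Estimate the constant Tg offset between two pressures
#'
#' Least-squares constant offset between Tg values measured for the same
#' compositions at ambient and elevated pressure; the per-composition
#' spread is reported as a constancy diagnostic.
#'
#' @param ambient_points,pressure_points Data frames with columns
#'   `wtpct_drug` and `tg_K`; compositions are matched on `wtpct_drug`.
#' @return List with `delta_tg` (mean offset, K), `spread` (sd of
#'   per-composition offsets, K), `offsets` (named per-composition vector)
#'   and `constant` (`TRUE` when spread < 1 K).
#' @export
estimate_delta_tg <- function(ambient_points, pressure_points) {
  a <- as.data.frame(ambient_points); p <- as.data.frame(pressure_points)
  m <- merge(a, p, by = "wtpct_drug", suffixes = c("_ambient", "_pressure"))
  if (nrow(m) == 0L) stopf("no matched compositions between the two sets")
  offsets <- setNames(m$tg_K_pressure - m$tg_K_ambient,
                      paste0(m$wtpct_drug, "wt%"))
  spread <- if (length(offsets) > 1L) sd(offsets) else 0
  list(delta_tg = mean(offsets), spread = spread, offsets = offsets,
       constant = spread < 1)
}

#' Transpose high-pressure solubility points to the ambient reference
#'
#' Shifts each point's temperature by the difference of the pure-drug
#' melting points, \eqn{T \mapsto T + (T_m^{0,ambient} - T_m^{0,P})};
#' compositions are unchanged.  Applying the inverse shift restores the
#' original points exactly.
#'
#' @param points Data frame with columns `temperature_K`, `wtpct_drug`
#'   (and optionally `pressure_MPa`).
#' @param tm0_ambient,tm0_at_p Pure-drug melting points at the ambient and
#'   elevated pressure, K.
#' @return The points data frame with shifted `temperature_K` and an added
#'   `temperature_shift_K` column.
#' @export
transpose_solubility_points <- function(points, tm0_ambient, tm0_at_p) {
  check_number(tm0_ambient, "tm0_ambient", positive = TRUE)
  check_number(tm0_at_p, "tm0_at_p", positive = TRUE)
  points <- as.data.frame(points)
  shift <- tm0_ambient - tm0_at_p
  points$temperature_K <- points$temperature_K + shift
  points$temperature_shift_K <- shift
  points
}

#' Combined Flory-Huggins fit of ambient and transposed high-pressure data
#'
#' Transposes the high-pressure solubility points to the ambient reference
#' (melting-point-referenced vertical shift), pools them with the ambient
#' points, and fits the Flory-Huggins liquidus with the ambient constants
#' in one of three modes: a single constant chi, the temperature-dependent
#' chi(T) = A + B/T, or chi(T) with B held at a supplied (typically the
#' ambient-only fitted) value.
#'
#' @param ambient_points Data frame of ambient solubility points
#'   (`temperature_K`, `wtpct_drug`).
#' @param pressure_points Data frame of high-pressure points (may be empty,
#'   in which case the result equals the ambient-only fit).
#' @param condition A [pressure_condition()] carrying `tm0_at_p`.
#' @param constants Ambient [component_constants()].
#' @param mode One of `"chi_constant"`, `"chi_temperature"`, `"fixed_b"`.
#' @param fixed_b_chi B value (K) used when `mode = "fixed_b"`.
#' @return An [fh_model()]; its `fit_report` records the pooled data and
#'   the applied shift.
#' @export
combined_fh_fit <- function(ambient_points, pressure_points, condition,
                            constants,
                            mode = c("chi_constant", "chi_temperature", "fixed_b"),
                            fixed_b_chi = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(constants, "component_constants"))
  ambient_points <- as.data.frame(ambient_points)
  pooled <- ambient_points[c("temperature_K", "wtpct_drug")]
  if (!is.null(pressure_points) && nrow(as.data.frame(pressure_points)) > 0L) {
    stopifnot(inherits(condition, "pressure_condition"))
    shifted <- transpose_solubility_points(pressure_points, constants$tm0,
                                           condition$tm0_at_p)
    pooled <- rbind(pooled, shifted[c("temperature_K", "wtpct_drug")])
  }
  model <- switch(mode,
    chi_constant = fit_fh_chi_constant(pooled, constants),
    chi_temperature = fit_fh_chi_temperature(pooled, constants),
    fixed_b = {
      if (is.null(fixed_b_chi)) stopf("mode 'fixed_b' requires 'fixed_b_chi'")
      fit_fh_chi_temperature(pooled, constants, fixed_b_chi = fixed_b_chi)
    })
  model$fit_report$pooled_points <- pooled
  model$fit_report$mode <- mode
  model
}

#' Pair solubility limits across pressures at equal relaxation time
#'
#' For each target relaxation time, computes the temperature at which each
#' pressure's VFT fit reaches that time ([isochrone_temperature()]) and
#' looks up the solubility limit at that temperature -- measured exactly
#' when available, otherwise linearly interpolated in temperature between
#' measured annealing points (flagged `interpolated`).  Targets outside a
#' fit's usable range are flagged, not fatal.
#'
#' @param fits_by_condition Named list of [vft_fit()] objects, one per
#'   pressure (names used as condition labels); at least 2.
#' @param solubilities_by_condition Named list (same names) of data frames
#'   with columns `temperature_K` and `wtpct_drug`.
#' @param tau_targets Relaxation times in s to pair at.
#' @return Data frame with one row per (tau target, condition):
#'   `tau_s`, `condition`, `temperature_K`, `wtpct_drug`, `interpolated`,
#'   `in_range`.
#' @export
isochronal_solubility_pairs <- function(fits_by_condition,
                                        solubilities_by_condition,
                                        tau_targets) {
  if (length(fits_by_condition) < 2L)
    stopf("need fits for at least 2 pressure conditions")
  if (!setequal(names(fits_by_condition), names(solubilities_by_condition)))
    stopf("condition names of fits and solubility tables must match")
  rows <- list()
  for (tau in tau_targets) {
    for (nm in names(fits_by_condition)) {
      fit <- fits_by_condition[[nm]]
      sol <- as.data.frame(solubilities_by_condition[[nm]])
      temp <- tryCatch(isochrone_temperature(fit, tau),
                       error = function(e) NA_real_)
      in_range <- !is.na(temp) && temp >= min(sol$temperature_K) &&
        temp <= max(sol$temperature_K)
      exact <- !is.na(temp) && any(abs(sol$temperature_K - temp) < 1e-6)
      w <- if (is.na(temp)) NA_real_
      else approx(sol$temperature_K, sol$wtpct_drug, xout = temp,
                  rule = 2)$y
      rows[[length(rows) + 1L]] <- data.frame(
        tau_s = tau, condition = nm, temperature_K = temp, wtpct_drug = w,
        interpolated = !exact, in_range = in_range)
    }
  }
  do.call(rbind, rows)
}
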