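#' Pipeline configuration
#'
#' Assembles and validates everything [run_solubility_pipeline()] needs.
#' Can also be loaded from a YAML or JSON file with the same field names
#' via [read_pipeline_config()].
#'
#' @param manifest Path to (or data frame of) the spectrum manifest:
#'   columns `path`, `annealing_K`, `pressure_MPa`.  Each row is one loss
#'   spectrum measured while reheating a sample previously annealed at
#'   `annealing_K` under `pressure_MPa`.
#' @param composition_tg Path to (or data frame of) the ambient
#'   composition-Tg table: columns `wtpct_drug`, `tg_K`.
#' @param constants A [component_constants()] or a named list of its
#'   arguments (ambient-pressure values; `tm0` at ambient).
#' @param pressure_conditions List of lists with `pressure_MPa`,
#'   `tm0_at_p_K`, `delta_tg_K` describing each elevated pressure present
#'   in the manifest.  May be empty.
#' @param tau_ref Reference relaxation time defining Tg, s (default 100).
#' @param lm_ftol Levenberg-Marquardt chi-square tolerance used by the FH
#'   fits (default 1e-9; informational -- the fitting functions use this
#'   value).
#' @param out_dir Output directory for stage artifacts.
#' @param seed Integer seed recorded in the report (the pipeline itself is
#'   deterministic; the seed matters when the inputs were simulated).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, composition_tg, constants,
                            pressure_conditions = list(), tau_ref = 100,
                            lm_ftol = 1e-9, out_dir = tempfile("asdsol-"),
                            seed = 1L) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stopf("manifest file not found: %s", manifest)
    manifest <- read_delim_table(manifest)
  }
  stopifnot(all(c("path", "annealing_K", "pressure_MPa") %in% names(manifest)))
  if (is.character(composition_tg)) {
    if (!file.exists(composition_tg))
      stopf("composition_tg file not found: %s", composition_tg)
    composition_tg <- read_delim_table(composition_tg)
  }
  if (!inherits(constants, "component_constants"))
    constants <- do.call(component_constants, as.list(constants))
  check_number(tau_ref, "tau_ref", positive = TRUE)
  check_number(lm_ftol, "lm_ftol", positive = TRUE)
  structure(list(manifest = as.data.frame(manifest),
                 composition_tg = as.data.frame(composition_tg),
                 constants = constants,
                 pressure_conditions = pressure_conditions,
                 tau_ref = tau_ref, lm_ftol = lm_ftol,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file; relative input
#'   paths are resolved against the file's directory.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- dirname(path)
  rel <- function(p) if (is.character(p) && !file.exists(p) &&
                         file.exists(file.path(base, p))) file.path(base, p) else p
  raw$manifest <- rel(raw$manifest)
  raw$composition_tg <- rel(raw$composition_tg)
  do.call(pipeline_config, raw)
}

#' Simulate a complete synthetic annealing study
#'
#' Generates, from a known ground truth, every input the solubility
#' pipeline consumes: per-condition loss spectra recorded above Tg after
#' annealing (with HN shape and multiplicative noise), the ambient
#' composition-Tg table, and a manifest.  The ground truth couples the
#' stages the way the experiment does: the generating Flory-Huggins model
#' fixes the equilibrium composition at each annealing temperature, the
#' Gordon-Taylor curve fixes the Tg of that composition (plus
#' `delta_tg_K` at elevated pressure), and a VFT curve anchored at that
#' Tg generates the relaxation times the spectra encode.
#'
#' @param out_dir Directory to write the study into (created).
#' @param config A [synthetic_config()]; its seed fixes all noise.
#' @param fh_truth Generating [fh_model()] (ambient constants).
#' @param gt_truth Generating [gt_params()].
#' @param annealing_K Ambient annealing temperatures, K.
#' @param pressure_conditions As in [pipeline_config()]; each elevated
#'   pressure gets its own annealing set `annealing_K_p`.
#' @param annealing_K_p Elevated-pressure annealing temperatures, K.
#' @param n_spectra Spectra (measurement temperatures) per condition.
#' @param b_vft,tau_inf VFT shape shared by all generated conditions.
#' @return The path of the written config file (`config.yaml`) invisibly;
#'   the ground truth is saved alongside as `truth.json`.
#' @export
simulate_study <- function(out_dir, config, fh_truth, gt_truth,
                           annealing_K = seq(368, 398, by = 5),
                           pressure_conditions = list(),
                           annealing_K_p = seq(368, 398, by = 10),
                           n_spectra = 5L, b_vft = 2000, tau_inf = 1e-14) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(fh_truth, "fh_model"), inherits(gt_truth, "gt_params"))
  dir.create(file.path(out_dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)

  manifest <- list(); truth_rows <- list()
  emit_condition <- function(t_ann, pressure, model_p, delta_tg, idx) {
    w_eq <- solve_liquidus_wtpct(t_ann, model_p)
    tg <- gt_predict(gt_truth, 1 - w_eq / 100) + delta_tg
    t0 <- tg - b_vft / log(100 / tau_inf)      # anchor: tau(tg) = 100 s
    t_meas <- tg + seq(10, 10 + 5 * (n_spectra - 1), by = 5)
    for (j in seq_along(t_meas)) {
      cfg_j <- config
      cfg_j$seed <- config$seed + 1000L * idx + j   # per-spectrum noise
      tau_a <- vft_tau(t_meas[j], tau_inf, b_vft, t0)
      if (config$tau_log10_sd > 0) {
        set.seed(cfg_j$seed + 500000L)
        tau_a <- 10^(log10(tau_a) + rnorm(1, 0, config$tau_log10_sd))
      }
      a <- 0.85; b <- 0.7
      tau_hn <- tau_a / (sin(a * pi / (2 * (1 + b)))^(-1 / a) *
                           sin(a * b * pi / (2 * (1 + b)))^(1 / a))
      sp <- generate_hn_spectrum(delta_eps = 1 + w_eq / 50, tau_hn = tau_hn,
                                 a = a, b = b, config = cfg_j,
                                 temperature = t_meas[j], pressure = pressure,
                                 label = sprintf("anneal_%gK_%gMPa", t_ann, pressure))
      fname <- sprintf("spectra/sp_%03d_%02d.tsv", idx, j)
      write_spectrum(sp, file.path(out_dir, fname))
      manifest[[length(manifest) + 1L]] <<- data.frame(
        path = fname, annealing_K = t_ann, pressure_MPa = pressure)
    }
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      annealing_K = t_ann, pressure_MPa = pressure, wtpct_drug_true = w_eq,
      tg_true_K = tg)
  }

  idx <- 0L
  for (t_ann in annealing_K) {
    idx <- idx + 1L
    emit_condition(t_ann, 0.1, fh_truth, 0, idx)
  }
  for (pc in pressure_conditions) {
    model_p <- fh_model(component_constants(
      tm0 = pc$tm0_at_p_K, dhfus = fh_truth$constants$dhfus,
      d_drug = fh_truth$constants$d_drug, d_poly = fh_truth$constants$d_poly,
      mw_drug = fh_truth$constants$mw_drug, mw_poly = fh_truth$constants$mw_poly),
      fh_truth$chi)
    for (t_ann in annealing_K_p) {
      idx <- idx + 1L
      emit_condition(t_ann, pc$pressure_MPa, model_p, pc$delta_tg_K, idx)
    }
  }

  # ambient composition-Tg table
  fr <- seq(0, 1, by = 0.125)
  ct <- generate_gt_curve(gt_truth$tg_drug, gt_truth$tg_poly, gt_truth$k,
                          fr, config)
  write_delim_table(ct[c("wtpct_drug", "tg_K")],
                    file.path(out_dir, "composition_tg.tsv"))
  write_delim_table(do.call(rbind, manifest), file.path(out_dir, "manifest.tsv"))
  writeLines(jsonlite::toJSON(list(
    fh = list(kind = fh_truth$chi$kind, chi = fh_truth$chi$chi,
              a_chi = fh_truth$chi$a_chi, b_chi = fh_truth$chi$b_chi),
    gt = list(tg_drug = gt_truth$tg_drug, tg_poly = gt_truth$tg_poly,
              k = gt_truth$k),
    conditions = do.call(rbind, truth_rows)), auto_unbox = TRUE, digits = NA),
    file.path(out_dir, "truth.json"))

  cfg <- list(manifest = "manifest.tsv", composition_tg = "composition_tg.tsv",
              constants = list(tm0 = fh_truth$constants$tm0,
                               dhfus = fh_truth$constants$dhfus,
                               d_drug = fh_truth$constants$d_drug,
                               d_poly = fh_truth$constants$d_poly,
                               mw_drug = fh_truth$constants$mw_drug,
                               mw_poly = fh_truth$constants$mw_poly),
              pressure_conditions = pressure_conditions,
              seed = config$seed)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(file.path(out_dir, "config.yaml"))
}

#' Run the full annealing-protocol solubility pipeline
#'
#' Executes the complete inference chain: HN fits of every manifest
#' spectrum, per-condition VFT fits of the resulting relaxation times
#' (with a horizontal-shift fallback when a condition has fewer than 3
#' usable points), 100 s extrapolation to Tg, Gordon-Taylor inversion of
#' Tg to composition (using the vertically shifted curve at elevated
#' pressure), assembly of solubility points, and Flory-Huggins fits:
#' approaches I and II per pressure plus, when elevated-pressure data are
#' present, the combined (transposed + pooled) fits in all three modes.
#'
#' All intermediate artifacts are written under `config$out_dir`
#' (`tau_table.tsv`, `tg_table.tsv`, `solubility_points.tsv`,
#' `summary.json`).  The pipeline is a pure function of its inputs:
#' re-running with the same config produces identical numeric output.
#'
#' @param config A [pipeline_config()] (or a path accepted by
#'   [read_pipeline_config()]).
#' @param base_dir Directory that relative manifest paths are resolved
#'   against (default: current directory).
#' @return A list of class `pipeline_report`: `tau_table`, `tg_table`,
#'   `solubility_points`, `gt`, `fh` (named list of fitted models),
#'   `summary` (the JSON-ready summary).
#' @export
run_solubility_pipeline <- function(config, base_dir = ".") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- config$manifest

  # stage 1: HN fits -> relaxation-time table
  tau_rows <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, man$path[i])
    if (!file.exists(p)) stopf("spectral fitting stage: file not found: %s", man$path[i])
    sp <- read_spectrum(p)
    fit <- fit_hn(sp)
    data.frame(annealing_K = man$annealing_K[i],
               pressure_MPa = man$pressure_MPa[i],
               temperature_K = sp$temperature, tau_alpha_s = fit$tau_alpha,
               delta_eps = fit$delta_eps, a = fit$a, b = fit$b,
               peak_outside_window = fit$peak_outside_window)
  })
  tau_table <- do.call(rbind, tau_rows)
  write_delim_table(tau_table, file.path(config$out_dir, "tau_table.tsv"))

  # stage 2: per-condition VFT -> Tg
  conds <- unique(tau_table[c("annealing_K", "pressure_MPa")])
  fits <- vector("list", nrow(conds)); tg <- numeric(nrow(conds))
  method <- character(nrow(conds))
  for (i in seq_len(nrow(conds))) {
    sel <- tau_table$annealing_K == conds$annealing_K[i] &
      tau_table$pressure_MPa == conds$pressure_MPa[i]
    sub <- tau_table[sel, ]
    if (nrow(sub) >= 3L) {
      fits[[i]] <- fit_vft(relaxation_series(sub$temperature_K,
                                             sub$tau_alpha_s),
                           tau_ref = config$tau_ref)
      tg[i] <- fits[[i]]$tg
      method[i] <- "vft"
    } else method[i] <- "pending_shift"
  }
  for (i in which(method == "pending_shift")) {
    same_p <- which(method == "vft" &
                      conds$pressure_MPa == conds$pressure_MPa[i])
    if (!length(same_p))
      stopf("VFT stage: condition %g K / %g MPa has < 3 points and no reference fit at the same pressure",
            conds$annealing_K[i], conds$pressure_MPa[i])
    ref <- same_p[which.min(abs(conds$annealing_K[same_p] - conds$annealing_K[i]))]
    sel <- tau_table$annealing_K == conds$annealing_K[i] &
      tau_table$pressure_MPa == conds$pressure_MPa[i]
    sub <- tau_table[sel, ]
    j <- which.max(sub$tau_alpha_s)   # slowest point: closest to Tg
    tg[i] <- horizontal_shift_tg(fits[[ref]], sub$temperature_K[j],
                                 sub$tau_alpha_s[j])
    method[i] <- sprintf("horizontal_shift(ref=%gK)", conds$annealing_K[ref])
  }
  tg_table <- cbind(conds, tg_K = tg, method = method)
  write_delim_table(tg_table, file.path(config$out_dir, "tg_table.tsv"))

  # stage 3: Gordon-Taylor inversion -> solubility points
  gt <- fit_gordon_taylor(config$composition_tg, fix_endpoints = TRUE)
  delta_tg_of <- function(p) {
    if (p <= 0.101) return(0)
    for (pc in config$pressure_conditions)
      if (isTRUE(all.equal(pc$pressure_MPa, p))) return(pc$delta_tg_K)
    stopf("composition stage: no pressure_conditions entry for %g MPa", p)
  }
  wt <- vapply(seq_len(nrow(tg_table)), function(i)
    100 * gt_invert(gt, tg_table$tg_K[i] - delta_tg_of(tg_table$pressure_MPa[i])),
    numeric(1))
  sol <- data.frame(temperature_K = tg_table$annealing_K,
                    wtpct_drug = wt, pressure_MPa = tg_table$pressure_MPa)
  write_delim_table(sol, file.path(config$out_dir, "solubility_points.tsv"))

  # stage 4: Flory-Huggins fits
  ambient <- sol[sol$pressure_MPa <= 0.101, ]
  fh <- list(ambient_chi_constant = fit_fh_chi_constant(ambient, config$constants),
             ambient_chi_temperature = fit_fh_chi_temperature(ambient, config$constants))
  for (pc in config$pressure_conditions) {
    pts <- sol[abs(sol$pressure_MPa - pc$pressure_MPa) < 1e-9, ]
    if (!nrow(pts)) next
    cc_p <- config$constants; cc_p$tm0 <- pc$tm0_at_p_K
    key <- sprintf("p%g", pc$pressure_MPa)
    fh[[paste0(key, "_chi_temperature")]] <-
      fit_fh_chi_temperature(pts, cc_p)
    cond <- pressure_condition(pc$pressure_MPa, pc$tm0_at_p_K, pc$delta_tg_K)
    b_amb <- fh$ambient_chi_temperature$chi$b_chi
    fh[[paste0("combined_", key, "_chi_constant")]] <-
      combined_fh_fit(ambient, pts, cond, config$constants, "chi_constant")
    fh[[paste0("combined_", key, "_chi_temperature")]] <-
      combined_fh_fit(ambient, pts, cond, config$constants, "chi_temperature")
    fh[[paste0("combined_", key, "_fixed_b")]] <-
      combined_fh_fit(ambient, pts, cond, config$constants, "fixed_b",
                      fixed_b_chi = b_amb)
  }

  fh_summary <- lapply(fh, function(mod) list(
    kind = mod$chi$kind, chi = mod$chi$chi, a_chi = mod$chi$a_chi,
    b_chi_K = mod$chi$b_chi, r_squared = mod$fit_report$r_squared,
    n = mod$fit_report$n,
    solubility_298K_wtpct = tryCatch(solve_liquidus_wtpct(298, mod),
                                     error = function(e) NA_real_)))
  summary <- list(seed = config$seed, tau_ref_s = config$tau_ref,
                  n_spectra = nrow(man), n_conditions = nrow(tg_table),
                  gt = list(tg_drug_K = gt$tg_drug, tg_poly_K = gt$tg_poly,
                            k = gt$k),
                  fh = fh_summary)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(config$out_dir, "summary.json"))
  structure(list(tau_table = tau_table, tg_table = tg_table,
                 solubility_points = sol, gt = gt, fh = fh,
                 summary = summary),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d spectra, %d conditions, %d FH fits\n",
              x$summary$n_spectra, x$summary$n_conditions, length(x$fh)))
  for (nm in names(x$fh)) {
    s <- x$summary$fh[[nm]]
    cat(sprintf("  %-36s R^2 = %.3f, 298 K solubility = %.2f wt%%\n",
                nm, s$r_squared, s$solubility_298K_wtpct))
  }
  invisible(x)
}
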