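#' Write / read a loss spectrum as delimited text
#'
#' The on-disk dialect is tab-separated columns `frequency_hz`, `eps_loss`
#' preceded by `#`-prefixed metadata lines carrying `temperature_K`,
#' `pressure_MPa` and `label`.
#'
#' @param spectrum A [loss_spectrum()].
#' @param path File path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum`
#'   returns a [loss_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "loss_spectrum"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# temperature_K: %.6g", spectrum$temperature),
               sprintf("# pressure_MPa: %.6g", spectrum$pressure),
               sprintf("# label: %s", spectrum$label)), con)
  write.table(data.frame(frequency_hz = spectrum$frequency,
                         eps_loss = spectrum$loss),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(temperature_K = NA_real_, pressure_MPa = 0.1, label = "")
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv)); val <- trimws(sub("^[^:]*:", "", kv))
    if (key %in% c("temperature_K", "pressure_MPa")) meta[[key]] <- as.numeric(val)
    if (key == "label") meta$label <- val
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  loss_spectrum(tab$frequency_hz, tab$eps_loss,
                temperature = meta$temperature_K,
                pressure = meta$pressure_MPa, label = meta$label)
}

#' Write / read a delimited data table with unit-bearing column names
#'
#' Thin wrappers around [utils::write.table()] / [utils::read.table()]
#' using the package's tab-separated dialect (`#` comment lines allowed).
#'
#' @param x Data frame.
#' @param path File path.
#' @return `read_delim_table` returns a data frame.
#' @export
write_delim_table <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_delim_table
#' @export
read_delim_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Serialize an HN fit to a JSON record
#'
#' @param fit An [hn_fit()].
#' @param spectrum Optional [loss_spectrum()] supplying condition metadata.
#' @return JSON string (also written to `path` when given).
#' @param path Optional output file.
#' @export
hn_fit_json <- function(fit, spectrum = NULL, path = NULL) {
  stopifnot(inherits(fit, "hn_fit"))
  rec <- list(delta_eps = fit$delta_eps, tau_hn_s = fit$tau_hn, a = fit$a,
              b = fit$b, tau_alpha_s = fit$tau_alpha,
              sigma_dc = fit$sigma_dc,
              conductivity_term = fit$sigma_dc != 0,
              peak_outside_window = fit$peak_outside_window,
              fit_quality = fit$fit_quality)
  if (!is.null(spectrum))
    rec <- c(list(temperature_K = spectrum$temperature,
                  pressure_MPa = spectrum$pressure,
                  label = spectrum$label), rec)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) writeLines(js, path)
  js
}

#' In-package study tables of the NMS + KVA system
#'
#' Returns the printed study tables shipped as plain-text fixtures:
#' composition-Tg pairs (DSC and BDS, ambient; BDS at 50 MPa) and the
#' post-annealing solubility-limit tables at ambient pressure (DSC and
#' BDS) and at 50 MPa (BDS).
#'
#' @return Named list of data frames: `composition_tg_dsc`,
#'   `composition_tg_bds`, `composition_tg_bds_50mpa`,
#'   `solubility_dsc_ambient`, `solubility_bds_ambient`,
#'   `solubility_bds_50mpa`.
#' @examples
#' names(nms_kva_data())
#' @export
nms_kva_data <- function() {
  dir <- system.file("extdata", package = "asdsol")
  files <- c(composition_tg_dsc = "composition_tg_dsc.tsv",
             composition_tg_bds = "composition_tg_bds.tsv",
             composition_tg_bds_50mpa = "composition_tg_bds_50mpa.tsv",
             solubility_dsc_ambient = "solubility_dsc_ambient.tsv",
             solubility_bds_ambient = "solubility_bds_ambient.tsv",
             solubility_bds_50mpa = "solubility_bds_50mpa.tsv")
  lapply(files, function(f) read_delim_table(file.path(dir, f)))
}
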