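# Plain-text interfaces: CSV series with a "# key: value" metadata header
# block (so analysis functions can self-configure), and JSON reports.

#' Write a data frame as CSV with a metadata header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named list written as leading `# key: value` comment lines.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(meta[[k]], digits = 15), collapse = " ")),
               con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_series_csv()]
#'
#' @param path Input path.
#' @return Data frame with attribute `meta` (values parsed as numeric where
#'   possible).
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    vn <- suppressWarnings(as.numeric(strsplit(v, "\\s+")[[1]]))
    meta[[trimws(k)]] <- if (all(!is.na(vn))) vn else v
  }
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "meta") <- meta
  df
}

#' Write a PFG series to CSV
#'
#' Columns `gradient_strength` (T/cm) and `intensity`; pulse timings go in
#' the metadata header.
#'
#' @param series A [pfg_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfg_csv <- function(series, path) {
  stopifnot(inherits(series, "pfg_series"))
  meta <- list(delta_s = series$delta, big_delta_s = series$big_delta,
               tau_s = series$tau, gamma = series$gamma)
  if (!is.null(attr(series, "seed"))) meta$seed <- attr(series, "seed")
  write_series_csv(data.frame(gradient_strength = series$gradient_strengths,
                              intensity = series$intensities),
                   path, meta)
}

#' Read a PFG series from CSV
#'
#' Accepts either a `gradient_strength` (T/cm) column or a
#' `gradient_fraction` column combined with a `g_max` metadata entry;
#' timings default to the package conventions when absent from the header.
#'
#' @param path Input path.
#' @return A [pfg_series()].
#' @export
read_pfg_csv <- function(path) {
  df <- read_series_csv(path)
  meta <- attr(df, "meta")
  g <- if ("gradient_strength" %in% names(df)) df$gradient_strength
       else if ("gradient_fraction" %in% names(df)) {
         if (is.null(meta$g_max)) stop("gradient_fraction needs g_max metadata")
         df$gradient_fraction * meta$g_max
       } else stop("no gradient column found")
  pfg_series(g, df$intensity,
             delta = meta$delta_s %||% 2.7e-3,
             big_delta = meta$big_delta_s %||% 0.150,
             tau = meta$tau_s %||% 100e-6,
             gamma = meta$gamma %||% .gamma_h)
}

#' Write a quenching series to CSV
#' @param series A [quench_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quench_csv <- function(series, path) {
  stopifnot(inherits(series, "quench_series"))
  write_series_csv(data.frame(ki_conc_M = series$quencher_conc,
                              f0_over_f = series$f0_over_f),
                   path, list(protein_conc_uM = series$protein_conc))
}

#' Read a quenching series from CSV
#' @param path Input path.
#' @return A [quench_series()].
#' @export
read_quench_csv <- function(path) {
  df <- read_series_csv(path)
  meta <- attr(df, "meta")
  quench_series(df$ki_conc_M, df$f0_over_f,
                protein_conc = meta$protein_conc_uM %||% NA_real_)
}

#' Write a scattering curve to CSV
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scattering_csv <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  df <- data.frame(q_invA = curve$q, intensity = curve$intensity)
  if (!is.null(curve$sigma)) df$sigma <- curve$sigma
  write_series_csv(df, path, list())
}

#' Read a scattering curve from CSV
#' @param path Input path.
#' @return A [scattering_curve()].
#' @export
read_scattering_csv <- function(path) {
  df <- read_series_csv(path)
  scattering_curve(df$q_invA, df$intensity, sigma = df$sigma)
}

#' Write a denaturation curve to CSV
#' @param curve A [denaturation_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_denaturation_csv <- function(curve, path) {
  stopifnot(inherits(curve, "denaturation_curve"))
  write_series_csv(data.frame(x = curve$x, y = curve$y),
                   path, list(probe = curve$probe,
                              axis = curve$axis %||% "chemical"))
}

#' Read a denaturation curve from CSV
#' @param path Input path.
#' @return A [denaturation_curve()].
#' @export
read_denaturation_csv <- function(path) {
  df <- read_series_csv(path)
  meta <- attr(df, "meta")
  out <- denaturation_curve(df$x, df$y,
                            probe = meta$probe %||% "fluorescence")
  out$axis <- meta$axis %||% "chemical"
  out
}

#' Write a SEC marker table to CSV
#' @param markers A [sec_markers()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers_csv <- function(markers, path) {
  stopifnot(inherits(markers, "sec_markers"))
  write_series_csv(as.data.frame(markers), path, list())
}

#' Read a SEC marker table from CSV
#' @param path Input path.
#' @return A [sec_markers()] table.
#' @export
read_markers_csv <- function(path) {
  df <- read_series_csv(path)
  sec_markers(df$name, df$mass_kda, df$volume_ml)
}

#' Write dilution-ITC heats to CSV
#' @param heats Heats vector (ucal), e.g. from [gen_itc()].
#' @param protocol The [dilution_protocol()] used.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heats_csv <- function(heats, protocol, path) {
  meta <- list(syringe_conc_M = protocol$syringe_conc,
               injection_volume_L = protocol$injection_volume,
               cell_volume_L = protocol$cell_volume,
               temperature_K = protocol$temperature)
  if (!is.null(attr(heats, "sigma"))) meta$sigma_ucal <- attr(heats, "sigma")
  write_series_csv(data.frame(injection = seq_along(heats),
                              heat_ucal = as.numeric(heats)),
                   path, meta)
}

#' Read dilution-ITC heats from CSV
#' @param path Input path.
#' @return List with `heats`, `protocol`, `sigma` (or NULL).
#' @export
read_heats_csv <- function(path) {
  df <- read_series_csv(path)
  meta <- attr(df, "meta")
  proto <- dilution_protocol(
    syringe_conc = meta$syringe_conc_M %||% 498e-6,
    injection_volume = meta$injection_volume_L %||% 10e-6,
    cell_volume = meta$cell_volume_L %||% 1.4e-3,
    n_injections = nrow(df),
    temperature = meta$temperature_K %||% 298.15)
  list(heats = df$heat_ucal, protocol = proto, sigma = meta$sigma_ucal)
}

# strip classes/attrs down to JSON-ready lists
.jsonify <- function(x) {
  if (inherits(x, "radius_prediction"))
    return(list(value = x$value, lower = x$lower, upper = x$upper,
                model = x$model))
  if (is.list(x)) return(lapply(unclass(x), .jsonify))
  x
}

#' Write an analysis result as JSON
#'
#' Serializes any of the package's result objects (sequence reports, fits,
#' verdicts) to pretty-printed JSON with attributes and classes flattened.
#'
#' @param x Result object or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  keep <- setdiff(names(x), c("curve", "series", "fitted", "residuals",
                              "protocol"))
  jsonlite::write_json(.jsonify(x[keep]), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
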