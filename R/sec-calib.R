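# Size-exclusion chromatography: log-linear calibration and apparent
# molecular weight estimation feeding oligomer-order assignment.

#' Construct a SEC marker table
#'
#' @param name Marker names.
#' @param mass_kda Marker masses, kDa (> 0).
#' @param volume_ml Elution volumes, mL.
#' @return A data.frame of class `sec_markers`.
#' @export
sec_markers <- function(name, mass_kda, volume_ml) {
  stopifnot(length(name) == length(mass_kda),
            length(name) == length(volume_ml), all(mass_kda > 0))
  structure(data.frame(name = as.character(name), mass_kda = mass_kda,
                       volume_ml = volume_ml, stringsAsFactors = FALSE),
            class = c("sec_markers", "data.frame"))
}

.sec_calibration <- function(slope, intercept, r_squared, markers_used) {
  if (slope >= 0)
    stop("positive calibration slope: larger species must elute earlier")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, markers_used = markers_used),
            class = "sec_calibration")
}

#' Fit a SEC calibration
#'
#' Linear least squares of `log10(mass)` on elution volume. Void-volume
#' markers (blue dextran by default) and any user-identified
#' column-interacting species are excluded before fitting; peaks delayed by
#' protein-column interactions cannot be auto-detected and must be named in
#' `exclude`.
#'
#' @param markers A [sec_markers()] table (>= 3 retained markers; a warning
#'   is issued when they span less than a decade in mass).
#' @param exclude Marker names excluded from the fit.
#' @return An object of class `sec_calibration` with `slope`
#'   (log10(kDa)/mL, negative), `intercept`, `r_squared`, `markers_used`.
#' @export
fit_sec_calibration <- function(markers, exclude = "blue dextran") {
  stopifnot(inherits(markers, "sec_markers"))
  keep <- !(tolower(markers$name) %in% tolower(exclude))
  m <- markers[keep, , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 markers after exclusions")
  if (max(m$mass_kda) / min(m$mass_kda) < 10)
    warning("markers span less than one decade in mass")
  fit <- stats::lm(log10(mass_kda) ~ volume_ml, data = m)
  .sec_calibration(unname(stats::coef(fit)[2]), unname(stats::coef(fit)[1]),
                   suppressWarnings(summary(fit))$r.squared, m$name)
}

#' Exact two-point SEC calibration
#'
#' Solves the log-linear law through exactly two (volume, mass) anchor
#' pairs; used when only two reference points are available.
#'
#' @param volume_ml Two elution volumes, mL.
#' @param mass_kda Two masses, kDa.
#' @return An object of class `sec_calibration`.
#' @export
sec_anchor_calibration <- function(volume_ml, mass_kda) {
  stopifnot(length(volume_ml) == 2L, length(mass_kda) == 2L,
            all(mass_kda > 0), volume_ml[1] != volume_ml[2])
  slope <- diff(log10(mass_kda)) / diff(volume_ml)
  intercept <- log10(mass_kda[1]) - slope * volume_ml[1]
  .sec_calibration(slope, intercept, 1,
                   paste0("anchor@", format(volume_ml), "mL"))
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf("SEC calibration: log10(M/kDa) = %.4f %+.4f V/mL  (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
coef.sec_calibration <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Apparent molecular weight from an elution volume
#'
#' `M = 10^(intercept + slope * V)`. Volumes outside the calibrated range
#' (+/- 10%) set an extrapolation attribute and raise a warning.
#'
#' @param calib A `sec_calibration`.
#' @param volume_ml Elution volume(s), mL.
#' @param range_ml Optional calibrated volume range c(min, max) used for the
#'   extrapolation check.
#' @return Apparent mass in kDa, with attribute `extrapolated`.
#' @export
apparent_mw <- function(calib, volume_ml, range_ml = NULL) {
  stopifnot(inherits(calib, "sec_calibration"))
  mw <- 10^(calib$intercept + calib$slope * volume_ml)
  extrap <- rep(FALSE, length(volume_ml))
  if (!is.null(range_ml)) {
    pad <- 0.1 * diff(range(range_ml))
    extrap <- volume_ml < min(range_ml) - pad | volume_ml > max(range_ml) + pad
    if (any(extrap))
      warning("elution volume outside calibrated range; extrapolating")
  }
  attr(mw, "extrapolated") <- extrap
  mw
}

#' Deviation of a marker from a calibration
#'
#' Compares the calibration's predicted mass at a marker's elution volume
#' with the marker's stated mass; relative deviations above `tol` raise a
#' calibration-curvature warning (the log-linear law bends at the column's
#' exclusion limit).
#'
#' @param calib A `sec_calibration`.
#' @param volume_ml Marker elution volume, mL.
#' @param mass_kda Marker stated mass, kDa.
#' @param tol Relative deviation triggering the warning (default 0.15).
#' @return List with `predicted_kda`, `stated_kda`, `relative_deviation`.
#' @export
calibration_deviation <- function(calib, volume_ml, mass_kda, tol = 0.15) {
  pred <- as.numeric(apparent_mw(calib, volume_ml))
  rel <- abs(pred - mass_kda) / mass_kda
  if (rel > tol)
    warning(sprintf("marker deviates %.0f%% from the log-linear calibration; possible curvature near the exclusion limit",
                    100 * rel))
  list(predicted_kda = pred, stated_kda = mass_kda, relative_deviation = rel)
}
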