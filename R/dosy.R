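# Pulse-field-gradient (DOSY) NMR: Stejskal-Tanner attenuation fitting and
# internal-reference conversion of the diffusion coefficient to a Stokes
# radius.

#' Proton gyromagnetic ratio, rad s^-1 T^-1
#' @keywords internal
.gamma_h <- 2.6752218744e8

#' Construct a PFG-NMR attenuation series
#'
#' Holds signal intensities measured over an increasing pulsed-field-gradient
#' ramp, together with the pulse-sequence timings needed to compute the
#' Stejskal-Tanner attenuation factor. Units: gradients in T/cm, timings in
#' seconds; with the gyromagnetic ratio in rad/s/T the fitted diffusion
#' coefficient comes out in cm^2/s.
#'
#' @param gradient_strengths Gradient strengths, T/cm, strictly increasing,
#'   at least 5 points.
#' @param intensities Signal intensities (arbitrary units), strictly positive.
#' @param delta Gradient pulse duration, s.
#' @param big_delta Diffusion delay between gradients, s.
#' @param tau Recovery delay between the bipolar gradient pair, s.
#' @param gamma Gyromagnetic ratio, rad/s/T.
#' @return An object of class `pfg_series`.
#' @export
pfg_series <- function(gradient_strengths, intensities,
                       delta = 2.7e-3, big_delta = 0.150, tau = 100e-6,
                       gamma = .gamma_h) {
  g <- as.numeric(gradient_strengths); i <- as.numeric(intensities)
  if (length(g) != length(i)) stop("gradient and intensity lengths differ")
  if (length(g) < 5L) stop("need at least 5 gradient points")
  if (any(diff(g) <= 0)) stop("gradient strengths must be strictly increasing")
  if (any(i <= 0)) stop("intensities must be strictly positive")
  if (big_delta - delta / 3 - tau / 2 <= 0)
    stop("unphysical timing: big_delta - delta/3 - tau/2 must be positive")
  structure(list(gradient_strengths = g, intensities = i, delta = delta,
                 big_delta = big_delta, tau = tau, gamma = gamma),
            class = "pfg_series")
}

#' Stejskal-Tanner attenuation factor
#'
#' `b(g) = gamma^2 delta^2 g^2 (Delta - delta/3 - tau/2)` for the bipolar
#' gradient pair, so that `I = I0 exp(-D b)`.
#'
#' @param series A [pfg_series()] (supplies the timings).
#' @param g Gradient strength(s), T/cm, non-negative.
#' @return Attenuation factor(s) in s/cm^2.
#' @export
attenuation_factor <- function(series, g) {
  stopifnot(inherits(series, "pfg_series"), all(g >= 0))
  eff <- series$big_delta - series$delta / 3 - series$tau / 2
  if (eff <= 0) stop("unphysical timing: big_delta - delta/3 - tau/2 <= 0")
  series$gamma^2 * series$delta^2 * g^2 * eff
}

#' Fit a PFG decay for the translational diffusion coefficient
#'
#' Nonlinear least squares of `I = I0 exp(-D b(g))`, started from the
#' linearization `ln I` vs `g^2` (whose slope is `-D gamma^2 delta^2
#' (Delta - delta/3 - tau/2)`). Both estimates are returned; a fitted
#' `D <= 0` is flagged non-physical instead of raising an error.
#'
#' Because the attenuation spans orders of magnitude, the noise on NMR peak
#' intensities is closer to proportional than additive over the usable
#' ramp; the default `"proportional"` weighting (1/I^2) keeps the late,
#' strongly attenuated gradients informative. `"uniform"` weighting is
#' available for data with constant absolute noise.
#'
#' @param series A [pfg_series()].
#' @param weighting `"proportional"` (default) or `"uniform"`.
#' @return An object of class `dosy_fit` with `d_coefficient` (cm^2/s), `i0`,
#'   `se_d`, `r_squared`, `d_linearized`, and `physical`.
#' @export
fit_decay <- function(series, weighting = c("proportional", "uniform")) {
  stopifnot(inherits(series, "pfg_series"))
  weighting <- match.arg(weighting)
  b <- attenuation_factor(series, series$gradient_strengths)
  y <- series$intensities
  w <- if (weighting == "proportional") 1 / y^2 else rep(1, length(y))
  lin <- stats::lm(log(y) ~ b)
  slin <- suppressWarnings(summary(lin))
  d_lin <- -unname(stats::coef(lin)[2])
  se_lin <- unname(slin$coefficients[2, 2])
  if (!is.finite(d_lin) || d_lin <= 0) {
    return(structure(list(d_coefficient = d_lin, i0 = exp(stats::coef(lin)[1]),
                          se_d = se_lin, r_squared = slin$r.squared,
                          d_linearized = d_lin, physical = FALSE,
                          series = series, fitted = rep(NA_real_, length(y))),
                     class = "dosy_fit"))
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ i0 * exp(-d * b),
      start = list(i0 = exp(unname(stats::coef(lin)[1])), d = d_lin),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit))
    stop("PFG decay fit did not converge; linearized D estimate was ",
         signif(d_lin, 4), " cm^2/s")
  cf <- stats::coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients["d", "Std. Error"]
  fitted_y <- stats::fitted(fit)
  r2 <- 1 - sum((y - fitted_y)^2) / sum((y - mean(y))^2)
  structure(list(d_coefficient = unname(cf["d"]), i0 = unname(cf["i0"]),
                 se_d = unname(se), r_squared = r2, d_linearized = d_lin,
                 physical = unname(cf["d"]) > 0,
                 series = series, fitted = as.numeric(fitted_y)),
            class = "dosy_fit")
}

#' @export
print.dosy_fit <- function(x, ...) {
  cat("PFG-NMR diffusion fit (Stejskal-Tanner)\n")
  cat(sprintf("  D = %.4g +/- %.2g cm^2/s  (linearized: %.4g)\n",
              x$d_coefficient, x$se_d, x$d_linearized))
  cat(sprintf("  I0 = %.4g, R^2 = %.5f%s\n", x$i0, x$r_squared,
              if (!x$physical) "  [NON-PHYSICAL: D <= 0]" else ""))
  invisible(x)
}

#' @export
coef.dosy_fit <- function(object, ...) {
  c(d_coefficient = object$d_coefficient, i0 = object$i0)
}

#' @export
predict.dosy_fit <- function(object, g = NULL, ...) {
  if (is.null(g)) return(object$fitted)
  b <- attenuation_factor(object$series, g)
  object$i0 * exp(-object$d_coefficient * b)
}

#' @export
residuals.dosy_fit <- function(object, ...) {
  object$series$intensities - object$fitted
}

#' Stokes radius from a diffusion reference
#'
#' Stokes-Einstein ratio method: `R_S = r_ref * d_ref / d_sample`, with an
#' internal reference of known hydrodynamic radius (default dioxane,
#' 2.12 Angstrom) measured in the same solution, so that viscosity and
#' temperature cancel.
#'
#' @param d_sample Sample diffusion coefficient, cm^2/s.
#' @param d_ref Reference diffusion coefficient, cm^2/s.
#' @param r_ref Reference hydrodynamic radius, Angstrom.
#' @return Stokes radius in Angstrom.
#' @export
rs_from_reference <- function(d_sample, d_ref = 8.53e-6, r_ref = 2.12) {
  stopifnot(d_sample > 0, d_ref > 0, r_ref > 0)
  r_ref * d_ref / d_sample
}
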