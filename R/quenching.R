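# Stern-Volmer analysis of collisional quenching and the
# protein-concentration trend of K_sv used as a self-association probe.

#' Construct a quenching series
#'
#' @param quencher_conc Quencher concentrations, M, non-negative and
#'   increasing.
#' @param f0_over_f F0/F ratios (dimensionless); the zero-quencher point, if
#'   present, must equal 1.
#' @param protein_conc Protein concentration in protomer units, micromolar.
#' @return An object of class `quench_series`.
#' @export
quench_series <- function(quencher_conc, f0_over_f, protein_conc = NA_real_) {
  x <- as.numeric(quencher_conc); y <- as.numeric(f0_over_f)
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0)) stop("quencher concentrations must be non-negative")
  if (any(diff(x) <= 0)) stop("quencher concentrations must be increasing")
  if (any(x == 0) && any(abs(y[x == 0] - 1) > 1e-9))
    stop("F0/F must equal 1 at zero quencher")
  structure(list(quencher_conc = x, f0_over_f = y,
                 protein_conc = protein_conc),
            class = "quench_series")
}

#' Stern-Volmer fit
#'
#' Linear least squares of `F0/F = 1 + Ksv [Q]`. By default the intercept is
#' fixed at 1 (the model has no free intercept); `fix_intercept = FALSE` fits
#' a free intercept as a baseline diagnostic, flagging intercepts more than
#' 2 SE from 1.
#'
#' @param series A [quench_series()].
#' @param fix_intercept Fix the intercept at 1 (default) or fit it freely.
#' @return An object of class `sv_fit` with `ksv` (1/M), `se_ksv`,
#'   `intercept`, `intercept_fixed`, `protein_conc` and `flags`.
#' @export
stern_volmer_fit <- function(series, fix_intercept = TRUE) {
  stopifnot(inherits(series, "quench_series"))
  x <- series$quencher_conc; y <- series$f0_over_f
  if (length(x) < 4L) stop("need at least 4 points")
  if (diff(range(x)) < 0.3)
    warning("quencher range spans less than 0.3 M; slope poorly determined")
  flags <- character(0)
  if (fix_intercept) {
    fit <- stats::lm(I(y - 1) ~ 0 + x)
    ksv <- unname(stats::coef(fit)[1])
    se <- unname(suppressWarnings(summary(fit))$coefficients[1, 2])
    intercept <- 1
  } else {
    fit <- stats::lm(y ~ x)
    sf <- suppressWarnings(summary(fit))
    ksv <- unname(stats::coef(fit)[2])
    se <- unname(sf$coefficients[2, 2])
    intercept <- unname(stats::coef(fit)[1])
    se_int <- unname(sf$coefficients[1, 2])
    if (abs(intercept - 1) > 2 * se_int) flags <- c(flags, "baseline_error")
  }
  if (ksv < 0) flags <- c(flags, "negative_ksv")
  structure(list(ksv = ksv, se_ksv = se, intercept = intercept,
                 intercept_fixed = fix_intercept,
                 protein_conc = series$protein_conc, flags = flags),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit: Ksv = %.3g +/- %.2g 1/M", x$ksv, x$se_ksv))
  if (is.finite(x$protein_conc))
    cat(sprintf("  (protein %.3g uM)", x$protein_conc))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) c(ksv = object$ksv)

#' Concentration trend of the Stern-Volmer constant
#'
#' A monotone decrease of K_sv with protein concentration indicates that
#' fluorophores become buried in oligomer interfaces as the protein
#' self-associates. The strict verdict requires strictly decreasing point
#' estimates with no reversal of the SE intervals; because point estimates
#' typically carry overlapping errors, the weaker "non-increasing within
#' error" verdict is reported alongside.
#'
#' @param fits List of [stern_volmer_fit()] results, each with a finite
#'   `protein_conc` (at least 3 concentrations).
#' @return A list of class `ksv_trend` with `protein_conc`, `ksv`, `se`,
#'   `decreasing`, `self_association` (flag), `within_error_nonincreasing`
#'   and `verdict` ("decreasing", "constant" or "inconclusive").
#' @export
ksv_trend <- function(fits) {
  if (length(fits) < 3L) stop("need fits at >= 3 protein concentrations")
  stopifnot(all(vapply(fits, inherits, logical(1), "sv_fit")))
  conc <- vapply(fits, `[[`, numeric(1), "protein_conc")
  if (any(!is.finite(conc))) stop("every fit needs a protein concentration")
  ord <- order(conc)
  conc <- conc[ord]
  k <- vapply(fits, `[[`, numeric(1), "ksv")[ord]
  se <- vapply(fits, `[[`, numeric(1), "se_ksv")[ord]
  strict <- all(diff(k) < 0)
  # no SE-interval containment reversal: no later upper bound above an
  # earlier lower bound being exceeded in the increasing direction
  no_reversal <- all(diff(k) < 0 | (k[-1] - se[-1]) <= (k[-length(k)] + se[-length(k)]))
  weak <- all(diff(k) <= 2 * sqrt(se[-1]^2 + se[-length(se)]^2))
  decreasing <- strict && no_reversal
  verdict <- if (decreasing) "decreasing"
             else if (all(abs(diff(k)) < 1e-12)) "constant"
             else "inconclusive"
  structure(list(protein_conc = conc, ksv = k, se = se,
                 decreasing = decreasing,
                 self_association = decreasing,
                 within_error_nonincreasing = weak,
                 verdict = verdict),
            class = "ksv_trend")
}

#' @export
print.ksv_trend <- function(x, ...) {
  cat("Ksv vs protein concentration:\n")
  for (i in seq_along(x$ksv))
    cat(sprintf("  %6.3g uM : %.3g +/- %.2g 1/M\n",
                x$protein_conc[i], x$ksv[i], x$se[i]))
  cat("  verdict:", x$verdict,
      if (x$self_association) "(self-association flagged)" else "", "\n")
  invisible(x)
}
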