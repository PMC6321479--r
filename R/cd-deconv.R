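# Far-UV CD deconvolution: non-negative least squares decomposition of a
# spectrum into secondary-structure class fractions against a packaged
# synthetic reference basis.

#' Synthetic far-UV CD reference basis
#'
#' Idealized class lineshapes on a 190-250 nm grid (1 nm steps): a
#' double-minimum (208/222 nm) helix band with a strong positive 192 nm band,
#' a single-minimum (217 nm) sheet band, a turn band, and a random-coil band
#' with its characteristic ~198 nm minimum. The basis is synthetic: it is
#' intended for round-trip decomposition of spectra generated over the same
#' basis, not for quantitative comparison against experimental reference
#' sets.
#'
#' @param path Optional path to a basis CSV (columns `wavelength_nm`, then
#'   one column per class); the packaged copy is used when `NULL`.
#' @return An object of class `cd_basis`: list with `wavelengths` (nm) and
#'   `basis` (classes x wavelengths matrix, rows helix/sheet/turn/coil).
#' @export
cd_reference_basis <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cd_basis_synthetic.csv",
                        package = "idpbiophys")
  df <- utils::read.csv(path, comment.char = "#")
  wl <- df$wavelength_nm
  classes <- setdiff(names(df), "wavelength_nm")
  b <- t(as.matrix(df[classes]))
  rownames(b) <- classes
  if (qr(b)$rank < nrow(b)) stop("degenerate basis: class spectra dependent")
  structure(list(wavelengths = wl, basis = b), class = "cd_basis")
}

#' Decompose a far-UV CD spectrum into secondary-structure fractions
#'
#' Non-negative least squares of the spectrum on the basis class spectra
#' (after linear interpolation onto the basis grid), followed by projection
#' onto the simplex: the raw non-negative coefficients are normalized to sum
#' to one. Both the raw coefficients and the normalized fractions are
#' returned; the normalized fractions are invariant to uniform scaling of
#' the input spectrum.
#'
#' @param wavelengths Spectrum wavelengths, nm; must cover 190-240 nm.
#' @param intensities Spectrum values (mean residue ellipticity or arbitrary
#'   units on the basis scale).
#' @param basis A [cd_reference_basis()] object.
#' @return An object of class `cd_deconvolution` with `fractions` (named,
#'   sums to 1), `raw_coefficients`, and `rmsd_fit`.
#' @export
deconvolve_cd <- function(wavelengths, intensities,
                          basis = cd_reference_basis()) {
  stopifnot(inherits(basis, "cd_basis"))
  w <- as.numeric(wavelengths); y <- as.numeric(intensities)
  if (length(w) != length(y)) stop("length mismatch")
  if (min(w) > 190 || max(w) < 240)
    stop("spectrum must cover at least the 190-240 nm region")
  grid <- basis$wavelengths
  keep <- grid >= min(w) & grid <= max(w)
  yi <- stats::approx(w, y, xout = grid[keep])$y
  a <- t(basis$basis[, keep, drop = FALSE])
  if (qr(a)$rank < ncol(a)) stop("degenerate basis on the covered grid")
  raw <- as.numeric(pracma::lsqnonneg(a, yi)$x)
  names(raw) <- rownames(basis$basis)
  if (sum(raw) == 0) stop("all-zero solution: spectrum orthogonal to basis")
  frac <- raw / sum(raw)
  resid <- yi - as.numeric(a %*% raw)
  structure(list(fractions = frac, raw_coefficients = raw,
                 rmsd_fit = sqrt(mean(resid^2))),
            class = "cd_deconvolution")
}

#' @export
print.cd_deconvolution <- function(x, ...) {
  cat("CD deconvolution (synthetic basis):\n")
  for (cl in names(x$fractions))
    cat(sprintf("  %-6s %5.1f%%\n", cl, 100 * x$fractions[[cl]]))
  cat(sprintf("  fit RMSD: %.3g\n", x$rmsd_fit))
  invisible(x)
}

#' @export
coef.cd_deconvolution <- function(object, ...) object$fractions
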