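# Seeded synthetic-data generators, one per modality, producing inputs with
# the statistical structure the analysis modules assume. Defaults emulate a
# small (~12.5 kDa), disordered, self-associating His-tagged domain: DOSY
# decay at D = 5.0e-7 cm^2/s, Stern-Volmer constants falling from 1.5 to
# 1.04 1/M between 5 and 40 uM protein, a generalized-Gaussian-coil
# scattering curve at Rg = 26 Angstrom and nu = 1/3, a log-linear SEC
# calibration anchored at (11.98 mL, 100 kDa) / (13.88 mL, 31.6 kDa),
# structureless (linear) denaturation traces, and dilution-ITC heats from a
# dimer-dissociation model.

# run expr under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Generate a synthetic PFG-NMR decay
#'
#' Sixteen gradient strengths ramped linearly from 2% to 95% of the maximum,
#' single-exponential Stejskal-Tanner decay at the true diffusion
#' coefficient, multiplicative Gaussian noise. The default maximum gradient
#' is chosen so the decay spans about two orders of magnitude at the default
#' D (near-complete attenuation at the top of the ramp).
#'
#' @param d_true True diffusion coefficient, cm^2/s.
#' @param noise Relative (multiplicative) noise level.
#' @param n_gradients Number of gradient steps.
#' @param g_max Maximum gradient strength, T/cm.
#' @param frac_range Ramp range as fractions of `g_max`.
#' @param i0 Zero-gradient intensity.
#' @param delta,big_delta,tau Pulse timings, s (see [pfg_series()]).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [pfg_series()] with attributes `truth` and `seed`.
#' @export
gen_dosy <- function(d_true = 5.0e-7, noise = 0.02, n_gradients = 16,
                     g_max = 0.0115, frac_range = c(0.02, 0.95), i0 = 1000,
                     delta = 2.7e-3, big_delta = 0.150, tau = 100e-6,
                     seed = NULL) {
  g <- seq(frac_range[1], frac_range[2], length.out = n_gradients) * g_max
  tmp <- pfg_series(g, rep(1, n_gradients), delta = delta,
                    big_delta = big_delta, tau = tau)
  b <- attenuation_factor(tmp, g)
  i <- .with_seed(seed, i0 * exp(-d_true * b) *
                    (1 + stats::rnorm(n_gradients, 0, noise)))
  i <- pmax(i, 1e-12 * i0)
  out <- pfg_series(g, i, delta = delta, big_delta = big_delta, tau = tau)
  attr(out, "truth") <- list(d = d_true, i0 = i0, noise = noise)
  attr(out, "seed") <- seed
  out
}

#' Generate synthetic Stern-Volmer quenching series
#'
#' Linear `F0/F = 1 + Ksv [KI]` over the 0-0.7 M iodide range, one series
#' per protein concentration, multiplicative Gaussian noise on the nonzero
#' quencher points (the zero-quencher point is 1 by construction). The
#' default Ksv triplet falls with protein concentration, the signature of
#' fluorophores buried by self-association.
#'
#' @param ksv True Stern-Volmer constants, 1/M, one per series.
#' @param protein_conc Protein concentrations, uM protomer.
#' @param noise Relative noise level.
#' @param n_points Points per series.
#' @param ki_max Maximum quencher concentration, M.
#' @param seed Integer seed.
#' @return List of [quench_series()] with attributes `truth` and `seed`.
#' @export
gen_quenching <- function(ksv = c(1.5, 1.1, 1.04),
                          protein_conc = c(5, 20, 40),
                          noise = 0.02, n_points = 8, ki_max = 0.7,
                          seed = NULL) {
  stopifnot(length(ksv) == length(protein_conc))
  x <- seq(0, ki_max, length.out = n_points)
  out <- .with_seed(seed, lapply(seq_along(ksv), function(j) {
    y <- 1 + ksv[j] * x
    eps <- stats::rnorm(n_points, 0, noise)
    y[-1] <- y[-1] * (1 + eps[-1])
    quench_series(x, y, protein_conc = protein_conc[j])
  }))
  attr(out, "truth") <- list(ksv = ksv, protein_conc = protein_conc,
                             noise = noise)
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic small-angle scattering curve
#'
#' Generalized Gaussian coil curve on the 0.008-0.2 1/Angstrom Q grid with
#' proportional Gaussian noise and an optional flat background; per-point
#' uncertainties equal to the noise level are attached.
#'
#' @param rg Radius of gyration, Angstrom.
#' @param nu Flory scaling exponent.
#' @param scale Forward-scattering intensity.
#' @param noise Proportional noise level.
#' @param background Flat background added to the curve.
#' @param q_range Q range, 1/Angstrom.
#' @param n_points Number of Q points.
#' @param seed Integer seed.
#' @return A [scattering_curve()] with attributes `truth` and `seed`.
#' @export
gen_saxs <- function(rg = 26, nu = 1 / 3, scale = 100, noise = 0.02,
                     background = 0, q_range = c(0.008, 0.2), n_points = 100,
                     seed = NULL) {
  q <- seq(q_range[1], q_range[2], length.out = n_points)
  ideal <- scale * ggc_intensity(q, rg, nu) + background
  sig <- noise * ideal
  i <- .with_seed(seed, ideal * (1 + stats::rnorm(n_points, 0, noise)))
  i <- pmax(i, 1e-9 * scale)
  out <- scattering_curve(q, i, sigma = if (noise > 0) sig else NULL)
  attr(out, "truth") <- list(rg = rg, nu = nu, scale = scale, noise = noise,
                             background = background)
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic denaturation trace
#'
#' Either a structureless linear trace (the disordered-domain default) or a
#' two-state sigmoid (folded control), on a chemical (0-7 M denaturant) or
#' thermal (25-85 C) axis. Noise is Gaussian with standard deviation given
#' as a fraction of the trace's signal span.
#'
#' @param mode `"linear"` or `"two_state"`.
#' @param axis `"chemical"` or `"thermal"`.
#' @param params Named list of truth parameters. Linear: `intercept`,
#'   `slope`. Two-state chemical: `m` (kcal/mol/M), `midpoint` (M), plus
#'   baselines `yN, sN, yU, sU`. Two-state thermal: `dhm` (kcal/mol),
#'   `tm` (C), plus baselines. Missing entries take defaults.
#' @param noise Noise standard deviation as a fraction of the signal span.
#' @param n_points Number of points.
#' @param probe Probe label passed to [denaturation_curve()].
#' @param seed Integer seed.
#' @return A [denaturation_curve()] with attributes `truth` and `seed`.
#' @export
gen_denaturation <- function(mode = c("linear", "two_state"),
                             axis = c("chemical", "thermal"),
                             params = list(), noise = 0.01, n_points = 15,
                             probe = "fluorescence", seed = NULL) {
  mode <- match.arg(mode); axis <- match.arg(axis)
  x <- if (axis == "chemical") seq(0, 7, length.out = n_points)
       else seq(25, 85, length.out = n_points)
  p <- params
  if (mode == "linear") {
    p$intercept <- p$intercept %||% if (axis == "chemical") 347 else 350
    p$slope <- p$slope %||% if (axis == "chemical") -1.2 else -0.08
    y <- p$intercept + p$slope * x
  } else if (axis == "chemical") {
    p <- utils::modifyList(list(m = 2.0, midpoint = 2.0, yN = 340, sN = 0.2,
                                yU = 352, sU = -0.1), p)
    k <- exp(p$m * (x - p$midpoint) / (.R_KCAL * 298.15))
    y <- (p$yN + p$sN * x + (p$yU + p$sU * x) * k) / (1 + k)
  } else {
    p <- utils::modifyList(list(dhm = 60, tm = 55, yN = -4000, sN = 5,
                                yU = -9000, sU = 10), p)
    tk <- x + 273.15
    k <- exp(p$dhm / .R_KCAL * (1 / (p$tm + 273.15) - 1 / tk))
    y <- (p$yN + p$sN * tk + (p$yU + p$sU * tk) * k) / (1 + k)
  }
  span <- max(diff(range(y)), 1e-9)
  y <- .with_seed(seed, y + stats::rnorm(n_points, 0, noise * span))
  out <- denaturation_curve(x, y, probe = probe)
  out$axis <- axis
  attr(out, "truth") <- c(list(mode = mode, axis = axis, noise = noise), p)
  attr(out, "seed") <- seed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic SEC marker table and sample peaks
#'
#' Marker elution volumes from a log-linear law (by default anchored so
#' that 11.98 mL maps to 100 kDa and 13.88 mL to 31.6 kDa) with Gaussian
#' volume jitter; a void (blue dextran) marker outside the law is included.
#'
#' @param slope,intercept Calibration law, log10(kDa) per mL and log10(kDa).
#' @param jitter_sd Volume jitter standard deviation, mL.
#' @param sample_volumes Sample peak elution volumes, mL.
#' @param seed Integer seed.
#' @return List with `markers` (a [sec_markers()] table) and
#'   `sample_volumes`, plus attributes `truth` and `seed`.
#' @export
gen_sec_markers <- function(slope = -0.263322588, intercept = 5.154604605,
                            jitter_sd = 0, sample_volumes = c(11.98, 13.88),
                            seed = NULL) {
  masses <- c(ferritin = 400, catalase = 232, aldolase = 158, albumin = 66,
              `RNase A` = 13.7)
  vols <- (log10(masses) - intercept) / slope
  vols <- .with_seed(seed, vols + stats::rnorm(length(vols), 0, jitter_sd))
  mk <- sec_markers(c(names(masses), "blue dextran"),
                    c(masses, 2000), c(vols, 8.0))
  out <- list(markers = mk, sample_volumes = sample_volumes)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             jitter_sd = jitter_sd)
  attr(out, "seed") <- seed
  out
}

# protomer speciation for a monomer-dimer-tetramer cascade:
# Kd1 = m^2/d, Kd2 = d^2/t; total protomer c = m + 2 m^2/Kd1 + 4 (m^2/Kd1)^2/Kd2
.cascade_monomer <- function(c_total, kd1, kd2) {
  if (c_total == 0) return(0)
  f <- function(m) m + 2 * m^2 / kd1 + 4 * (m^2 / kd1)^2 / kd2 - c_total
  stats::uniroot(f, c(0, c_total), tol = 1e-15 * max(c_total, 1e-9))$root
}

# enthalpy deficit E (ucal) of a volume v at total protomer conc c, relative
# to the all-monomer state: dissociating everything would absorb E
.cascade_deficit <- function(c, v, kd1, kd2, dh1, dh2) {
  if (c <= 0) return(0)
  m <- .cascade_monomer(c, kd1, kd2)
  d <- m^2 / kd1; t <- d^2 / kd2
  (dh1 * d + (2 * dh1 + dh2) * t) * v * 1e9
}

#' Generate synthetic dilution-ITC heats
#'
#' Forward-simulates per-injection heats under either the simple
#' dimer-dissociation model (via [simulate_dilution()]) or a
#' monomer-dimer-tetramer cascade (a construction used to exercise the
#' adequacy test; no claim it is any particular system's true mechanism),
#' then adds Gaussian noise scaled to the largest heat.
#'
#' @param truth `"dimer"` or `"dimer_tetramer"`.
#' @param kd Dimer dissociation constant, M.
#' @param dh Dimer dissociation enthalpy, kcal/mol dimer.
#' @param kd2 Tetramer-to-dimers dissociation constant, M (cascade only).
#' @param dh2 Tetramer dissociation enthalpy, kcal/mol tetramer.
#' @param baseline Baseline heat per injection, ucal.
#' @param noise Noise standard deviation as a fraction of the largest
#'   absolute heat.
#' @param protocol A [dilution_protocol()].
#' @param seed Integer seed.
#' @return Numeric heats (ucal) with attributes `truth`, `seed`, `sigma`.
#' @export
gen_itc <- function(truth = c("dimer", "dimer_tetramer"),
                    kd = 100e-6, dh = 5, kd2 = 1e-6, dh2 = 8,
                    baseline = 0.5, noise = 0.02,
                    protocol = dilution_protocol(), seed = NULL) {
  truth <- match.arg(truth)
  if (truth == "dimer") {
    h <- as.numeric(simulate_dilution(protocol, kd, dh, baseline))
  } else {
    v0 <- protocol$cell_volume; v <- protocol$injection_volume
    cs <- protocol$syringe_conc
    h <- numeric(protocol$n_injections)
    c_cell <- 0
    for (i in seq_len(protocol$n_injections)) {
      e_before <- .cascade_deficit(c_cell, v0 - v, kd, kd2, dh, dh2) +
        .cascade_deficit(cs, v, kd, kd2, dh, dh2)
      c_new <- (c_cell * (v0 - v) + cs * v) / v0
      e_after <- .cascade_deficit(c_new, v0, kd, kd2, dh, dh2)
      h[i] <- (e_before - e_after) + baseline
      c_cell <- c_new
    }
  }
  sig <- noise * max(abs(h), 1e-12)
  h <- .with_seed(seed, h + stats::rnorm(length(h), 0, sig))
  attr(h, "truth") <- list(model = truth, kd = kd, dh = dh, kd2 = kd2,
                           dh2 = dh2, baseline = baseline, noise = noise)
  attr(h, "seed") <- seed
  attr(h, "sigma") <- sig
  h
}

#' Generate a synthetic far-UV CD spectrum
#'
#' Linear mixture of the packaged basis class spectra plus Gaussian noise
#' scaled to the largest absolute signal.
#'
#' @param fractions Named fractions over the basis classes (helix, sheet,
#'   turn, coil); normalized to sum to one.
#' @param noise Noise standard deviation as a fraction of max |signal|.
#' @param basis A [cd_reference_basis()].
#' @param seed Integer seed.
#' @return List with `wavelengths` and `intensities`, plus attributes
#'   `truth` and `seed`.
#' @export
gen_cd_spectrum <- function(fractions = c(helix = 0.07, sheet = 0.35,
                                          turn = 0.12, coil = 0.46),
                            noise = 0.02, basis = cd_reference_basis(),
                            seed = NULL) {
  stopifnot(inherits(basis, "cd_basis"))
  cls <- rownames(basis$basis)
  f <- fractions[cls]
  if (any(is.na(f))) stop("fractions must name the basis classes")
  f <- f / sum(f)
  y <- as.numeric(f %*% basis$basis)
  y <- .with_seed(seed, y + stats::rnorm(length(y), 0, noise * max(abs(y))))
  out <- list(wavelengths = basis$wavelengths, intensities = y)
  attr(out, "truth") <- list(fractions = f, noise = noise)
  attr(out, "seed") <- seed
  out
}
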