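# Sequence-derived physical properties: mass, charge, pI, and the
# hydrodynamic-radius predictors that serve as the reference frame for the
# experimental modalities.

# ExPASy-style average residue masses (Da); free amino acid minus one water.
.residue_masses <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.01524

# Bjellqvist pKa set (ExPASy-compatible).
.pka_positive <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
.pka_negative <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
.pka_nterm_by_residue <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                           V = 7.44, E = 7.7)
.pka_cterm_by_residue <- c(D = 4.55, E = 4.75)

.avogadro <- 6.02214076e23

#' Construct a validated protein sequence
#'
#' @param residues One-letter amino-acid string (the 20 canonical codes).
#' @param name Free-text name for the sequence.
#' @return An object of class `protein_sequence` with fields `residues` and
#'   `name`.
#' @examples
#' protein_sequence("MKYFG", name = "toy")
#' @export
protein_sequence <- function(residues, name = "") {
  if (!is.character(residues) || length(residues) != 1L)
    stop("'residues' must be a single character string")
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) < 1L) stop("sequence must contain at least one residue")
  letters <- strsplit(residues, "")[[1]]
  bad <- which(!letters %in% names(.residue_masses))
  if (length(bad) > 0L)
    stop(sprintf("non-canonical residue '%s' at position %d",
                 letters[bad[1]], bad[1]))
  structure(list(residues = residues, name = as.character(name)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("Protein sequence", if (nzchar(x$name)) sQuote(x$name) else "", "\n")
  cat("  length:", nchar(x$residues), "residues\n")
  cat("  ", x$residues, "\n", sep = "")
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

#' Read a single-record FASTA file
#'
#' Reads one amino-acid record and validates it against the 20 canonical
#' one-letter codes; the description line is kept as the sequence name.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A [protein_sequence()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             whole.header = TRUE)
  if (length(recs) != 1L)
    stop("expected a single FASTA record, found ", length(recs))
  protein_sequence(as.character(recs[[1]]),
                   name = attr(recs[[1]], "Annot"))
}

#' Average molecular mass of a protein sequence
#'
#' Sum of isotope-abundance-weighted (average) residue masses plus one water.
#'
#' @param seq A [protein_sequence()].
#' @param vbar Partial specific volume in mL/g (default 0.721), carried along
#'   for downstream sphere-radius calculations.
#' @return A list of class `mass_properties` with `average_mass` (Da),
#'   `residue_count` and `partial_specific_volume` (mL/g).
#' @export
average_mass <- function(seq, vbar = 0.721) {
  stopifnot(inherits(seq, "protein_sequence"))
  letters <- strsplit(seq$residues, "")[[1]]
  m <- sum(.residue_masses[letters]) + .water_mass
  n <- length(letters)
  if (m <= n * 57) stop("mass below glycine lower bound; invalid sequence")
  structure(list(average_mass = m, residue_count = n,
                 partial_specific_volume = vbar),
            class = "mass_properties")
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups (both termini and
#' D, E, C, Y, H, K, R side chains) using the Bjellqvist pKa set, with
#' residue-specific terminal pKa values where defined.
#'
#' @param seq A [protein_sequence()].
#' @param pH pH value (scalar or vector).
#' @return Net charge in elementary-charge units.
#' @export
net_charge <- function(seq, pH) {
  stopifnot(inherits(seq, "protein_sequence"))
  letters <- strsplit(seq$residues, "")[[1]]
  first <- letters[1]; last <- letters[length(letters)]
  pk_n <- if (first %in% names(.pka_nterm_by_residue))
    .pka_nterm_by_residue[[first]] else .pka_positive[["Nterm"]]
  pk_c <- if (last %in% names(.pka_cterm_by_residue))
    .pka_cterm_by_residue[[last]] else .pka_negative[["Cterm"]]
  counts <- table(factor(letters, levels = names(.residue_masses)))
  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - pk_n)) +
      sum(vapply(c("K", "R", "H"), function(a)
        counts[[a]] / (1 + 10^(p - .pka_positive[[a]])), numeric(1)))
    neg <- 1 / (1 + 10^(pk_c - p)) +
      sum(vapply(c("D", "E", "C", "Y"), function(a)
        counts[[a]] / (1 + 10^(.pka_negative[[a]] - p)), numeric(1)))
    pos - neg
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' Bisection on pH in \[0, 14\] for the zero of [net_charge()], iterated to
#' `|charge| < 1e-4`.
#'
#' @param seq A [protein_sequence()].
#' @return The pI (pH units).
#' @export
isoelectric_point <- function(seq) {
  lo <- 0; hi <- 14
  # net charge is monotone decreasing in pH
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Protein concentration from UV absorbance
#'
#' Nucleic-acid-corrected estimate `1.55 * A280 - 0.75 * A260` in mg/mL.
#'
#' @param a280,a260 Absorbance at 280 and 260 nm (AU, non-negative).
#' @return Concentration in mg/mL.
#' @export
concentration_from_absorbance <- function(a280, a260) {
  stopifnot(a280 >= 0, a260 >= 0)
  pc <- 1.55 * a280 - 0.75 * a260
  if (any(pc <= 0))
    stop("non-positive concentration: nucleic-acid-dominated or blank sample")
  pc
}

.radius_prediction <- function(value, lower, upper, model) {
  stopifnot(lower <= value, value <= upper, value > 0)
  structure(list(value = value, lower = lower, upper = upper, model = model),
            class = "radius_prediction")
}

#' @export
print.radius_prediction <- function(x, ...) {
  cat(sprintf("%s radius: %.2f Angstrom", x$model, x$value))
  if (x$lower != x$upper)
    cat(sprintf("  [%.2f, %.2f]", x$lower, x$upper))
  cat("\n")
  invisible(x)
}

#' Radius of the unsolvated equivalent sphere
#'
#' `R = (3 M vbar / (4 N_A pi))^(1/3)`, the radius of a compact anhydrous
#' sphere with the molecular mass and partial specific volume of the protein.
#'
#' @param mass Molecular mass in Da (or a `mass_properties` object).
#' @param vbar Partial specific volume, mL/g.
#' @return A `radius_prediction` (Angstrom), model `"anhydrous_sphere"`.
#' @export
anhydrous_sphere_radius <- function(mass, vbar = 0.721) {
  if (inherits(mass, "mass_properties")) {
    vbar <- mass$partial_specific_volume
    mass <- mass$average_mass
  }
  stopifnot(mass > 0, vbar > 0)
  r_cm <- (3 * mass * vbar / (4 * .avogadro * pi))^(1 / 3)
  r <- r_cm * 1e8
  .radius_prediction(r, r, r, "anhydrous_sphere")
}

#' Hydrated sphere radius
#'
#' Adds a hydration-shell thickness (default 3.2 Angstrom, roughly one water
#' layer) to the anhydrous equivalent-sphere radius.
#'
#' @param anhydrous A `radius_prediction` from [anhydrous_sphere_radius()],
#'   or a bare radius in Angstrom.
#' @param shell Shell thickness in Angstrom (>= 0).
#' @return A `radius_prediction`, model `"hydrated_sphere"`.
#' @export
hydrated_radius <- function(anhydrous, shell = 3.2) {
  if (shell < 0) stop("hydration shell thickness must be non-negative")
  r0 <- if (inherits(anhydrous, "radius_prediction")) anhydrous$value
        else anhydrous
  r <- r0 + shell
  .radius_prediction(r, r, r, "hydrated_sphere")
}

#' Stokes-radius scaling law for folded proteins
#'
#' `R_S = (4.75 +/- 1.11) N^0.29` with N the residue count; the coefficient
#' uncertainty is propagated to the prediction band, the exponent is treated
#' as exact.
#'
#' @param n_residues Number of residues (>= 1).
#' @return A `radius_prediction` (Angstrom), model `"folded_scaling"`.
#' @export
rs_folded <- function(n_residues) {
  stopifnot(n_residues >= 1)
  f <- n_residues^0.29
  .radius_prediction(4.75 * f, (4.75 - 1.11) * f, (4.75 + 1.11) * f,
                     "folded_scaling")
}

#' Stokes-radius scaling law for unfolded chains
#'
#' `R_S = (2.21 +/- 1.07) N^0.57`; see [rs_folded()] for conventions.
#'
#' @inheritParams rs_folded
#' @return A `radius_prediction` (Angstrom), model `"unfolded_scaling"`.
#' @export
rs_unfolded <- function(n_residues) {
  stopifnot(n_residues >= 1)
  f <- n_residues^0.57
  .radius_prediction(2.21 * f, (2.21 - 1.07) * f, (2.21 + 1.07) * f,
                     "unfolded_scaling")
}

#' Oligomer order from an apparent molecular mass
#'
#' Nearest-integer ratio of apparent to monomer mass, with the rounding
#' residual reported so that ambiguous assignments (residual near 0.5) are
#' visible rather than silently rounded.
#'
#' @param apparent_mass Apparent mass, kDa.
#' @param monomer_mass Monomer (protomer) mass, kDa.
#' @param source Free-text provenance, e.g. "SEC", "BN-PAGE", "cross-linking".
#' @return An object of class `oligomer_assignment` with fields
#'   `apparent_mass`, `monomer_mass`, `order`, `residual_fraction`, `source`,
#'   `ambiguous`.
#' @export
oligomer_order <- function(apparent_mass, monomer_mass, source = "") {
  stopifnot(apparent_mass > 0, monomer_mass > 0)
  if (apparent_mass < 0.5 * monomer_mass)
    stop("apparent mass below half the monomer mass; sub-monomeric input")
  ratio <- apparent_mass / monomer_mass
  k <- max(1L, as.integer(round(ratio)))
  res <- abs(ratio - k)
  structure(list(apparent_mass = apparent_mass, monomer_mass = monomer_mass,
                 order = k, residual_fraction = res, source = source,
                 ambiguous = res > 0.4),
            class = "oligomer_assignment")
}

#' @export
print.oligomer_assignment <- function(x, ...) {
  cat(sprintf("Oligomer order %d (%s): apparent %.3g kDa / monomer %.4g kDa, residual %.2f%s\n",
              x$order, x$source, x$apparent_mass, x$monomer_mass,
              x$residual_fraction, if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

#' Sequence property report
#'
#' Collects length, mass, pI and the four radius predictors into one list,
#' the JSON-ready summary used as the reference frame by [build_report()].
#'
#' @param seq A [protein_sequence()].
#' @param vbar Partial specific volume, mL/g.
#' @param shell Hydration shell thickness, Angstrom.
#' @return A list with `sequence`, `length`, `mass_da`, `pi` and a `radii`
#'   sub-list holding the four `radius_prediction` objects.
#' @export
sequence_report <- function(seq, vbar = 0.721, shell = 3.2) {
  mp <- average_mass(seq, vbar = vbar)
  anh <- anhydrous_sphere_radius(mp)
  list(sequence = seq$residues,
       length = mp$residue_count,
       mass_da = mp$average_mass,
       pi = isoelectric_point(seq),
       radii = list(anhydrous = anh,
                    hydrated = hydrated_radius(anh, shell),
                    folded = rs_folded(mp$residue_count),
                    unfolded = rs_unfolded(mp$residue_count)))
}
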