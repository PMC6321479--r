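---
title: "Methods: models, estimators and design choices in idpbiophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in idpbiophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpbiophys)
```

`idpbiophys` packages the estimators a solution-biophysics lab chains
together to decide whether a protein domain is intrinsically disordered
and whether it self-associates. This vignette documents the models behind
each estimator, the tunable parameters and their defaults, the numerical
choices, what the synthetic generators do and do not emulate, and the
places where the design was genuinely open.

## Sequence layer

The reference frame for every hydrodynamic comparison is computed from
sequence alone.

**Mass and pI.** `average_mass()` sums ExPASy-style average residue
masses plus one water. `isoelectric_point()` bisects the
Henderson–Hasselbalch net charge on pH ∈ [0, 14] to |charge| < 10⁻⁴,
using the Bjellqvist pKa set with residue-specific terminal values
(N-terminal M 7.0, S 6.93, …; C-terminal D 4.55, E 4.75). pKa sets differ
across tools at the ±0.1 pH level, which is the tolerance we attach to
any pI comparison.

**Radius predictors.** Four models bracket the plausible sizes of an
N-residue chain of mass M:

* anhydrous equivalent sphere, R = (3MV̄/4N_Aπ)^(1/3), with the partial
  specific volume V̄ defaulting to 0.721 mL/g (typical for proteins);
* hydrated sphere, adding a `shell` of 3.2 Å — roughly one water layer,
  the conventional correction that turns an anhydrous 15.3 Å sphere of a
  12.45 kDa protein into an 18.5 Å hydrated one;
* empirical folded-chain scaling R_S = (4.75 ± 1.11)N^0.29 and
  unfolded-chain scaling R_S = (2.21 ± 1.07)N^0.57. Only the printed
  coefficient uncertainties are propagated into the prediction bands; the
  exponents are treated as exact, matching how these laws are quoted.

A note on the two scaling laws: with these coefficients the unfolded
prediction exceeds the folded one only for N ≥ 16 (brute-force check in
the test suite); below that the laws are not discriminating, which is
irrelevant for realistic domains but worth knowing.

**Oligomer order.** `oligomer_order()` rounds apparent/monomer mass to
the nearest integer but reports the rounding residual and flags residuals
above 0.4 as ambiguous: an apparent mass 2.5× the monomer should read as
"between dimer and trimer", never silently as one of them.

## DOSY-NMR

The bipolar-gradient Stejskal–Tanner model is
I(G) = I₀ exp(−D·b(G)) with b(G) = γ²δ²G²(Δ − δ/3 − τ/2). Defaults:
gradient duration δ = 2.7 ms, diffusion delay Δ = 150 ms, bipolar
recovery τ = 100 μs, proton γ = 2.6752218744 × 10⁸ rad s⁻¹ T⁻¹. With G
in T/cm, b comes out in s/cm² and D in cm²/s with no further conversion;
all units are centralized in `pfg_series()`.

`fit_decay()` starts from the exact linearization (ln I vs G², slope
−D·γ²δ²(Δ−δ/3−τ/2)) and refines by nonlinear least squares. Because the
usable decay spans about two orders of magnitude, noise on peak
intensities is closer to proportional than additive, and an unweighted
fit is dominated by the first few gradients; the default therefore
weights residuals by 1/I² (the efficient choice under proportional
noise), with `weighting = "uniform"` available for constant-noise data.
The object reports both the nonlinear and linearized estimates — they
must agree within 1% on clean data — plus the fit standard error. Whether
a quoted D uncertainty is a fit SE or a replicate SD is often ambiguous
in practice; the test suite calibrates the fit SE against the empirical
SD of 200 seeded replicates.

Degenerate input (no decay) yields D ≈ 0 flagged `physical = FALSE`
rather than an error, since a flat decay is a legitimate observation.

`rs_from_reference()` converts D to a Stokes radius by ratio against an
internal reference measured in the same tube
(R_S = r_ref·D_ref/D_sample, dioxane r_ref = 2.12 Å by default), so
viscosity and temperature cancel exactly.

**Generator.** `gen_dosy()` ramps 16 gradients linearly over 2–95% of
`g_max` and applies multiplicative Gaussian noise (default 2%). The
maximum gradient (default 0.0115 T/cm) is set so the decay spans ~two
decades at the default D = 5.0 × 10⁻⁷ cm²/s — i.e., near-complete
attenuation at the top of the ramp, which is what a well-set-up
experiment looks like. `g_max` is a plain parameter for other probes.

## Stern–Volmer quenching

The collisional-quenching model F₀/F = 1 + K_sv[KI] has no free
intercept, so `stern_volmer_fit()` fixes the intercept at 1 by default
(the closed form is then K_sv = Σx(y−1)/Σx²). A free-intercept mode
exists purely as a baseline diagnostic: an intercept more than 2 SE from
1 flags a mis-referenced F₀. Whether published fits fixed the intercept
is rarely stated; both modes are first-class here.

`ksv_trend()` asks whether K_sv falls as protein concentration rises —
the buried-fluorophore signature of self-association. The strict flag
requires strictly decreasing point estimates with no SE-interval
reversal; because real triplets carry overlapping errors, the weaker
"non-increasing within error" verdict is reported alongside, and a
non-monotone sequence returns "inconclusive" rather than a guess.

**Generator.** `gen_quenching()` produces one series per protein
concentration over 0–0.7 M iodide (8 points), with the zero-quencher
point exactly 1 (it is a ratio definition, not a measurement) and 2%
multiplicative noise elsewhere. Default truth K_sv = 1.5/1.1/1.04 M⁻¹ at
5/20/40 μM.

## Denaturation analysis

**Spectral summaries.** `spectral_mass_center()` implements
⟨λ⟩ = ΣI / Σ(I/λ) — the inverse of the intensity-weighted mean inverse
wavelength, i.e. the spectral average *energy* expressed as a
wavelength. Conventions differ in the literature; the plain
intensity-weighted mean wavelength is available via
`method = "direct"` for sensitivity checks, and both stay inside the
spectral support. `mean_residue_ellipticity()` uses the standard
[θ] = θ_mdeg·MRW/(10·l·c) with MRW = mass/(N−1), per peptide bond.

**Two-state fits.** The chemical fit is the linear extrapolation model
with ΔG = m([D]₁/₂ − [D]) and linear native/unfolded baselines; the
thermal fit is the Gibbs–Helmholtz two-state model with ΔCp = 0
(no ΔCp is estimable from a single trace, let alone a non-transitioning
one) and R = 1.987 × 10⁻³ kcal mol⁻¹ K⁻¹. Both fits multi-start
(midpoints at the 35/50/65% quantiles of the x-range crossed with a
small m or ΔH grid) and never abort: a non-convergent or degenerate fit
returns an object with `physical = FALSE` and named flags, because for a
disordered domain *that is the result*. Physicality requires m (or ΔH_m)
> 0 and at least twice its SE, a midpoint inside the sampled range, and
finite SEs with SE(m) < m. The `transition_not_significant` flag exists
because a broad shallow sigmoid can mimic a straight line with formally
in-range parameters; demanding the transition slope be distinguishable
from zero closes that loophole.

Each fit also carries a small-sample-corrected information criterion
(AICc) for itself and for a straight line through the same data;
`classify_denaturation()` returns "non-cooperative (IDP-like)" only when
every probe is non-physical *and* loses to the line, "cooperative" when
any probe yields a physical sigmoid, and "mixed" otherwise.

**Generator.** `gen_denaturation()` makes either linear traces (the
disordered default: ⟨λ⟩ drifting ~1.2 nm/M over 0–7 M denaturant, or a
gentle thermal drift over 25–85 °C) or two-state sigmoids (folded
control: m = 2 kcal mol⁻¹ M⁻¹ at [D]₁/₂ = 2 M; ΔH_m = 60 kcal/mol at
T_m = 55 °C), with noise given as a fraction (default 1%) of the signal
span. Chemical traces default to 15 points, thermal sigmoid recovery
tests use 61 (a 1 °C grid — far coarser than a real 0.2 °C scan but
ample for a two-state fit).

## Far-UV CD deconvolution

`deconvolve_cd()` solves a non-negative least squares problem over a
four-class basis (helix, sheet, turn, coil) after interpolating the
query spectrum onto the basis grid, then projects onto the simplex by
normalizing the non-negative coefficients to sum to one. Raw
coefficients and normalized fractions are both reported: the fractions
are invariant to uniform scaling of the input (miscalibrated
concentration), while the raw coefficients absorb it.

The packaged basis (190–250 nm, 1 nm steps) is **synthetic** — idealized
Gaussian-band lineshapes with the canonical features (double-minimum
208/222 nm helix, single-minimum 217 nm sheet, ~198 nm coil minimum).
It supports round-trip validation of spectra generated over the same
basis; it is *not* an experimental reference set, so fractions obtained
from real spectra against this basis are qualitative. Reproducing any
published percentage ranges would require the original reference
database and algorithm, which is out of scope.

## SAXS

`ggc_intensity()` evaluates the generalized Gaussian coil form factor

I(Q) = (1/ν)U^(−1/2ν)γ(1/2ν, U) − (1/ν)U^(−1/ν)γ(1/ν, U),
U = (2ν+1)(2ν+2)Q²Rg²/6,

with the lower incomplete gamma via `pgamma` (relative accuracy well
beyond the 10⁻¹⁰ needed). For U < 10⁻⁶ a three-term series keeps the
Q → 0 limit exactly 1 without cancellation; the series coefficient
reproduces the Guinier expansion 1 − Q²Rg²/3 + O(Q⁴) analytically. At
ν = 0.5 the expression collapses to the Debye function (a closed-form
oracle used in the tests at 10⁻⁸ relative tolerance) and the high-Q
log-log slope tends to −1/ν.

`guinier_fit()` iterates a linear ln I vs Q² fit to self-consistency of
the q·Rg ≤ 1.3 window — 1.3 being the standard validity cutoff for
compact particles, configurable for extended ones. It refuses windows
below 5 points and non-decaying data.

`fit_ggc()` does weighted nonlinear least squares for (scale, Rg, ν)
with ν free in [0.25, 0.7] (spanning the three reference regimes with
margin; estimates at a bound are flagged) and multi-starts ν at
{0.33, 0.5, 0.6}; weights are 1/σ² when uncertainties exist, else 1/I²
for proportional noise. Fixing ν (e.g. at 1/3) is first-class: whether
to float or fix ν on real data is a judgement call, so both modes are
exposed and tested. `classify_compaction()` assigns the nearest of
{globule 1/3, Θ-coil 0.5, swollen 0.6}; when the two nearest distances
differ by < 0.005 the call is flagged ambiguous and the tie breaks
toward the less compact class (claiming collapse needs the stronger
evidence).

**Generator.** `gen_saxs()` covers Q ∈ [0.008, 0.2] Å⁻¹ (100 points)
with 2% proportional noise and optional flat background, defaults
Rg = 26 Å, ν = 1/3 — a compact-but-unfolded chain. It emulates
buffer-subtracted lab-source data; it does not emulate inter-particle
structure factors, so concentration-dependent repulsion/attraction
effects are invisible to these tests.

## SEC calibration

`fit_sec_calibration()` regresses log₁₀(mass) on elution volume — the
simplest defensible form when void and total volumes are unknown (a
K_av-based calibration needs both). Void markers (blue dextran) are
excluded by name, as are any user-identified column-interacting species:
delayed peaks from protein–matrix interaction cannot be auto-detected
and must be excluded by inspection. The fit demands ≥ 3 markers and a
negative slope; an exact two-point constructor
(`sec_anchor_calibration()`) covers the anchored two-reference case.
`calibration_deviation()` surfaces markers that bend away from the
log-linear law (e.g. high-mass markers near the exclusion limit) as a
curvature warning, not an error. `apparent_mw()` flags extrapolation
beyond the calibrated range ± 10%.

## Dilution ITC

The forward model (`simulate_dilution()`) uses the standard
displacement-cell convention: each injection expels an equal volume of
current cell contents *before* mixing, the incoming aliquot is at the
syringe equilibrium, and the cell re-equilibrates at the diluted
concentration. The monomer fraction of a dissociating dimer is the
mass-action closed form f = (−K_d + √(K_d² + 8K_dC))/4C. Heat per
injection is ΔH × (moles of dimer newly dissociated) + baseline. The
bookkeeping (protomer and dimer moles injected, displaced and resident)
is carried on the result, and the tests assert exact mole conservation
and the exact heat balance Σq = ΔH × (dimer in − dimer out − dimer
left). Protocol defaults: 498 μM protomer syringe, 10 μL injections
into a 1.4 mL cell, 28 injections, 25 °C.

`fit_dimer_dissociation()` exploits that for fixed K_d the model is
linear in (ΔH, baseline): those are profiled out by weighted linear
least squares and a 1-D search over log₁₀K_d ∈ [−9, −1] does the rest —
much more robust than a 3-parameter nonlinear search. Adequacy of the
dimer-only mechanism combines a Wald–Wolfowitz runs test on residual
signs at the 5% level with χ²/dof < 2 when per-injection uncertainties
are available; patterned residuals mean the mechanism, not the noise, is
wrong. Near-zero signals are flagged `no_signal` and considered
trivially adequate.

**Generator.** `gen_itc()` simulates either the dimer truth
(K_d = 100 μM, ΔH = 5 kcal/mol dimer — a weak association with
substantial dissociation over this dilution range) or a
monomer–dimer–tetramer cascade used to exercise the adequacy flag. The
cascade's tetramer step is strongly cooperative (K_d2 = 1 μM,
ΔH₂ = 8 kcal/mol tetramer): with a weaker second step the simulated
heats are statistically indistinguishable from a dimer-only model at 2%
noise and the adequacy flag rightly stays TRUE — the construction must
actually express the higher-order equilibrium in the data to be a test
of anything. No claim is made that this cascade is any real system's
mechanism. Noise is Gaussian, scaled to the largest heat (default 2%).

## Evidence aggregation

`build_report()` itemizes each modality's contribution
(supports_disorder / supports_order / supports_oligomer / neutral) and
applies conjunctive rules: "IDP-like" requires the denaturation verdict
to be non-cooperative and every other disorder-capable probe present to
agree (DOSY: measured R_S inside the unfolded band *and* above the
folded upper bound; SAXS: ν in the globule-to-coil range *and* Rg above
the hydrated sphere). "Self-associating" is disjunctive — any oligomer
order ≥ 2, a falling K_sv, or ITC dissociation heats suffices.
Contradictions produce "mixed evidence" explicitly. Aggregation is
monotone: adding a supporting item never flips a verdict away from the
supported state.

## Problem sizes and reproducibility

All generators route randomness through a caller-supplied integer seed
and restore the caller's RNG state, so identical configurations produce
byte-identical output files (asserted by hashing in the tests). The test
suite uses the study-scale defaults throughout: 16-gradient DOSY decays
(200 replicates for the SE calibration), 8-point quenching triplets,
100-point scattering curves, 15–61-point denaturation traces (200
replicates for the model-selection rate), 28-injection ITC runs, and the
109-residue packaged construct for the sequence layer.

## Known limitations

* The CD basis is synthetic; fractions from real spectra are qualitative.
* No multi-component diffusion (biexponential DOSY), no
  accessible-fraction (modified Stern–Volmer) analysis, no ΔCp-floating
  or three-state denaturation models, no SAXS structure factor or P(r)
  inversion, no chromatogram peak picking, no multi-species global ITC
  modelling. Each omission is a deliberate scope boundary, not an
  oversight: the package implements the estimators whose agreement or
  failure constitutes the disorder/oligomer argument.
* Passing tests demonstrate correct recovery of data with the generators'
  statistical structure (independent Gaussian noise, ideal baselines);
  real data add drifts, correlated noise and systematic baselines that
  these tests do not exercise.
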