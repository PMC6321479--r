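# idpbiophys

Solution-biophysics estimators for deciding two questions about a protein
domain: **is it intrinsically disordered?** and **does it self-associate?**

Neither question is answered by a single experiment. Intrinsically
disordered proteins (IDPs) betray themselves through converging negatives —
denaturation curves with no cooperative transition, hydrodynamic radii far
above globular predictions, polymer-like scattering — while
self-association shows up as super-monomeric apparent masses, quenching
constants that fall with protein concentration, and dissociation heats upon
dilution. `idpbiophys` implements each of those estimators as a small,
testable model-fitting function, plus seeded synthetic generators for every
modality so the full pipeline runs and is validated without instrument
data. The bundled worked example is a ~12.5 kDa His-tagged C-terminal
domain of a cyanobacterial ribosome-hibernation protein, an oligomeric IDP.

## What it computes

**Sequence layer.** Average mass, Bjellqvist-style isoelectric point
(bisection on the Henderson–Hasselbalch net charge), and four hydrodynamic
reference radii:

- anhydrous equivalent sphere: R = (3MV̄ / 4N_Aπ)^(1/3)
- hydrated sphere: R + 3.2 Å shell
- folded-chain Stokes radius: R_S = (4.75 ± 1.11) N^0.29
- unfolded-chain Stokes radius: R_S = (2.21 ± 1.07) N^0.57

**DOSY-NMR.** Stejskal–Tanner fit of pulse-field-gradient attenuation,
I = I₀ exp(−D γ²δ²G²(Δ−δ/3−τ/2)), and conversion to a Stokes radius via an
internal reference (dioxane, 2.12 Å): R_S = r_ref · D_ref / D.

**Fluorescence quenching.** Stern–Volmer fit F₀/F = 1 + K_sv[KI] with
fixed unit intercept, and a monotone-decrease test of K_sv versus protein
concentration (buried-fluorophore signature of self-association).

**Denaturation.** Spectral mass centre ⟨λ⟩ = ΣI / Σ(I/λ), mean residue
ellipticity, and two-state fits — chemical (linear extrapolation model,
ΔG = m([D]₁/₂ − [D])) and thermal (Gibbs–Helmholtz with ΔCp = 0) — with
physicality flags and a small-sample information-criterion comparison
against a plain line. For an IDP the *failure* of these fits is the result.

**Far-UV CD.** Non-negative least squares decomposition into
helix/sheet/turn/coil fractions against a packaged synthetic basis.

**SAXS.** Guinier analysis (iterated q·Rg ≤ 1.3 window) and the
generalized Gaussian coil form factor parameterized by Rg and the Flory
exponent ν (Debye function at ν = 0.5, I ∝ Q^(−1/ν) at high Q), with
compaction classification (globule 1/3, Θ-coil 0.5, swollen 0.6).

**SEC.** log₁₀(M) vs elution-volume calibration, apparent molecular
weight, and nearest-integer oligomer-order assignment with ambiguity
reporting.

**Dilution ITC.** Displacement-cell forward model of a dissociating dimer
(2M ⇌ D), profiled least-squares fit of (K_d, ΔH, baseline), and a
residual runs-test adequacy flag that detects higher-order association.

**Aggregation.** `build_report()` combines the modality results into the
two headline verdicts with itemized evidence.

## Worked example

```r
library(idpbiophys)

fa  <- system.file("extdata", "c_lrta_construct.fasta", package = "idpbiophys")
rep <- sequence_report(read_fasta(fa))
#> length 109, mass 12449.89 Da, pI 5.72
#> hydrated_sphere radius: 18.47 Angstrom
#> folded_scaling radius: 18.52 Angstrom  [14.19, 22.84]
#> unfolded_scaling radius: 32.04 Angstrom  [16.53, 47.56]

fit <- fit_decay(gen_dosy(d_true = 5.0e-7, noise = 0.02, seed = 42))
fit
#> PFG-NMR diffusion fit (Stejskal-Tanner)
#>   D = 5.009e-07 +/- 1.7e-09 cm^2/s  (linearized: 5.009e-07)
#>   I0 = 1012, R^2 = 0.99951
rs <- rs_from_reference(fit$d_coefficient, d_ref = 8.53e-6, r_ref = 2.12)
#> 36.1 Angstrom  -- far above the folded prediction, inside the unfolded band

saxs_fit <- fit_ggc(gen_saxs(rg = 26, nu = 1/3, noise = 0.02, seed = 43))
#> Rg = 26.01 Angstrom, nu = 0.334 (globule-like compaction, chi^2/dof = 0.98)

den <- classify_denaturation(list(
  fit_chemical_two_state(gen_denaturation("linear", "chemical", seed = 44)),
  fit_thermal_two_state(gen_denaturation("linear", "thermal",
                                         probe = "cd222", seed = 45))))
trend <- ksv_trend(lapply(gen_quenching(seed = 46), stern_volmer_fit))
cal   <- sec_anchor_calibration(c(11.98, 13.88), c(100, 31.6))
olig  <- oligomer_order(apparent_mw(cal, 11.98), 12.45, "SEC")

build_report(seq_report = rep, denaturation = den, dosy_rs = rs,
             saxs = saxs_fit, quenching = trend, oligomers = list(olig))
#> Evidence report
#>   disorder verdict:   IDP-like
#>   oligomer verdict:   self-associating
#>   evidence:
#>     [denaturation ] supports_disorder  two-state fits: non-cooperative (IDP-like)
#>     [dosy         ] supports_disorder  measured Rs 36.1 A vs folded [14.2, 22.8] / unfolded [16.5, 47.6]
#>     [saxs         ] supports_disorder  Rg 26.0 A (globule, nu = 0.33) vs hydrated sphere 18.5 A
#>     [SEC          ] supports_oligomer  apparent 100 kDa -> order 8
#>     [quenching    ] supports_oligomer  Ksv trend: decreasing
```

Reading the output: the measured Stokes radius (36 Å) sits inside the
unfolded-scaling band and well above the folded prediction; the SAXS Rg
(26 Å) exceeds the hydrated-sphere radius of a compact monomer while ν ≈
1/3 indicates a collapsed (but not folded) chain; denaturation traces are
structureless; and an apparent 100 kDa species with a falling K_sv marks
self-association. Jointly: an oligomeric IDP.

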