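# nucleospec

UV-spectrophotometric inference for nucleoside phosphorylase (NP) chemistry.

Nucleoside phosphorylases reversibly cleave a nucleoside with phosphate into
the free nucleobase and ribose 1-phosphate (Rib1P); run backwards, they
glycosylate a base. When such an enzyme produces an unusual riboside — for
example an N7-ribosylated xanthosine instead of the canonical N9 isomer —
nearly everything one wants to know about the new compound can be read out of
UV absorbance alone: its extinction coefficients, its acidity, the
equilibrium constant of its phosphorolysis, and the enzyme's kinetics toward
its precursor. `nucleospec` implements that complete inference chain for
plate-reader data, together with a forward simulator that generates every
input the pipeline consumes, so each stage is testable end to end without
laboratory data.

It is written for enzymologists and biophysical chemists who monitor
reactions and titrations by UV and want the downstream arithmetic —
unit-safe, validated, and reproducible — handled by code.

## What it computes

**Extinction calibration and transfer.** The Beer-Lambert law
*A*(λ) = ε(λ) · *c*/1000 · *l* (ε in mM⁻¹cm⁻¹, *c* in µM, *l* in cm) gives
ε for a compound of known concentration (`calibrate_extinction`). A compound
that cannot be weighed accurately inherits an absolute scale through an
isosbestic point it shares with a calibrated partner
(`transfer_calibration`): after normalizing both spectra at λ_iso, the
target spectrum is scaled by ε_ref(λ_iso)/A_ref(λ_iso).

**Isosbestic analysis.** `find_isosbestic` locates the wavelengths where two
interconverting species absorb identically (sign changes of the extinction
difference, refined to sub-nm precision); `isosbestic_normalize` rescales a
series there, removing per-well concentration error — the reason titration
fits work at 5% pipetting error.

**Spectrophotometric pKa.** A two-state acid-base system follows the
Henderson-Hasselbalch fraction *f* = 1/(1 + 10^(pKa − pH)). `fit_pka`
normalizes a pH series at the isosbestic point of deprotonation, picks the
reporter wavelength of maximum endpoint contrast, and fits
*A*(pH) = *A*_HA + (*A*_A − *A*_HA) · *f*(pH; pKa) by least squares, with a
linearized 95% CI.

**Equilibrium constant of phosphorolysis.** Two-wavelength monitoring
(analysis at 300 nm, Δε₃₀₀ = 3.6 mM⁻¹cm⁻¹; control at the 288 nm isosbestic
point of the glycosylation) converts progress curves to conversions
(`absorbance_to_conversion`), detects plateaus (`detect_equilibrium`), and
fits the apparent constant K of X + Rib1P ⇌ N7X + Pi — stored in the
phosphorolysis convention — by global least squares over runs at different
substrate ratios (`fit_K_global`), using the mass-balance equilibrium
K·(N₀+x)(P₀+x) = (X₀−x)(R₀−x).

**Michaelis-Menten kinetics with AICc.** `initial_rate` turns early linear
absorbance slopes into observed rate constants k_obs = v₀/[E];
`fit_michaelis_menten` fits both k_obs = k_cat·S/(K_M + S) and a
proportional law k_obs = a·S and prefers the model with the lower
small-sample corrected Akaike criterion. A fitted K_M far beyond the assayed
range is reported one-sided, the signature of a substrate whose K_M exceeds
its solubility limit.

**Predicted UV spectra from excited-state tables.** `assemble_spectrum`
Boltzmann-weights candidate structures by relative electronic energy
(w_i ∝ exp(−E_i/RT)), broadens their excitation sticks with Gaussians in
energy space, and normalizes the most redshifted peak to 1; `redshift_rank`
screens candidates against an observed spectrum.

## Worked example

```r
library(nucleospec)

# synthetic extinction pair shaped like the N7-riboside's protonation states
pre  <- extinction_preset("n7x_titration")
pair <- gen_extinction_pair(pre$peaks_HA, pre$peaks_A, species = pre$species)
pair$isosbestic
#> <isosbestic_result> 279.0 nm (spread 6.9e-13)

# simulate a plate-reader titration (pH 2-12, 5% concentration jitter,
# 0.002 AU noise) at pKa 8.5 and fit it back
series <- gen_titration(pair$HA, pair$A, pKa = 8.5, seed = 1)
fit_pka(series, lambda_iso = 279)
#> <deprotonation_model> pKa = 8.485 (95% CI 8.472-8.498)
#>   lambda_iso = 279 nm, reporter = 295 nm, residual rms = 0.0023 AU

# equilibrium constant from noisy endpoints of a 2 x 5 substrate design
runs <- gen_equilibrium_endpoints(K = 0.5, seed = 1)
fit_K_global(runs)
#> <equilibrium_fit> K(phosphorolysis) = 0.4929 (95% CI 0.472-0.515), 10 runs, rms 0.00573
#>   glycosylation-direction constant 1/K = 2.029 (reporting only)

# Michaelis-Menten vs proportional rate law at 2% rate noise
fit_michaelis_menten(gen_rate_data("mm", kcat = 0.08, KM = 250, seed = 1))
#> <michaelis_menten_fit> preferred model: MM (AICC MM -456.19 vs linear -303.26)
#>   kcat = 0.07963 s^-1, KM = 246.9 uM, 95% CI KM 232-262 uM
```

The fitted pKa (8.485 vs the generating 8.5), equilibrium constant (0.493 vs
0.5), and kinetic parameters (k_cat 0.0796 s⁻¹ vs 0.08; K_M 247 µM vs 250)
show single-replicate recovery under the reference noise model; the AICc
margin of ~150 units is why the hyperbolic model is preferred decisively.

A shell interface wrapping the same functions lives at
`inst/cli/nucleospec.R`:

```sh
Rscript inst/cli/nucleospec.R simulate --scenario keq --seed 7 -o fixtures/
Rscript inst/cli/nucleospec.R keq fixtures/ -o results/
```

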