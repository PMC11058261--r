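---
title: "UV-spectrophotometric inference for nucleoside phosphorylase chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UV-spectrophotometric inference for nucleoside phosphorylase chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleospec)
```

## Scope

`nucleospec` analyzes plate-reader UV data for nucleoside phosphorylase (NP)
chemistry: extinction calibration, isosbestic normalization,
spectrophotometric pKa determination, continuous monitoring of the
reversible glycosylation X + Rib1P ⇌ N7X + Pi with equilibrium-constant
estimation, Michaelis-Menten/AICc kinetics, and assembly of predicted UV
spectra from tabulated excited-state calculations. Electronic-structure
calculations themselves are out of scope; the package consumes their
tabulated output (relative electronic energies and excitation tables).

This vignette documents the models, their assumptions, the tunable
parameters, the synthetic-data generator, and the numerical choices — in
particular the places where the design was genuinely open and the package
had to commit to one behavior.

## Units and the Beer-Lambert convention

All concentrations are micromolar, extinction coefficients are mM⁻¹ cm⁻¹,
and path lengths are cm, so

$$A(\lambda) = \varepsilon(\lambda)\,\frac{c}{1000}\,l .$$

The 1000-fold µM→mM conversion lives in exactly one pair of helpers
(`absorbance_from`, `conc_from_absorbance`); every module calls them rather
than repeating the factor. Default path lengths are 1.0 cm for a cuvette and
0.56 cm for a 200 µL fill of a 96-well UV plate — the plate geometry is not
stated by typical plate protocols, and 0.56 cm is the standard liquid height
of that fill volume in a flat-bottom well; it is an explicit parameter
everywhere and can be overridden or calibrated away against a standard.

## Isosbestic points: detection, normalization, and their limits

Two interconverting species absorb identically at an isosbestic point, so
the absorbance there depends only on total concentration. That single fact
powers three separate steps:

1. **Normalization.** Scaling every spectrum of a series to a common
   absorbance at λ_iso removes per-well concentration (pipetting) error
   exactly.
2. **Calibration transfer.** A compound available only in small purified
   amounts inherits the absolute extinction scale of a well-characterized
   partner through the isosbestic point of their interconversion.
3. **Drift control.** During reaction monitoring, the control wavelength is
   placed at the isosbestic point of the transformation; any excursion there
   flags evaporation, precipitation, or a side reaction rather than the
   reaction of interest.

**Detection.** `find_isosbestic` looks for significant sign changes of the
signed difference between the two most dissimilar curves of the family. A
sign change is detectable even when the crossing falls between grid points
of a steep difference curve — a case where the sampled spread never dips
near zero and a pure below-threshold minimum search fails. Each candidate is
refined by the root of a local quadratic through the three surrounding
points (the vertex of the V-shaped spread is biased when the two flanks have
different slopes; the root of the signed difference is not), and accepted
only if the across-series spread at the refined wavelength is below the
threshold, by default 2% of the series' median signal. The flank test — the
difference must exceed the threshold within five grid points on both sides —
rejects spurious sign changes in near-zero spectral tails. Multiple
crossings are all reported (two-crossing deprotonation pairs exist; the
N9-riboside family is the canonical example).

**A genuine identifiability limit.** With unknown per-well concentrations,
a two-state titration does **not** identify its isosbestic point from the
data alone: a rescaling of the endpoint spectra can be absorbed jointly by
the per-well concentrations and the fitted midpoint, so the apparent pKa and
the endpoint concentration ratio are confounded. This is precisely why the
experimental protocol establishes λ_iso on reference material first and then
*uses the known point* to correct concentration errors. The package mirrors
that reality: `fit_pka` accepts a known `lambda_iso` (the recommended path,
and what `pka_recovery` does), attempts threshold detection when none is
given, and falls back to an unnormalized fit with a warning when detection
fails — which inflates the pKa error measurably (the test suite demonstrates
a > 1.5× RMSE inflation at 5% jitter).

## The two-state pKa model

The deprotonated fraction follows Henderson-Hasselbalch,
$f = 1/(1 + 10^{\,\mathrm{p}K_a - \mathrm{pH}})$, and the reporter-wavelength
absorbance is the two-state mixture

$$A(\mathrm{pH}) = A_\mathrm{HA} + (A_\mathrm{A} - A_\mathrm{HA})\,
f(\mathrm{pH};\,\mathrm{p}K_a).$$

One pKa per series: the analysis targets the monoanion equilibrium of
xanthine-family compounds; multiprotic fitting is out of scope. pH values
are taken as exact (a universal buffer adjusted to target pH), and the
reporter wavelength is chosen by maximum endpoint contrast
|A(λ, pH_max) − A(λ, pH_min)|, with an option to average the most
contrasting wavelengths (off by default).

Numerically the fit is a variable projection: for any trial pKa the two
endpoint absorbances solve linearly, so the problem reduces to a 1-D profile
over pKa (coarse grid, then golden-section polish to 10⁻¹⁰). This cannot
diverge and needs no starting values. The 95% CI comes from the linearized
parameter covariance — appropriate for the small per-series sample sizes —
rather than a bootstrap. A fitted midpoint not bracketed by at least 0.5 pH
units on both sides is flagged `extrapolated`.

## Equilibrium constant of phosphorolysis

By convention K is stored for the phosphorolytic direction, so the
glycosylation experiments that approach equilibrium from the nucleobase side
probe 1/K; the package exposes the glycosylation constant only at the
reporting layer, never in stored state, to keep the convention single-ended.
All concentrations are totals over protonation states and K is apparent at
the stated pH (the reference experiments run at pH 10, where nucleoside and
base are monoanions); no activity or ionic-strength corrections are applied.

Conversion traces come from the extinction difference at the analysis
wavelength, χ(t) = (A(t) − A(t₀)) / (Δε · X₀/1000 · l), with defaults
λ_analysis = 300 nm, Δε₃₀₀ = 3.6 mM⁻¹ cm⁻¹ and the control wavelength at
the 288 nm isosbestic point of the glycosylation (established at pH 10; its
validity at other pH values is not asserted). χ is soft-clipped to
[−0.02, 1.02] with a calibration warning outside that band.

**Plateau criterion.** A run is equilibrated when the mean conversion over
the final 30 min window differs from the mean over the preceding 30 min by
less than 0.5% of the plateau level, with an absolute floor of 0.005
conversion units. Windowed means rather than endpoint differences keep
measurement noise from vetoing a true plateau; the absolute floor keeps the
criterion usable for low-conversion runs, whose relative threshold would
otherwise sit below the noise. A non-equilibrated run yields an absent
plateau, not an error.

**Equilibrium algebra.** With extent x of glycosylation, mass balance gives
$K (N_0 + x)(P_0 + x) = (X_0 - x)(R_0 - x)$ — a quadratic whose physically
admissible root lies in [−min(N₀, P₀), min(X₀, R₀)]. The solver uses the
numerically stable quadratic form (no catastrophic cancellation), selects
the admissible root, and — in the guarded case of two admissible roots —
takes the smaller extent with a warning. `fit_K_global` minimizes the sum of
squared deviations between observed and predicted equilibrium conversions by
bounded 1-D optimization on log K (bounds 10⁻⁶–10⁶: K is positive and spans
decades across nucleosides, with typical purine values of 0.01–0.1), and
profiles log K for a likelihood-ratio 95% CI. Drift-flagged runs are
excluded; the fit refuses to run when every run is flagged.

## Michaelis-Menten kinetics and model discrimination

Initial rates are ordinary least-squares slopes over the first 20% of a
trace or the first 300 s, whichever is shorter — traces of the reference
design are 20 min, so the window stays well inside the linear regime. A
quadratic refit that improves the residual sum of squares by more than 20%
flags the window as curved. Rates convert to observed rate constants per
enzyme subunit, k_obs = v₀/[E], with a default subunit mass of 26 kDa for
the mass-to-molar conversion (consistent with the reference enzyme's printed
mass↔molarity equivalences) — overridable.

Replicates are fitted pooled, not averaged, so the information criterion
sees the true number of observations. Both candidate models are fitted by
least squares: the proportional law k_obs = a·S (k = 2 parameters counting
the residual variance) and the hyperbola k_obs = k_cat·S/(K_M + S) (k = 3).
The criterion is the small-sample corrected
AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1); with ~30 pooled observations the
correction is material, and plain AIC remains available as a switch. The
hyperbola is fitted with `minpack.lm::nlsLM`; when K_M runs far beyond the
assayed range the gradient columns become collinear and gradient-based
fitters lose rank, so the package falls back to a variable-projection
profile over log K_M that handles the degenerate limit without a gradient.
A fitted K_M more than twice the largest assayed concentration is reported
with a one-sided CI ("exceeds range") — the appropriate statement for a
substrate whose K_M lies beyond its solubility.

## Predicted UV spectra from excitation tables

Candidate structures are weighted by their relative electronic energies with
shift-stabilized Boltzmann factors, $w_i \propto e^{-E_i/RT}$, at a default
298.15 K (the weighting temperature is a package choice; it is a visible
parameter). Weighting uses electronic energies, not free energies, matching
how such ensembles are typically tabulated. Excitation sticks are broadened
with Gaussians in the energy domain — the physically standard choice — and
evaluated on the wavelength grid through E(eV) = 1239.842/λ(nm); a default
width of σ = 0.30 eV is a package choice and is deliberately a
mandatory-visible configuration value so published widths can be
substituted. The most redshifted peak (largest-wavelength interior local
maximum above 5% of the global maximum) is normalized to 1; if no interior
maximum exists the global maximum is used with a warning. Candidate ranking
orders predicted spectra by the distance between their most redshifted peak
and the observed one, breaking near-ties (0.5 nm) by peak-shape correlation.

## The synthetic-data generator

The generator produces every input format the pipeline reads, with the
statistical structure the analysis assumes:

* **Extinction curves** are sums of Gaussians. The built-in presets are
  frozen constants tuned analytically — once — so that each protonation pair
  crosses at its literature isosbestic wavelength (274 nm for xanthine,
  279 nm for the N7-riboside, 259/268 nm for the two-crossing N9 pair) and
  the pH 10 glycosylation pair crosses at 288 nm with Δε₃₀₀ = 3.6 mM⁻¹ cm⁻¹.
  They are synthetic stand-ins shaped like the real curves, not measured
  data.
* **Noise model**: additive Gaussian absorbance noise (σ_A = 0.002 AU) and
  Gaussian relative concentration jitter (5%); these defaults are package
  choices representing a well-maintained plate reader and routine pipetting,
  calibrated so that recovery is attainable yet non-trivial. The jitter
  distribution (Gaussian in relative error) is a package choice.
* **Titrations**: pH 2–12 in 0.5 steps at 100 µM nominal, 0.56 cm path.
* **Reaction courses** integrate the single-extent mass-action law
  dx/dt = k_f[(X₀−x)(R₀−x) − K(N₀+x)(P₀+x)] with `deSolve::ode`
  (rtol = atol = 10⁻¹⁰), whose stationary point is exactly the equilibrium
  of the analysis module — an internal consistency the tests exploit. The
  default k_f = 2·10⁻⁵ µM⁻¹s⁻¹ brings the slowest run of the reference
  design beyond 99.5% of equilibrium within the simulated 4 h. Mass balance
  is structural (one extent coordinate), so conservation holds to machine
  precision at every time point. The adaptive multistep integrator replaces
  a fixed-step scheme by design: it is the established tool and strictly
  more robust.
* **Kinetics**: 20 min linear traces at the target initial slopes, four
  replicates per substrate level; plus a direct rate-level generator with 2%
  multiplicative noise for model-discrimination studies.
* **Determinism**: every generator is a pure function of (parameters, seed);
  the caller's RNG state is saved and restored. `write_fixtures` emits the
  delimited-text files plus a manifest of the true generating parameters,
  byte-identically under a fixed seed.

What the generator does **not** emulate: baseline drift other than an
injected linear ramp, scatter and lamp noise structure, buffer absorbance,
pH-dependent side products (such as N9-riboside formation at neutral pH), or
enzymatic product hydrolysis. Passing recovery tests therefore demonstrate
the correctness and noise robustness of the inference chain under its stated
assumptions — not immunity to systematic effects absent from the simulation.

## Reference study sizes

The validation studies run 100 simulated titrations per generating pKa
(5.3, 7.3, 8.5), 100 replicates of the 2 × 5 equilibrium design at K = 0.5,
200 random instances for the equilibrium-solver oracle, and 50 + 50 seeded
series for rate-law discrimination — sizes chosen so each study estimates
its error statistics stably while the whole suite remains quick to run on a
laptop.

## Known limitations

* Two-state protonation and two-species unmixing only; no multiprotic or
  multi-component (> 2 species) spectral analysis.
* K is apparent at the stated pH; no activity corrections.
* The 288 nm control point is established at pH 10 and not asserted
  elsewhere; drift flagging is the only guard against side reactions.
* No substrate inhibition, cooperativity, or bi-substrate kinetic
  mechanisms; the co-substrate is assumed saturating.
* Isosbestic detection from jittered titrations is fundamentally limited
  (see above); supply a known λ_iso for quantitative work.
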