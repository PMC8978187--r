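---
title: "Hybrid planar/SPECT internal dosimetry for Lu-177 peptide therapy: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid planar/SPECT internal dosimetry for Lu-177 peptide therapy: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ludosim)
```

## The problem

After a therapeutic administration of a Lu-177-labeled tumor-targeting
peptide (here modeled on Lu-177-FAP-2286 therapy of advanced
adenocarcinomas), the absorbed dose delivered to the whole body, the
kidneys, the red marrow and individual tumor lesions per unit administered
activity (Gy/GBq) is estimated from serial imaging. The clinical workflow
this package implements is the hybrid planar/SPECT MIRD-schema chain:

1. **Conjugate-view quantification.** At least five serial anterior/posterior
   whole-body scintigraphy studies are acquired, starting immediately after
   injection and before bladder voiding. Because nothing has left the body at
   the first scan, its total-body counts are *defined* to be 100% of the
   administered activity; all later region-of-interest counts are expressed
   as fractions of injected activity (FIA). Counts are combined as the
   geometric mean of the anterior/posterior pair, divided by the square root
   of the regional transmission factor.
2. **Hybrid SPECT rescaling.** One quantitative SPECT/CT per cycle provides
   an absolute activity for each source region; the shape-only planar curve
   is multiplied by a single factor so that it passes through the SPECT
   point. The whole-body curve is never rescaled (the SPECT field of view is
   regional).
3. **Curve fitting.** Each region's time-activity curve (TAC) is fitted with
   a mono- or biexponential retention function; the model is chosen by
   corrected AIC. The fit yields the effective half-life
   ($1/T_\mathrm{eff} = 1/T_\mathrm{bio} + 1/T_\mathrm{phys}$) and the
   time-integrated activity coefficient (TIAC)
   $\tilde a = \sum_j a_j/\lambda_j$ in hours, the analytic integral of the
   fitted curve from 0 to infinity.
4. **Absorbed dose.** The self-dose is
   $D = \tilde A \, \Delta / m$ with
   $\tilde A = 10^9\,\mathrm{decays\,s^{-1}GBq^{-1}} \times \tilde a \times 3600$
   and $\Delta = (E_e + \phi E_\gamma)$ MeV per decay converted to joules.
   Organs use ICRP-89 reference masses adapted to the individual; tumor
   lesions use the unit-density sphere model; the red marrow uses the
   blood-based method when blood samples exist and the whole-body
   distribution method otherwise.

The clinical raw data behind the published cohort are not public, so the
package ships a seeded virtual-patient generator that emulates the protocol
end to end; the real-data entry points accept the same tidy CSV tables.

## Physical constants

Lu-177: physical half-life 159.53 h (6.647 d), mean electron energy (beta +
conversion + Auger) 0.1479 MeV/decay, mean photon energy (gamma + x-ray)
0.0335 MeV/decay — ICRP-107 values stored in
`inst/extdata/dosimetry_constants.yaml` and overridable via
`radionuclide()`. Electron energy is treated as fully absorbed locally: the
Lu-177 beta range (~2 mm maximum) is far below the dimensions of any region
considered here, which is also why the electron absorbed fraction is fixed at
1 for spheres of 1 g and above. At least ~78% of the emitted energy is
electron energy, so omitting photon cross-organ dose (we model photon
*self*-dose only, through an absorbed fraction) is an accuracy caveat rather
than a structural error; cross-fire would add a few percent to small-organ
doses.

The photon self-absorbed fraction uses a smooth saturating form
$\phi(m) = c_1 m^{c_3}/(c_2 + m^{c_3})$ (mass in grams), monotone, vanishing
with mass and bounded below 1. Its three constants were fit once by least
squares to representative published absorbed fractions for ~208-keV photons
in unit-density spheres and frozen in the constants file; the whole-body
anchor is $\phi(73\,\mathrm{kg}) = 0.35$. The same curve supplies the organ
photon self-dose at the organ mass.

## What the simulator emulates — and what it does not

`virtual_patient()` carries per-region retention kinetics: one or two
exponential terms with *biological* half-lives, evaluated together with
physical decay by `region_activity()`. Uptake (rising) phases are out of
scope: the clinical analysis fits decaying retention only, and the first
scan anchors the curve at its maximum. Excretion is implicit in whole-body
biological clearance; the first-scan = 100% normalization makes explicit
urine modeling unnecessary. The remainder of the body is whatever whole-body
activity is not assigned to a source region.

`simulate_planar_series()` places each region at mid-depth of a single
global patient thickness (default 20 cm) under one effective attenuation
coefficient (default 0.11 cm^-1 for the 208-keV photopeak) — no CT maps, no
scatter windows, no camera dead time, no organ overlap, no pixel-level image
formation. Counts are Poisson-drawn (camera sensitivity default 600 counts
per MBq·min, 15-min effective acquisition) under the protocol seed. A
uniform background term exists but defaults to off, mirroring a
counts-ratio-only reading of the clinical normalization. Consequently,
passing tests demonstrate that the *computational chain* is correct and
well-calibrated under the stated noise model; they do not demonstrate
robustness to organ overlap, scatter, background, patient motion or
reconstruction artifacts in real data.

The default schedule is {0.5, 3, 24, 48, 72, 168} h — the mandatory clinical
time points (immediately; 2-3 h; 1, 2, 3 d) plus the optional delayed scan.
The acquisition validator requires at least five scans with the first within
1 h of injection.

### The normalization offset

The 100% convention assigns FIA = 1 to the first scan even though ~1% of the
activity has already decayed/cleared by 0.5 h. This biases every fitted
amplitude upward by the same factor and leaves all rates, half-lives and
dose *ratios* untouched; SPECT rescaling removes it entirely for source
regions. Exactness ("machine precision") round-trip tests therefore use an
idealized first scan at t = 0; the default schedule keeps the clinical 0.5 h.

## Fitting choices

Fits are unweighted least squares in linear space (the clinical analysis
names only a generic curve-fitting tool with no weighting statement),
Levenberg-Marquardt, with starting values from log-linear regression (exact
on noiseless monoexponential data) and, for the biexponential, a tail/peel
decomposition. Decay rates are bounded below by the physical decay constant:
measured activity cannot decline slower than physical decay, and a fit
landing on that bound (a near-constant curve) is flagged `at_bound`.
Amplitudes are free parameters, not pinned to the first-scan value.

Model selection uses corrected AIC computed from the residual sum of squares
with k = the number of fitted parameters (2 or 4):
$\mathrm{AICc} = n\log(\mathrm{rss}/n) + 2k + 2k(k+1)/(n-k-1)$. Including
the usual extra variance parameter in k would make the denominator vanish at
the default six-point schedule and silently forbid the biexponential model,
so the parameter-count form is used. Ties and the doubly-degenerate case
(both fits numerically exact) go to the monoexponential model. If the two
biexponential rates collapse (relative difference below 0.1%), the fit falls
back to mono with a warning. For biexponential fits the single reported
effective half-life is the TIAC-equivalent value
$\ln 2 \cdot \tilde a / \sum_j a_j$, which preserves the TIAC under the
one-number-per-region reporting convention.

The TIAC is always the analytic integral to infinity (no cut at the last
scan), matching the exponential-model workflow of OLINDA-style dose engines;
a brute-force trapezoid + analytic-tail oracle agrees within 0.1% in the
test suite.

Blood sampling uses six time points (0.5, 2, 4, 24, 48, 96 h). Five would
nominally satisfy the biexponential minimum, but at n = 5 the AICc of the
four-parameter model is undefined (n - k - 1 = 0), so the biexponential
blood model could never be selected and the time-integrated concentration
would be systematically underestimated.

## Dose models

* **Organs** (`self_absorbed_dose()` + `mass_adapted_dose()`): electron-only
  energy fully absorbed, photon self-dose via $\phi$(organ mass); the
  reference-phantom dose scales as $m_\mathrm{ref}/m_\mathrm{patient}$ when
  CT-derived masses are supplied (electron self-dose scaling).
* **Tumors** (`sphere_dose()`): unit-density sphere, electron absorbed
  fraction 1, photon fraction $\phi(m)$.
* **Red marrow**: the whole-body method assumes the marrow activity
  concentration equals the whole-body average, so the marrow dose equals the
  whole-body electron-only self-dose. The blood method fits the blood
  concentration curve (FIA per liter), integrates it to $\hat c$ (h/L), and
  sets the marrow TIAC to $\hat c \times \mathrm{RMBLR} \times m_{RM}$ with
  the red-marrow-to-blood ratio defaulting to 1.0, the conventional value
  for small peptides (configurable). Both methods are electron-only, the
  standard concentration-based approximation.

The published whole-body value is labeled an "effective dose" but printed in
Gy/GBq; this package computes and reports the whole-body *absorbed* dose
(a Sv-weighted effective dose is a non-goal), and the engine is an
OLINDA-*equivalent* formulation, not a bit-exact clone of proprietary sphere
or marrow tables.

Reporting precision follows the clinical convention: doses to 2 decimals,
half-lives to the nearest hour, cohort statistics as mean ± SD (range) with
the n-1 SD and the treatment *cycle* as the cohort unit.

## The reference virtual cohort

`simulate_reference_cohort()` reproduces the published study conditions: 10
dosimetry cycles, 13 bone metastases and 1 hepatic metastasis, blood
sampling in 4 of 10 cycles, administered activity ~ Normal(5.8, 2.0) GBq
truncated to the reported 2.4-9.9 GBq. Effective half-lives are drawn
uniformly inside the published per-region ranges (whole body 25-48 h,
kidneys 30-161 h capped just below the physical half-life, bone lesions
21-120 h) and converted to biological half-lives. Because the cohort is
known only through its summary statistics, region uptake amplitudes are
back-calculated from dose targets drawn inside the published dose ranges
(e.g. kidneys 0.5-1.8 of the 0.4-2.0 Gy/GBq range) given the drawn
half-life and a mildly varied organ mass — the natural way to emulate a
cohort defined by its reported ranges. Blood kinetics are a fast bolus
clearance (90%, T_bio 1 h) plus a small slow component (10%, T_bio 8-25 h),
typical of rapidly cleared peptides. The liver-lesion window (28-36 h,
0.32-0.48 Gy/GBq) brackets the single published estimation.

Problem sizes used throughout the suite — 200 seeded replicates for the
noise-recovery and 3-standard-error calibration properties, 1000 random
models for the closed-form-vs-numerical TIAC oracle, a 10-cycle cohort for
the range checks — are the package's chosen defaults and complete in
seconds.

## Degenerate inputs and numerical corners

* Half-life algebra accepts `Inf` as the no-biological-clearance sentinel.
* Zero first-scan whole-body counts, non-positive transmission, SPECT times
  outside the sampled span, zero SPECT activity, and missing regions all
  raise errors rather than propagate silently.
* Log-linear interpolation (used to read the planar curve at the SPECT time)
  requires strictly positive values and refuses to extrapolate.
* A TAC with fewer than 3 (mono) or 5 (bi) points is rejected; a constant
  TAC fits at the physical-decay bound and is flagged.
* Counts are coerced to double before the conjugate-view product to avoid
  32-bit overflow when reading integer CSVs.
* `dose_result()` enforces dose = 0 exactly when TIAC = 0.

## Known limitations

No photon cross-organ dose, no scatter/background/overlap modeling, no
voxel-level or Monte Carlo transport, no trabecular-microstructure marrow
model, no uptake phases, no Sv-weighted effective dose, no triexponential or
population (Bayesian) kinetics. Regions that overlap on planar images (lymph
node, peritoneal lesions) are simply not quantified, as in the clinical
protocol. The interface is the package's functions plus the numbered
analysis scripts; no separate command-line wrapper is provided.
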