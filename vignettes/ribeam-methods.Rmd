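---
title: "Models, generators and design choices in ribeam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, generators and design choices in ribeam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribeam)
```

`ribeam` compares positron-emitting ion beams (¹⁰C, ¹¹C, ¹⁵O) with their
stable therapy analogs (¹²C, ¹⁶O) on two axes: radiobiological effectiveness
along the beam path, and the quality of the positron-annihilation maps
available for range verification during and after a treatment. Full particle
transport is out of scope; everywhere a Monte Carlo code would supply a
depth-dose curve, a microdosimetric spectrum or a decay event stream, a
documented parametric generator supplies one instead. This vignette records
the models, every tunable that matters, and the reasoning behind the choices
that were genuinely open.

## 1. The MKM chain

The microdosimetric kinetic model predicts the linear-quadratic α from the
saturation-corrected dose-mean lineal energy of the local radiation field,

$$y^{*} = y_0^2\,\frac{\int (1-e^{-(y/y_0)^2})\,f(y)\,dy}{\int y f(y)\,dy},
\qquad
\alpha = \alpha_0 + \frac{\beta_0}{\rho \pi r_d^2}\,y^{*},$$

and RBE₁₀ follows as the 200 kVp X-ray dose for 10% survival divided by the
positive root of $\beta D^2 + \alpha D - \ln 10 = 0$.

Parameters (all overridable through `mkm_params()`):

| parameter | default | units | origin |
|---|---|---|---|
| α₀ | 0.13 | Gy⁻¹ | HSG cell line |
| β₀ (= β) | 0.05 | Gy⁻² | HSG; β taken radiation-independent, standard MKM practice |
| r_d | 0.42 | μm | sub-cellular domain radius |
| ρ | 1 | g/cm³ | domain density |
| D₁₀ reference | 5 | Gy | 200 kVp X-rays, HSG |
| y₀ | 150 | keV/μm | canonical MKM saturation parameter; not fixed by the study design, so explicit and configurable |

Three conventions are locked by tests rather than by documentation alone:

* **log(0.1) is the natural log.** Only ln makes a beam whose own D₁₀ is
  exactly 5 Gy return RBE₁₀ = 1; the suite asserts this to 10⁻⁹.
* **The unit constant k = 0.1602** converts keV/(μm³·g/cm³) to Gy in the α
  relation, which is otherwise unit-implicit.
* **Quadrature.** y* is a trapezoid on the spectrum's own grid; a
  single-point spectrum is treated as a point mass so the delta-spectrum
  closed form $y^* = y_0^2(1-e^{-(y_d/y_0)^2})/y_d$ holds exactly. Tests
  check agreement with an independent log-space Simpson oracle to 10⁻⁶ on
  log-normal spectra, and the y₀ → ∞ limit against the plain dose-mean.

The mean path length through the 1 mm × 1 mm × 10 μm sensitive volume is
taken as the 10 μm slab thickness — appropriate for a forward-directed field
crossing a thin slab, and isolated in `sv_spec()` so a different chord-length
convention is one argument away.

## 2. The synthetic generators (the "stated world")

### Depth-dose curves

`depth_dose_profile()` evaluates a closed-form curve with an entrance plateau
$0.2 + 0.3\,(z/R)^3$, a Gaussian Bragg peak of amplitude 3.0 at the
Bragg–Kleeman range $R = c\,(A/Z^2)\,E^{1.75}$ (c calibrated so 290 MeV/u
¹²C → 160 mm of water — a conventional anchor, not a measured value), and an
optional exponential fragmentation tail (default 3% of the peak, 20 mm decay
length). With the tail off the curve is identically zero beyond R + 3σ.

Two shape choices deserve explanation:

* **Plateau-to-peak balance.** A flat SOBP superposes one sharp peak per
  component on the accumulated plateaus of all deeper components; the
  entrance dose is (plateau level) × (total weight) while the in-SOBP level
  is (peak area) × (weight density). The 0.2 / 3.0 balance keeps the
  entrance-to-SOBP ratio below one (≈ 0.4 for the default carbon plan), as
  for measured SOBPs. A first draft with a taller plateau produced an
  entrance dose three times the target — numerically fine, physically
  nonsense — and was reshaped on this argument.
* **Straggling defaults to σ = 1% of range** everywhere (profiles, the
  lineal-energy mixture, the event simulator). The validation beamlines'
  relative energy spreads (0.2% for stable primary-course beams, 5% for
  secondary-course radioactive beams) can be mapped through the power law as
  σ_R = 1.75 · (σ_E/E) · R via the `energy_spread` argument, but they are a
  property of one experimental facility, not of the planned treatment beams
  the study simulates.

### Lineal-energy spectra

`synthetic_lineal_spectrum()` draws event lineal energies from a log-normal
mixture with one component per beam energy: component probability ∝ weight ×
local dose, component mean $L_i(z) = a_y Z^2 \max(R_i - z,\, r_\min)^{-q}$
before the range (a stopping-power-like rise toward the peak) and a flat
2 keV/μm fragment floor beyond it, with common shape sdlog = 0.7. Defaults
a_y = 2.0, q = 0.45, r_min = 0.5 mm give a ¹²C beam ≈ 7 keV/μm at entrance
rising to ≈ 100 keV/μm at the peak — the magnitudes over which the MKM
saturation correction acts, producing entrance RBE₁₀ ≈ 1.3 rising to ≈ 2.2–2.5
at the distal SOBP for the default plan. `lineal_mixture_params()` exposes
the mixture so tests can compute analytic moments independently of the
sampler.

What a green test does and does not establish: the generator reproduces the
*structure* real transport produces — dose-mean lineal energy rising toward
the Bragg peak, spectra of a radioactive beam statistically identical to its
stable analog's at matched ranges, low-LET fragment tails — so ordering and
ratio assertions (radioactive/stable RBE ≈ 1; CNR orderings across species)
are meaningful. Absolute RBE₁₀ or CNR values are properties of the stated
parameters, not predictions; nothing here models TEPC response, fragment
spectra species by species, lateral scattering, or neutron transport.

### Decay events

`simulate_treatment()` assigns each primary a birth time uniform in a
beam-on interval of the spill schedule (default 20 spills, 1.9 s on, 1.4 s
off, 10⁹ primaries/s), a stopping depth at its component's straggled range,
and an exponential decay delay by species half-life (¹¹C 20.334 min, ¹⁰C
19.29 s, ¹⁵O 122.24 s). A configurable fraction of primaries (default 0.2 —
an open parameter, not a measured truth) instead yields a positron-emitting
fragment, with species mix 80/5/15% (¹¹C/¹⁰C/¹⁵O) for carbon beams and
44/7/49% for oxygen beams, stopped upstream with the linearly decreasing
density $f(u) \propto 1 - u/2$, $u = z/R$ (chosen because fragments are
produced along the whole path with a mild bias toward the entrance; no
functional form is prescribed by the study design). Annihilation positions
add a 1 mm isotropic positron-range blur; acollinearity is folded into the
3.5 mm system PSF applied to maps rather than modelled separately.
Desk-scale runs default to 10⁶ primaries with the 10⁹-rescaling weight
recorded on the event set.

## 3. SOBP construction

Weights are non-negative least squares of the per-energy *biological* dose
columns against a constant target over the planned range, solved by an
in-package Lawson–Hanson solver (no NNLS implementation exists among the
package's allowed dependencies; `quadprog` serves as an independent oracle in
tests, never as the implementation). Flatness worse than the plan tolerance
(default 2% — "flat" is not quantified in the study design) is an error
reporting the achieved value, not a silent acceptance.

The biological conversion used *for optimization* evaluates the expected
(deterministic) y* of the documented mixture by quadrature
(`rbe_profile_expected()`): sampling noise in the optimizer's columns would
only degrade the solution. The stochastic 11-volume evaluation
(`rbe_depth_profile()`, below) remains the instrument for the
radioactive-vs-stable comparison.

`run_study()` generates anchor profiles directly at 1 MeV/u spacing rather
than interpolating between sparse anchors: with 1%-σ analytic peaks, linear
interpolation across ≥ 2 MeV gaps creates bimodal pseudo-profiles and a
scalloped SOBP that misses the 2% tolerance. `interpolate_profiles()` is
still a first-class operation (endpoint identity and linearity are tested)
for users whose simulated anchors are expensive.

The radioactive spectrum is the stable one mapped affinely in energy so that
the analog's Bragg peaks land on the same proximal/distal depths (closed-form
inversion of the range law), weights untouched; the suite verifies the mapped
peak depths through the profile peak finder to within one grid step.

## 4. RBE statistics and the tissue correction

RBE₁₀ at a reporting depth is the mean over 11 consecutive sensitive volumes
spaced 100 μm along the beam, each scored from its own seeded spectrum
(default 2000 events); the paired SD defines the 95% band as mean ± 2 SD.
Where the phantom material is brain-modelled-as-muscle a 1.05
stopping-power/density correction applies. Whether the original procedure
scaled depth or dose is ambiguous; `ribeam` scales the water-equivalent
lookup depth by default (`correction = "depth"`), with `"dose"` scaling y*
instead — for monotone spectra the two differ only in the depth direction of
the shift, and the switch documents the ambiguity instead of hiding it.

## 5. Maps, CNR and the TAC decomposition

Maps are half-open 1.5 mm voxel binnings of events in half-open time
windows; the first inter-spill window is [1.9 s, 3.3 s), and the
post-irradiation window opens at the end of spill 20. Gaussian blurring uses
a reflective boundary and a kernel normalized to conserve total intensity to
10⁻⁶. CNR uses *population* SDs (the defining expression carries no n−1
convention) and is computed on blurred maps by default, matching the imaging
context. Edge regions are 10 mm slabs immediately inside/outside each SOBP
boundary, restricted to the central 50% of the transverse field for the
proximal/distal pairs — geometry the study design leaves unstated, so it is
explicit and configurable.

Time-activity curves are fitted with half-lives *fixed* to the physical
constants, making the model linear in the initial activities; NNLS enforces
their non-negativity. Frames are treated as frame-averaged activity, so the
design matrix uses the analytic frame averages
$(e^{-\lambda t_1}-e^{-\lambda t_2})/(\lambda\,\Delta t)$. The covariance is
a counting-statistics sandwich (per-frame variance ∝ fitted activity /
frame length, dispersion from residuals): a homoscedastic covariance
understates the uncertainty of the short-lived components, whose information
sits in one or two early frames. Relative yields are A₀-based
(A₀ₛ/ΣA₀ × 100) and sum to 100 by construction.

The 5%-rule ROI runs from the first depth 5% above the entrance-plateau mean
(plateau = first 10% of the grid, a definition the study design leaves
numeric-free) to the last depth above 5% of the peak.

## 6. Incidental dosimetry

Bulk order-of-magnitude estimates only: activity concentration
$A_0/V = N \ln 2 / T_{1/2} / V$ and decay dose
$N(\bar E_\beta + f_\gamma \cdot 1.022\,\mathrm{MeV}) \cdot 1.602\times10^{-13} / (V\rho)$
in mSv. The mean ¹¹C positron energy (0.386 MeV) and the annihilation-photon
absorbed fraction (0.3 for a head-sized volume) are package assumptions,
echoed into every report. For 2.3 × 10¹¹ ¹¹C ions in 1000 cc the formula
gives 0.13 MBq/cc; claims of ~10× higher concentrations for this
configuration do not follow from λN/V, and the package reports the formula's
value rather than tuning to any external figure. `convergence_study()`
implements the variance-based sample-size procedure (M = 50 replicates,
doubling N until SD/mean < 1%).

## 7. Determinism and numerical choices

Every stochastic stage takes an explicit seed (no wall-clock seeding) and
restores the caller's RNG state; `run_study()` derives per-stage child seeds
so stages can be regression-tested independently, and regenerates every
output byte-identically from the same config. Spectra are binned into 160
fixed logarithmic bins over 0.05–2000 keV/μm with out-of-range draws clamped
into edge bins (counts conserved). Tables are TSV with 10 significant
digits; maps are MetaImage (text header + float64 raw) plus a TSV dump of
nonzero voxels — the MetaImage writer is hand-rolled because no 3D medical
image writer is available among the allowed dependencies.

## 8. Known limitations

* No nuclear cross-sections, fluence attenuation, lateral spreading or
  neutron physics; fragment yields are inputs, not predictions.
* No scanner geometry, coincidence detection, randoms/scatter or iterative
  reconstruction — the "image" is the ground-truth annihilation map blurred
  by the system PSF.
* Absolute dose is relative (per-primary, arbitrary units); the planned 10⁹
  primaries enter only through the event-weight rescaling and the dosimetry
  report.
* CNR magnitudes at desk scale (10⁶ primaries) are count-statistics limited;
  only orderings and structural comparisons across species are meaningful at
  that scale.
* HSG is the only built-in cell line; other parameter sets enter through
  `mkm_params()`.
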