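---
title: "Entrance and exit dose verification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entrance and exit dose verification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transitdose)
```

## The problem

In-vivo dosimetry compares a dose measured on the patient — conventionally at
1.5 cm inside the beam entry surface (the *entrance* dose) and 1.5 cm inside
the beam exit surface (the *exit* dose), depths at which a 6 MV beam has
reasonable electronic equilibrium — against an expected value, usually taken
from the treatment planning system (TPS). The comparison is only as good as
the expected value. Two physical effects make the expected value non-trivial:

* at the **exit** level there is almost no material behind the measurement
  point, so backscattered photons are missing and the true dose is *lower*
  than a full-scatter calculation predicts (by up to ~4% at large depth and
  field size);
* some dose engines (historically pencil-beam convolution and the analytical
  anisotropic algorithm) assume full backscatter everywhere and therefore
  *overestimate* exit doses, which produces false positives when in-vivo
  readings are compared against them.

This package provides the reference-dose machinery for that comparison:
full-backscatter dose reconstruction from beam data, backscatter correction
factors (BCF), 2D absolute dose-plane synthesis from water-tank scans, and
gamma analysis — plus a synthetic beam generator and TPS failure-mode
emulators so the entire pipeline is testable without any measured dataset.

## Models

### Full-backscatter central-axis dose

For a machine calibrated to deliver $D_{max}$ cGy/MU at the depth of maximum
dose $d_{max}$ for the reference $10\times10$ cm field,

$$D_{fs,d} = D_{max}\cdot MU\cdot \frac{PDD_{fs,d}}{100}\cdot OF_{fs}$$

with $PDD_{fs,d}$ the percentage depth dose and $OF_{fs}$ the field-size
output factor, both taken from scanned water-tank commissioning data
(`dose_full_backscatter()`). Field size always refers to the square side
defined at 100 cm from the source. PDD and OF are interpolated linearly
(depth within each curve, then across field size); queries outside the
tabulated hull are refused rather than extrapolated, because commissioning
tables carry no information beyond their range.

### Backscatter correction factor

$$BCF = \frac{\text{dose without backscatter}}{\text{dose with full backscatter}}, \qquad BCF \le 1$$

The expected in-vivo dose is $D_{fs,d}\cdot BCF$ (`expected_dose()`). BCF
tables have two blocks mirroring how they are measured: an **entrance**
block at fixed depth 1.5 cm keyed by field size × backscatter thickness, and
an **exit** block at fixed backscatter thickness 1.5 cm keyed by field size
× depth. At depth 1.5 cm the exit geometry *is* the entrance geometry, so
the exit block starts at 6.5 cm and lookups below that fall through to the
entrance 1.5 cm column. The entrance block is strictly a
partial-backscatter ratio rather than a no-backscatter BCF; summaries label
it as such but no special handling is applied.

The package ships the measured tables for two clinical 6 MV beams, a Varian
Clinac 21EX ($TPR_{20,10} = 0.669$) and an Elekta Synergy
($TPR_{20,10} = 0.687$), as `bcf_reference_table()`. Their headline
statistics (computed, not quoted): minimum entrance BCF 0.972 (Clinac) and
0.978 (Synergy), both at 1.5 cm backscatter and the 20 cm field; entrance
dose reduction at or beyond 11.5 cm of backscatter at most 0.4%;
cross-machine entrance agreement 0.1% mean absolute per-cell difference.

```{r}
cl <- suppressWarnings(bcf_reference_table("clinac21ex"))
summarize_bcf(cl)
```

Mixed geometries (entrance at a depth other than 1.5 cm, exit at a
backscatter other than 1.5 cm) are rejected rather than guessed — the table
carries no information about them. BCF interpolation between tabulated field
sizes and thicknesses is linear; the original measurement protocol does not
state an interpolation rule, so linear-with-refusal-to-extrapolate is this
package's choice. Isocentric (variable-SSD) queries reuse the fixed-SSD
table, justified by the measured SSD-invariance of BCF (maximum difference
below 1%); `allow_variable_ssd = FALSE` turns that reuse off.

### Plausibility bounds for BCF

Measured factors near unity can exceed 1 through noise (the Clinac entrance
block contains 1.001). Values in $(1, 1.01]$ are accepted with a warning and
never clamped — clamping would silently alter measured data. Values outside
$(0.9, 1.01]$ are rejected as implausible for these geometries when reading
or computing single ratios. Tables *derived* from single noisy measurement
sessions are the one exception: with the 0.5% session reproducibility used
throughout, a 3σ excursion above a near-unity entrance factor reaches
≈1.015, so `build_bcf_table()` defaults to an upper bound of 1.02 (still
warning above 1). The strict 1.01 bound continues to apply to serialized and
bundled tables.

### 2D plane synthesis and gamma analysis

Orthogonal 1D scans are normalized to the central axis and cross-multiplied:
$plane(x,y) = \hat p_x(x)\,\hat p_y(y)\,D_{cax}$ (`synthesize_plane()`).
Planes built this way are exactly separable; true corner dose is not. That
limitation is accepted because the construction is validated against 2D
array measurements at the profile level, not corrected — diagonal profiles
extracted from synthesized planes (`extract_profile()`) are the practical
check, with diagonal positions parameterized as signed radial distances
along the diagonal (water-tank convention).

The absolute gamma index (`gamma_index()`) uses a dose criterion expressed
as a percentage of the reference plane's central-axis dose by default
(`global_cax`): absolute planes are anchored to the measured CAX point dose,
so that dose is the natural global normalization; `global_max` is available
as an alternative. Numerical search parameters: search radius 3 × DTA and
evaluated-plane subsampling at DTA/10 (0.3 mm for 3 mm DTA), standard
bounds for a convergent minimum; the subsample step is capped at DTA/3. The
C++ kernel enumerates subsample offsets sorted by distance and terminates
early once the spatial term alone exceeds the current minimum; it is tested
point-by-point (to 1e-6, observed ~1e-14) against `gamma_exhaustive()`, a
deliberately independent pure-R full enumeration. No low-dose threshold is
applied by default: all reference points inside the ROI are scored.

Pass rates are reported over two square regions of interest: the full
projected field (edge $fs\cdot(ssd+depth)/100$) and its central 80%,
implemented as 0.8 linear edge scaling (so it contains 64% of the
full-field points). The alternative reading — 80% of *area*, edge factor
$\sqrt{0.8}$ — is a known ambiguity; the width convention is this package's
choice and is stated, not claimed as universal.

## The synthetic beam generator

`generate_beam()` produces an analytic 6 MV beam:

* **Depth dose**: $(1-e^{-b(d+s)})\,e^{-\mu d}$ with the shift $s$ solved in
  closed form so the maximum falls exactly at $d_{max} = 1.5$ cm. There is
  deliberately no inverse-square term (phantom-ratio convention), which
  makes $TPR_{20,10} \approx e^{-10\mu}$; the default
  $\mu = 0.0402\ \mathrm{cm^{-1}}$ gives 0.669, matching the Clinac-class
  beam (0.0376 gives the Synergy's 0.687). Attenuation softens by 0.3% per
  cm of field size above 10 cm so PDD rises with field size, as measured.
* **Profiles**: flat core × error-function penumbra
  ($\sigma = 0.35$ cm) with the field edge divergence-scaled to each depth,
  plus small off-axis horns (3% at $d_{max}$, fading with depth), sampled at
  the 0.2 cm scan resolution. The 50%-of-CAX level lands on the projected
  geometric edge to within 0.05 cm.
* **Output factors**: $OF(fs) = 1 + 0.0065\,(fs-10) - 8\times10^{-5}(fs-10)^2$,
  anchored at 1 for the reference field and strictly increasing — typical
  6 MV magnitudes (0.966 at 5 cm, 1.057 at 20 cm).

The **backscatter deficit model** (`backscatter_deficit_spec()`) uses the
simplest forms matching the measured monotonicities: entrance deficit
$A(fs)\,e^{-kt}$ (decaying to zero with backscatter thickness, larger for
larger fields) and exit deficit $B(fs) + c\,d$ (growing with depth and field
size). Default coefficients place every implied factor in the measured
0.96–1.00 range — e.g. exit BCF 0.995 at (5 cm, 6.5 cm) and 0.963 at
(20 cm, 31.5 cm) — without fitting either bundled machine table. These
defaults are the package's fixed study conditions, not tuning knobs.

Simulated measurements multiply the full-backscatter dose by the
deficit-implied BCF and by $(1+\varepsilon)$,
$\varepsilon \sim N(0, 0.005)$ — the 0.5% setup reproducibility of repeated
solid-phantom sessions — from a single seeded stream, so campaigns are
bit-reproducible. Because the depth-dose model is divergence-free, BCF
SSD-invariance holds *exactly* in this generator; the isocentric geometry
option exercises bookkeeping and noise, not divergence physics.

**TPS failure emulators** (`tps_emulator_spec()`): `exact` reproduces truth
bit-for-bit; `full_backscatter` omits the exit deficit, overestimating the
CAX dose by exactly $1/BCF - 1$; `shoulder_boost` raises the in-field
shoulder band by a set fraction at depths beyond an onset; `center_dip`
lowers the field centre. The shoulder band defaults to 0.80–0.98 of the
field half-width: the observed failure signature lives in the outer 20% of
the field (full-field gamma pass rates drop while central-80% rates stay
above 98%), and a band reaching deeper into the field would destroy exactly
the contrast the emulator exists to reproduce. Both the band and the onset
depth (default 11.5 cm) are parameters.

### What the generator does and does not emulate

It reproduces the *structure* of commissioning data (PDD/OF/profile tables
at scan resolution), realistic 6 MV magnitudes, the measured deficit
monotonicities, and session noise. It does not model head scatter, electron
contamination, beam tilt or asymmetry, inhomogeneities, the buildup region
(< 1.5 cm), detector volume effects, or Monte Carlo statistical noise in
TPS planes. Passing closed-loop tests therefore demonstrates that the
pipeline's algebra, interpolation, I/O and search are correct under
realistic magnitudes — not that any particular clinical beam model is
accurate.

## Numerical choices and degenerate inputs

* Interpolation is piecewise linear in every key dimension, exact on nodes,
  refusing extrapolation (hull tolerance $10^{-12}$ cm).
* PDD serializes at 1 decimal (percent scale), BCF at 3 decimals, matching
  measurement precision; round trips are exact at those precisions.
* Profiles must bracket the central axis; normalization divides by the
  linearly interpolated value at 0 and fails on non-positive values.
* Plane grids are uniform (checked to $10^{-9}$ cm) with the origin on the
  central axis; synthesized planes use 0.2 cm spacing and extend to 1.6 ×
  the projected field half-width, covering penumbra and out-of-field tails.
* Gamma reference points whose zero offset falls outside the evaluated
  plane get NA (counted as failures); the evaluated plane must cover the
  ROI plus the search radius or the comparison is refused.
* Cross-machine BCF comparison uses unsigned per-cell differences and the
  population SD; the unsigned mean is the convention that reproduces the
  published entrance-block statistic.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
4 field sizes × 7 + 6 measurement cells per campaign, 211 × 211 dose planes
at 0.2 cm spacing for the 20 cm field at 31.5 cm depth, 50 random 7 × 7
plane pairs for the gamma-oracle comparison, and 0.3 mm gamma subsampling.
These sizes keep a full run in seconds while exercising every code path at
the resolutions the formats define.

## Known limitations

* Cross-multiplied planes are exactly separable; corner dose is
  approximate.
* BCF tables cover 6 MV beams of near-identical quality; no energy
  dependence is modelled, and electron or high-energy photon BCFs are out
  of scope.
* The exit deficit model is linear in depth; real deficits saturate slowly.
  Within 1.5–31.5 cm the linear form stays inside the measured range, which
  is all the closed-loop tests require.
* Gamma is 2D, global-normalization only; no local gamma, gamma angle, or
  3D extension.
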