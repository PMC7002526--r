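---
title: "Angular compounding and digital focusing: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angular compounding and digital focusing: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octac)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. It states no empirical number that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The speckle model

A voxel of a coherent image contains many sub-resolution scatterers; the
detected amplitude is the modulus of their phasor sum. For two
equal-amplitude scatterers the amplitude is
$|S_{12}| = \sqrt{2}\,A_1\sqrt{1+\cos\Delta P_{12}}$, swinging between a
dark pixel (odd multiples of $\pi$) and $2A_1$ (even multiples). Averaged
over a uniform sweep of the phase difference through one period, the pixel
stabilises at $(4/\pi)A_1 \approx 1.27\,A_1$ independent of the initial
phase, while the un-averaged value is spread with standard deviation
$\sqrt{2-16/\pi^2}\,A_1 \approx 0.62\,A_1$. (The figure 0.62 is sometimes
loosely called a "variance"; dimensionally it is a standard deviation in
amplitude units, which is how `phase_averaged_std()` implements it.)

Tilting the incident beam by $\Delta\alpha$ shifts the round-trip phase
difference of a pair separated by $D_{12}$ by
$2 k\, RI\, D_{12}\, \Delta\alpha$ (`phase_shift_from_angle()`, with
$\Delta\alpha$ the in-sample angle change). Two printed-precision
consequences, both recomputed by `octac_selftest()`:
an 8° range at 920 nm completes a $2\pi$ fringe for pairs
$\geq 3.3\,\mu m$ apart — well inside the $8\,\mu m$ focal spot — and
requiring a full fringe for a pair one focal-spot radius apart caps the
useful scanner travel at $\pi/4 \approx 0.8$ of the beam diameter.

For $N$ scatterers (`multi_scatterer_signal()`), each pair has its own
fringe period; the exact ergodic average would require sweeping the least
common multiple of all periods. `angle_ensemble_mean()` instead averages
over the user-supplied finite angle set, matching the experimental
practice of 11 discrete angles. The sign of each stored distance
$D_{1,n}$ is positive when a positive angle change decreases the phase
difference.

## 2. Beam optics and units

Internal units are micrometres and radians; constructors accept mm and
degrees where those are instrument units. The beam is the stigmatic
Gaussian
$(w_0/w_b)\exp(-x'^2/w_b^2)\exp\{-iky' - ikx'^2 y'/[2(y'^2+R_y^2)] +
i\arctan(y'/R_y)\}$ in the frame rotated by the in-sample angle about the
focus, with $w_0 = 2\lambda f/(\pi D_B)$ by default (overridable for
non-ideal lenses) and the in-medium wavenumber and Rayleigh range
($k\,RI$, $R_y\,RI$). The curvature term is written as
$x'^2y'/[2(y'^2+R_y^2)]$, which is regular at the focal plane.

One property test deviates knowingly from a naive energy argument: for
this (three-dimensional) amplitude profile restricted to a 1-D cut, the
conserved transverse integral is $\int |A|\,dx' = w_0\sqrt{\pi}$, not
$\int |A|^2 dx'$ (which scales as $1/w_b$); the invariant test asserts the
former.

The round-trip optical pathlength (`round_trip_pathlength()`) is twice
the one-way path — the confocal gate admits only back-scattered light
retracing the illumination — including the air standoff, the $RI$-scaled
geometric distance along the beam axis, and the quadratic wavefront
curvature term for off-axis points. This same expression generates both
the simulator's phase and the digital-focusing PSF, which is what makes
the matched filter exact for simulated data.

## 3. The synthetic acquisition

`simulate_bscan()` renders one angle-coded complex B-scan per scanner
offset: each column is a ray entering the (flat) surface at
$x_e(u) = x_{e0} + p_u(u-u_f) + q(u-u_f)^2$, refracted to the in-sample
angle; a scatterer contributes its amplitude, the beam envelope at its
across-axis offset, a Gaussian axial gate (FWHM = axial resolution,
expressed in one-way optical-pathlength pixels), and the round-trip phase.
The quadratic coefficient $q = (g-f)\,p_u^2/(2f^2)$ models the galvo
sitting $g = 59$ mm from the $f = 36$ mm lens rather than in its back
focal plane. Repeats differ only by circular complex Gaussian noise (a
shot-noise proxy). The per-offset beams all pass through one physical
focus, which is the angle-independent reference point of the whole
geometry.

Two detection-model decisions shape everything downstream:

* **Amplitude once, phase doubled.** A scatterer is weighted by the beam
  amplitude envelope once, while its phase carries the doubled (round
  trip) pathlength. A consequence worth stating plainly: after matched
  filtering, a defocused point collapses to *below* the single-pass
  in-focus width (the chirp bandwidth exceeds the envelope bandwidth
  by up to 2×) — the acceptance test for refocusing therefore passes with
  margin, and the measured post-focusing FWHM (≈5 µm vs 6.5 µm in focus)
  should be read as a property of this detection model, not of any real
  instrument.
* **2-D only.** The simulation lives in the xz scan plane; out-of-plane
  scatterers, polarisation, multiple scattering and dispersion are not
  modelled. That matches the single-plane validity of the digital
  focusing method itself.

`simulate_spectral_interferogram()` synthesises the raw spectrometer
frames (Gaussian spectral window chosen so the transform-domain axial
envelope equals the simulator's gate); its FFT reconstruction agrees with
the direct render to 2%, exercising the preparation step end to end.

**Generator fidelity.** `make_speckle_phantom()` defaults to 40
scatterers per 8×2 µm resolution voxel. At low densities the generator
leaves a static reflectivity texture — Poisson fluctuations of the local
scatterer count, relative amplitude $\sim 1/\sqrt{N}$ — that is identical
at every angle and therefore survives any amount of compounding. Real
agar or tissue approximates a continuum, so the density was set high
enough to push this artifact well below the Rayleigh speckle contrast of
0.52. A green compounding test therefore establishes that *speckle*
averages out, not that arbitrary sample texture does (it should not).

## 4. Registration and its gauge freedoms

The pixel→physical mapping (`registration_model()`) realises translation,
scaling, rotation and quadratic deformation: ray entry
$x_e(u)$ as above, geometric depth $s = p_v(v - v_{surf}(u))/RI$ beyond
the per-column detected surface, then
$x = x_e + s\sin\alpha_s$, $z = z_{surf} + s\cos\alpha_s$. It is, by
construction, the exact inverse of the simulator's geometry; the
acceptance surface is self-consistency (forward/inverse round trip
< 0.1 px) plus the physical claim that matters: a bead imaged at all 11
offsets registers to the same physical position within one pixel at
±300 µm from the focal plane — pure angular compounding at all depths,
not only in the focal region.

Two parameters of the model are *gauges*, not measurables:

* $u_f$ (focus column): because every angular image is anchored at the
  same focus column and the quadratic distortion is angle-independent, an
  error in $u_f$ shifts **all** registered images by the same amount. The
  composite's spectrum magnitude is shift-invariant, so the R_HF
  objective is exactly flat in $u_f$. It is fixed by the coarse
  equal-surface-distance/symmetry convention instead.
* $x_f$ (lateral focus position): a common lateral datum, set to 0.

The focus **row** $v_f$ is identifiable — an error $\Delta$ displaces
each angular image laterally by $\sin\alpha_s \cdot p_v\Delta/RI$, which
differs across angles — but only weakly: at ±4° and 1 µm pixels the
differential displacement is 0.04 µm per pixel of error, far below the
lateral resolution, so the R_HF landscape is shallow and the estimate has
a few-pixel spread. The acceptance test measures the median over three
phantom realisations, which recovers the true row within 2 px; single
runs can be off by more, and the pipeline is insensitive to such errors
for exactly the same reason the landscape is shallow.

Surface detection takes the first half-maximum crossing per column,
validates the peak against the image background (so featureless images
raise an error rather than hallucinating a surface), rejects outliers and
median-smooths across columns. Bulk motion between angular acquisitions
is corrected by integer-pixel vertical shifts estimated from the median
surface offsets; sub-pixel motion is out of scope.

## 5. Digital focusing

The depth-$v$ PSF across the scan direction is the beam amplitude
envelope times the round-trip curvature chirp; the matched filter is its
conjugate, scaled by 1/max amplitude per depth so every kernel peaks at
magnitude 1. Convolution is row-wise in the frequency domain with
padding to the next power of two past the kernel support (wrap-around
suppression), kernels truncated at $10^{-3}$ of their peak amplitude.
One convention needed fixing: with the detected-signal phase written as
$\exp(-i2kr)$, the filter that compresses is the conjugate of *that*
response; the package uses this convention consistently (simulator, PSF,
MF), so "MF = conj(PSF)" holds and compresses by construction.

The in-focus kernel is the diffraction-limited envelope, about 7 px wide
at the instrument's pitches — a consequence of the stated optics. (A
description of the focal kernel as "support ≤ 3 px" is only compatible
with a much coarser lateral pitch; the invariant asserted here is that
the support is minimal at focus and grows monotonically away from it.)

`unity_magnitude_filter()` (MF$_U$) flattens the spectral magnitude to 1
and keeps only the phase. The trade-off is as expected and is asserted as
an ordering: MF retains higher CNR in noisy deep regions (its Gaussian
spectral envelope suppresses out-of-band noise), MF$_U$ gives equal or
narrower width.

`refine_filter_depth()` handles the RI-induced focal shift at the
air-sample interface by searching integer vertical bank offsets and
maximising the horizontal-only R_HF of the refocused magnitude. The
objective is always evaluated with the phase-only version of the bank:
with the amplitude-weighted MF, kernels further from (apparent) focus
have wider spectral envelopes, giving the landscape a monotonic gain
trend that swamps the phase-match signal. Even so, the discrete objective
on a finite slab carries a small (1–2 px) positive bias; the refinement
contract is therefore "within 2 px", which is also what the pipeline
needs.

## 6. Compounding statistics and where 1/√k holds

How fast angular patterns decorrelate is set by the width of the
detection area (the beam envelope at that depth). The field correlation
between angles separated by $\Delta\alpha$ is the normalised Fourier
transform of the squared envelope: $\exp[-(2k\Delta\alpha\,\sigma_x)^2/2]$
with $\sigma_x = w_b/2$. Two regimes follow, both measured by the tests:

* **Near focus** ($w_b = w_0 = 3.9$ µm): adjacent 0.8° steps are ~0.93
  correlated in field (~0.87 in magnitude, matching the measured 0.874),
  there are only ~3 independent looks across ±4°, and the 11-angle STD
  reduction floors near 0.65–0.73. No registration method can do better
  there; this is physics, not an implementation limit.
* **A few hundred µm from focus** ($w_b \approx 15$–17 µm): adjacent
  correlation drops to ~0.1 and the measured reduction curve tracks
  1/√k within 20%, reaching ≈0.35 at k = 11.

The compounding acceptance criterion is therefore evaluated in a
background band 240–340 µm below the focal plane, with the near-focus
correlation asserted separately (decorrelation must still be monotone in
angle separation). The 1/√k reference behaviour itself is additionally
verified on truly independent patterns (different phantom seeds).

## 7. Metrics conventions

* R_HF: sum of the centred spectrum magnitude outside a central
  low-frequency block over the total; block width 2/100 and height 5/100
  of the spectrum (midpoints of the stated working ranges); a
  horizontal-only variant FFTs rows individually. Scale- and
  shift-invariant; strictly lowered by blurring.
* Bead/background segmentation: per depth row, threshold at the weakest
  of the top-10% brightest pixels; rows narrower than 10 px fall back to
  the global threshold.
* Relative STD = STD/mean over a mask, computed on **linear** magnitudes
  (the log scale is display-only); Rayleigh reference 0.522.
* CNR $= 20\log_{10}[(\mu_s-\mu_b)/\sigma_b]$ dB — an amplitude-ratio
  convention chosen here, so dB values are comparable within this
  package only.
* FWHM: linear interpolation at half of (max − baseline), baseline the
  median of the outer quartiles.
* "Normalized STD vs number of angles": STD of the running k-angle
  composite over a region, normalised at k = 1.

## 8. Numerical and interface choices

1-based pixel indexing (R convention) with the focus pixel and surface
row documented accordingly. Bilinear resampling; a target node is valid
only if all four source neighbours exist. The quadratic column equation
is inverted with the numerically stable root. Complex stacks travel in a
self-describing JSON container (no community standard exists for raw
complex OCT data and no HDF5/TIFF R packages are assumed); magnitude
previews are ASCII PGM. All randomness flows through explicit seeds and
the pipeline re-runs bit-identically.

## 9. Known limitations

Single-plane (xz) simulation; flat surfaces in the simulator (tilted
surfaces are exercised synthetically in the surface-detection tests);
monochromatic beam with the axial point-spread modelled directly as a
Gaussian gate; no multiple scattering; tilt-specific PSFs are not built
(the on-axis bank is applied to all offsets before registration); bulk
motion is integer-pixel vertical only; $u_f$ is a gauge (see §4), so
"focus recovery" claims concern the focus row; CNR values are
internal-convention dB, not comparable across instruments.
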