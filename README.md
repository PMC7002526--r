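# octac — angular compounding and digital focusing for OCT

Optical coherence tomography (OCT) images are corrupted by speckle: the
coherent sum of echoes from the sub-resolution scatterers inside a voxel,

    |S| = | Σₙ Aₙ exp(−i·2k·Δrₙ) | ,      k = 2π/λ,

modulates a pixel anywhere between 0 and ΣAₙ depending on the scatterers'
round-trip phase differences. Tilting the incident beam by Δα shifts the
phase difference of a scatterer pair separated by D₁₂ by

    δOP₁₂ ≈ 2·k·RI·D₁₂·Δα ,

so sweeping the angle sweeps each pair through its interference fringe.
Averaging images acquired over a range of angles (*angular compounding*)
replaces the random two-scatterer amplitude
|S₁₂| = √2·A₁·√(1 + cos ΔP₁₂) — mean (4/π)·A₁ ≈ 1.27·A₁, spread
√(2 − 16/π²)·A₁ ≈ 0.62·A₁ under a uniform phase — by its stable mean,
removing speckle without averaging away structure. Doing this at every
depth requires mapping each pixel of every angle-coded B-scan to its true
physical position (the tilted beam changes optical pathlengths and
propagation directions), and lateral resolution away from the focal plane
is restored by *digital focusing*: convolving each depth row of the
complex B-scan with the conjugate of the depth-dependent point spread
function.

The package is aimed at researchers developing or validating OCT speckle
reduction pipelines. It provides, as a faithful in-silico counterpart of an
offset-scanner spectral-domain system (λ = 920 nm, beam diameter 5.4 mm,
f = 36 mm objective, 11 offsets −2.5…2.5 mm ≙ incident angles −4°…4°,
2 µm axial resolution, 0.976 µm scan step):

* `beam_optics` — Gaussian-beam geometry: `beam_geometry()`,
  `incident_angle()`, `in_sample_angle()`, `focal_spot_radius()`,
  `gaussian_field()`, `round_trip_pathlength()`.
* `speckle_model` — analytic/Monte-Carlo speckle statistics:
  `two_scatterer_amplitude()`, `phase_shift_from_angle()`,
  `phase_averaged_mean()`, `phase_averaged_std()`,
  `multi_scatterer_signal()`, `angle_ensemble_mean()`.
* `phantom_simulator` — `make_bead_phantom()`, `make_speckle_phantom()`,
  `simulate_bscan()` (compiled scatterer summation),
  `simulate_angular_set()`, `simulate_spectral_interferogram()`,
  `forward_map()`.
* `registration` — `registration_model()` (quadratic pixel→physical
  mapping), `detect_surface()`, `correct_bulk_motion()`,
  `estimate_focus()`, `register_image()`, `fuse_images()`.
* `digital_focusing` — `build_psf()`, `build_matched_filter()`,
  `unity_magnitude_filter()`, `matched_filter_bank()`,
  `apply_digital_focusing()`, `refine_filter_depth()`.
* `metrics` — `r_hf()`, `segment_beads()`, `std_reduction_curve()`,
  `relative_std()`, `contrast_ratio()`, `cnr_db()`, `fwhm()`.
* `pipeline_io` — `run_preparation()`, `run_pipeline()`,
  `read_stack()`/`write_stack()` (JSON complex-stack container),
  `octac_cli()` with verbs `simulate | focus | register | run | metrics |
  selftest`.

## Worked example

The analytic self-test recomputes the closed-form quantities of the model
from quadrature / geometry and prints them:

```r
library(octac)
octac_selftest()
```

```
{"t1_phase_averaged_mean":1.27324,"t2_unaveraged_spread":0.615517,
 "t3_min_separation_um":3.294507,"t4_max_offset_over_beam_diameter":0.785398,
 "t5_offset_angle_deg":3.972496,"t6_full_angle_range_deg":7.944992,
 "t7_focal_spot_diameter_um":7.809203}
```

t1/t2 are the phase-averaged mean and un-averaged spread of the
two-scatterer amplitude (1.27·A₁ and 0.62·A₁); t3 says an 8° angle range
drives a scatterer pair 3.3 µm apart — well inside the 8 µm focal spot
(t7) — through a full 2π fringe; t4 is the maximum useful scanner travel,
π/4 ≈ 0.8 of the beam diameter; t5/t6 map the ±2.5 mm offsets to ±4°.

Digital focusing of a simulated bead 200 µm below the focal plane:

```r
g  <- beam_geometry()
ph <- oct_phantom(data.frame(x = 0, z = 300, amp = 1),
                  extent = list(x = c(-80, 80), z = c(0, 350)),
                  refractive_index = 1.34)
n_v <- 16 + ceiling(1.34 * 340)
acq <- acquisition(n_u = 161, n_v = n_v, u_f = 81, surface_row = 16)
inc <- incidence_config(0, g, focus_physical = c(0, 100))
st  <- simulate_bscan(ph, g, inc, acq)

img <- Mod(st$data[, , 1])
row <- which.max(apply(img, 1, max))
cat(sprintf("defocused bead FWHM: %.1f um\n", fwhm(img[row, ], g$p_u)))

bank <- matched_filter_bank(g, n_v, st$truth$v_f, 161, 1.34, variant = "mf")
out  <- Mod(apply_digital_focusing(st$data[, , 1], bank))
row  <- which.max(apply(out, 1, max))
cat(sprintf("after digital focusing:  %.1f um\n", fwhm(out[row, ], g$p_u)))
```

```
defocused bead FWHM: 19.0 um
after digital focusing:  5.0 um
```

The defocused width (≈19 µm) collapses back to the diffraction scale: the
matched filter conjugates the round-trip wavefront-curvature chirp that
the simulator itself imprints on off-focus scatterers. The full
compounding pipeline (`run_pipeline()` or the `run` CLI verb) registers
the 11 angular images to physical space, fuses them, and reports focus
pixel, bulk-motion shifts and the high-frequency ratio R_HF; in the
defocused background the 11-angle composite lowers the speckle STD to
≈ 0.35 of a single angle (1/√11 ≈ 0.30; see the methods vignette for the
depth dependence of angular decorrelation).

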