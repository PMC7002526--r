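#' Point-scatterer phantom
#'
#' A phantom is a list of point scatterers (physical x, depth z, amplitude)
#' below a flat surface, plus the sample refractive index and the lateral /
#' depth extent. It is the ground truth for all simulator-based tests.
#'
#' @param scatterers Data frame with columns `x`, `z`, `amp` (um, um, >= 0).
#' @param extent List `list(x = c(min, max), z = c(min, max))` in um.
#' @param surface_z Flat surface height (um), default 0; all scatterers must
#'   lie at or below it.
#' @param refractive_index Sample refractive index.
#' @return An object of class `oct_phantom`.
#' @export
oct_phantom <- function(scatterers, extent, surface_z = 0,
                        refractive_index = 1.34) {
  stopifnot(is.data.frame(scatterers),
            all(c("x", "z", "amp") %in% names(scatterers)))
  if (nrow(scatterers) > 0) {
    stopifnot(all(scatterers$amp >= 0),
              all(scatterers$z >= surface_z),
              all(scatterers$x >= extent$x[1] & scatterers$x <= extent$x[2]),
              all(scatterers$z <= extent$z[2]))
  }
  structure(list(scatterers = scatterers, extent = extent,
                 surface_z = surface_z,
                 refractive_index = refractive_index),
            class = "oct_phantom")
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("OCT phantom: %d scatterers, x [%g, %g] um, z [%g, %g] um, RI %.2f\n",
              nrow(x$scatterers), x$extent$x[1], x$extent$x[2],
              x$extent$z[1], x$extent$z[2], x$refractive_index))
  invisible(x)
}

#' Sparse bead phantom
#'
#' Draws a Poisson number of beads with mean `density * volume`, where the
#' volume is the extent area times an assumed out-of-plane slab thickness
#' (the simulation is restricted to the xz scan plane). Bead positions are
#' uniform over the extent; reproducible for a fixed seed. The default
#' density matches a 1 um polystyrene bead suspension of 3.64e7 beads/ml.
#'
#' @param density_per_ml Bead concentration (beads per ml), >= 0.
#' @param extent List `list(x = c(min, max), z = c(min, max))` (um).
#' @param slab_thickness_um Out-of-plane thickness used to convert the
#'   volumetric density to an in-plane count (um); default the 8 um beam
#'   width, i.e. beads within one beam waist of the scan plane.
#' @param amplitude Either a single amplitude or a `function(n)` returning n
#'   amplitudes.
#' @param seed RNG seed.
#' @param surface_z,refractive_index Passed to [oct_phantom()].
#' @return An `oct_phantom`.
#' @export
make_bead_phantom <- function(density_per_ml = 3.64e7, extent,
                              slab_thickness_um = 8, amplitude = 1,
                              seed = 1, surface_z = 0,
                              refractive_index = 1.34) {
  if (density_per_ml < 0) stop("density must be >= 0")
  vol_um3 <- diff(extent$x) * (diff(extent$z)) * slab_thickness_um
  mean_n <- density_per_ml * vol_um3 / 1e12  # 1 ml = 1e12 um^3
  with_seed(seed, {
    n <- rpois(1, mean_n)
    z_lo <- max(extent$z[1], surface_z)
    sc <- data.frame(
      x = runif(n, extent$x[1], extent$x[2]),
      z = runif(n, z_lo, extent$z[2]),
      amp = if (is.function(amplitude)) amplitude(n) else rep(amplitude, n)
    )
    oct_phantom(sc, extent, surface_z, refractive_index)
  })
}

#' Dense sub-resolution speckle phantom
#'
#' Fills the extent with many weak scatterers whose spacing is far below the
#' focal spot, so the coherent voxel sum has uniformly distributed phase and
#' the resulting B-scan background shows fully developed (Rayleigh)
#' speckle: relative STD of the magnitude about sqrt(4/pi - 1) = 0.52.
#'
#' The default density of 40 scatterers per resolution voxel keeps the
#' generator's finite-sampling artifact -- a static reflectivity texture
#' from Poisson density fluctuations, relative amplitude about
#' 1/sqrt(N) per voxel, identical at every angle -- well below the speckle
#' contrast, approximating the continuum scatterer field of agar or
#' tissue. Sparser settings leave an angle-independent texture floor that
#' no amount of compounding can remove.
#'
#' @param scatterers_per_voxel Mean number of scatterers per resolution
#'   voxel (8 um x 2 um), default 40.
#' @param extent List `list(x = c(min, max), z = c(min, max))` (um).
#' @param seed RNG seed.
#' @param surface_z,refractive_index Passed to [oct_phantom()].
#' @return An `oct_phantom`.
#' @export
make_speckle_phantom <- function(scatterers_per_voxel = 40, extent, seed = 1,
                                 surface_z = 0, refractive_index = 1.34) {
  stopifnot(scatterers_per_voxel >= 0)
  voxel_area <- 8 * 2  # um^2, focal width x axial resolution
  z_lo <- max(extent$z[1], surface_z)
  area <- diff(extent$x) * (extent$z[2] - z_lo)
  mean_n <- scatterers_per_voxel * area / voxel_area
  with_seed(seed, {
    n <- rpois(1, mean_n)
    sc <- data.frame(
      x = runif(n, extent$x[1], extent$x[2]),
      z = runif(n, z_lo, extent$z[2]),
      amp = runif(n, 0.5, 1.5)
    )
    oct_phantom(sc, extent, surface_z, refractive_index)
  })
}

#' Acquisition grid for simulated B-scans
#'
#' @param n_u,n_v Image width (scan direction) and depth in pixels.
#' @param u_f Focus column (1-based); the beams of all offsets cross at the
#'   focus, which sits in this column for every angular image.
#' @param surface_row Image row (1-based) at which the (flat) surface
#'   appears for zero bulk shift.
#' @return An object of class `oct_acquisition`.
#' @export
acquisition <- function(n_u = 128, n_v = 256, u_f = ceiling(n_u / 2),
                        surface_row = 16) {
  stopifnot(n_u >= 1, n_v >= 1, u_f >= 1, u_f <= n_u,
            surface_row >= 1, surface_row <= n_v)
  structure(list(n_u = as.integer(n_u), n_v = as.integer(n_v),
                 u_f = u_f, surface_row = surface_row),
            class = "oct_acquisition")
}

# Shared scan-geometry parameters used by the simulator, forward_map and the
# registration model. Must be the single source of truth for the pixel <->
# physical mapping.
scan_params <- function(geometry, inc, acq, surface_z = 0,
                        ri = geometry$ri, bulk_shift = 0) {
  sa <- sin(inc$alpha_s); ca <- cos(inc$alpha_s)
  s_f <- (inc$focus_physical[2] - surface_z) / ca
  x_e0 <- inc$focus_physical[1] - s_f * sa
  # quadratic scan distortion from the galvo sitting off the back focal plane
  q <- (geometry$galvo_lens_distance - geometry$f) *
    geometry$p_u^2 / (2 * geometry$f^2)
  du <- seq_len(acq$n_u) - acq$u_f
  entry_x <- x_e0 + geometry$p_u * du + q * du^2
  v_surf0 <- acq$surface_row + bulk_shift
  v_f <- v_surf0 + ri * s_f / geometry$p_v
  phase0 <- -2 * geometry$k0 * inc$air_standoff / cos(inc$alpha)
  list(sin_as = sa, cos_as = ca, s_f = s_f, x_e0 = x_e0, q = q,
       entry_x = entry_x, v_surf0 = v_surf0, v_f = v_f, phase0 = phase0,
       ri = ri, p_u = geometry$p_u, p_v = geometry$p_v)
}

# Axial gate sigma in pixels: amplitude-Gaussian with FWHM equal to the
# axial resolution, expressed in one-way OPL pixels.
gate_sigma_px <- function(geometry) {
  geometry$axial_resolution / (2 * sqrt(2 * log(2))) / geometry$p_v
}

#' Simulate a complex B-scan stack at one scanner offset
#'
#' For each pixel the signal is the coherent sum over scatterers of
#' amplitude x beam envelope x axial gate x `exp(-i k * round-trip OPL)`:
#' the detection area of a pixel is set by the light wavefronts (width) and
#' the axial resolution (height), and the echoes of everything inside it
#' interfere. Independent circular complex Gaussian noise (shot-noise
#' proxy) is added per repeat.
#'
#' @param phantom An [oct_phantom()].
#' @param geometry A [beam_geometry()].
#' @param inc An [incidence_config()].
#' @param acq An [acquisition()] grid.
#' @param n_repeat Number of repeated B-scans (noise realisations).
#' @param noise_level SD of the additive complex noise (total over both
#'   quadratures), in signal amplitude units.
#' @param seed RNG seed for the noise.
#' @param bulk_shift_px Integer vertical bulk-motion shift to inject (px).
#' @param surface_amp Amplitude of the specular surface echo line; 0 for
#'   none.
#' @return An object of class `oct_stack`: complex array `data`
#'   (n_v x n_u x n_repeat) plus geometry/incidence metadata and the
#'   simulation ground truth (focus pixel, surface row).
#' @export
simulate_bscan <- function(phantom, geometry, inc, acq = acquisition(),
                           n_repeat = 1, noise_level = 0, seed = 1,
                           bulk_shift_px = 0, surface_amp = 0) {
  stopifnot(inherits(phantom, "oct_phantom"),
            inherits(geometry, "beam_geometry"),
            inherits(inc, "incidence_config"),
            inherits(acq, "oct_acquisition"))
  sp <- scan_params(geometry, inc, acq, phantom$surface_z,
                    phantom$refractive_index, bulk_shift_px)
  if (min(sp$entry_x) < phantom$extent$x[1] - 1e-9 ||
      max(sp$entry_x) > phantom$extent$x[2] + 1e-9) {
    warning("scan positions outside the phantom extent; those columns contain no scatterers")
  }
  mb <- medium_beam(geometry, phantom$refractive_index)
  sc <- phantom$scatterers
  sig <- cpp_scatter_image(sc$x, sc$z, sc$amp, sp$entry_x, phantom$surface_z,
                           sp$sin_as, sp$cos_as, sp$s_f, mb$w0, mb$ry,
                           geometry$k0, phantom$refractive_index,
                           geometry$p_v, rep(sp$v_surf0, acq$n_u), acq$n_v,
                           gate_sigma_px(geometry), 1e-6, sp$phase0)
  if (surface_amp > 0) {
    gs <- gate_sigma_px(geometry)
    rows <- seq_len(acq$n_v)
    gate <- surface_amp * exp(-(rows - sp$v_surf0)^2 / (2 * gs^2)) *
      exp(1i * sp$phase0)
    sig <- sig + matrix(gate, acq$n_v, acq$n_u)
  }
  data <- array(0i, dim = c(acq$n_v, acq$n_u, n_repeat))
  with_seed(seed, {
    for (r in seq_len(n_repeat)) {
      noise <- if (noise_level > 0) {
        (rnorm(length(sig), sd = noise_level / sqrt(2)) +
           1i * rnorm(length(sig), sd = noise_level / sqrt(2)))
      } else {
        0
      }
      data[, , r] <- sig + noise
    }
  })
  structure(list(data = data, pitch_u = geometry$p_u, pitch_v = geometry$p_v,
                 offset_d = inc$d, seed = seed, geometry = geometry,
                 inc = inc, acq = acq, noise_level = noise_level,
                 bulk_shift = bulk_shift_px, surface_amp = surface_amp,
                 surface_z = phantom$surface_z,
                 ri = phantom$refractive_index,
                 truth = list(v_f = sp$v_f, u_f = acq$u_f,
                              v_surf = sp$v_surf0,
                              focus_physical = inc$focus_physical)),
            class = "oct_stack")
}

# Pure-R reference implementation of the scatterer accumulation, used by the
# test suite as the independent oracle for the compiled kernel. Slow; tiny
# inputs only.
r_scatter_image <- function(phantom, geometry, inc, acq, bulk_shift_px = 0) {
  sp <- scan_params(geometry, inc, acq, phantom$surface_z,
                    phantom$refractive_index, bulk_shift_px)
  mb <- medium_beam(geometry, phantom$refractive_index)
  gs <- gate_sigma_px(geometry)
  img <- matrix(0i, acq$n_v, acq$n_u)
  sc <- phantom$scatterers
  for (j in seq_len(acq$n_u)) {
    for (i in seq_len(nrow(sc))) {
      dx <- sc$x[i] - sp$entry_x[j]
      dz <- sc$z[i] - phantom$surface_z
      if (dz < 0) next
      s_ax <- dx * sp$sin_as + dz * sp$cos_as
      if (s_ax < 0) next
      xp <- dx * sp$cos_as - dz * sp$sin_as
      yp <- s_ax - sp$s_f
      wb <- mb$w0 * sqrt(1 + (yp / mb$ry)^2)
      amp <- (mb$w0 / wb) * exp(-xp^2 / wb^2)
      lat <- xp^2 * yp / (2 * (yp^2 + mb$ry^2))
      opl <- phantom$refractive_index * (s_ax + lat)
      vc <- sp$v_surf0 + opl / geometry$p_v
      contrib <- amp * sc$amp[i] * exp(1i * (sp$phase0 - 2 * geometry$k0 * opl))
      v <- seq_len(acq$n_v)
      keep <- abs(v - vc) <= 4 * gs
      img[v[keep], j] <- img[v[keep], j] +
        contrib * exp(-(v[keep] - vc)^2 / (2 * gs^2))
    }
  }
  img
}

#' Simulate the full angle-coded acquisition
#'
#' Convenience wrapper producing one [simulate_bscan()] stack per scanner
#' offset, with per-offset noise seeds and optional injected bulk-motion
#' shifts. The physical focus is shared across offsets.
#'
#' @param phantom An [oct_phantom()].
#' @param geometry A [beam_geometry()].
#' @param offsets_mm Scanner offsets (mm); default the 11 offsets
#'   -2.5 ... 2.5 in 0.5 mm steps.
#' @param acq An [acquisition()].
#' @param focus_physical Physical focus `c(x, z)` (um).
#' @param n_repeat,noise_level,surface_amp Passed to [simulate_bscan()].
#' @param seed Base seed; offset i uses seed + i.
#' @param bulk_shifts_px Integer vector of per-offset vertical shifts
#'   (recycled).
#' @return List of `oct_stack` objects, one per offset.
#' @export
simulate_angular_set <- function(phantom, geometry,
                                 offsets_mm = seq(-2.5, 2.5, by = 0.5),
                                 acq = acquisition(),
                                 focus_physical = c(0, 350),
                                 n_repeat = 1, noise_level = 0,
                                 surface_amp = 0, seed = 1,
                                 bulk_shifts_px = 0) {
  shifts <- rep_len(bulk_shifts_px, length(offsets_mm))
  lapply(seq_along(offsets_mm), function(i) {
    inc <- incidence_config(offsets_mm[i], geometry, focus_physical)
    simulate_bscan(phantom, geometry, inc, acq, n_repeat, noise_level,
                   seed = seed + i, bulk_shift_px = shifts[i],
                   surface_amp = surface_amp)
  })
}

#' Synthesise spectral-domain interferograms
#'
#' Produces the raw spectrometer frames whose Fourier transform over
#' wavenumber recovers the complex depth-encoded A-scans, exercising the
#' preparation step end to end. The Gaussian spectral window is chosen so
#' the transform-domain axial envelope matches the simulator's axial gate.
#' Intended for sparse phantoms (cost is scatterers x columns in R).
#'
#' @param phantom An [oct_phantom()] (sparse).
#' @param geometry A [beam_geometry()].
#' @param inc An [incidence_config()].
#' @param acq An [acquisition()].
#' @param n_pixels Spectrometer pixels, default 2048.
#' @param noise_level SD of additive real noise on the spectra.
#' @param seed RNG seed.
#' @return List with `spectra` (n_pixels x n_u real matrix), `n_v`, and
#'   normalisation metadata for [spectra_to_bscan()].
#' @export
simulate_spectral_interferogram <- function(phantom, geometry, inc,
                                            acq = acquisition(),
                                            n_pixels = 2048,
                                            noise_level = 0, seed = 1) {
  sp <- scan_params(geometry, inc, acq, phantom$surface_z,
                    phantom$refractive_index)
  mb <- medium_beam(geometry, phantom$refractive_index)
  gs <- gate_sigma_px(geometry)
  n <- n_pixels
  j <- seq_len(n)
  sigma_j <- n / (2 * pi * gs)
  win <- exp(-(j - (n + 1) / 2)^2 / (2 * sigma_j^2))
  spectra <- matrix(0, n, acq$n_u)
  sc <- phantom$scatterers
  for (col in seq_len(acq$n_u)) {
    if (nrow(sc) == 0) break
    dx <- sc$x - sp$entry_x[col]
    dz <- sc$z - phantom$surface_z
    s_ax <- dx * sp$sin_as + dz * sp$cos_as
    xp <- dx * sp$cos_as - dz * sp$sin_as
    yp <- s_ax - sp$s_f
    wb <- mb$w0 * sqrt(1 + (yp / mb$ry)^2)
    amp <- (mb$w0 / wb) * exp(-xp^2 / wb^2) * sc$amp
    lat <- xp^2 * yp / (2 * (yp^2 + mb$ry^2))
    opl <- phantom$refractive_index * (s_ax + lat)
    vc <- sp$v_surf0 + opl / geometry$p_v  # fractional depth bin, 1-based
    keep <- s_ax >= 0 & dz >= 0 & amp > 1e-6 & vc < n / 2 - 8 * gs
    if (!any(keep)) next
    ph <- sp$phase0 - 2 * geometry$k0 * opl[keep]
    for (i in seq_along(ph)) {
      spectra[, col] <- spectra[, col] + amp[keep][i] * win *
        cos(2 * pi * (j - 1) * (vc[keep][i] - 1) / n + ph[i])
    }
  }
  if (noise_level > 0) {
    spectra <- spectra + with_seed(seed, {
      matrix(rnorm(length(spectra), sd = noise_level), n, acq$n_u)
    })
  }
  list(spectra = spectra, n_v = acq$n_v, win_sum = sum(win),
       n_pixels = n)
}

#' Reconstruct complex B-scan from spectral frames
#'
#' FFT over the spectrometer axis, single (positive-depth) side, scaled so
#' that a reflector of amplitude a appears with peak magnitude a.
#'
#' @param sp Output of [simulate_spectral_interferogram()].
#' @return Complex matrix (n_v x n_u).
#' @export
spectra_to_bscan <- function(sp) {
  ft <- mvfft(sp$spectra)
  ft[seq_len(sp$n_v), , drop = FALSE] * 2 / sp$win_sum
}

#' Map an image pixel to its physical position
#'
#' Forward geometric mapping `(u, v) -> (x, z)` for one incidence
#' configuration: column u is a ray entering the sample at lateral position
#' `x_e(u) = x_e0 + p_u (u - u_f) + q (u - u_f)^2` (q from the galvo not
#' sitting in the back focal plane), refracted to the in-sample angle; pixel
#' v lies at geometric distance `s = p_v (v - v_surf) / RI` along the ray
#' beyond the surface. Exact inverse of the simulator's pixel assignment.
#'
#' @param u,v Pixel coordinates (1-based, fractional allowed; vectors).
#' @param inc An [incidence_config()].
#' @param geometry A [beam_geometry()].
#' @param acq An [acquisition()] (supplies the focus column and surface row).
#' @param surface_z Physical surface height (um).
#' @param ri Sample refractive index (defaults to the geometry's).
#' @return List with vectors `x`, `z` (um).
#' @export
forward_map <- function(u, v, inc, geometry, acq, surface_z = 0,
                        ri = geometry$ri) {
  sp <- scan_params(geometry, inc, acq, surface_z, ri)
  du <- u - acq$u_f
  xe <- sp$x_e0 + sp$p_u * du + sp$q * du^2
  s <- sp$p_v * (v - sp$v_surf0) / ri
  list(x = xe + s * sp$sin_as, z = surface_z + s * sp$cos_as)
}
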