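#' Optical system geometry for an offset-scanner OCT system
#'
#' Bundles the optical constants of the instrument: centre wavelength,
#' collimated beam diameter, objective focal length, galvo-to-lens distance,
#' sample refractive index, axial resolution and the scan/axial pixel
#' pitches. Derived quantities (focal spot radius, Rayleigh range, wave
#' number) are computed once and stored.
#'
#' Defaults match a 920 nm spectral-domain system with a 5.4 mm beam,
#' a 36 mm objective, a 59 mm galvo-lens distance, 2 um axial resolution
#' and a 0.976 um scanning step.
#'
#' @param wavelength_um Centre wavelength (um).
#' @param beam_diameter_mm Collimated (single-mode) beam diameter D_B (mm).
#' @param focal_length_mm Objective focal length f (mm).
#' @param galvo_lens_distance_mm Distance between galvo mirror and lens (mm).
#'   When it differs from f the lateral scan acquires a quadratic distortion.
#' @param refractive_index Sample (group) refractive index, >= 1.
#' @param axial_resolution_um Axial resolution (um, in air), FWHM.
#' @param scan_step_um Lateral scan step / pixel pitch p_u (um).
#' @param axial_pitch_um Axial image pixel pitch p_v in one-way optical
#'   pathlength units (um).
#' @param waist_radius_um Focal (waist) 1/e^2 amplitude radius w0 (um).
#'   Defaults to the diffraction value 2*lambda*f/(pi*D_B).
#' @return An object of class `beam_geometry`.
#' @export
#' @examples
#' g <- beam_geometry()
#' 2 * g$w0  # 1/e^2 focal spot diameter, about 8 um
beam_geometry <- function(wavelength_um = 0.92,
                          beam_diameter_mm = 5.4,
                          focal_length_mm = 36,
                          galvo_lens_distance_mm = 59,
                          refractive_index = 1.34,
                          axial_resolution_um = 2,
                          scan_step_um = 0.976,
                          axial_pitch_um = 1,
                          waist_radius_um = NULL) {
  stopifnot(wavelength_um > 0, beam_diameter_mm > 0, focal_length_mm > 0,
            galvo_lens_distance_mm > 0, axial_resolution_um > 0,
            scan_step_um > 0, axial_pitch_um > 0)
  if (refractive_index < 1) {
    stop("refractive_index must be >= 1")
  }
  f <- focal_length_mm * 1e3
  db <- beam_diameter_mm * 1e3
  w0 <- if (is.null(waist_radius_um)) {
    focal_spot_radius(wavelength_um, f, db)
  } else {
    stopifnot(waist_radius_um > 0)
    waist_radius_um
  }
  g <- list(
    lambda = wavelength_um,
    k0 = 2 * pi / wavelength_um,
    beam_diameter = db,
    f = f,
    galvo_lens_distance = galvo_lens_distance_mm * 1e3,
    ri = refractive_index,
    axial_resolution = axial_resolution_um,
    p_u = scan_step_um,
    p_v = axial_pitch_um,
    w0 = w0,
    rayleigh_air = pi * w0^2 / wavelength_um
  )
  class(g) <- "beam_geometry"
  g
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat("OCT beam geometry\n")
  cat(sprintf("  wavelength      %.3f um (k0 = %.3f rad/um)\n", x$lambda, x$k0))
  cat(sprintf("  beam diameter   %.1f mm, focal length %.1f mm\n",
              x$beam_diameter / 1e3, x$f / 1e3))
  cat(sprintf("  focal spot w0   %.2f um (1/e^2 diameter %.1f um)\n",
              x$w0, 2 * x$w0))
  cat(sprintf("  Rayleigh range  %.1f um (air)\n", x$rayleigh_air))
  cat(sprintf("  sample RI       %.2f, axial resolution %.1f um\n",
              x$ri, x$axial_resolution))
  cat(sprintf("  pixel pitch     u: %.3f um, v: %.3f um\n", x$p_u, x$p_v))
  invisible(x)
}

#' Incident angle produced by a scanner offset
#'
#' The lateral offset d between the scanner pivot and the lens optical axis
#' tilts the beam after the objective by alpha = arctan(d / f).
#'
#' @param d_mm Offset (mm); may be a vector. Odd in d.
#' @param f_mm Focal length (mm), > 0.
#' @return Incident angle(s) in degrees.
#' @export
#' @examples
#' incident_angle(2.5, 36)  # ~4 degrees
incident_angle <- function(d_mm, f_mm) {
  if (!is.numeric(f_mm) || length(f_mm) != 1L || !is.finite(f_mm) || f_mm <= 0) {
    stop("invalid geometry: focal length must be a positive number")
  }
  rad2deg(atan(d_mm / f_mm))
}

#' Refracted beam angle inside the sample
#'
#' Snell refraction at the (flat) air-sample interface:
#' alpha_s = asin(sin(alpha) / RI).
#'
#' @param alpha Incident angle in air (radians unless `degrees = TRUE`).
#' @param ri Sample refractive index, >= 1.
#' @param degrees Interpret `alpha` (and the return value) as degrees.
#' @return In-sample angle, same units as the input.
#' @export
in_sample_angle <- function(alpha, ri, degrees = FALSE) {
  if (any(ri < 1)) stop("refractive index must be >= 1")
  a <- if (degrees) deg2rad(alpha) else alpha
  out <- asin(sin(a) / ri)
  if (degrees) rad2deg(out) else out
}

#' Focal spot radius of the focused Gaussian beam
#'
#' R_S = 2 * lambda * f / (pi * D_B), the 1/e^2 amplitude radius at focus.
#'
#' @param lambda_um Wavelength (um).
#' @param f_um Focal length (um).
#' @param beam_diameter_um Collimated beam diameter (um).
#' @return Focal spot radius (um).
#' @export
focal_spot_radius <- function(lambda_um, f_um, beam_diameter_um) {
  if (any(c(lambda_um, f_um, beam_diameter_um) <= 0)) {
    stop("invalid geometry: all lengths must be > 0")
  }
  2 * lambda_um * f_um / (pi * beam_diameter_um)
}

#' Incidence configuration for one scanner offset
#'
#' Holds the offset d, the incident angle in air, the refracted in-sample
#' angle, and the physical focus position shared by all offsets (the beams
#' for the different offsets cross at the focus, which therefore serves as
#' the angle-independent reference point).
#'
#' @param d_mm Scanner offset (mm).
#' @param geometry A [beam_geometry()].
#' @param focus_physical Physical focus position `c(x, z)` in um; z is depth
#'   below the nominal surface (positive down), x is lateral.
#' @param air_standoff_um Geometric air path from the reference plane to the
#'   surface along the lens axis (um); enters phase only.
#' @return An object of class `incidence_config`.
#' @export
incidence_config <- function(d_mm, geometry,
                             focus_physical = c(0, 350),
                             air_standoff_um = 0) {
  stopifnot(inherits(geometry, "beam_geometry"), length(focus_physical) == 2)
  alpha <- atan(d_mm * 1e3 / geometry$f)
  alpha_s <- in_sample_angle(alpha, geometry$ri)
  inc <- list(
    d = d_mm,
    alpha = alpha,
    alpha_s = alpha_s,
    focus_physical = as.numeric(focus_physical),
    air_standoff = air_standoff_um
  )
  class(inc) <- "incidence_config"
  inc
}

# In-medium beam constants for a geometry (wavelength shortens by RI,
# Rayleigh range grows by RI; transverse wavevector is continuous).
medium_beam <- function(geometry, ri = geometry$ri) {
  list(
    k = geometry$k0 * ri,
    ry = geometry$rayleigh_air * ri,
    w0 = geometry$w0
  )
}

#' Complex Gaussian beam field
#'
#' Evaluates the focused Gaussian beam in the sample medium at physical
#' points `(x, z)`, in the frame rotated by the in-sample angle about the
#' focus centre:
#' `(w0/w_b) exp(-x'^2 / w_b^2) * exp(-i k y' - i k x'^2 y'/(2 (y'^2 + R_y^2)) + i atan(y'/R_y))`
#' with `w_b = w0 sqrt(1 + y'^2/R_y^2)`. The curvature term is written in a
#' form regular at the focal plane (y' = 0).
#'
#' @param x,z Physical coordinates (um); vectors of equal length (recycled).
#' @param geometry A [beam_geometry()].
#' @param inc An [incidence_config()]; sets rotation angle and focus centre.
#' @return Complex field values, unit amplitude and zero phase at the focus.
#' @export
gaussian_field <- function(x, z, geometry, inc) {
  stopifnot(all(is.finite(x)), all(is.finite(z)))
  mb <- medium_beam(geometry)
  ca <- cos(inc$alpha_s); sa <- sin(inc$alpha_s)
  dx <- x - inc$focus_physical[1]
  dz <- z - inc$focus_physical[2]
  xp <- dx * ca - dz * sa
  yp <- dx * sa + dz * ca
  wb <- mb$w0 * sqrt(1 + (yp / mb$ry)^2)
  amp <- (mb$w0 / wb) * exp(-xp^2 / wb^2)
  curv <- xp^2 * yp / (2 * (yp^2 + mb$ry^2))
  phase <- -mb$k * yp - mb$k * curv + atan(yp / mb$ry)
  amp * exp(1i * phase)
}

#' Round-trip optical pathlength to a point in the sample
#'
#' Twice the one-way optical pathlength from the reference plane to the
#' point along the (tilted) beam: the confocal gate only collects
#' back-scattered light retracing the illumination path. The one-way path
#' is `air_standoff/cos(alpha) + RI * (s + x'^2 y' / (2 (y'^2 + R_y^2)))`
#' where s is the geometric distance along the beam axis beyond the surface
#' and the quadratic term is the Gaussian wavefront curvature at lateral
#' offset x'.
#'
#' @param x,z Physical coordinates (um), z >= surface.
#' @param geometry A [beam_geometry()].
#' @param inc An [incidence_config()].
#' @param surface_z Flat surface height (um), default 0.
#' @return Round-trip optical pathlength (um).
#' @export
round_trip_pathlength <- function(x, z, geometry, inc, surface_z = 0) {
  mb <- medium_beam(geometry)
  ri <- geometry$ri
  ca <- cos(inc$alpha_s); sa <- sin(inc$alpha_s)
  s_f <- (inc$focus_physical[2] - surface_z) / ca
  x_entry <- inc$focus_physical[1] - s_f * sa
  dx <- x - x_entry
  dz <- z - surface_z
  s_ax <- dx * sa + dz * ca
  xp <- dx * ca - dz * sa
  yp <- s_ax - s_f
  lat <- xp^2 * yp / (2 * (yp^2 + mb$ry^2))
  air <- inc$air_standoff / cos(inc$alpha)
  2 * (air + ri * (s_ax + lat))
}
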