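#' Two-scatterer interference amplitude
#'
#' Two equal-amplitude scatterers in one voxel interfere to give
#' `|S| = sqrt(2) * A1 * sqrt(1 + cos(dP))`, where dP is their (round-trip)
#' phase difference. The result sweeps the pixel between fully dark (dP an
#' odd multiple of pi) and 2*A1 (even multiples); this modulation is the
#' elementary speckle mechanism.
#'
#' @param dP Phase difference (radians); vectorised.
#' @param A1 Reference scatterer amplitude, >= 0.
#' @return Amplitude in `[0, 2*A1]`, 2*pi-periodic in `dP`.
#' @export
two_scatterer_amplitude <- function(dP, A1 = 1) {
  stopifnot(all(A1 >= 0))
  sqrt(2) * A1 * sqrt(pmax(0, 1 + cos(dP)))
}

#' Angle-induced phase shift between two scatterers
#'
#' A change of incidence angle dalpha shifts the round-trip phase difference
#' between two scatterers separated by D12:
#' `dOP = 2 * (2*pi/lambda) * RI * D12 * dalpha`.
#' Linear in every argument.
#'
#' @param dalpha Angle change (radians, in-sample).
#' @param D12 Scatterer separation (um), signed.
#' @param lambda_um Wavelength (um).
#' @param ri Refractive index.
#' @return Phase shift (radians).
#' @export
phase_shift_from_angle <- function(dalpha, D12, lambda_um, ri = 1) {
  stopifnot(lambda_um > 0)
  2 * (2 * pi / lambda_um) * ri * D12 * dalpha
}

#' Phase-averaged mean of the two-scatterer amplitude
#'
#' Uniformly averaging the two-scatterer amplitude over one full period of
#' the phase difference gives `(4/pi) * A1` (about 1.27*A1), independent of
#' the initial phase. This is the stabilised pixel value that angular
#' compounding converges to.
#'
#' @param A1 Reference amplitude, >= 0.
#' @return `(4/pi) * A1`.
#' @export
phase_averaged_mean <- function(A1 = 1) {
  stopifnot(all(A1 >= 0))
  (4 / pi) * A1
}

#' Spread of the un-averaged two-scatterer amplitude
#'
#' Standard deviation of `|S| = sqrt(2) A1 sqrt(1 + cos(phi))` under a
#' uniformly distributed phase difference: `A1 * sqrt(2 - 16/pi^2)`
#' (about 0.62*A1). This is the speckle spread a single angle exhibits
#' before any averaging.
#'
#' @param A1 Reference amplitude, >= 0.
#' @return `A1 * sqrt(2 - 16/pi^2)`.
#' @export
phase_averaged_std <- function(A1 = 1) {
  stopifnot(all(A1 >= 0))
  A1 * sqrt(2 - 16 / pi^2)
}

#' Scatterer content of one voxel
#'
#' Amplitudes, initial phase differences and signed axial-projected
#' distances of the N scatterers in a voxel, all relative to the first
#' scatterer (whose entries are fixed at 0). The sign of a distance is
#' positive if a positive angle change decreases the phase difference.
#'
#' @param amplitudes Non-negative amplitudes, length N >= 1.
#' @param phase_diffs Initial phase differences dP_1n (radians); first
#'   element forced to 0.
#' @param distances Signed separations D_1n (um); first element forced to 0.
#' @return An object of class `voxel_scatterers`.
#' @export
voxel_scatterers <- function(amplitudes, phase_diffs = NULL, distances = NULL) {
  n <- length(amplitudes)
  stopifnot(n >= 1, all(amplitudes >= 0))
  if (is.null(phase_diffs)) phase_diffs <- numeric(n)
  if (is.null(distances)) distances <- numeric(n)
  stopifnot(length(phase_diffs) == n, length(distances) == n)
  phase_diffs[1] <- 0
  distances[1] <- 0
  structure(list(A = as.numeric(amplitudes),
                 dP = as.numeric(phase_diffs),
                 D = as.numeric(distances)),
            class = "voxel_scatterers")
}

#' Coherent multi-scatterer voxel signal under an angle change
#'
#' `|S(dalpha)| = |sum_n A_n exp(-i 2 dP_1n) exp(-i 2 k RI D_1n dalpha)|`.
#' Reduces to A1 for a single scatterer; bounded by sum(A_n).
#'
#' @param v A [voxel_scatterers()].
#' @param dalpha Angle change (radians); vectorised.
#' @param lambda_um Wavelength (um).
#' @param ri Refractive index.
#' @return `|S|` for each angle change.
#' @export
multi_scatterer_signal <- function(v, dalpha, lambda_um, ri = 1) {
  stopifnot(inherits(v, "voxel_scatterers"))
  k <- 2 * pi / lambda_um
  vapply(dalpha, function(a) {
    Mod(sum(v$A * exp(-1i * 2 * v$dP) * exp(-1i * 2 * k * ri * v$D * a)))
  }, numeric(1))
}

#' Mean voxel signal over a finite set of angle changes
#'
#' Averages [multi_scatterer_signal()] over the supplied angle changes,
#' mirroring the experimental practice of compounding a finite angle set
#' rather than integrating over the full (possibly very long) period.
#'
#' @param v A [voxel_scatterers()].
#' @param angle_changes Non-empty vector of angle changes (radians).
#' @param lambda_um Wavelength (um).
#' @param ri Refractive index.
#' @return Mean amplitude over the angle set.
#' @export
angle_ensemble_mean <- function(v, angle_changes, lambda_um, ri = 1) {
  stopifnot(length(angle_changes) >= 1)
  mean(multi_scatterer_signal(v, angle_changes, lambda_um, ri))
}
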