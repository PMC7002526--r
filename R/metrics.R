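#' High-frequency mask specification
#'
#' The high-frequency ratio R_HF removes a small central (low-frequency)
#' block from the centred spectrum; its width and height are given as
#' fractions of the spectrum dimensions. Defaults are the midpoints of the
#' working ranges: width 2/100, height 5/100.
#'
#' @param width_fraction Central block width / spectrum width, in (0, 0.5).
#' @param height_fraction Central block height / spectrum height.
#' @param axis_mode `"both"` for the 2-D spectrum, `"horizontal"` for
#'   per-row 1-D spectra (used when only lateral sharpness matters, e.g.
#'   digital focusing).
#' @return An object of class `hf_mask_spec`.
#' @export
hf_mask_spec <- function(width_fraction = 0.02, height_fraction = 0.05,
                         axis_mode = c("both", "horizontal")) {
  stopifnot(width_fraction > 0, width_fraction < 0.5,
            height_fraction > 0, height_fraction < 0.5)
  structure(list(width_fraction = width_fraction,
                 height_fraction = height_fraction,
                 axis_mode = match.arg(axis_mode)),
            class = "hf_mask_spec")
}

# indices of the excluded central band of length n for a fraction f
central_band <- function(n, f) {
  half <- max(0L, floor(n * f / 2))
  c0 <- floor(n / 2) + 1L  # zero-frequency index after fftshift
  seq(max(1L, c0 - half), min(n, c0 + half))
}

fftshift2 <- function(m) {
  n_r <- nrow(m); n_c <- ncol(m)
  m[c(seq(floor(n_r / 2) + 1, n_r), seq_len(floor(n_r / 2))),
    c(seq(floor(n_c / 2) + 1, n_c), seq_len(floor(n_c / 2)))]
}

#' High-frequency spectral energy ratio R_HF
#'
#' Ratio of the summed magnitude of the centred Fourier spectrum outside a
#' small central low-frequency block to the total:
#' `R_HF = sum_HF |FT(CI)| / sum_All |FT(CI)|`. Sharper, better-registered
#' images put more energy outside the block, so R_HF is maximised when
#' registration / focusing are correct. Invariant to intensity scaling and
#' to spatial shifts.
#'
#' @param image Magnitude matrix.
#' @param spec An [hf_mask_spec()].
#' @return Ratio in `[0, 1]`.
#' @export
r_hf <- function(image, spec = hf_mask_spec()) {
  stopifnot(length(image) > 0)
  if (all(image == 0)) stop("all-zero image: R_HF undefined")
  if (spec$axis_mode == "horizontal") {
    sp <- Mod(t(mvfft(t(image))))  # 1-D FFT along rows
    sp <- sp[, c(seq(floor(ncol(sp) / 2) + 1, ncol(sp)),
                 seq_len(floor(ncol(sp) / 2))), drop = FALSE]
    lf <- sum(sp[, central_band(ncol(sp), spec$width_fraction)])
  } else {
    sp <- Mod(fftshift2(fft(image)))
    lf <- sum(sp[central_band(nrow(sp), spec$height_fraction),
                 central_band(ncol(sp), spec$width_fraction)])
  }
  1 - lf / sum(sp)
}

#' Segment beads from background by the top-10% rule
#'
#' At each depth row, the weakest intensity among the row's top 10%
#' brightest pixels is the threshold: pixels at or above it are signal
#' (beads), the rest background. Rows narrower than 10 px fall back to the
#' global image threshold.
#'
#' @param image Magnitude matrix (rows indexed by depth).
#' @param top_fraction Brightest fraction defining the threshold.
#' @return List of logical matrices `signal` and `background`.
#' @export
segment_beads <- function(image, top_fraction = 0.1) {
  n_u <- ncol(image)
  sig <- matrix(FALSE, nrow(image), n_u)
  global_thr <- {
    k <- max(1L, ceiling(top_fraction * length(image)))
    min(sort(as.numeric(image), decreasing = TRUE)[seq_len(k)])
  }
  for (i in seq_len(nrow(image))) {
    row <- image[i, ]
    thr <- if (n_u < 10) {
      global_thr
    } else {
      k <- max(1L, ceiling(top_fraction * n_u))
      min(sort(row, decreasing = TRUE)[seq_len(k)])
    }
    sig[i, ] <- row >= thr
  }
  list(signal = sig, background = !sig)
}

#' Background STD versus number of compounded angles
#'
#' Standard deviation over a region of the running k-angle composite
#' (mean of the first k images), k = 1..N, normalised by the single-image
#' value. For identical images the curve is flat at 1; for independent
#' speckle it follows 1/sqrt(k).
#'
#' @param images List of magnitude matrices on a common grid.
#' @param region Logical mask (or index vector) selecting the background
#'   region; default everything.
#' @return Numeric vector of length N, first element 1.
#' @export
std_reduction_curve <- function(images, region = NULL) {
  stopifnot(length(images) >= 2)
  if (is.null(region)) region <- rep(TRUE, length(images[[1]]))
  acc <- images[[1]] * 0
  out <- numeric(length(images))
  for (k in seq_along(images)) {
    acc <- acc + images[[k]]
    out[k] <- sd((acc / k)[region])
  }
  out / out[1]
}

#' Relative standard deviation (STD/Mean) over a region
#'
#' The standard speckle-contrast measure: fully developed (Rayleigh)
#' amplitude speckle gives sqrt(4/pi - 1) = 0.52; compounding lowers it.
#'
#' @param image Magnitude matrix.
#' @param mask Logical mask (default everything).
#' @return STD/Mean (dimensionless); errors on zero mean.
#' @export
relative_std <- function(image, mask = NULL) {
  vals <- if (is.null(mask)) as.numeric(image) else image[mask]
  stopifnot(length(vals) > 0)
  m <- mean(vals)
  if (m == 0) stop("zero mean over the region: relative STD undefined")
  sd(vals) / m
}

#' Bead-to-background contrast
#'
#' `contrast = signal_mean / background_mean - 1`.
#'
#' @param signal_mean Mean intensity over the feature.
#' @param background_mean Mean intensity over the background, > 0.
#' @return Dimensionless contrast.
#' @export
contrast_ratio <- function(signal_mean, background_mean) {
  stopifnot(background_mean > 0)
  signal_mean / background_mean - 1
}

#' Contrast-to-noise ratio in dB
#'
#' `CNR = 20 log10((signal_mean - background_mean) / background_std)`,
#' an amplitude-ratio convention: values are comparable within this
#' package.
#'
#' @param signal_mean,background_mean Mean magnitudes.
#' @param background_std Background magnitude SD, > 0.
#' @return CNR in dB; `-Inf` when the signal does not exceed background.
#' @export
cnr_db <- function(signal_mean, background_mean, background_std) {
  stopifnot(background_std > 0)
  num <- signal_mean - background_mean
  ifelse(num <= 0, -Inf, 20 * log10(num / background_std))
}

#' Full width at half maximum of a 1-D profile
#'
#' Baseline is the median of the outer quartiles of the profile; the width
#' is measured at half of (max - baseline) with linear interpolation of the
#' two crossings around the (unique) maximum.
#'
#' @param profile Numeric samples with a single peak above baseline.
#' @param pitch Sample spacing (um).
#' @return FWHM (um).
#' @export
fwhm <- function(profile, pitch = 1) {
  n <- length(profile)
  stopifnot(n >= 5)
  q <- max(1L, n %/% 4)
  baseline <- median(c(head(profile, q), tail(profile, q)))
  pk <- which.max(profile)
  half <- baseline + (profile[pk] - baseline) / 2
  if (profile[pk] <= baseline) stop("profile has no peak above baseline")
  cross <- function(idx) {
    # linear interpolation between the last sample below `half` and the
    # first at/above it
    i0 <- idx[1]; i1 <- idx[2]
    i0 + (half - profile[i0]) / (profile[i1] - profile[i0]) * (i1 - i0)
  }
  left <- {
    below <- which(profile[seq_len(pk)] < half)
    if (!length(below)) 1 else cross(c(max(below), max(below) + 1))
  }
  right <- {
    below <- which(profile[pk:n] < half) + pk - 1
    if (!length(below)) n else cross(c(min(below), min(below) - 1))
  }
  (right - left) * pitch
}
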