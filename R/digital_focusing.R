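#' Lateral point spread function at one depth
#'
#' Samples the system response of a point scatterer across the scan
#' direction u at fixed depth row v, for on-axis (d = 0) incidence: the
#' Gaussian beam amplitude envelope and the round-trip phase of the
#' wavefront curvature,
#' `PSF(du) = A(du) exp(-i 2 k RI lat(du))` with
#' `A = (w0/w_b) exp(-dx^2/w_b^2)`, `lat = dx^2 y' / (2 (y'^2 + R_y^2))`,
#' `dx = p_u du`, `y' = (v - v_f) p_v / RI`. The kernel is truncated where
#' the amplitude falls below `trunc` of its maximum. The phase sign follows
#' the detected-signal convention (`exp(-i k 2 r)`), so the conjugate
#' filter compresses the data chirp.
#'
#' @param v Depth row (1-based, fractional allowed).
#' @param geometry A [beam_geometry()].
#' @param v_f Focus row.
#' @param ri Sample refractive index.
#' @param trunc Relative amplitude truncation threshold.
#' @return Complex kernel (odd length, centred), with attribute `half`
#'   (half-width in pixels).
#' @export
build_psf <- function(v, geometry, v_f, ri = geometry$ri, trunc = 1e-3) {
  mb <- medium_beam(geometry, ri)
  yp <- (v - v_f) * geometry$p_v / ri
  wb <- mb$w0 * sqrt(1 + (yp / mb$ry)^2)
  half <- max(1L, as.integer(ceiling(wb * sqrt(log(1 / trunc)) / geometry$p_u)))
  du <- seq(-half, half)
  dx <- geometry$p_u * du
  amp <- (mb$w0 / wb) * exp(-dx^2 / wb^2)
  lat <- dx^2 * yp / (2 * (yp^2 + mb$ry^2))
  kern <- amp * exp(-1i * 2 * geometry$k0 * ri * lat)
  attr(kern, "half") <- half
  kern
}

#' Matched filter from a PSF kernel
#'
#' The matched filter is the complex conjugate of the PSF; with
#' `normalize = TRUE` it is scaled by 1/max of the PSF amplitude over the
#' depth row, so the filter peak magnitude is 1 at every depth (the
#' vertical amplitude normalisation).
#'
#' @param psf Complex kernel from [build_psf()].
#' @param normalize Apply the 1/max(A) scaling.
#' @return Complex kernel, same support.
#' @export
build_matched_filter <- function(psf, normalize = TRUE) {
  m <- max(Mod(psf))
  if (m == 0) stop("zero PSF kernel")
  out <- Conj(psf)
  if (normalize) out <- out / m
  attr(out, "half") <- attr(psf, "half")
  out
}

#' Phase-only (unity spectral magnitude) variant of a filter
#'
#' `MF_U = FT^-1 { exp(i Phase(FT(MF))) }`: keeps the spectral phase of the
#' matched filter but flattens its Gaussian spectral envelope to unit
#' magnitude at all frequencies (zero-magnitude bins get phase 0). Sharper
#' than MF but amplifies high-frequency noise.
#'
#' @param mf Complex kernel.
#' @return Complex kernel of the same length with `|FT| = 1` at all bins.
#' @export
unity_magnitude_filter <- function(mf) {
  if (all(Mod(mf) == 0)) stop("zero filter kernel")
  ft <- fft(mf)
  ph <- Arg(ft)
  ph[Mod(ft) == 0] <- 0
  out <- fft(exp(1i * ph), inverse = TRUE) / length(mf)
  attr(out, "half") <- attr(mf, "half")
  out
}

#' Depth-dependent matched filter bank
#'
#' Builds one matched-filter kernel per depth row, for on-axis incidence
#' (the same bank is applied to every angular image before registration),
#' and caches their padded FFTs for row-wise frequency-domain convolution.
#'
#' @param geometry A [beam_geometry()].
#' @param n_v Number of depth rows.
#' @param v_f Focus row.
#' @param n_u Image width the bank will be applied to.
#' @param ri Sample refractive index.
#' @param variant `"mf"` (amplitude-weighted matched filter) or `"mfu"`
#'   (phase-only unity-magnitude variant).
#' @param trunc Kernel truncation threshold.
#' @return An object of class `mf_bank`.
#' @export
matched_filter_bank <- function(geometry, n_v, v_f, n_u,
                                ri = geometry$ri, variant = c("mf", "mfu"),
                                trunc = 1e-3) {
  variant <- match.arg(variant)
  halves <- integer(n_v)
  kerns <- vector("list", n_v)
  for (v in seq_len(n_v)) {
    psf <- build_psf(v, geometry, v_f, ri, trunc)
    kerns[[v]] <- build_matched_filter(psf)
    halves[v] <- attr(psf, "half")
  }
  npad <- 2^ceiling(log2(n_u + 2 * max(halves) + 1))
  kfft <- matrix(0i, npad, n_v)
  for (v in seq_len(n_v)) {
    k <- kerns[[v]]; h <- halves[v]
    pad <- complex(npad)
    pad[1] <- k[h + 1]
    if (h > 0) {
      pad[1 + seq_len(h)] <- k[h + 1 + seq_len(h)]
      pad[npad - h + seq_len(h)] <- k[seq_len(h)]
    }
    kfft[, v] <- fft(pad)
  }
  if (variant == "mfu") {
    ph <- Arg(kfft)
    ph[Mod(kfft) == 0] <- 0
    kfft <- exp(1i * ph)
  }
  structure(list(kfft = kfft, npad = npad, n_v = as.integer(n_v),
                 n_u = as.integer(n_u), v_f = v_f, variant = variant,
                 halves = halves, geometry = geometry, ri = ri),
            class = "mf_bank")
}

# Row-wise frequency-domain convolution of one complex image with the bank,
# with an optional integer vertical offset of the bank (kernel for row v
# taken from bank row v - offset, clamped at the ends).
apply_bank_matrix <- function(img, bank, depth_offset = 0) {
  n_v <- nrow(img); n_u <- ncol(img)
  if (n_v != bank$n_v || n_u > bank$npad) {
    stop("image axes do not match the filter bank")
  }
  pad <- matrix(0i, bank$npad, n_v)
  pad[seq_len(n_u), ] <- t(img)
  sp <- mvfft(pad)
  rows <- pmin(pmax(seq_len(n_v) - depth_offset, 1), bank$n_v)
  sp <- sp * bank$kfft[, rows]
  out <- mvfft(sp, inverse = TRUE) / bank$npad
  t(out[seq_len(n_u), , drop = FALSE])
}

#' Digitally refocus complex OCT data
#'
#' Convolves every depth row of the complex image(s) with its depth-matched
#' filter in the frequency domain (`conv_u = FT_u^-1[FT_u(MF) FT_u(OCT)]`),
#' with zero-padding against wrap-around. Output has the input shape.
#'
#' @param x A complex matrix (n_v x n_u), or an `oct_stack` (each repeat is
#'   processed).
#' @param bank A [matched_filter_bank()].
#' @param depth_offset Integer vertical fine adjustment of the bank (px),
#'   e.g. from [refine_filter_depth()].
#' @return Same type as the input.
#' @export
apply_digital_focusing <- function(x, bank, depth_offset = 0) {
  if (inherits(x, "oct_stack")) {
    for (r in seq_len(dim(x$data)[3])) {
      x$data[, , r] <- apply_bank_matrix(x$data[, , r], bank, depth_offset)
    }
    return(x)
  }
  apply_bank_matrix(x, bank, depth_offset)
}

#' Vertical fine adjustment of the filter bank
#'
#' The air-sample interface shifts the focal plane, so the nominal focus
#' row of the bank may be off by a few pixels. This searches integer bank
#' offsets and returns the one maximising the horizontal-only
#' high-frequency ratio of the refocused magnitude (digital focusing only
#' sharpens horizontally, so the Fourier transform is taken along u only).
#'
#' The objective is always evaluated with the phase-only (unity spectral
#' magnitude) version of the bank: the Gaussian spectral envelope of the
#' amplitude-weighted MF gives depth rows a gain that varies monotonically
#' with the bank offset and swamps the phase-match signal, whereas the
#' phase-only spectrum isolates chirp correctness. The returned offset is
#' then applied to whichever variant the bank carries.
#'
#' @param img Complex matrix (one B-scan), typically at d = 0.
#' @param bank A [matched_filter_bank()].
#' @param search_range Non-negative integer; offsets `-search_range ...
#'   search_range` are tried.
#' @param hf An [hf_mask_spec()]; forced to horizontal-only mode.
#' @return List `offset` (the arg-max) and `r_hf` (per-offset values).
#' @export
refine_filter_depth <- function(img, bank, search_range = 6,
                                hf = hf_mask_spec()) {
  stopifnot(search_range >= 0)
  hf$axis_mode <- "horizontal"
  sbank <- bank
  if (bank$variant != "mfu") {
    ph <- Arg(sbank$kfft)
    ph[Mod(sbank$kfft) == 0] <- 0
    sbank$kfft <- exp(1i * ph)
  }
  offs <- seq(-search_range, search_range)
  score <- vapply(offs, function(o) {
    r_hf(Mod(apply_bank_matrix(img, sbank, o)), hf)
  }, numeric(1))
  list(offset = offs[which.max(score)], r_hf = score)
}
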