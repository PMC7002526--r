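#' Geometric pixel-to-physical registration model
#'
#' Maps pixels `(u, v)` of one angular image to physical space `(x, z)`.
#' Column u is a ray entering the sample at
#' `x_e(u) = x_e0 + p_u (u - u_f) + q (u - u_f)^2`, refracted to the
#' in-sample angle `alpha_s`; pixel v sits at geometric distance
#' `s = p_v (v - v_surf(u)) / RI` along the ray beyond the detected
#' surface; then `x = x_e + s sin(alpha_s)`, `z = z_surf + s cos(alpha_s)`.
#' The anchor `x_e0` is chosen so the ray of the focus column passes
#' through the physical focus, which is shared by all offsets and acts as
#' the angle-independent reference point. The quadratic coefficient q stems
#' from the galvo mirror not sitting in the lens back focal plane; the
#' model realises translation, scaling, rotation and quadratic deformation.
#'
#' @param geometry A [beam_geometry()].
#' @param inc An [incidence_config()] for this offset.
#' @param u_f,v_f Focus pixel (1-based, fractional allowed).
#' @param n_u,n_v Source image dimensions.
#' @param v_surf Detected surface row per column (vector length n_u, or a
#'   scalar for a flat surface).
#' @param ri Sample refractive index.
#' @param surface_z Physical height of the surface (um); the depth datum.
#' @param x_f Physical lateral position of the focus (um). This is a gauge
#'   choice (a common lateral datum for all offsets); default 0.
#' @return An object of class `registration_model`.
#' @export
registration_model <- function(geometry, inc, u_f, v_f, n_u, n_v,
                               v_surf, ri = geometry$ri, surface_z = 0,
                               x_f = 0) {
  stopifnot(length(v_surf) %in% c(1L, n_u))
  sa <- sin(inc$alpha_s); ca <- cos(inc$alpha_s)
  v_surf <- rep_len(as.numeric(v_surf), n_u)
  v_surf_uf <- stats::approx(seq_len(n_u), v_surf, xout = u_f, rule = 2)$y
  s_f <- geometry$p_v * (v_f - v_surf_uf) / ri
  q <- (geometry$galvo_lens_distance - geometry$f) *
    geometry$p_u^2 / (2 * geometry$f^2)
  m <- list(u_f = u_f, v_f = v_f, n_u = as.integer(n_u),
            n_v = as.integer(n_v), p_u = geometry$p_u, p_v = geometry$p_v,
            q = q, sin_as = sa, cos_as = ca, ri = ri,
            surface_z = surface_z, v_surf = v_surf, s_f = s_f,
            x_f = x_f, z_f = surface_z + s_f * ca,
            x_e0 = x_f - s_f * sa, alpha = inc$alpha, d = inc$d)
  class(m) <- "registration_model"
  m
}

# Surface row at (possibly fractional) column positions.
v_surf_at <- function(model, u) {
  stats::approx(seq_len(model$n_u), model$v_surf, xout = u, rule = 2)$y
}

#' Forward mapping of a registration model
#'
#' @param model A [registration_model()].
#' @param u,v Pixel coordinates (vectors, recycled).
#' @return List of vectors `x`, `z` (um).
#' @export
map_forward <- function(model, u, v) {
  du <- u - model$u_f
  xe <- model$x_e0 + model$p_u * du + model$q * du^2
  s <- model$p_v * (v - v_surf_at(model, u)) / model$ri
  list(x = xe + s * model$sin_as, z = model$surface_z + s * model$cos_as)
}

#' Inverse mapping of a registration model
#'
#' Solves the quadratic column equation with the numerically stable root
#' adjacent to the linear solution; errors if the model is not invertible
#' over the requested points.
#'
#' @param model A [registration_model()].
#' @param x,z Physical coordinates (um; vectors or matrices of equal shape).
#' @return List `u`, `v` of pixel coordinates (same shape as input).
#' @export
map_inverse <- function(model, x, z) {
  s <- (z - model$surface_z) / model$cos_as
  xe_need <- x - s * model$sin_as
  delta <- xe_need - model$x_e0
  disc <- model$p_u^2 + 4 * model$q * delta
  if (any(disc <= 0)) {
    stop("registration model is not invertible over the requested extent")
  }
  t <- if (abs(model$q) < 1e-15) {
    delta / model$p_u
  } else {
    2 * delta / (model$p_u + sqrt(disc))
  }
  u <- model$u_f + t
  v <- v_surf_at(model, u) + model$ri * s / model$p_v
  if (is.matrix(x)) {
    u <- matrix(u, nrow(x), ncol(x)); v <- matrix(v, nrow(x), ncol(x))
  }
  list(u = u, v = v)
}

# Bilinear interpolation of a (possibly complex) image at fractional pixel
# coordinates; coordinates must have all four neighbours in-domain.
bilinear_sample <- function(img, v, u) {
  fv <- floor(v); fu <- floor(u)
  wv <- v - fv; wu <- u - fu
  idx <- function(dv, du) img[cbind(fv + dv, fu + du)]
  idx(0, 0) * (1 - wv) * (1 - wu) + idx(1, 0) * wv * (1 - wu) +
    idx(0, 1) * (1 - wv) * wu + idx(1, 1) * wv * wu
}

#' Physical target grid for registration
#'
#' @param x,z Node coordinate vectors (um), ascending.
#' @return A list of class `oct_grid`.
#' @export
oct_grid <- function(x, z) {
  structure(list(x = as.numeric(x), z = as.numeric(z)), class = "oct_grid")
}

#' Resample an angular image onto a physical grid
#'
#' Evaluates the inverse mapping at every grid node and samples the image
#' bilinearly. A node is valid only if all four source-pixel neighbours are
#' inside the image.
#'
#' @param image Magnitude (or complex) matrix, n_v x n_u.
#' @param model A [registration_model()].
#' @param grid An [oct_grid()]; rows of the output correspond to `grid$z`,
#'   columns to `grid$x`.
#' @return List with `values` (matrix, 0 where invalid) and `valid`
#'   (logical matrix).
#' @export
register_image <- function(image, model, grid) {
  nz <- length(grid$z); nx <- length(grid$x)
  zz <- matrix(grid$z, nz, nx)
  xx <- matrix(grid$x, nz, nx, byrow = TRUE)
  uv <- map_inverse(model, xx, zz)
  valid <- uv$u >= 1 & uv$u <= ncol(image) - 1 + 1e-9 &
    uv$v >= 1 & uv$v <= nrow(image) - 1 + 1e-9
  # clamp so floor()+1 stays in range on the boundary
  u <- pmin(pmax(uv$u, 1), ncol(image) - 1e-9)
  v <- pmin(pmax(uv$v, 1), nrow(image) - 1e-9)
  vals <- matrix(if (is.complex(image)) 0i else 0, nz, nx)
  if (any(valid)) {
    vals[valid] <- bilinear_sample(image, v[valid], u[valid])
  }
  list(values = vals, valid = valid)
}

#' Fuse registered angular images into a composite
#'
#' Per-pixel mean of the magnitudes over the contributing (valid) angles;
#' the per-pixel contributing count is recorded and count-zero pixels are
#' flagged invalid.
#'
#' @param registered List of outputs of [register_image()].
#' @param grid The [oct_grid()] the images were registered to.
#' @return An object of class `oct_composite` with `magnitude`, `count`,
#'   `x`, `z`.
#' @export
fuse_images <- function(registered, grid = NULL) {
  stopifnot(length(registered) >= 1)
  acc <- 0; cnt <- 0
  for (r in registered) {
    acc <- acc + r$values * r$valid
    cnt <- cnt + r$valid
  }
  mag <- acc / pmax(cnt, 1)
  mag[cnt == 0] <- NA_real_
  structure(list(magnitude = mag, count = cnt,
                 x = if (is.null(grid)) NULL else grid$x,
                 z = if (is.null(grid)) NULL else grid$z),
            class = "oct_composite")
}

#' Detect the sample surface in a magnitude image
#'
#' Per column, the surface is the first depth at which the axially smoothed
#' intensity exceeds half the column maximum; columns whose maximum does not
#' stand out from the image background (peak < `peak_factor` x image
#' median) yield no crossing and are interpolated from their neighbours.
#' The per-column estimates are then median-smoothed across columns.
#'
#' @param image Magnitude matrix (depth x scan).
#' @param smooth_v Axial boxcar half-width (px) applied before thresholding.
#' @param smooth_u Across-column running-median half-width (px).
#' @param peak_factor Peak-to-background validation factor.
#' @return Integer vector of surface rows, one per column.
#' @export
detect_surface <- function(image, smooth_v = 1, smooth_u = 2,
                           peak_factor = 4) {
  n_v <- nrow(image); n_u <- ncol(image)
  bg <- median(image)
  kern <- rep(1, 2 * smooth_v + 1) / (2 * smooth_v + 1)
  surf <- rep(NA_real_, n_u)
  for (j in seq_len(n_u)) {
    col <- image[, j]
    if (smooth_v > 0) {
      col <- as.numeric(stats::filter(col, kern, sides = 2))
      col[is.na(col)] <- image[, j][is.na(col)]
    }
    m <- max(col)
    if (!(m > peak_factor * bg)) next
    hit <- which(col >= 0.5 * m)
    if (length(hit)) surf[j] <- hit[1]
  }
  if (sum(!is.na(surf)) < max(3, 0.2 * n_u)) {
    stop("no surface detected: no column shows an air-sample transition")
  }
  if (stats::IQR(surf, na.rm = TRUE) > 15) {
    stop("no surface detected: candidate crossings are inconsistent across columns")
  }
  # reject outliers, interpolate gaps, smooth across columns
  med <- median(surf, na.rm = TRUE)
  surf[!is.na(surf) & abs(surf - med) > 12] <- NA
  if (anyNA(surf)) {
    ok <- which(!is.na(surf))
    surf <- stats::approx(ok, surf[ok], xout = seq_len(n_u), rule = 2)$y
  }
  if (smooth_u > 0) {
    surf <- stats::runmed(surf, 2 * smooth_u + 1, endrule = "keep")
  }
  as.integer(round(surf))
}

#' Correct vertical bulk motion across angular images
#'
#' Environmental vibration can shift the sample by a few pixels between
#' angular acquisitions. The shift of each angular image is estimated as
#' the rounded median offset of its detected surface from the across-set
#' reference, and removed by integer vertical translation of the image
#' (and, when present, of the underlying complex stack).
#'
#' @param aset An `oct_angular_set` (see [run_preparation()]).
#' @param max_shift Warn when an estimated shift exceeds this bound (px).
#' @return The aligned set, with a `shifts` element (integer per image).
#' @export
correct_bulk_motion <- function(aset, max_shift = 10) {
  stopifnot(inherits(aset, "oct_angular_set"))
  surfs <- lapply(aset$images, detect_surface)
  meds <- vapply(surfs, median, numeric(1))
  ref <- median(meds)
  shifts <- as.integer(round(meds - ref))
  if (any(abs(shifts) > max_shift)) {
    warning(sprintf("bulk-motion shift exceeds %d px", max_shift))
  }
  roll_rows <- function(mat, by) {
    # shift content up by `by` rows (remove a +by surface offset)
    if (by == 0) return(mat)
    out <- mat * 0
    n <- nrow(mat)
    if (by > 0) out[seq_len(n - by), ] <- mat[seq_len(n - by) + by, ]
    if (by < 0) out[seq_len(n + by) - by, ] <- mat[seq_len(n + by), ]
    out
  }
  for (i in seq_along(aset$images)) {
    if (shifts[i] != 0) {
      aset$images[[i]] <- roll_rows(aset$images[[i]], shifts[i])
      if (!is.null(aset$stacks)) {
        st <- aset$stacks[[i]]
        for (r in seq_len(dim(st$data)[3])) {
          st$data[, , r] <- roll_rows(st$data[, , r], shifts[i])
        }
        aset$stacks[[i]] <- st
      }
    }
  }
  aset$shifts <- shifts
  aset
}

#' Estimate the focus pixel of an angular set
#'
#' Coarse stage: the focus column is taken from the equal-surface-distance
#' criterion (the column minimising the across-angle spread of the detected
#' surfaces; with flat, motion-corrected surfaces this is a gauge choice
#' and falls back to `u_init` / the image centre). Fine stage: grid search
#' over candidate focus rows (and optionally columns), maximising the
#' high-frequency ratio R_HF of the trial composite: misplacing the focus
#' row misaligns the angular images laterally in proportion to
#' `sin(alpha_s)`, blurring the composite and lowering R_HF.
#'
#' @param aset An `oct_angular_set` with at least 3 images.
#' @param v_init Initial guess for the focus row; defaults to mid-depth.
#' @param u_init Initial guess for the focus column; defaults to the coarse
#'   estimate.
#' @param v_search,u_search Integer offsets searched around the guesses.
#' @param hf An [hf_mask_spec()] used for the R_HF objective.
#' @param grid Optional [oct_grid()] for the trial composites.
#' @return List `u_f`, `v_f`, `r_hf` (objective at the optimum), and
#'   `surface` (per-image detected surfaces).
#' @export
estimate_focus <- function(aset, v_init = NULL, u_init = NULL,
                           v_search = -6:6, u_search = 0,
                           hf = hf_mask_spec(), grid = NULL) {
  stopifnot(inherits(aset, "oct_angular_set"), length(aset$images) >= 3)
  g <- aset$geometry
  n_v <- nrow(aset$images[[1]]); n_u <- ncol(aset$images[[1]])
  surfs <- lapply(aset$images, detect_surface)
  smat <- do.call(rbind, surfs)
  spread <- apply(smat, 2, stats::var)
  u_coarse <- if (max(spread) - min(spread) < 1e-9) {
    ceiling(n_u / 2)
  } else {
    round(mean(which(spread == min(spread))))
  }
  if (is.null(u_init)) u_init <- u_coarse
  if (is.null(v_init)) v_init <- round(mean(smat) + 0.45 * (n_v - mean(smat)))
  if (is.null(grid)) {
    hw <- floor(n_u * 0.3)
    x <- g$p_u * seq(-hw, hw)
    srow <- mean(smat)
    z <- seq(2 * g$p_v, (n_v - srow - 2) * g$p_v / aset$ri * cos(0),
             by = g$p_v / aset$ri)
    grid <- oct_grid(x, z)
  }
  cand <- expand.grid(du = u_search, dv = v_search)
  score <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    uf <- u_init + cand$du[i]; vf <- v_init + cand$dv[i]
    regs <- lapply(seq_along(aset$images), function(k) {
      inc <- incidence_config(aset$offsets[k], g,
                              focus_physical = c(0, 1))  # anchor unused here
      mod <- registration_model(g, inc, uf, vf, n_u, n_v, surfs[[k]],
                                ri = aset$ri)
      register_image(aset$images[[k]], mod, grid)
    })
    comp <- fuse_images(regs, grid)
    mag <- comp$magnitude
    mag[is.na(mag)] <- 0
    score[i] <- r_hf(mag, hf)
  }
  if (nrow(cand) > 1 && max(score) - min(score) < 1e-10) {
    stop("featureless images: flat R_HF landscape, cannot estimate focus")
  }
  best <- which.max(score)
  list(u_f = u_init + cand$du[best], v_f = v_init + cand$dv[best],
       r_hf = score[best], surfaces = surfs)
}
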