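#' Preparation step: angular images from complex stacks
#'
#' For each offset, averages the magnitudes of the repeated complex B-scans
#' (photon-noise suppression) to form the angular image; the complex stacks
#' are retained for digital focusing.
#'
#' @param stacks List of `oct_stack` objects (one per offset), e.g. from
#'   [simulate_angular_set()] or [read_stack()].
#' @return An object of class `oct_angular_set`: `images` (magnitude
#'   matrices), `stacks`, `offsets`, `geometry`, `acq`, `ri`.
#' @export
run_preparation <- function(stacks) {
  stopifnot(length(stacks) >= 1,
            all(vapply(stacks, inherits, logical(1), "oct_stack")))
  images <- lapply(stacks, function(s) {
    apply(Mod(s$data), c(1, 2), mean)
  })
  structure(list(images = images, stacks = stacks,
                 offsets = vapply(stacks, `[[`, numeric(1), "offset_d"),
                 geometry = stacks[[1]]$geometry, acq = stacks[[1]]$acq,
                 ri = stacks[[1]]$ri),
            class = "oct_angular_set")
}

#' @export
print.oct_angular_set <- function(x, ...) {
  cat(sprintf("OCT angular image set: %d offsets (%s mm), %d x %d px\n",
              length(x$images), paste(range(x$offsets), collapse = " .. "),
              nrow(x$images[[1]]), ncol(x$images[[1]])))
  invisible(x)
}

#' Pipeline options
#'
#' @param digital_focusing Apply matched-filter digital focusing.
#' @param variant Filter variant, `"mf"` or `"mfu"`.
#' @param refine_range Search range (px) for the vertical filter-bank
#'   adjustment; 0 disables refinement.
#' @param v_search,u_search Focus grid-search offsets, see
#'   [estimate_focus()].
#' @param v_init Initial focus-row guess (optional).
#' @param hf An [hf_mask_spec()].
#' @param grid Optional [oct_grid()] for the composite.
#' @param max_shift Bulk-motion warning bound (px).
#' @return List of class `oct_pipeline_options`.
#' @export
pipeline_options <- function(digital_focusing = TRUE,
                             variant = c("mf", "mfu"),
                             refine_range = 4, v_search = -6:6,
                             u_search = 0, v_init = NULL,
                             hf = hf_mask_spec(), grid = NULL,
                             max_shift = 10) {
  structure(list(digital_focusing = digital_focusing,
                 variant = match.arg(variant), refine_range = refine_range,
                 v_search = v_search, u_search = u_search, v_init = v_init,
                 hf = hf, grid = grid, max_shift = max_shift),
            class = "oct_pipeline_options")
}

#' Run the full angular-compounding pipeline
#'
#' Executes the four-step flow on a set of per-offset complex stacks:
#' (1) preparation (magnitude averaging over repeats), (2) surface
#' detection, bulk-motion correction and focus estimation (coarse
#' equal-surface-distance + R_HF grid search), (3) matched-filter digital
#' focusing of every complex B-scan (with vertical bank refinement),
#' (4) registration of the angular images to physical space and fusion
#' into the composite. Deterministic for fixed inputs.
#'
#' @param stacks List of `oct_stack` objects, one per offset.
#' @param options A [pipeline_options()].
#' @return List of class `oct_pipeline_result`: `composite`
#'   (an `oct_composite`), `report` (focus pixel, shifts, filter offset,
#'   R_HF before/after, background metrics), and `grid`.
#' @export
run_pipeline <- function(stacks, options = pipeline_options()) {
  if (length(stacks) == 0) stop("no input stacks")
  aset <- run_preparation(stacks)
  aset <- correct_bulk_motion(aset, options$max_shift)
  foc <- estimate_focus(aset, v_init = options$v_init,
                        v_search = options$v_search,
                        u_search = options$u_search, hf = options$hf,
                        grid = options$grid)
  g <- aset$geometry
  n_v <- nrow(aset$images[[1]]); n_u <- ncol(aset$images[[1]])
  depth_offset <- 0L
  if (options$digital_focusing) {
    bank <- matched_filter_bank(g, n_v, foc$v_f, n_u, aset$ri,
                                options$variant)
    if (options$refine_range > 0) {
      i0 <- which.min(abs(aset$offsets))
      ref_img <- aset$stacks[[i0]]$data[, , 1]
      depth_offset <- refine_filter_depth(ref_img, bank,
                                          options$refine_range,
                                          options$hf)$offset
    }
    for (i in seq_along(aset$stacks)) {
      st <- apply_digital_focusing(aset$stacks[[i]], bank, depth_offset)
      aset$stacks[[i]] <- st
      aset$images[[i]] <- apply(Mod(st$data), c(1, 2), mean)
    }
  }
  grid <- options$grid
  if (is.null(grid)) {
    srow <- mean(vapply(foc$surfaces, median, numeric(1)))
    hw <- floor(n_u * 0.35)
    grid <- oct_grid(g$p_u * seq(-hw, hw),
                     seq(2 * g$p_v, (n_v - srow - 2) * g$p_v / aset$ri,
                         by = g$p_v / aset$ri))
  }
  regs <- lapply(seq_along(aset$images), function(k) {
    inc <- incidence_config(aset$offsets[k], g)
    mod <- registration_model(g, inc, foc$u_f, foc$v_f, n_u, n_v,
                              foc$surfaces[[k]], ri = aset$ri)
    register_image(aset$images[[k]], mod, grid)
  })
  comp <- fuse_images(regs, grid)
  mag0 <- comp$magnitude
  mag0[is.na(mag0)] <- 0
  i0 <- which.min(abs(aset$offsets))
  single <- regs[[i0]]$values
  report <- list(
    focus = c(u_f = foc$u_f, v_f = foc$v_f),
    shifts = aset$shifts,
    filter_depth_offset = depth_offset,
    variant = if (options$digital_focusing) options$variant else "none",
    r_hf_composite = r_hf(mag0, options$hf),
    r_hf_single = r_hf(single, options$hf),
    n_offsets = length(stacks)
  )
  structure(list(composite = comp, report = report, grid = grid,
                 registered = regs, set = aset),
            class = "oct_pipeline_result")
}

#' Write / read a complex B-scan stack container
#'
#' Self-describing JSON container holding the real and imaginary parts of
#' the stack plus acquisition metadata (offset, pitches, seed, dimensions).
#' Geometry is stored by its constructor arguments so the round trip is
#' lossless.
#'
#' @param stack An `oct_stack`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "oct_stack"))
  g <- stack$geometry
  obj <- list(
    format = "octac-stack-v1",
    dim = dim(stack$data),
    real = as.numeric(Re(stack$data)),
    imag = as.numeric(Im(stack$data)),
    pitch_u = stack$pitch_u, pitch_v = stack$pitch_v,
    offset_d = stack$offset_d, seed = stack$seed,
    noise_level = stack$noise_level, bulk_shift = stack$bulk_shift,
    surface_amp = stack$surface_amp, surface_z = stack$surface_z,
    ri = stack$ri,
    geometry = list(wavelength_um = g$lambda,
                    beam_diameter_mm = g$beam_diameter / 1e3,
                    focal_length_mm = g$f / 1e3,
                    galvo_lens_distance_mm = g$galvo_lens_distance / 1e3,
                    refractive_index = g$ri,
                    axial_resolution_um = g$axial_resolution,
                    scan_step_um = g$p_u, axial_pitch_um = g$p_v,
                    waist_radius_um = g$w0),
    inc = list(d_mm = stack$inc$d,
               focus_physical = stack$inc$focus_physical,
               air_standoff_um = stack$inc$air_standoff),
    acq = list(n_u = stack$acq$n_u, n_v = stack$acq$n_v,
               u_f = stack$acq$u_f, surface_row = stack$acq$surface_row),
    truth = stack$truth
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @param path Input file path.
#' @export
read_stack <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("not a readable octac stack container: ",
                         conditionMessage(e))
                  })
  if (is.null(obj$format) || !identical(obj$format, "octac-stack-v1")) {
    stop("not an octac stack container (missing format tag)")
  }
  if (length(obj$real) != prod(obj$dim)) {
    stop("corrupt stack container: data length does not match dimensions")
  }
  g <- do.call(beam_geometry, as.list(obj$geometry))
  inc <- incidence_config(obj$inc$d_mm, g, obj$inc$focus_physical,
                          obj$inc$air_standoff_um)
  acq <- acquisition(obj$acq$n_u, obj$acq$n_v, obj$acq$u_f,
                     obj$acq$surface_row)
  data <- array(complex(real = obj$real, imaginary = obj$imag),
                dim = obj$dim)
  structure(list(data = data, pitch_u = obj$pitch_u, pitch_v = obj$pitch_v,
                 offset_d = obj$offset_d, seed = obj$seed, geometry = g,
                 inc = inc, acq = acq, noise_level = obj$noise_level,
                 bulk_shift = obj$bulk_shift, surface_amp = obj$surface_amp,
                 surface_z = obj$surface_z, ri = obj$ri,
                 truth = obj$truth),
            class = "oct_stack")
}

#' Export a magnitude image as an ASCII PGM preview
#'
#' Plain-text (P2) portable graymap on a log scale, for quick visual
#' inspection without binary image dependencies.
#'
#' @param image Magnitude matrix.
#' @param path Output `.pgm` path.
#' @param dynamic_range_db Display dynamic range below the maximum.
#' @return `path`, invisibly.
#' @export
write_magnitude_pgm <- function(image, path, dynamic_range_db = 40) {
  image[is.na(image)] <- 0
  mx <- max(image)
  if (mx <= 0) mx <- 1
  db <- 20 * log10(pmax(image, mx * 10^(-dynamic_range_db / 20 - 1)) / mx)
  lev <- round(255 * (db + dynamic_range_db) / dynamic_range_db)
  lev <- pmin(pmax(lev, 0), 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(image), nrow(image)), "255"),
             con)
  write(t(lev), con, ncolumns = ncol(image))
  invisible(path)
}
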