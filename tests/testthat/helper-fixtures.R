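# Shared fixtures. Heavy simulated sets are built once per test run and
# cached; everything is generated in code from fixed seeds.

g_std <- beam_geometry()
RI <- 1.34
OFFSETS <- seq(-2.5, 2.5, by = 0.5)

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 11-offset acquisition of a sparse bead phantom spanning +-300 um about the
# focal plane (z_f = 350 um), with a specular surface line. Used by the
# registration and acceptance tests.
bead_set_fixture <- function(seed = 5) {
  beads <- data.frame(x = c(-30, 20, -10, 35, 0, -25, 15),
                      z = c(55, 155, 255, 350, 455, 560, 645),
                      amp = 2)
  ph <- oct_phantom(beads, extent = list(x = c(-130, 130), z = c(0, 700)),
                    refractive_index = RI)
  n_v <- 20 + ceiling(RI * 690)
  acq <- acquisition(n_u = 185, n_v = n_v, u_f = 93, surface_row = 20)
  stacks <- simulate_angular_set(ph, g_std, OFFSETS, acq,
                                 focus_physical = c(0, 350), n_repeat = 2,
                                 noise_level = 0.02, surface_amp = 5,
                                 seed = seed)
  list(stacks = stacks, phantom = ph, acq = acq, beads = beads, n_v = n_v)
}

# Deep speckle slab (240-340 um below the focal plane at z = 40 um) for the
# compounding-statistics tests: the detection area there is wide, so the
# angular speckle patterns decorrelate (see vignette).
deep_speckle_set_fixture <- function() {
  sp <- make_speckle_phantom(40, extent = list(x = c(-90, 90),
                                               z = c(250, 400)),
                             seed = 7, refractive_index = RI)
  n_v <- 10 + ceiling(RI * 400)
  acq <- acquisition(n_u = 121, n_v = n_v, u_f = 61, surface_row = 10)
  stacks <- suppressWarnings(
    simulate_angular_set(sp, g_std, OFFSETS, acq,
                         focus_physical = c(0, 40), seed = 3))
  grid <- oct_grid(x = g_std$p_u * seq(-40, 40),
                   z = seq(280, 380, by = g_std$p_v / RI))
  regs <- lapply(seq_along(OFFSETS), function(k) {
    inc <- incidence_config(OFFSETS[k], g_std, focus_physical = c(0, 40))
    mod <- registration_model(g_std, inc, u_f = 61,
                              v_f = stacks[[k]]$truth$v_f, n_u = 121,
                              n_v = n_v, v_surf = 10, ri = RI, x_f = 0)
    register_image(Mod(stacks[[k]]$data[, , 1]), mod, grid)
  })
  list(stacks = stacks, regs = regs, grid = grid)
}

# centroid of a registered blob near a nominal physical position
blob_centroid <- function(mat, x0, z0, gx, gz, w = 12) {
  ix <- which.min(abs(gx - x0)); iz <- which.min(abs(gz - z0))
  rr <- max(1, iz - w):min(nrow(mat), iz + w)
  cc <- max(1, ix - w):min(ncol(mat), ix + w)
  m <- mat[rr, cc]
  m[is.na(m)] <- 0
  m <- m - median(m); m[m < 0] <- 0
  c(x = sum(t(m) * gx[cc]) / sum(m), z = sum(m * gz[rr]) / sum(m))
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) < tol,
              label = sprintf("|%g - %g| < %g", object, expected, tol))
}
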