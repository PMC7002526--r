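test_that("detect_surface finds flat and tilted surfaces and rejects noise", {
  set.seed(3)
  n_v <- 120; n_u <- 100
  mk_img <- function(srow) {
    img <- matrix(abs(rnorm(n_v * n_u, 0, 0.05)), n_v, n_u)
    for (j in seq_len(n_u)) {
      s <- round(srow(j))
      img[s, j] <- img[s, j] + 3
      deep <- seq(s + 1, n_v)
      img[deep, j] <- img[deep, j] + abs(rnorm(length(deep), 0, 0.3))
    }
    img
  }
  flat <- detect_surface(mk_img(function(j) 40))
  expect_true(all(abs(flat - 40) <= 1))
  tilt <- detect_surface(mk_img(function(j) 40 + 0.1 * j))
  slope <- coef(lm(tilt ~ seq_len(n_u)))[2]
  expect_close(slope, 0.1, 0.01)
  expect_error(detect_surface(matrix(abs(rnorm(5000)), 100, 50)),
               "no surface")
})

test_that("register_image with the d = 0 model reproduces the image", {
  set.seed(5)
  img <- matrix(runif(80 * 60), 80, 60)
  inc <- incidence_config(0, g_std, focus_physical = c(0, 30))
  mod <- registration_model(g_std, inc, u_f = 30, v_f = 50, n_u = 60,
                            n_v = 80, v_surf = 10, ri = RI, x_f = 0)
  # grid at the exact forward-mapped pixel centres
  fw_x <- map_forward(mod, seq_len(60), rep(40, 60))$x
  fw_z <- map_forward(mod, rep(30, 70), 6:75)$z
  grid <- oct_grid(fw_x, fw_z)
  reg <- register_image(img, mod, grid)
  expect_true(all(reg$valid[, 2:59]))
  expect_equal(reg$values[, 2:59], img[6:75, 2:59], tolerance = 1e-9)
})

test_that("map_inverse round-trips 1000 random pixels below 0.1 px", {
  inc <- incidence_config(-2.0, g_std, focus_physical = c(0, 200))
  mod <- registration_model(g_std, inc, u_f = 90, v_f = 280, n_u = 180,
                            n_v = 500, v_surf = 15, ri = RI)
  set.seed(12)
  u <- runif(1000, 1, 180); v <- runif(1000, 1, 500)
  xz <- map_forward(mod, u, v)
  uv <- map_inverse(mod, xz$x, xz$z)
  expect_lt(max(abs(uv$u - u), abs(uv$v - v)), 0.1)
})

test_that("beads align across all 11 angles within one physical pixel", {
  fx <- fixture("bead_set", bead_set_fixture)
  aset <- run_preparation(fx$stacks)
  grid <- oct_grid(x = g_std$p_u * seq(-70, 70),
                   z = seq(5, 680, by = g_std$p_v / RI))
  pos <- array(NA_real_, c(length(OFFSETS), nrow(fx$beads), 2))
  for (k in seq_along(OFFSETS)) {
    inc <- incidence_config(OFFSETS[k], g_std, focus_physical = c(0, 350))
    mod <- registration_model(g_std, inc, u_f = 93,
                              v_f = fx$stacks[[k]]$truth$v_f,
                              n_u = 185, n_v = fx$n_v,
                              v_surf = detect_surface(aset$images[[k]]),
                              ri = RI, x_f = 0)
    reg <- register_image(aset$images[[k]], mod, grid)
    for (b in seq_len(nrow(fx$beads))) {
      pos[k, b, ] <- blob_centroid(reg$values, fx$beads$x[b],
                                   fx$beads$z[b], grid$x, grid$z)
    }
  }
  # beads sit from 295 um above to 295 um below focus; the across-angle
  # spread of each registered centroid stays below one grid pixel
  for (b in seq_len(nrow(fx$beads))) {
    expect_lt(diff(range(pos[, b, 1])), g_std$p_u)
    expect_lt(diff(range(pos[, b, 2])), g_std$p_u)
  }
})

test_that("dropping the quadratic scan term misplaces wide-field beads", {
  # galvo 59 mm from a 36 mm lens: the scan is quadratically distorted;
  # the full model corrects it, a rotation+translation-only model does not
  beads <- data.frame(x = c(-420, 0, 420), z = rep(260, 3), amp = 3)
  ph <- oct_phantom(beads, extent = list(x = c(-520, 520), z = c(0, 300)),
                    refractive_index = RI)
  n_v <- 12 + ceiling(RI * 295)
  acq <- acquisition(n_u = 1025, n_v = n_v, u_f = 513, surface_row = 12)
  inc <- incidence_config(2.5, g_std, focus_physical = c(0, 130))
  st <- suppressWarnings(simulate_bscan(ph, g_std, inc, acq))
  grid <- oct_grid(x = seq(-460, 460, by = g_std$p_u),
                   z = seq(240, 280, by = g_std$p_v / RI))
  img <- Mod(st$data[, , 1])
  err <- function(truncate_q) {
    mod <- registration_model(g_std, inc, 513, st$truth$v_f, 1025, n_v,
                              v_surf = 12, ri = RI, x_f = 0)
    if (truncate_q) mod$q <- 0
    reg <- register_image(img, mod, grid)
    vapply(seq_len(nrow(beads)), function(b) {
      abs(blob_centroid(reg$values, beads$x[b], beads$z[b],
                        grid$x, grid$z, w = 30)["x"] - beads$x[b])
    }, numeric(1))
  }
  e_full <- err(FALSE); e_trunc <- err(TRUE)
  expect_lt(max(e_full), 1)
  expect_gt(max(e_trunc), 2 * max(e_full))
})

test_that("fuse_images averages magnitudes and tracks validity", {
  img <- matrix(runif(300), 20, 15)
  all_ok <- matrix(TRUE, 20, 15)
  same <- replicate(11, list(values = img, valid = all_ok),
                    simplify = FALSE)
  fz <- fuse_images(same)
  expect_equal(fz$magnitude, img)
  expect_true(all(fz$count == 11))
  # pixels masked out everywhere are flagged invalid
  bad <- all_ok; bad[3, ] <- FALSE
  fz2 <- fuse_images(list(list(values = img, valid = bad),
                          list(values = img, valid = bad)))
  expect_true(all(is.na(fz2$magnitude[3, ])))
  expect_true(all(fz2$count[3, ] == 0))
  # averaging never raises the background mean or STD
  set.seed(2)
  a <- matrix(abs(rnorm(300)), 20, 15)
  b <- matrix(abs(rnorm(300)), 20, 15)
  fz3 <- fuse_images(list(list(values = a, valid = all_ok),
                          list(values = b, valid = all_ok)))
  expect_lte(mean(fz3$magnitude), max(mean(a), mean(b)))
  expect_lte(sd(fz3$magnitude), max(sd(a), sd(b)))
})

test_that("two-angle fusion of independent speckle lowers STD by ~1/sqrt(2)", {
  acq <- acquisition(n_u = 91, n_v = 130, u_f = 46, surface_row = 10)
  inc <- incidence_config(0, g_std, focus_physical = c(0, 45))
  imgs <- lapply(1:2, function(s) {
    sp <- make_speckle_phantom(10, list(x = c(-60, 60), z = c(0, 80)),
                               seed = s, refractive_index = RI)
    Mod(suppressWarnings(simulate_bscan(sp, g_std, inc, acq))$data[, , 1])
  })
  ok <- matrix(TRUE, 130, 91)
  fz <- fuse_images(list(list(values = imgs[[1]], valid = ok),
                         list(values = imgs[[2]], valid = ok)))
  r <- 40:110; cc <- 16:76
  ratio <- sd(fz$magnitude[r, cc]) /
    mean(c(sd(imgs[[1]][r, cc]), sd(imgs[[2]][r, cc])))
  expect_close(ratio, 1 / sqrt(2), 0.15 / sqrt(2))
})

test_that("correct_bulk_motion recovers injected vertical shifts", {
  ph <- make_bead_phantom(2e8, list(x = c(-130, 130), z = c(0, 150)),
                          amplitude = 2, seed = 6, refractive_index = RI)
  acq <- acquisition(n_u = 101, n_v = 230, u_f = 51, surface_row = 18)
  shifts_in <- c(0, 3, -1, 1, -1)
  stacks <- suppressWarnings(
    simulate_angular_set(ph, g_std, seq(-1, 1, by = 0.5), acq,
                         focus_physical = c(0, 75), surface_amp = 5,
                         seed = 4, bulk_shifts_px = shifts_in))
  aset <- correct_bulk_motion(run_preparation(stacks))
  expect_equal(aset$shifts, as.integer(shifts_in - round(median(shifts_in))))
  # surfaces coincide after correction
  surfs <- vapply(aset$images, function(im) median(detect_surface(im)),
                  numeric(1))
  expect_true(all(abs(surfs - surfs[1]) <= 1))
  # a zero-shift set reports all-zero shifts
  stacks0 <- suppressWarnings(
    simulate_angular_set(ph, g_std, seq(-1, 1, by = 0.5), acq,
                         focus_physical = c(0, 75), surface_amp = 5,
                         seed = 4))
  expect_true(all(correct_bulk_motion(run_preparation(stacks0))$shifts == 0L))
  # an oversized shift warns
  stacks_big <- suppressWarnings(
    simulate_angular_set(ph, g_std, seq(-1, 1, by = 0.5), acq,
                         focus_physical = c(0, 75), surface_amp = 5,
                         seed = 4, bulk_shifts_px = c(0, 0, 14, 0, 0)))
  expect_warning(correct_bulk_motion(run_preparation(stacks_big)),
                 "bulk-motion")
})

test_that("estimate_focus returns the symmetric centre and errors on flat input", {
  fx <- fixture("bead_set", bead_set_fixture)
  aset <- run_preparation(fx$stacks)
  vtrue <- fx$stacks[[6]]$truth$v_f
  foc <- estimate_focus(aset, v_init = round(vtrue) + 3, v_search = -5:5)
  # the focus column is the (gauge) centre of the symmetric set
  expect_close(foc$u_f, 93, 1)
  # the R_HF objective at the optimum beats a 10 px displaced candidate
  far <- estimate_focus(aset, v_init = foc$v_f + 10, v_search = 0)
  expect_gte(foc$r_hf, far$r_hf)
  # featureless images give a flat landscape
  flat <- aset
  flat$images <- lapply(flat$images, function(im) im * 0 + 1)
  expect_error(estimate_focus(flat, v_init = 100, v_search = -2:2),
               "featureless|no surface")
})
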