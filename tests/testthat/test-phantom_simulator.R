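ext <- list(x = c(-70, 70), z = c(0, 90))

test_that("make_bead_phantom draws a reproducible Poisson bead count", {
  expect_equal(nrow(make_bead_phantom(0, ext, seed = 1)$scatterers), 0)
  p1 <- make_bead_phantom(3.64e8, ext, seed = 3)
  p2 <- make_bead_phantom(3.64e8, ext, seed = 3)
  expect_identical(p1$scatterers, p2$scatterers)
  expect_error(make_bead_phantom(-1, ext), "density")
  # mean count over 200 seeds within 3 SE of density x volume
  lam <- 3.64e8 * diff(ext$x) * diff(ext$z) * 8 / 1e12
  n <- vapply(1:200, function(s) {
    nrow(make_bead_phantom(3.64e8, ext, seed = s)$scatterers)
  }, numeric(1))
  expect_close(mean(n), lam, 3 * sqrt(lam / 200))
})

test_that("make_speckle_phantom yields fully developed Rayleigh speckle", {
  sp <- make_speckle_phantom(40, ext, seed = 7, refractive_index = RI)
  acq <- acquisition(n_u = 151, n_v = 150, u_f = 76, surface_row = 10)
  inc <- incidence_config(0, g_std, focus_physical = c(0, 45))
  img <- Mod(suppressWarnings(simulate_bscan(sp, g_std, inc,
                                             acq))$data[, , 1])
  # interior band around the focal plane; Rayleigh sigma/mu = 0.522
  band <- img[40:110, 31:121]
  expect_close(relative_std(band), sqrt(4 / pi - 1), 0.05)
  # determinism and the empty-extent case
  sp2 <- make_speckle_phantom(40, ext, seed = 7, refractive_index = RI)
  expect_identical(sp$scatterers, sp2$scatterers)
  emp <- make_speckle_phantom(0, ext, seed = 1)
  expect_equal(nrow(emp$scatterers), 0)
  img0 <- suppressWarnings(simulate_bscan(emp, g_std, inc, acq))$data[, , 1]
  expect_true(all(img0 == 0))
})

test_that("a single in-focus scatterer reproduces the beam profile", {
  ph <- oct_phantom(data.frame(x = 0, z = 150, amp = 1),
                    extent = list(x = c(-45, 45), z = c(0, 200)),
                    refractive_index = RI)
  acq <- acquisition(n_u = 91, n_v = 240, u_f = 46, surface_row = 16)
  inc <- incidence_config(0, g_std, focus_physical = c(0, 150))
  st <- suppressWarnings(simulate_bscan(ph, g_std, inc, acq))
  img <- Mod(st$data[, , 1])
  pk <- which(img == max(img), arr.ind = TRUE)
  # peak at the focus pixel (u_f, v_f)
  expect_equal(pk[1, "col"], 46, ignore_attr = TRUE)
  expect_close(pk[1, "row"], st$truth$v_f, 1)
  # lateral FWHM of the amplitude envelope: 2 sqrt(ln 2) w0
  expect_close(fwhm(img[pk[1], ], g_std$p_u),
               2 * sqrt(log(2)) * g_std$w0, 0.15)
  # axial FWHM equals the axial resolution
  expect_close(fwhm(img[, pk[2]], g_std$p_v), g_std$axial_resolution, 0.1)
  # linearity: doubling amplitudes doubles the noiseless image
  ph2 <- ph; ph2$scatterers$amp <- 2
  st2 <- suppressWarnings(simulate_bscan(ph2, g_std, inc, acq))
  expect_equal(st2$data, 2 * st$data)
})

test_that("compiled scatterer accumulation matches the pure-R oracle", {
  set.seed(9)
  sc <- data.frame(x = runif(25, -30, 30), z = runif(25, 5, 90),
                   amp = runif(25, 0.3, 2))
  ph <- oct_phantom(sc, extent = list(x = c(-40, 40), z = c(0, 100)),
                    refractive_index = RI)
  acq <- acquisition(n_u = 61, n_v = 150, u_f = 31, surface_row = 12)
  for (d in c(0, 2.5)) {
    inc <- incidence_config(d, g_std, focus_physical = c(0, 50))
    st <- suppressWarnings(simulate_bscan(ph, g_std, inc, acq))
    ref <- octac:::r_scatter_image(ph, g_std, inc, acq)
    expect_lt(max(Mod(st$data[, , 1] - ref)), 1e-4 * max(Mod(ref)))
  }
})

test_that("a two-scatterer voxel follows the angle-phase interference law", {
  # cross-module oracle: simulated focus-pixel magnitude vs the analytic
  # two-scatterer amplitude driven by the angle-induced phase shift
  D12 <- 3.3
  ph <- oct_phantom(data.frame(x = c(-D12 / 2, D12 / 2), z = c(150, 150),
                               amp = c(1, 1)),
                    extent = list(x = c(-60, 60), z = c(0, 200)),
                    refractive_index = RI)
  acq <- acquisition(n_u = 111, n_v = 240, u_f = 56, surface_row = 16)
  simv <- vapply(OFFSETS, function(d) {
    inc <- incidence_config(d, g_std, focus_physical = c(0, 150))
    st <- suppressWarnings(simulate_bscan(ph, g_std, inc, acq))
    vf <- st$truth$v_f; img <- Mod(st$data[, , 1])
    f0 <- floor(vf); w <- vf - f0
    img[f0, 56] * (1 - w) + img[f0 + 1, 56] * w
  }, numeric(1))
  alpha_s <- in_sample_angle(atan(OFFSETS * 1e3 / g_std$f), RI)
  pred <- two_scatterer_amplitude(
    phase_shift_from_angle(alpha_s, D12, g_std$lambda, RI), 1)
  expect_lt(max(abs(simv / max(simv) - pred / max(pred))), 0.05)
})

test_that("spectral interferograms round-trip to the direct B-scan", {
  ph <- oct_phantom(data.frame(x = c(-10, 8), z = c(40, 80),
                               amp = c(1, 0.7)),
                    extent = list(x = c(-40, 40), z = c(0, 120)),
                    refractive_index = RI)
  acq <- acquisition(n_u = 61, n_v = 180, u_f = 31, surface_row = 12)
  inc <- incidence_config(0, g_std, focus_physical = c(0, 60))
  st <- suppressWarnings(simulate_bscan(ph, g_std, inc, acq))
  sp <- simulate_spectral_interferogram(ph, g_std, inc, acq,
                                        n_pixels = 1024)
  rec <- spectra_to_bscan(sp)
  m1 <- Mod(st$data[, , 1]); m2 <- Mod(rec)
  expect_lt(max(abs(m2 - m1)), 0.02 * max(m1))
  # single reflector: peak at the one-way-OPL pixel v_surf + RI z / p_v
  ph1 <- oct_phantom(data.frame(x = 0, z = 60, amp = 1),
                     extent = list(x = c(-40, 40), z = c(0, 120)),
                     refractive_index = RI)
  sp1 <- simulate_spectral_interferogram(ph1, g_std, inc, acq,
                                         n_pixels = 1024)
  a <- Mod(spectra_to_bscan(sp1)[, 31])
  expect_close(which.max(a), 12 + RI * 60 / g_std$p_v, 1)
  # empty phantom: spectra at the noise floor only
  emp <- oct_phantom(data.frame(x = numeric(0), z = numeric(0),
                                amp = numeric(0)),
                     extent = list(x = c(-40, 40), z = c(0, 120)),
                     refractive_index = RI)
  spn <- simulate_spectral_interferogram(emp, g_std, inc, acq,
                                         n_pixels = 512,
                                         noise_level = 0.01, seed = 2)
  expect_lt(max(Mod(spectra_to_bscan(spn))), 0.05)
})

test_that("forward_map is the exact inverse of the pixel assignment", {
  acq <- acquisition(n_u = 81, n_v = 300, u_f = 41, surface_row = 14)
  for (d in c(-2.5, 0, 1.5)) {
    inc <- incidence_config(d, g_std, focus_physical = c(0, 150))
    sp <- octac:::scan_params(g_std, inc, acq, 0, RI)
    # the focus pixel maps to the shared physical focus
    fp <- forward_map(41, sp$v_f, inc, g_std, acq, ri = RI)
    expect_close(fp$x, 0, 1e-9)
    expect_close(fp$z, 150, 1e-9)
    # round trip against the registration-model inverse
    mod <- registration_model(g_std, inc, 41, sp$v_f, 81, 300,
                              v_surf = 14, ri = RI, x_f = 0)
    set.seed(4)
    u <- runif(300, 1, 81); v <- runif(300, 1, 300)
    xz <- forward_map(u, v, inc, g_std, acq, ri = RI)
    uv <- map_inverse(mod, xz$x, xz$z)
    expect_lt(max(abs(uv$u - u), abs(uv$v - v)), 1e-6)
  }
  # d = 0 with the galvo at the back focal plane: pure per-axis scaling
  g_bfp <- beam_geometry(galvo_lens_distance_mm = 36)
  inc0 <- incidence_config(0, g_bfp, focus_physical = c(0, 150))
  xz <- forward_map(c(41, 51), c(14, 40), inc0, g_bfp, acq, ri = RI)
  expect_equal(xz$x, c(0, 10 * g_bfp$p_u))
  expect_equal(xz$z, c(0, 26 * g_bfp$p_v / RI))
})

test_that("angular speckle patterns decorrelate with angle separation", {
  dset <- fixture("deep_speckle", deep_speckle_set_fixture)
  vals <- lapply(dset$regs, function(r) r$values)
  ok <- Reduce(`&`, lapply(dset$regs, function(r) r$valid))
  c_adj <- cor(vals[[6]][ok], vals[[7]][ok])
  c_far <- cor(vals[[1]][ok], vals[[11]][ok])
  expect_lt(c_far, c_adj)
  expect_lt(c_far, 0.2)
})

test_that("compounding independent patterns follows 1/sqrt(N)", {
  # independent realisations (different phantom seeds): the generator's
  # reference behaviour for the STD-reduction trend
  acq <- acquisition(n_u = 91, n_v = 130, u_f = 46, surface_row = 10)
  inc <- incidence_config(0, g_std, focus_physical = c(0, 45))
  imgs <- lapply(1:6, function(s) {
    sp <- make_speckle_phantom(10, list(x = c(-60, 60), z = c(0, 80)),
                               seed = s, refractive_index = RI)
    Mod(suppressWarnings(simulate_bscan(sp, g_std, inc, acq))$data[, , 1])
  })
  region <- matrix(FALSE, 130, 91)
  region[40:110, 16:76] <- TRUE
  curve <- std_reduction_curve(imgs, region)
  expect_true(all(abs(curve - 1 / sqrt(1:6)) < 0.2 / sqrt(1:6)))
  expect_true(all(diff(curve) < 0))
})

test_that("repeat averaging suppresses shot noise as 1/sqrt(n)", {
  emp <- oct_phantom(data.frame(x = numeric(0), z = numeric(0),
                                amp = numeric(0)),
                     extent = list(x = c(-50, 50), z = c(0, 100)),
                     refractive_index = RI)
  acq <- acquisition(n_u = 91, n_v = 130, u_f = 46, surface_row = 10)
  inc <- incidence_config(0, g_std, focus_physical = c(0, 45))
  st <- simulate_bscan(emp, g_std, inc, acq, n_repeat = 20,
                       noise_level = 0.1, seed = 5)
  cmean <- apply(st$data, c(1, 2), mean)
  ratio <- sd(Re(cmean)) / sd(Re(st$data[, , 1]))
  expect_close(ratio, 1 / sqrt(20), 0.1 / sqrt(20))
  # repeats carry independent noise
  expect_false(identical(st$data[, , 1], st$data[, , 2]))
})

test_that("simulate_bscan warns when the scan leaves the phantom extent", {
  ph <- make_speckle_phantom(5, list(x = c(-20, 20), z = c(0, 40)),
                             seed = 1, refractive_index = RI)
  acq <- acquisition(n_u = 121, n_v = 80, u_f = 61, surface_row = 10)
  inc <- incidence_config(0, g_std, focus_physical = c(0, 20))
  expect_warning(simulate_bscan(ph, g_std, inc, acq), "outside")
})
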