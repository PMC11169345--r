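# Bead-based PSF and light-sheet characterization.

test_that("the Gaussian FWHM estimator is exact on noiseless profiles", {
  for (sigma in c(1.5, 2, 3, 4.5, 6)) {
    x <- seq_len(61)
    prof <- 10 + 250 * exp(-(x - 30.4)^2 / (2 * sigma^2))
    f <- measure_fwhm(prof, pitch_um = 0.104)
    truth <- 2 * sqrt(2 * log(2)) * sigma * 104
    expect_lt(abs(f$fwhm_nm - truth) / truth, 1e-6)
  }
  # closed form: sigma = 2 px at 104 nm pitch
  x <- seq_len(31)
  f <- measure_fwhm(1000 * exp(-(x - 16)^2 / 8), 0.104)
  expect_equal(f$fwhm_nm, 2 * sqrt(2 * log(2)) * 2 * 104, tolerance = 1e-6)
  expect_error(measure_fwhm(c(1, 2, 1), 0.1), "7 samples")
})

test_that("the FWHM estimate is invariant to a constant baseline", {
  x <- seq_len(41)
  prof <- 500 * exp(-(x - 20.7)^2 / (2 * 2.6^2))
  f0 <- measure_fwhm(prof, 0.104)
  f1 <- measure_fwhm(prof + 100, 0.104)
  expect_equal(f0$fwhm_nm, f1$fwhm_nm, tolerance = 1e-6)
})

test_that("Poisson noise leaves the mean FWHM within 2% of truth", {
  set.seed(21)
  x <- seq_len(41)
  sigma <- 2.5
  truth <- 2 * sqrt(2 * log(2)) * sigma * 104
  est <- replicate(100, {
    prof <- rpois(length(x), 1000 * exp(-(x - 20.5)^2 / (2 * sigma^2)) + 20)
    measure_fwhm(prof, 0.104)$fwhm_nm
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - truth) / truth, 0.02)
})

test_that("MIP slabs obey max-projection identities", {
  v <- array(runif(10 * 8 * 8), c(10, 8, 8))
  mip <- mip_slab(v, axis = 1, n_slices = Inf)
  for (z in 1:10) expect_true(all(mip >= v[z, , ]))
  # identical slices project to one slice
  vv <- array(rep(v[1, , ], each = 10), c(10, 8, 8))
  expect_equal(mip_slab(vv, axis = 1, n_slices = 4), v[1, , ])
  # a single bright voxel lands at the same (y, x)
  v2 <- array(0, c(10, 8, 8)); v2[4, 3, 6] <- 7
  m2 <- mip_slab(v2, axis = 1, n_slices = Inf)
  expect_equal(which(m2 == 7, arr.ind = TRUE), cbind(row = 3L, col = 6L))
  expect_warning(mip_slab(v, axis = 1, center = 1, n_slices = 10), "clip")
})

test_that("bead detection has perfect precision/recall on clean separated fields", {
  pos <- grid_bead_positions(n = 12, spacing = 5, seed = 13)
  spec <- sim_spec(seed = 13, shape = grid_bead_shape(12, 5), noise = NULL,
                   n_beads = 12)
  bs <- generate_bead_stack(spec, bead_positions_um = pos)
  psf <- gaussian_psf_model()
  det <- detect_beads(bs$stack, psf, min_separation = 2)
  expect_equal(nrow(det), 12)
  # every detection within 1 voxel of a true bead (lateral)
  for (i in seq_len(nrow(det))) {
    d2 <- sqrt((det$y_um[i] - bs$truth$y_um)^2 +
                 (det$x_um[i] - bs$truth$x_um)^2)
    expect_lt(min(d2), 1.5 * max(spec$pitch_um))
  }
})

test_that("beads closer than the separation floor are all rejected", {
  pos <- rbind(c(10, 8, 8), c(10, 9.2, 8), c(10, 16, 16))
  spec <- sim_spec(seed = 5, shape = c(41, 232, 232), noise = NULL,
                   n_beads = 3)
  bs <- generate_bead_stack(spec, bead_positions_um = pos)
  det <- detect_beads(bs$stack, gaussian_psf_model(), min_separation = 1.6)
  # the 1.2-um pair is rejected outright; the isolated bead survives
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$y_um[1] - 16), 0.5)
})

test_that("a noise-only stack yields no detections at a high threshold", {
  set.seed(2)
  v <- array(rpois(21 * 64 * 64, 100), c(21, 64, 64))
  st <- volume_stack(v, c(0.5, 0.104, 0.104))
  det <- detect_beads(st, gaussian_psf_model(), corr_threshold = 0.9)
  expect_equal(nrow(det), 0)
})

test_that("bead measurement via the MIP-slab protocol recovers generator truth", {
  pos <- grid_bead_positions(n = 20, spacing = 5, seed = 7)
  spec <- sim_spec(seed = 101, shape = grid_bead_shape(20, 5), n_beads = 20)
  bs <- generate_bead_stack(spec, bead_positions_um = pos)
  det <- detect_beads(bs$stack, gaussian_psf_model(), min_separation = 2)
  expect_gte(nrow(det), 15)
  meas <- measure_bead_fwhm(bs$stack, det, mode = "mip", n_slices = 10)
  m <- meas[meas$converged, ]
  expect_lt(abs(mean(m$fwhm_x_nm) - 570), 26)
  expect_lt(abs(mean(m$fwhm_y_nm) - 666), 44)
  expect_lt(abs(mean(m$fwhm_z_nm) - 924), 14)
})

test_that("light-sheet cropping follows the tilted waist line", {
  spec <- sim_spec(seed = 11, shape = c(21, 120, 32), noise = NULL,
                   n_beads = 40,
                   lightsheet = list(waist_fwhm_nm = 850, yR_um = 2.3,
                                     tilt = 0.14))
  # beads on the tilted waist line itself, one per slice and then some,
  # so every slice carries signal inside the tracked window
  set.seed(11)
  z <- runif(40, 0, 10)
  ext_y <- 119 * 0.104
  y <- ext_y / 2 + 0.14 * (z - 5) + runif(40, -1, 1)
  x <- runif(40, 0.8, 2.4)
  bs <- generate_bead_stack(spec, bead_positions_um = cbind(z, y, x))
  # a = 0: identical window for every slice
  cr0 <- crop_lightsheet_region(bs$stack, fov_length = 8, tilt_a = 0)
  expect_equal(length(unique(attr(cr0, "crop_table")$y_start)), 1L)
  # a = 0.14, dz = 0.5 um: the window advances 0.07 um per slice on
  # average (0.673 voxels per slice at 104 nm pitch)
  cr <- crop_lightsheet_region(bs$stack, fov_length = 8, tilt_a = 0.14)
  starts <- attr(cr, "crop_table")$y_start
  expect_equal(mean(diff(starts)), 0.14 * 0.5 / 0.104, tolerance = 0.05)
  # construction oracle: beads sit on the waist line, so the tracked crop
  # holds more intensity than the complement, slice by slice
  v <- bs$stack$voxels
  ct <- attr(cr, "crop_table")
  w <- dim(cr$voxels)[2]
  for (z in seq(1, 21, by = 4)) {
    inside <- mean(cr$voxels[z, , ])
    outside <- mean(v[z, -(ct$y_start[z]:(ct$y_start[z] + w - 1)), ])
    expect_gt(inside, outside)
  }
  expect_error(crop_lightsheet_region(bs$stack, fov_length = 50,
                                      tilt_a = 0), "extent")
})

test_that("resolution summaries partition beads into axial segments", {
  meas <- data.frame(bead = 1:12,
                     z_um = seq(0.5, 23.5, length.out = 12),
                     y_um = 5, x_um = 5,
                     fwhm_x_nm = 570, fwhm_y_nm = 666, fwhm_z_nm = 924,
                     quality = 0, converged = TRUE)
  s <- summarize_resolution(meas, segment_um = 5)
  expect_equal(sum(s$segments$n), 12)       # every bead in exactly one segment
  expect_true(all(s$segments$mean_fwhm_x_nm == 570))
  expect_true(all(s$segments$sd_fwhm_x_nm == 0 |
                    is.na(s$segments$sd_fwhm_x_nm)))
  # permutation invariance
  perm <- meas[sample(nrow(meas)), ]
  s2 <- summarize_resolution(perm, segment_um = 5)
  expect_equal(s2$segments, s$segments)
})

test_that("segment means recover a common generator FWHM within one sd", {
  pos <- grid_bead_positions(n = 20, spacing = 5, seed = 3)
  spec <- sim_spec(seed = 77, shape = grid_bead_shape(20, 5), n_beads = 20)
  bs <- generate_bead_stack(spec, bead_positions_um = pos)
  det <- detect_beads(bs$stack, gaussian_psf_model(), min_separation = 2)
  meas <- measure_bead_fwhm(bs$stack, det)
  s <- summarize_resolution(meas, segment_um = 25)  # one segment
  seg <- s$segments[1, ]
  expect_lt(abs(seg$mean_fwhm_x_nm - 570), max(seg$sd_fwhm_x_nm, 26))
})

test_that("light-sheet quantification recovers waist, tilt and analytic FOV", {
  spec <- sim_spec(seed = 11, shape = c(41, 160, 64), noise = NULL,
                   n_beads = 120,
                   lightsheet = list(waist_fwhm_nm = 850, yR_um = 2.3,
                                     tilt = 0.14))
  tr <- generate_bead_stack(spec)$truth
  df <- data.frame(z_um = tr$z_um, y_um = tr$y_um, fwhm_z_nm = tr$fwhm_z_nm)
  q <- quantify_lightsheet(df)
  expect_equal(q$tilt_a, 0.14, tolerance = 0.01)
  expect_equal(q$waist_fwhm_nm, 850, tolerance = 850 * 0.02)
  # FOV (width where FWHMz doubles) = 2 sqrt(3) yR for the Gaussian beam
  expect_equal(q$fov_length_um, 2 * sqrt(3) * 2.3,
               tolerance = 2 * sqrt(3) * 2.3 * 0.02)
  # a = 0 means y' = y exactly
  q0 <- quantify_lightsheet(df, tilt_a = 0)
  expect_equal(q0$y_corrected_um, df$y_um)
})

test_that("noisy width measurements still recover the waist within 5%", {
  spec <- sim_spec(seed = 11, shape = c(41, 160, 64), noise = NULL,
                   n_beads = 120,
                   lightsheet = list(waist_fwhm_nm = 850, yR_um = 2.3,
                                     tilt = 0.14))
  tr <- generate_bead_stack(spec)$truth
  set.seed(31)
  waists <- replicate(40, {
    df <- data.frame(z_um = tr$z_um, y_um = tr$y_um,
                     fwhm_z_nm = tr$fwhm_z_nm *
                       (1 + rnorm(nrow(tr), 0, 0.05)))
    quantify_lightsheet(df)$waist_fwhm_nm
  })
  expect_lt(abs(mean(waists) - 850) / 850, 0.05)
})
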