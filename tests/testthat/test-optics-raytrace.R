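# Paraxial ABCD ray tracing of the folded detection path.

test_that("effective focal length follows f_tube * n / M and rejects bad input", {
  expect_equal(effective_focal_length(200, 40, 1.33), 6.65)
  expect_equal(effective_focal_length(200, 20, 1.0), 10)
  expect_equal(effective_focal_length(100, 10, 1.0), 10)
  expect_error(effective_focal_length(-200, 40, 1.33), "positive")
  expect_error(effective_focal_length(200, 0, 1.33), "positive")
})

test_that("translation and thin-lens matrices match their defining forms", {
  tr <- make_translation(10, 1.33)
  expect_equal(tr$matrix, rbind(c(1, 0), c(10 / 1.33, 1)))
  expect_equal(det(tr$matrix), 1)
  expect_equal(make_translation(0)$matrix, diag(2))
  le <- make_thin_lens(10, 1.33)
  expect_equal(le$matrix, rbind(c(1, -1.33 / 10), c(0, 1)))
  expect_equal(det(le$matrix), 1)
  # near-identity in the long-focal-length limit
  expect_equal(make_thin_lens(1e12)$matrix, diag(2), tolerance = 1e-10)
  expect_error(make_thin_lens(0), "nonzero")
  expect_error(make_translation(5, n = 0), "positive")
})

test_that("ray propagation applies elements in order and handles folds", {
  r <- paraxial_ray(0.1, 0)
  expect_identical(propagate_ray(r, list()), r)
  out <- propagate_ray(r, list(make_translation(10, 1)))
  expect_equal(c(out$reduced_angle, out$height), c(0.1, 1.0))
  # d/n scaling: 13.3 mm in water behaves like 10 mm in air
  out <- propagate_ray(r, list(make_translation(13.3, 1.33)))
  expect_equal(out$height, 1.0)
  # parallel ray crosses the axis at the focus
  out <- propagate_ray(paraxial_ray(0, 5),
                       list(make_thin_lens(10), make_translation(10)))
  expect_equal(out$height, 0)
  # folds are identity on the ray vector
  out <- propagate_ray(paraxial_ray(0.05, 2), list(make_fold(45)))
  expect_equal(c(out$reduced_angle, out$height), c(0.05, 2))
})

test_that("traced imaging matches the thin-lens equation on random systems", {
  set.seed(42)
  for (i in 1:100) {
    f <- runif(1, 5, 200)
    s <- runif(1, 1.05 * f, 6 * f)   # real image
    m <- system_matrix(list(make_translation(s), make_thin_lens(f)))
    ip <- image_plane(m)
    s_true <- 1 / (1 / f - 1 / s)
    expect_equal(ip$distance, s_true, tolerance = 1e-9)
    expect_equal(ip$magnification, -s_true / s, tolerance = 1e-9)
  }
})

test_that("composed system matrices are unimodular", {
  m <- detection_model_preset()
  els <- rflsm:::model_elements(m, 9.9, "camera")
  expect_equal(det(system_matrix(els)), 1, tolerance = 1e-12)
  els2 <- rflsm:::model_elements(detection_model(), 10, "second_obj2")
  expect_equal(det(system_matrix(els2)), 1, tolerance = 1e-12)
})

test_that("the detection model computes f_obj, delta_L and 4f-nominal gaps", {
  m <- build_detection_model(list(f_tube_design = 200, m_obj = 40,
                                  n_water = 1.33))
  expect_equal(m$f_obj, 6.65)
  expect_equal(m$d1, 6.65 + 200)
  expect_equal(m$gap_l4_l5, 500)
  expect_equal(m$gap_l5_obj2, 310)
  # delta_L = f_obj2 * theta(rad): 10 mm x 8 deg
  m8 <- detection_model(theta = 8)
  expect_equal(m8$delta_l, 10 * 8 * pi / 180, tolerance = 1e-12)
  expect_error(build_detection_model(list(nonsense = 1)), "unknown")
  expect_error(detection_model(gap_l5_obj2 = 100, gap_pbs_obj2 = 400),
               "inconsistent")
})

test_that("delta_L is exactly linear in theta with slope f_obj2", {
  th <- seq(0.5, 20, by = 0.5)
  dl <- delta_l(10, th)
  slopes <- dl / (th * pi / 180)
  expect_equal(slopes, rep(10, length(th)), tolerance = 1e-12)
})

test_that("exact-4f pupil-matched relay magnifies by n_water/n_air", {
  m <- detection_model(pupil_matched = TRUE)
  tf <- trace_field(m)
  expect_equal(tf$remote_image$magnification, 1.33, tolerance = 1e-9)
  expect_true(tf$converged)
  # literal 300 mm relay lens: M_obj * f_obj2 / f_L5 = 4/3
  tf2 <- trace_field(detection_model())
  expect_equal(tf2$remote_image$magnification, 40 * 10 / 300,
               tolerance = 1e-9)
  # on-axis chief ray stays on axis at every sampled plane
  chief <- tf$rays[tf$rays$field_point == "axis" &
                     tf$rays$pupil_ray == "center", ]
  expect_true(all(abs(chief$height) < 1e-12))
})

test_that("magnification vs scan is smooth, monotone locally, and scale invariant", {
  m <- detection_model_preset()
  offs <- seq(-40, 40, by = 5)
  cur <- magnification_vs_scan(m, offs)
  expect_equal(nrow(cur), length(offs))
  # smooth: second differences small relative to the first differences
  d1 <- diff(cur$magnification)
  expect_true(all(abs(diff(d1)) < 0.1 * max(abs(d1))))
  # monotone in a neighbourhood of 0 for the non-4f preset
  near <- magnification_vs_scan(m, c(-5, 0, 5))
  expect_true(all(diff(near$magnification) < 0) ||
                all(diff(near$magnification) > 0))
  # paraxial scale invariance: scaling all lengths and offsets together
  k <- 2.5
  ms <- detection_model(f_tube_design = 200 * k, m_obj = 40,
                        n_water = 1.33, f_l4 = 200 * k, f_l5 = 300 * k,
                        f_obj2 = 10 * k, f_l6 = 300 * k,
                        s1 = m$s1 * k, d1 = m$d1 * k,
                        gap_l4_l5 = m$gap_l4_l5 * k,
                        gap_l5_obj2 = m$gap_l5_obj2 * k,
                        gap_pbs_obj2 = m$gap_pbs_obj2 * k)
  cs <- magnification_vs_scan(ms, offs * k, max_offset = 40 * k)
  expect_equal(cs$magnification, cur$magnification, tolerance = 1e-9)
  expect_error(magnification_vs_scan(m, 60), "outside")
})

test_that("exact-4f scan reduces to the trace_field magnification at offset 0", {
  m <- detection_model(pupil_matched = TRUE)
  cur <- magnification_vs_scan(m, 0)
  expect_equal(cur$magnification, 1.33, tolerance = 1e-9)
})

test_that("collection efficiency matches a Monte-Carlo ray-clipping oracle", {
  m <- detection_model()
  mc_oracle <- function(defocus_um, offset_um, n = 10000) {
    f <- m$f_obj2; r <- f * m$na_obj2
    d <- defocus_um / 1000; x <- offset_um / 1000
    th <- sqrt(runif(n)); ph <- runif(n, 0, 2 * pi)
    u <- r * th * cos(ph); v <- r * th * sin(ph)
    px <- 2 * (1 + d / f) * x - (1 + 2 * d / f) * u
    py <- -(1 + 2 * d / f) * v
    mean(px^2 + py^2 <= r^2)
  }
  set.seed(11)
  for (i in 1:20) {
    defo <- runif(1, -400, 400)
    off <- runif(1, 0, 900)
    expect_equal(collection_efficiency(m, defo, off),
                 mc_oracle(defo, off), tolerance = 0.01)
  }
  expect_equal(collection_efficiency(m, 0, 0), 1.0)
  # mirror symmetry in the field offset
  expect_equal(collection_efficiency(m, 120, 500),
               collection_efficiency(m, 120, -500))
  expect_error(collection_efficiency(m, 0, 0, aperture_radius = -1),
               "non-negative")
})

test_that("collection efficiency decays monotonically with outward defocus", {
  # outward mirror displacement grows the returning footprint, so rays are
  # lost monotonically; inward displacement first shrinks the footprint
  # (efficiency recovers toward 1), so the decay is one-sided
  m <- detection_model()
  for (off in c(400, 700)) {
    pos <- sapply(seq(0, 400, by = 50),
                  function(d) collection_efficiency(m, d, off))
    expect_true(all(diff(pos) <= 1e-12))
    inward <- collection_efficiency(m, -400, off)
    expect_gte(inward, collection_efficiency(m, 0, off))
  }
})

test_that("launch-angle selection returns the smallest feasible grid angle", {
  m <- detection_model_preset()
  sel <- choose_theta(m, min_separation = delta_l(10, 8) - 1e-9)
  expect_equal(sel$theta, 8)
  # a larger required separation forces a larger angle
  sel2 <- choose_theta(m, min_separation = 2)
  expect_gt(sel2$theta, sel$theta)
  expect_gte(sel2$delta_l, 2)
})

test_that("d1 and S1 calibrate against measured magnifications", {
  truth <- detection_model_preset()
  mv <- magnification_vs_scan(truth, seq(-40, 40, 20))
  meas <- data.frame(
    offset_um = mv$offset_um,
    relative_magnification = mv$magnification /
      mv$magnification[mv$offset_um == 0])
  cal <- calibrate_d1(detection_model_preset(), meas, interval = c(50, 200))
  expect_equal(cal$d1, truth$d1, tolerance = 1e-3)
  m0 <- magnification_vs_scan(truth, 0)$magnification
  cal2 <- calibrate_s1(detection_model_preset(s1 = 6.68), m0)
  expect_equal(cal2$s1, truth$s1, tolerance = 1e-4)
})
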