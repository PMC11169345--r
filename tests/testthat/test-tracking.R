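# Granule trajectory analysis: linking, MSD, model fitting, populations.

test_that("linking keeps stationary and well-separated particles on their tracks", {
  frames <- rep(list(data.frame(x = 5, y = 5, z = 5)), 10)
  tr <- link_detections(frames, max_displacement = 1)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
  # two distant particles never swap
  frames2 <- lapply(1:8, function(f) {
    data.frame(x = c(2, 20) + 0.05 * f, y = c(2, 20), z = c(2, 20))
  })
  tr2 <- link_detections(frames2, max_displacement = 3)
  expect_equal(length(unique(tr2$track_id)), 2)
  counts <- table(tr2$track_id)
  expect_true(all(counts == 8))
})

test_that("linking is >= 95% correct on simulated diffusing granules", {
  dt <- 0.12; D <- 0.01
  spec <- sim_spec(seed = 17, shape = c(41, 192, 192),
                   granules = list(n = 10, d_um2_s = D,
                                   velocity_um_s = c(0, 0, 0),
                                   frame_interval_s = dt, n_frames = 40,
                                   loc_sd_nm = 0))
  truth <- simulate_granules(spec)
  frames <- lapply(split(truth, truth$frame), function(f) {
    data.frame(x = f$x_um, y = f$y_um, z = f$z_um, id = f$track_id)
  })
  linked <- link_detections(lapply(frames, function(f) f[, 1:3]),
                            max_displacement = 5 * sqrt(6 * D * dt),
                            frame_interval_s = dt)
  # score: fraction of consecutive links joining the same true particle
  ok <- 0; total <- 0
  for (tid in unique(linked$track_id)) {
    tr <- linked[linked$track_id == tid, ]
    if (nrow(tr) < 2) next
    ids <- vapply(seq_len(nrow(tr)), function(i) {
      f <- frames[[tr$frame[i]]]
      f$id[which.min((f$x - tr$x_um[i])^2 + (f$y - tr$y_um[i])^2 +
                       (f$z - tr$z_um[i])^2)]
    }, numeric(1))
    ok <- ok + sum(ids[-1] == ids[-length(ids)])
    total <- total + nrow(tr) - 1
  }
  expect_gt(ok / total, 0.95)
})

test_that("the time-averaged MSD matches a brute-force all-pairs oracle", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    tr <- data.frame(t_s = (seq_len(n) - 1) * 0.12,
                     x_um = cumsum(rnorm(n, 0, 0.1)),
                     y_um = cumsum(rnorm(n, 0, 0.1)),
                     z_um = cumsum(rnorm(n, 0, 0.1)))
    cv <- compute_msd(tr, max_lag_frac = 1)
    for (k in unique(c(1, 2, nrow(cv)))) {
      pairs <- 0; tot <- 0
      for (i in seq_len(n - k)) {
        pairs <- pairs + sum((tr[i + k, 2:4] - tr[i, 2:4])^2)
        tot <- tot + 1
      }
      expect_equal(cv$msd_um2[k], pairs / tot, tolerance = 1e-12)
      expect_equal(cv$n[k], tot)
    }
  }
})

test_that("MSD closed forms: stationary tracks and uniform motion", {
  tr0 <- data.frame(t_s = (0:19) * 0.5, x_um = 1, y_um = 2, z_um = 3)
  expect_true(all(compute_msd(tr0)$msd_um2 == 0))
  v <- 0.25
  trv <- data.frame(t_s = (0:19) * 0.5, x_um = v * (0:19) * 0.5,
                    y_um = 0, z_um = 0)
  cv <- compute_msd(trv)
  expect_equal(cv$msd_um2, v^2 * cv$lag_s^2, tolerance = 1e-12)
  expect_error(compute_msd(tr0[1:4, ]), "short")
})

test_that("the ensemble MSD of simulated Brownian motion matches 6 D t", {
  D <- 0.05; dt <- 0.12
  spec <- sim_spec(seed = 23, shape = c(201, 962, 962),
                   granules = list(n = 400, d_um2_s = D,
                                   velocity_um_s = c(0, 0, 0),
                                   frame_interval_s = dt, n_frames = 40,
                                   loc_sd_nm = 0))
  tracks <- simulate_granules(spec)
  curves <- lapply(split(tracks, tracks$track_id),
                   function(tr) compute_msd(tr)$msd_um2[1:5])
  mean_msd <- Reduce(`+`, curves) / length(curves)
  lag_t <- (1:5) * dt
  expect_lt(max(abs(mean_msd / (6 * lag_t) - D) / D), 0.03)
})

test_that("noiseless MSD curves are fit exactly and classified by their terms", {
  t <- (1:20) * 0.12
  mk <- function(y) structure(data.frame(lag_s = t, msd_um2 = y, n = 50),
                              class = c("msd_curve", "data.frame"))
  f1 <- fit_msd(mk(6 * 0.1 * t))
  expect_equal(f1$D, 0.1, tolerance = 1e-10)
  expect_equal(f1$v, 0, tolerance = 1e-5)
  expect_equal(f1$offset, 0, tolerance = 1e-10)
  expect_equal(f1$classification, "brownian")
  f2 <- fit_msd(mk(0.1^2 * t^2))
  expect_equal(f2$v, 0.1, tolerance = 1e-8)
  expect_equal(f2$D, 0, tolerance = 1e-10)
  expect_equal(f2$classification, "directed")
  # mixed model with offset: exact recovery
  f3 <- fit_msd(mk(6 * 0.02 * t + 0.3^2 * t^2 + 0.01))
  expect_lt(abs(f3$D - 0.02) / 0.02, 1e-8)
  expect_lt(abs(f3$v - 0.3) / 0.3, 1e-8)
  expect_lt(abs(f3$offset - 0.01) / 0.01, 1e-6)
  expect_error(fit_msd(mk(t)[1:3, ]), "4 lags")
})

test_that("the strict printed-form fit exposes its degeneracy", {
  t <- (1:20) * 0.12
  cv <- structure(data.frame(lag_s = t, msd_um2 = 0.1 * t^2 + 0.01, n = 50),
                  class = c("msd_curve", "data.frame"))
  f <- fit_msd(cv, strict_form = TRUE)
  expect_true(f$strict_form)
  expect_equal(f$D, 0.1 / 6, tolerance = 1e-8)  # all curvature lumped into D
  expect_true(is.na(f$v))
})

test_that("diffusion recovery from noisy tracks hits the reported conditions", {
  spec <- sim_spec(seed = 21,
                   shape = c(81, 385, 770),
                   granules = list(n = 100, d_um2_s = 0.41,
                                   velocity_um_s = c(0, 0, 0),
                                   frame_interval_s = 1 / 8.3,
                                   n_frames = 80, loc_sd_nm = 30))
  g <- observe_tracks(simulate_granules(spec), 30, seed = 22)
  fits <- fit_all_tracks(g)
  expect_equal(nrow(fits), 100)
  expect_lt(abs(median(fits$D) - 0.41) / 0.41, 0.15)
})

test_that("classification type-I error stays at the nominal level", {
  spec <- sim_spec(seed = 29, shape = c(81, 385, 770),
                   granules = list(n = 1000, d_um2_s = 0.41,
                                   velocity_um_s = c(0, 0, 0),
                                   frame_interval_s = 1 / 8.3,
                                   n_frames = 80, loc_sd_nm = 30))
  g <- observe_tracks(simulate_granules(spec), 30, seed = 30)
  fits <- fit_all_tracks(g)
  expect_lte(mean(fits$classification == "directed"), 0.07)
})

test_that("fitted D is invariant under rigid rotation of trajectories", {
  spec <- sim_spec(seed = 33, granules = list(n = 5, d_um2_s = 0.2,
                                              velocity_um_s = c(0, 0, 0),
                                              frame_interval_s = 0.12,
                                              n_frames = 60, loc_sd_nm = 0))
  g <- simulate_granules(spec)
  th <- 0.7
  rot <- g
  rot$x_um <- cos(th) * g$x_um - sin(th) * g$y_um
  rot$y_um <- sin(th) * g$x_um + cos(th) * g$y_um
  f0 <- fit_all_tracks(g)
  f1 <- fit_all_tracks(rot)
  expect_equal(f1$D, f0$D, tolerance = 1e-9)
})

test_that("population summaries floor immobile fits and track fold changes", {
  fits_lo <- data.frame(D = rep(5e-4, 10), v = 0,
                        classification = "brownian")
  expect_warning(s0 <- summarize_population(fits_lo), "floor")
  expect_equal(s0$n, 0L)
  set.seed(40)
  fits_a <- data.frame(D = rlnorm(300, log(0.41), 0.3), v = 0)
  fits_b <- data.frame(D = rlnorm(300, log(0.01), 0.3), v = 0)
  s <- summarize_population(fits_a, fits2 = fits_b)
  truth <- exp(log(0.41) + 0.3^2 / 2) / exp(log(0.01) + 0.3^2 / 2)
  expect_lt(abs(s$fold_change - truth) / truth, 0.2)
  # cumulative distribution: non-decreasing, ends at 1
  xs <- seq(min(s$d_values), max(s$d_values), length.out = 50)
  expect_true(all(diff(s$d_ecdf(xs)) >= 0))
  expect_equal(s$d_ecdf(max(s$d_values)), 1)
})

test_that("simulated populations reproduce a large diffusion fold change", {
  mk <- function(seed, D, dt) {
    sim_spec(seed = seed, shape = c(81, 385, 770),
             granules = list(n = 400, d_um2_s = D,
                             velocity_um_s = c(0, 0, 0),
                             frame_interval_s = dt, n_frames = 80,
                             loc_sd_nm = 30))
  }
  fa <- fit_all_tracks(observe_tracks(simulate_granules(mk(41, 0.41, 1 / 8.3)),
                                      30, seed = 43))
  fb <- fit_all_tracks(observe_tracks(simulate_granules(mk(42, 0.01, 1 / 0.6)),
                                      30, seed = 44))
  s <- summarize_population(fa, fits2 = fb)
  expect_lt(abs(s$fold_change - 41) / 41, 0.2)
})
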