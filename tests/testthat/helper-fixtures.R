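# Shared fixture builders (everything generated in code; no stored data).

# Sparse random blob image: enough structure for correlation tests.
blob_image <- function(n = 64, n_blobs = 12, sigma = 2, seed = 7) {
  set.seed(seed)
  img <- matrix(0, n, n)
  xs <- runif(n_blobs, 8, n - 8)
  ys <- runif(n_blobs, 8, n - 8)
  amp <- runif(n_blobs, 0.5, 1)
  gr <- expand.grid(r = seq_len(n), c = seq_len(n))
  for (i in seq_len(n_blobs)) {
    img <- img + amp[i] * matrix(
      exp(-((gr$r - ys[i])^2 + (gr$c - xs[i])^2) / (2 * sigma^2)), n, n)
  }
  img
}

# Well-separated bead positions on a jittered grid (z, y, x in um):
# emulates the selection of isolated beads for resolution measurements.
grid_bead_positions <- function(n = 20, z_center = 10, spacing = 5,
                                jitter = 0.4, seed = 7) {
  set.seed(seed)
  ny <- ceiling(sqrt(n)); nx <- ceiling(n / ny)
  gy <- rep(seq_len(ny), each = nx)[seq_len(n)]
  gx <- rep(seq_len(nx), times = ny)[seq_len(n)]
  cbind(z_center + runif(n, -2, 2),
        gy * spacing + runif(n, -jitter, jitter),
        gx * spacing + runif(n, -jitter, jitter))
}

# Stack shape that comfortably holds those beads.
grid_bead_shape <- function(n = 20, spacing = 5, pitch = c(0.5, 0.104, 0.104),
                            z_slices = 41) {
  ny <- ceiling(sqrt(n)); nx <- ceiling(n / ny)
  c(z_slices,
    ceiling((ny + 1) * spacing / pitch[2]),
    ceiling((nx + 1) * spacing / pitch[3]))
}

# Brute-force circular normalized cross-correlation (spatial-domain oracle).
brute_crosscorr <- function(a, b) {
  d <- dim(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  den <- length(a) * sqrt(mean(a0^2)) * sqrt(mean(b0^2))
  lags_r <- seq_len(d[1]) - (d[1] %/% 2) - 1
  lags_c <- seq_len(d[2]) - (d[2] %/% 2) - 1
  out <- matrix(0, d[1], d[2])
  for (i in seq_along(lags_r)) for (j in seq_along(lags_c)) {
    shifted <- b0[((seq_len(d[1]) - 1 + lags_r[i]) %% d[1]) + 1,
                  ((seq_len(d[2]) - 1 + lags_c[j]) %% d[2]) + 1]
    out[i, j] <- sum(a0 * shifted) / den
  }
  out
}
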