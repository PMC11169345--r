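# Dual-color live-cell processing chain: crop, MIP-based drift correction,
# channel registration, Richardson-Lucy deconvolution, isotropic
# resampling, and quantile normalization.

#' 5-d time series container
#'
#' Volumes indexed (time, channel, Z, Y, X) with a common spatial pitch and
#' frame interval.
#'
#' @param data 5-d numeric array (T, C, Z, Y, X).
#' @param pitch Spatial pitch (z, y, x) in um.
#' @param frame_interval_s Time between volumes (s).
#' @return Object of class `time_series_5d`.
#' @export
time_series_5d <- function(data, pitch, frame_interval_s = 1) {
  stopifnot(is.array(data), length(dim(data)) == 5)
  if (length(pitch) != 3 || any(pitch <= 0)) stop("pitch must be 3 positive values")
  structure(list(data = data, pitch = as.numeric(pitch),
                 frame_interval_s = frame_interval_s),
            class = "time_series_5d")
}

#' @export
print.time_series_5d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("time_series_5d: %d frames x %d channels x %d x %d x %d (Z,Y,X), dt = %.3g s\n",
              d[1], d[2], d[3], d[4], d[5], x$frame_interval_s))
  invisible(x)
}

#' 3-axis drift between two volumes from MIP-pair registration
#'
#' Generates the maximum-intensity projection of both volumes along each
#' axis and registers each 2-d MIP pair by scaled cross-correlation; each
#' axis shift is observed by two of the three projections and the two
#' estimates are averaged.  Degenerate (constant) projections are dropped
#' with a warning, falling back to the remaining observer.
#'
#' @param vol_t,vol_ref 3-d (Z, Y, X) arrays of identical shape.
#' @return Numeric shift `(dz, dy, dx)` in voxels: the displacement of
#'   `vol_t` relative to `vol_ref`.
#' @export
estimate_drift <- function(vol_t, vol_ref) {
  stopifnot(identical(dim(vol_t), dim(vol_ref)))
  # MIP along axis k leaves the other two axes; each 2-d registration
  # observes those two shifts
  observers <- list(`1` = c(2, 3), `2` = c(1, 3), `3` = c(1, 2))
  est <- matrix(NA_real_, 3, 3)   # rows: projection axis; cols: shifted axis
  for (ax in 1:3) {
    ma <- apply(vol_ref, observers[[ax]], max)
    mb <- apply(vol_t, observers[[ax]], max)
    sh <- tryCatch(register_images(ma, mb)$shift, error = function(e) {
      warning("degenerate MIP along axis ", ax, "; using remaining projections")
      NULL
    })
    if (!is.null(sh)) est[ax, observers[[ax]]] <- sh
  }
  drift <- colMeans(est, na.rm = TRUE)
  if (any(!is.finite(drift))) stop("drift unobservable: all projections degenerate")
  drift
}

# Shift one axis of a 3-d array by a fractional amount (linear
# interpolation, edges filled), positive toward increasing indices.
shift_axis <- function(vol, axis, s, fill = 0) {
  if (s == 0) return(vol)
  d <- dim(vol)
  n <- d[axis]
  src <- seq_len(n) - s
  lo <- floor(src)
  fr <- src - lo
  take <- function(i) {
    i <- pmin(pmax(i, 1L), n)
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[axis]] <- i
    do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
  }
  # interpolation weights broadcast along the shifted axis
  w <- array(fr, dim = d[c(axis, setdiff(1:3, axis))])
  w <- aperm(w, order(c(axis, setdiff(1:3, axis))))
  out <- (1 - w) * take(lo) + w * take(lo + 1L)
  oob <- src < 1 | src > n
  if (any(oob)) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[axis]] <- which(oob)
    out <- do.call(`[<-`, c(list(out), idx, list(value = fill)))
  }
  out
}

#' Shift a volume by a fractional (dz, dy, dx)
#'
#' Separable linear interpolation; out-of-frame voxels are filled with
#' `fill` (no Fourier wrap-around, so clamped data stay artifact-free).
#'
#' @param vol 3-d array.
#' @param shift Numeric (dz, dy, dx); positive moves content toward
#'   increasing indices.
#' @param fill Fill value for exposed edges.
#' @return Shifted array.
#' @export
shift_volume <- function(vol, shift, fill = 0) {
  stopifnot(length(shift) == 3)
  for (ax in 1:3) vol <- shift_axis(vol, ax, shift[ax], fill = fill)
  vol
}

#' Inter-channel shift of a dual-color series
#'
#' Averages each channel over time, then estimates the 3-axis shift of
#' channel `b` relative to channel `a` from the MIP pairs.
#'
#' @param series A `time_series_5d`.
#' @param channels Indices of the two channels (reference first).
#' @return Numeric `(dz, dy, dx)` shift of channel 2 relative to channel 1.
#' @export
register_channels <- function(series, channels = c(1, 2)) {
  stopifnot(inherits(series, "time_series_5d"))
  d <- dim(series$data)
  avg <- function(ch) {
    v <- array(0, d[3:5])
    for (t in seq_len(d[1])) v <- v + series$data[t, ch, , , ]
    v / d[1]
  }
  estimate_drift(avg(channels[2]), avg(channels[1]))
}

# Circular FFT convolution of a volume with a PSF stack (PSF centered).
psf_otf <- function(psf_stack, dims) {
  dp <- dim(psf_stack)
  stopifnot(all(dp <= dims))
  pad <- array(0, dims)
  pad[seq_len(dp[1]), seq_len(dp[2]), seq_len(dp[3])] <- psf_stack
  # center the PSF at the origin so convolution does not translate
  pad <- roll_nd(pad, -floor(dp / 2))
  fft(pad)
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative maximum-likelihood update for Poisson noise,
#' `est <- est * [ (obs / (est (*) psf)) (*) psf^T ]`, with FFT (circular)
#' convolution.  The PSF must be normalized to unit sum; the output is
#' non-negative and conserves the flux of interior structures.
#'
#' @param volume Non-negative 3-d array (or `volume_stack`).
#' @param psf A `psf_model` (unit-sum stack).
#' @param iterations Number of RL iterations (>= 1).
#' @return Deconvolved array (or `volume_stack`, matching the input), with
#'   attribute `update_norm`: the per-iteration mean absolute update.
#' @export
richardson_lucy <- function(volume, psf, iterations = 20) {
  if (iterations < 1) stop("iterations must be >= 1")
  is_vs <- inherits(volume, "volume_stack")
  v <- if (is_vs) volume$voxels else volume
  if (any(v < 0)) stop("volume must be non-negative")
  stopifnot(inherits(psf, "psf_model"))
  if (abs(sum(psf$stack) - 1) > 1e-6) stop("PSF must be normalized to unit sum")
  d <- dim(v)
  otf <- psf_otf(psf$stack, d)
  otf_c <- Conj(otf)
  conv <- function(x, o) Re(fft(fft(x) * o, inverse = TRUE)) / prod(d)
  est <- array(mean(v), d)
  eps <- 1e-12
  upd <- numeric(iterations)
  for (it in seq_len(iterations)) {
    blur <- pmax(conv(est, otf), eps)
    ratio <- v / blur
    nxt <- est * conv(ratio, otf_c)
    nxt[nxt < 0] <- 0
    upd[it] <- mean(abs(nxt - est))
    est <- nxt
  }
  out <- if (is_vs) volume_stack(est, volume$pitch, volume$channel,
                                 volume$time) else est
  attr(out, "update_norm") <- upd
  out
}

#' Resample the scan axis to isotropic voxels
#'
#' Linear interpolation along the scan (Z) axis only, to the target pitch
#' (default: the finer lateral pitch); lateral axes are untouched.
#'
#' @param volume 3-d array.
#' @param pitch Current (z, y, x) pitch (um).
#' @param target_pitch New Z pitch (um); default `min(pitch[2:3])`.
#' @return List: `volume` (resampled array), `pitch` (new pitch).
#' @export
isotropize <- function(volume, pitch, target_pitch = NULL) {
  if (is.null(target_pitch)) target_pitch <- min(pitch[2:3])
  d <- dim(volume)
  if (abs(pitch[1] - target_pitch) < 1e-12)
    return(list(volume = volume, pitch = pitch))
  span <- (d[1] - 1) * pitch[1]
  n_new <- floor(span / target_pitch) + 1L
  zi <- (seq_len(n_new) - 1) * target_pitch / pitch[1]   # 0-based source idx
  lo <- pmin(floor(zi), d[1] - 2)
  fr <- zi - lo
  out <- array(0, c(n_new, d[2], d[3]))
  for (k in seq_len(n_new)) {
    out[k, , ] <- (1 - fr[k]) * volume[lo[k] + 1, , ] +
      fr[k] * volume[lo[k] + 2, , ]
  }
  list(volume = out, pitch = c(target_pitch, pitch[2], pitch[3]))
}

#' Background subtraction and quantile normalization
#'
#' Subtracts a scalar background, clamps negative voxels to zero, and
#' divides by the given quantile of the clamped values, so the chosen
#' quantile of the output is exactly 1 (per time point and channel when
#' applied framewise; corrects photobleaching).
#'
#' @param volume Numeric array.
#' @param background Scalar background value.
#' @param quantile Normalization quantile in (0, 1).
#' @return Normalized array.
#' @export
normalize_volume <- function(volume, background = 0, quantile = 0.9995) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  v <- pmax(volume - background, 0)
  q <- stats::quantile(v, quantile, names = FALSE)
  if (q <= 0) stop("all-background volume: zero normalizer")
  v / q
}

#' Scalar background estimate (histogram mode)
#'
#' @param volume Numeric array.
#' @param n_bins Histogram bins.
#' @return The center of the most populated intensity bin.
#' @export
estimate_background <- function(volume, n_bins = 100) {
  h <- graphics::hist(as.numeric(volume), breaks = n_bins, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Run the dual-color live-cell processing pipeline
#'
#' Executes, in order: user-region crop, per-channel drift estimation
#' against the reference time point, channel-averaged drift correction,
#' inter-channel registration, Richardson-Lucy deconvolution, isotropic
#' resampling of the scan axis, and per-frame/channel quantile
#' normalization.  Deterministic given the inputs and config.
#'
#' @param series A `time_series_5d`.
#' @param psf A `psf_model` or list of one per channel.
#' @param config List: `crop` (list of z/y/x index ranges or NULL),
#'   `iterations` (RL, default 20), `quantile` (default 0.9995),
#'   `background` (scalar or NULL = histogram mode of the first frame),
#'   `reference` (drift reference time point, default 1),
#'   `isotropize` (default TRUE).
#' @return List of class `livecell_result`: `series` (processed
#'   `time_series_5d`), `drift` (data frame: per time point and channel and
#'   the applied average), `channel_shift`, `background`, `log`.
#' @export
run_pipeline <- function(series, psf, config = list()) {
  stopifnot(inherits(series, "time_series_5d"))
  cfg <- utils::modifyList(list(crop = NULL, iterations = 20,
                                quantile = 0.9995, background = NULL,
                                reference = 1, isotropize = TRUE), config)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  d <- dim(series$data)
  n_t <- d[1]; n_c <- d[2]
  dat <- series$data
  stage <- "crop"
  if (!is.null(cfg$crop)) {
    dat <- dat[, , cfg$crop$z, cfg$crop$y, cfg$crop$x, drop = FALSE]
    d <- dim(dat)
    note("crop: volume now %d x %d x %d", d[3], d[4], d[5])
  }
  res <- tryCatch({
    stage <- "drift"
    ref <- cfg$reference
    per <- array(0, c(n_t, n_c, 3))
    for (t in seq_len(n_t)) for (ch in seq_len(n_c)) {
      if (t == ref) next
      per[t, ch, ] <- estimate_drift(dat[t, ch, , , ], dat[ref, ch, , , ])
    }
    avg <- apply(per, c(1, 3), mean)
    for (t in seq_len(n_t)) {
      if (all(avg[t, ] == 0)) next
      for (ch in seq_len(n_c))
        dat[t, ch, , , ] <- shift_volume(dat[t, ch, , , ], -avg[t, ])
    }
    note("drift: corrected %d time points (reference %d)", n_t - 1L, ref)

    stage <- "channel registration"
    ch_shift <- rep(0, 3)
    if (n_c >= 2) {
      tmp <- time_series_5d(dat, series$pitch, series$frame_interval_s)
      ch_shift <- register_channels(tmp, c(1, 2))
      for (t in seq_len(n_t))
        dat[t, 2, , , ] <- shift_volume(dat[t, 2, , , ], -ch_shift)
      note("channels: shift (%.3f, %.3f, %.3f) voxels applied",
           ch_shift[1], ch_shift[2], ch_shift[3])
    }

    stage <- "background"
    bg <- cfg$background
    if (is.null(bg)) bg <- estimate_background(dat[1, 1, , , ])
    note("background: %.4g", bg)

    stage <- "deconvolution"
    psfs <- if (inherits(psf, "psf_model")) rep(list(psf), n_c) else psf
    for (t in seq_len(n_t)) for (ch in seq_len(n_c)) {
      dat[t, ch, , , ] <- richardson_lucy(pmax(dat[t, ch, , , ], 0),
                                          psfs[[ch]],
                                          iterations = cfg$iterations)
    }
    note("deconvolution: %d RL iterations", cfg$iterations)

    stage <- "isotropize"
    pitch <- series$pitch
    if (isTRUE(cfg$isotropize)) {
      iso1 <- isotropize(dat[1, 1, , , ], pitch)
      nd <- c(n_t, n_c, dim(iso1$volume))
      newdat <- array(0, nd)
      for (t in seq_len(n_t)) for (ch in seq_len(n_c))
        newdat[t, ch, , , ] <- isotropize(dat[t, ch, , , ], pitch)$volume
      dat <- newdat
      pitch <- iso1$pitch
      note("isotropize: Z resampled to %.3f um", pitch[1])
    }

    stage <- "normalize"
    for (t in seq_len(dim(dat)[1])) for (ch in seq_len(n_c))
      dat[t, ch, , , ] <- normalize_volume(dat[t, ch, , , ], bg,
                                           cfg$quantile)
    note("normalize: background %.4g, quantile %.4f", bg, cfg$quantile)

    drift_df <- do.call(rbind, lapply(seq_len(n_t), function(t) {
      rbind(
        data.frame(time = t, channel = as.character(seq_len(n_c)),
                   dz = per[t, , 1], dy = per[t, , 2], dx = per[t, , 3]),
        data.frame(time = t, channel = "average",
                   dz = avg[t, 1], dy = avg[t, 2], dx = avg[t, 3]))
    }))
    structure(list(series = time_series_5d(dat, pitch,
                                           series$frame_interval_s),
                   drift = drift_df, channel_shift = ch_shift,
                   background = bg, log = log),
              class = "livecell_result")
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
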