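# Bead-based resolution quantification: light-sheet region cropping, bead
# detection, per-axis Gaussian FWHM estimation, axial segmentation
# summaries, and light-sheet dimension quantification.

FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

#' Parametric 3-d Gaussian PSF model
#'
#' Builds a normalized, centered 3-d Gaussian point-spread-function stack
#' from per-axis FWHM values (a parametric stand-in for an inversely
#' modeled experimental PSF; an arbitrary measured stack can be supplied to
#' [psf_model()] instead).
#'
#' @param fwhm_nm FWHM per axis in nm, named `(x, y, z)` or in that order.
#' @param pitch_um Voxel pitch (z, y, x) in um.
#' @param extent_sigmas Half-extent of the model stack in units of sigma.
#' @return Object of class `psf_model`: `stack` (unit-sum (Z,Y,X) array),
#'   `pitch`, `sigma_vox`, `fwhm_nm`.
#' @export
gaussian_psf_model <- function(fwhm_nm = c(x = 570, y = 666, z = 924),
                               pitch_um = c(0.5, 0.104, 0.104),
                               extent_sigmas = 4) {
  fwhm <- unname(fwhm_nm[c("x", "y", "z")] %||% fwhm_nm)
  stopifnot(length(fwhm) == 3, all(fwhm > 0))
  sigma_um <- fwhm / 1000 / FWHM_PER_SIGMA          # (x, y, z) um
  sigma_vox <- rev(sigma_um) / pitch_um              # (z, y, x) voxels
  half <- pmax(2L, ceiling(extent_sigmas * sigma_vox))
  ax <- lapply(seq_len(3), function(k) seq(-half[k], half[k]))
  g <- lapply(seq_len(3), function(k) exp(-ax[[k]]^2 / (2 * sigma_vox[k]^2)))
  stack <- outer(outer(g[[1]], g[[2]]), g[[3]])
  dim(stack) <- c(length(ax[[1]]), length(ax[[2]]), length(ax[[3]]))
  psf_model(stack / sum(stack), pitch_um, fwhm_nm = fwhm)
}

#' PSF model from an arbitrary stack
#'
#' Normalizes to unit sum and verifies the centroid sits within half a voxel
#' of the array center.
#'
#' @param stack 3-d (Z, Y, X) array.
#' @param pitch_um Voxel pitch (z, y, x) in um.
#' @param fwhm_nm Optional parametric origin, FWHM (x, y, z) in nm.
#' @return Object of class `psf_model`.
#' @export
psf_model <- function(stack, pitch_um, fwhm_nm = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3, all(stack >= 0))
  stack <- stack / sum(stack)
  d <- dim(stack)
  ctr <- vapply(seq_len(3), function(ax) {
    w <- apply(stack, ax, sum)
    sum(w * seq_along(w))
  }, numeric(1))
  if (any(abs(ctr - (d + 1) / 2) > 0.5))
    stop("PSF stack is not centered (centroid > 0.5 voxel from center)")
  structure(list(stack = stack, pitch = pitch_um, fwhm_nm = fwhm_nm),
            class = "psf_model")
}

#' Gaussian FWHM of a 1-d intensity profile
#'
#' Least-squares fit of `amplitude * exp(-(i - mu)^2 / (2 sigma^2)) +
#' baseline` to the profile; the width is reported as
#' `2 sqrt(2 ln 2) * sigma` in nm.  Non-convergent fits are returned
#' flagged (`converged = FALSE`, `fwhm_nm = NA`) so callers can exclude
#' them from summaries.
#'
#' @param profile Numeric vector (length >= 7, single dominant peak).
#' @param pitch_um Physical sample spacing of the profile (um).
#' @return List: `fwhm_nm`, `sigma_px`, `mu_px`, `baseline`, `amplitude`,
#'   `residual_norm`, `converged`.
#' @export
measure_fwhm <- function(profile, pitch_um) {
  if (length(profile) < 7) stop("profile must have at least 7 samples")
  if (pitch_um <= 0) stop("pitch must be positive")
  x <- seq_along(profile)
  base0 <- min(profile)
  amp0 <- max(profile) - base0
  if (amp0 <= 0) stop("profile has no peak")
  w <- pmax(profile - base0, 0)
  mu0 <- sum(w * x) / sum(w)
  sd0 <- sqrt(pmax(sum(w * (x - mu0)^2) / sum(w), 0.25))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-(x - m)^2 / (2 * s^2)),
      data = data.frame(x = x, y = profile),
      start = list(b = base0, a = amp0, m = mu0, s = sd0),
      lower = c(-Inf, 0, 1, 1e-3), upper = c(Inf, Inf, length(profile), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(fwhm_nm = NA_real_, sigma_px = NA_real_, mu_px = NA_real_,
                baseline = NA_real_, amplitude = NA_real_,
                residual_norm = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(fwhm_nm = FWHM_PER_SIGMA * cf[["s"]] * pitch_um * 1000,
       sigma_px = cf[["s"]], mu_px = cf[["m"]],
       baseline = cf[["b"]], amplitude = cf[["a"]],
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       converged = TRUE)
}

#' Maximum-intensity projection of a slab
#'
#' Voxelwise maximum over `n_slices` consecutive slices along one axis,
#' centered on `center`; slabs exceeding the stack are clipped with a
#' warning.
#'
#' @param stack A `volume_stack` or 3-d array.
#' @param axis Projection axis (1 = Z, 2 = Y, 3 = X).
#' @param center Central slice index (default: middle of the axis).
#' @param n_slices Slab thickness in slices; `Inf` projects the whole axis.
#' @return 2-d matrix of the projected intensities.
#' @export
mip_slab <- function(stack, axis = 1, center = NULL, n_slices = 10) {
  v <- if (inherits(stack, "volume_stack")) stack$voxels else stack
  d <- dim(v)
  n_ax <- d[axis]
  if (is.infinite(n_slices)) { lo <- 1L; hi <- n_ax }
  else {
    if (is.null(center)) center <- (n_ax + 1L) %/% 2L
    lo <- center - (n_slices - 1L) %/% 2L
    hi <- lo + n_slices - 1L
    if (lo < 1L || hi > n_ax) {
      warning("slab exceeds stack bounds; clipping")
      lo <- max(1L, lo); hi <- min(n_ax, hi)
    }
  }
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- lo:hi
  slab <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  apply(slab, setdiff(1:3, axis), max)
}

# Local normalized cross-correlation of a 2-d image with a template
# (FFT-based; circular edges, so callers exclude a template-sized border).
local_ncc <- function(image, template) {
  di <- dim(image); dt_ <- dim(template)
  stopifnot(all(dt_ <= di))
  t0 <- template - mean(template)
  tn <- sqrt(sum(t0^2))
  if (tn == 0) stop("constant template")
  pad <- function(m) {
    out <- array(0, di)
    out[seq_len(dt_[1]), seq_len(dt_[2])] <- m
    out
  }
  conv_with <- function(img, kern) {
    Re(fft(fft(img) * Conj(fft(pad(kern))), inverse = TRUE)) / prod(di)
  }
  num <- conv_with(image, t0)
  ones <- array(1, dt_)
  s1 <- conv_with(image, ones)
  s2 <- conv_with(image^2, ones)
  nden <- sqrt(pmax(s2 - s1^2 / prod(dt_), 0)) * tn
  ncc <- ifelse(nden > 1e-9 * tn, num / nden, 0)
  # ncc[i,j] corresponds to the template's [1,1] corner at (i,j); shift so
  # it refers to the template center
  roll_nd(ncc, floor(dt_ / 2))
}

# 2-d local maxima (8-neighbourhood) above a threshold, excluding a border.
local_maxima_2d <- function(m, threshold, border = 1L) {
  d <- dim(m)
  ok <- m >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & (m >= roll_nd(m, c(dy, dx)))
  }
  ok[c(seq_len(border), d[1] - seq_len(border) + 1L), ] <- FALSE
  ok[, c(seq_len(border), d[2] - seq_len(border) + 1L)] <- FALSE
  which(ok, arr.ind = TRUE)
}

#' Detect beads by PSF template correlation
#'
#' Correlates the Z maximum-intensity projection of the stack (over a
#' central slab) with the Z-MIP of the PSF model; candidate beads are local
#' correlation maxima above `corr_threshold` that are sufficiently bright
#' (peak above the background by `brightness_sigmas` robust standard
#' deviations).  Any pair of candidates closer than `min_separation` is
#' rejected outright (both members), preventing overlapping measurements.
#'
#' @param stack A `volume_stack`.
#' @param psf A `psf_model` with matching pitch.
#' @param corr_threshold Minimum local normalized correlation.
#' @param min_separation Minimum pairwise lateral distance (um).
#' @param brightness_sigmas Brightness floor in robust background sigmas.
#' @param n_slices Z slab thickness for the stack MIP (`Inf` = all).
#' @return Data frame: `bead`, voxel positions `z`, `y`, `x`, physical
#'   `z_um`, `y_um`, `x_um`, `corr`, `peak_intensity`.
#' @export
detect_beads <- function(stack, psf, corr_threshold = 0.6,
                         min_separation = 2, brightness_sigmas = 5,
                         n_slices = Inf) {
  stopifnot(inherits(stack, "volume_stack"), inherits(psf, "psf_model"))
  if (any(abs(stack$pitch - psf$pitch) > 1e-9))
    stop("PSF pitch must match the stack pitch")
  mip <- mip_slab(stack, axis = 1, n_slices = n_slices)
  tmpl <- apply(psf$stack, c(2, 3), max)
  ncc <- local_ncc(mip, tmpl)
  border <- max(dim(tmpl))
  cand <- local_maxima_2d(ncc, corr_threshold, border = border)
  if (!nrow(cand))
    return(data.frame(bead = integer(0), z = integer(0), y = integer(0),
                      x = integer(0), z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), corr = numeric(0),
                      peak_intensity = numeric(0)))
  bg_mu <- stats::median(mip)
  bg_sd <- stats::mad(mip)
  peak <- mip[cand]
  bright <- peak >= bg_mu + brightness_sigmas * max(bg_sd, 1e-12)
  cand <- cand[bright, , drop = FALSE]
  peak <- peak[bright]
  if (nrow(cand) > 1) {
    py <- cand[, 1] * stack$pitch[2]
    px <- cand[, 2] * stack$pitch[3]
    dmat <- as.matrix(stats::dist(cbind(py, px)))
    diag(dmat) <- Inf
    keep <- apply(dmat, 1, min) >= min_separation
    cand <- cand[keep, , drop = FALSE]
    peak <- peak[keep]
  }
  if (!nrow(cand))
    return(data.frame(bead = integer(0), z = integer(0), y = integer(0),
                      x = integer(0), z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), corr = numeric(0),
                      peak_intensity = numeric(0)))
  zpos <- vapply(seq_len(nrow(cand)), function(i) {
    which.max(stack$voxels[, cand[i, 1], cand[i, 2]])
  }, integer(1))
  data.frame(bead = seq_len(nrow(cand)),
             z = zpos, y = cand[, 1], x = cand[, 2],
             z_um = (zpos - 1) * stack$pitch[1],
             y_um = (cand[, 1] - 1) * stack$pitch[2],
             x_um = (cand[, 2] - 1) * stack$pitch[3],
             corr = ncc[cand],
             peak_intensity = peak)
}

#' Per-axis FWHM of detected beads
#'
#' For each bead, lateral profiles are taken through the bead center on the
#' Z maximum-intensity projection of `n_slices` slices around the bead
#' (`mode = "mip"`, matching the characterization protocol) or on the raw
#' central slice (`mode = "profile"`); the axial profile is taken along Z
#' through the bead after projecting a small lateral neighbourhood.  Each
#' profile is Gaussian-fitted with [measure_fwhm()].
#'
#' @param stack A `volume_stack`.
#' @param beads Data frame from [detect_beads()] (or with voxel `z`, `y`,
#'   `x` columns).
#' @param mode Lateral profile source: `"mip"` or `"profile"`.
#' @param n_slices Z slab thickness for the lateral MIP.
#' @param halfwidth Profile half-length in voxels per lateral axis.
#' @return Data frame of class `fwhm_measurements`: `bead`, positions (um),
#'   `fwhm_x_nm`, `fwhm_y_nm`, `fwhm_z_nm`, `quality` (summed residual
#'   norm), `converged`.
#' @export
measure_bead_fwhm <- function(stack, beads, mode = c("mip", "profile"),
                              n_slices = 10, halfwidth = NULL) {
  mode <- match.arg(mode)
  if (!nrow(beads)) stop("no beads to measure")
  v <- stack$voxels
  d <- dim(v)
  if (is.null(halfwidth))
    halfwidth <- max(7L, ceiling(1 / min(stack$pitch[2:3])))  # ~1 um
  hz <- max(4L, ceiling(3 / stack$pitch[1]))
  # the axial profile projects only a tight lateral neighbourhood, so a
  # neighbouring bead outside ~0.3 um cannot leak into the z profile
  hax <- pmax(2L, ceiling(0.3 / stack$pitch[2:3]))
  rows <- lapply(seq_len(nrow(beads)), function(i) {
    z0 <- beads$z[i]; y0 <- beads$y[i]; x0 <- beads$x[i]
    ys <- max(1L, y0 - halfwidth):min(d[2], y0 + halfwidth)
    xs <- max(1L, x0 - halfwidth):min(d[3], x0 + halfwidth)
    zs <- max(1L, z0 - hz):min(d[1], z0 + hz)
    lat <- if (mode == "mip") {
      lo <- max(1L, z0 - (n_slices - 1L) %/% 2L)
      hi <- min(d[1], lo + n_slices - 1L)
      apply(v[lo:hi, ys, xs, drop = FALSE], c(2, 3), max)
    } else v[z0, ys, xs]
    fx <- measure_fwhm(lat[which(ys == y0), ], stack$pitch[3])
    fy <- measure_fwhm(lat[, which(xs == x0)], stack$pitch[2])
    ya <- max(1L, y0 - hax[1]):min(d[2], y0 + hax[1])
    xa <- max(1L, x0 - hax[2]):min(d[3], x0 + hax[2])
    axial <- apply(v[zs, ya, xa, drop = FALSE], 1, max)
    fz <- measure_fwhm(axial, stack$pitch[1])
    data.frame(bead = if (is.null(beads$bead)) i else beads$bead[i],
               z_um = (z0 - 1) * stack$pitch[1],
               y_um = (y0 - 1) * stack$pitch[2],
               x_um = (x0 - 1) * stack$pitch[3],
               fwhm_x_nm = fx$fwhm_nm, fwhm_y_nm = fy$fwhm_nm,
               fwhm_z_nm = fz$fwhm_nm,
               quality = sum(c(fx$residual_norm, fy$residual_norm,
                               fz$residual_norm), na.rm = TRUE),
               converged = fx$converged && fy$converged && fz$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fwhm_measurements", class(out))
  out
}

#' Crop the light-sheet region, tracking the tilted waist line
#'
#' Crops a Y window of physical width `fov_length` from every Z slice,
#' centered on the light-sheet waist line `y_waist(z) = y0 + a z` (the
#' sheet translates in Y while scanning in Z).  Windows are aligned to
#' integer voxels with the fractional remainder carried forward so the mean
#' crop center tracks the waist line exactly; out-of-bounds windows are
#' clipped (content padded with the slice edge value) and flagged.
#'
#' @param stack A `volume_stack`.
#' @param fov_length Crop width along Y (um).
#' @param tilt_a Waist Y shift per unit Z (um/um).
#' @param y0_um Waist Y position at z = 0 (um); default stack center.
#' @return A `volume_stack` of the cropped region with attributes
#'   `crop_table` (data frame: `z`, `y_start`, `clipped`) and `y0_um`.
#' @export
crop_lightsheet_region <- function(stack, fov_length, tilt_a, y0_um = NULL) {
  stopifnot(inherits(stack, "volume_stack"))
  d <- dim(stack$voxels)
  py <- stack$pitch[2]; pz <- stack$pitch[1]
  if (fov_length > d[2] * py) stop("fov_length exceeds the Y extent")
  w <- max(3L, round(fov_length / py))
  if (is.null(y0_um)) y0_um <- (d[2] - 1) / 2 * py
  z_um <- (seq_len(d[1]) - 1) * pz
  centers <- (y0_um + tilt_a * z_um) / py + 1   # voxel coords of waist
  desired <- centers - (w - 1) / 2
  if (tilt_a == 0) {
    # flat waist line: one window for every slice
    starts <- rep(round(desired[1]), d[1])
  } else {
    # integer windows with the fractional remainder carried forward, so
    # the mean crop center tracks the waist line exactly
    starts <- integer(d[1]); carry <- 0
    for (i in seq_len(d[1])) {
      s <- round(desired[i] + carry)
      carry <- carry + desired[i] - s
      starts[i] <- s
    }
  }
  if (all(starts > d[2]) || all(starts + w - 1L < 1L))
    stop("waist line exits the frame for every slice: empty crop")
  out <- array(0, c(d[1], w, d[3]))
  clipped <- logical(d[1])
  for (i in seq_len(d[1])) {
    idx <- starts[i]:(starts[i] + w - 1L)
    inb <- pmin(pmax(idx, 1L), d[2])
    clipped[i] <- any(idx != inb)
    out[i, , ] <- stack$voxels[i, inb, ]
  }
  res <- volume_stack(out, stack$pitch, channel = stack$channel,
                      time = stack$time)
  attr(res, "crop_table") <- data.frame(z = seq_len(d[1]), y_start = starts,
                                        clipped = clipped)
  attr(res, "y0_um") <- y0_um
  res
}

#' Per-segment resolution summary
#'
#' Divides the measurements into axial segments of `segment_um` and reports
#' the per-segment mean and standard deviation of each axis FWHM, with an
#' optional polynomial trend over the segment means.  Non-convergent
#' measurements are excluded; empty segments are omitted.
#'
#' @param measurements A `fwhm_measurements` data frame.
#' @param segment_um Axial segment height (um).
#' @param trend_degree Degree of the polynomial trend over segment means
#'   (0 = none).
#' @return List: `segments` (data frame with per-axis mean/sd and counts),
#'   `trend` (list of `lm` fits per axis or NULL).
#' @export
summarize_resolution <- function(measurements, segment_um = 5,
                                 trend_degree = 0) {
  keep <- if (is.null(measurements$converged)) TRUE else measurements$converged
  m <- measurements[keep, , drop = FALSE]
  if (!nrow(m)) stop("no valid measurements")
  seg <- floor(m$z_um / segment_um)
  agg <- function(x) {
    mu <- tapply(x, seg, mean)
    sdv <- tapply(x, seg, stats::sd)
    list(mean = mu, sd = sdv)
  }
  ax <- lapply(list(x = m$fwhm_x_nm, y = m$fwhm_y_nm, z = m$fwhm_z_nm), agg)
  segs <- sort(unique(seg))
  out <- data.frame(
    segment = segs,
    z_center_um = (segs + 0.5) * segment_um,
    n = as.integer(table(factor(seg, levels = segs))),
    mean_fwhm_x_nm = unname(ax$x$mean[as.character(segs)]),
    sd_fwhm_x_nm = unname(ax$x$sd[as.character(segs)]),
    mean_fwhm_y_nm = unname(ax$y$mean[as.character(segs)]),
    sd_fwhm_y_nm = unname(ax$y$sd[as.character(segs)]),
    mean_fwhm_z_nm = unname(ax$z$mean[as.character(segs)]),
    sd_fwhm_z_nm = unname(ax$z$sd[as.character(segs)]))
  trend <- NULL
  if (trend_degree > 0 && nrow(out) > trend_degree) {
    trend <- lapply(c("x", "y", "z"), function(a) {
      stats::lm(out[[paste0("mean_fwhm_", a, "_nm")]] ~
                  stats::poly(out$z_center_um, trend_degree))
    })
    names(trend) <- c("x", "y", "z")
  }
  list(segments = out, trend = trend)
}

#' Light-sheet dimension quantification
#'
#' From per-bead `(z, y, FWHMz)` measurements: estimates the waist tilt `a`
#' (Y shift of the waist per unit Z) by profiled least squares (the tilt
#' minimizing the residual of the beam-width fit in the corrected
#' coordinate), corrects the bead coordinates `y' = y - a z`, fits the beam
#' width as an even polynomial of `y'`, and reports the waist (fit minimum)
#' and the light-sheet FOV length: the width over which the fitted FWHMz
#' stays below twice the waist.
#'
#' By default the polynomial is fitted to the squared width
#' (`fit_space = "squared"`), where the Gaussian-beam profile
#' `W(y') = W0 sqrt(1 + (y'/yR)^2)` is exactly quadratic, so waist and FOV
#' are recovered without approximation bias; `fit_space = "direct"` fits
#' the width itself with an even polynomial of degree `degree`.
#'
#' @param measurements Data frame with `z_um`, `y_um` and `fwhm_z_nm`.
#' @param degree Even-polynomial degree (2, 4 or 6); applies to the chosen
#'   fit space.
#' @param fit_space `"squared"` (fit FWHMz^2; default degree 2) or
#'   `"direct"` (fit FWHMz; default degree 4).
#' @param tilt_a Known tilt to use instead of estimating (optional).
#' @param tilt_bracket Search interval for the tilt estimate (um/um).
#' @return Object of class `lightsheet_quant`: `tilt_a`, `coefficients`
#'   (of the fitted polynomial, in the chosen space, about the centered
#'   y'), `waist_fwhm_nm`, `waist_y_um`, `fov_length_um`,
#'   `y_corrected_um`.
#' @export
quantify_lightsheet <- function(measurements, degree = NULL,
                                fit_space = c("squared", "direct"),
                                tilt_a = NULL, tilt_bracket = c(-1, 1)) {
  fit_space <- match.arg(fit_space)
  if (is.null(degree)) degree <- if (fit_space == "squared") 2 else 4
  stopifnot(all(c("z_um", "y_um", "fwhm_z_nm") %in% names(measurements)),
            degree %in% c(2, 4, 6))
  m <- measurements[is.finite(measurements$fwhm_z_nm), , drop = FALSE]
  if (nrow(m) < 6) stop("too few valid measurements")
  pows <- seq_len(degree)
  tilt_given <- tilt_a
  estimate_on <- function(mm) {
    resp <- if (fit_space == "squared") mm$fwhm_z_nm^2 else mm$fwhm_z_nm
    fit_at <- function(a) {
      u <- mm$y_um - a * mm$z_um
      u <- u - mean(u)
      X <- matrix(1, length(u), length(pows) + 1)
      for (k in seq_along(pows)) X[, k + 1] <- u^pows[k]
      f <- stats::lm.fit(X, resp)
      list(rss = sum(f$residuals^2), cf = f$coefficients, u = u,
           resid = f$residuals)
    }
    a <- if (is.null(tilt_given)) {
      stats::optimize(function(a) fit_at(a)$rss,
                      interval = tilt_bracket)$minimum
    } else tilt_given
    c(fit_at(a), list(a = a))
  }
  # gross width outliers (a contaminated profile fit can be tens of times
  # too wide) would dominate the least squares; trim by robust residuals
  fit <- estimate_on(m)
  for (pass in 1:2) {
    s <- stats::mad(fit$resid)
    keep <- abs(fit$resid) <= 6 * max(s, 1e-9)
    if (all(keep) || sum(keep) < 6) break
    m <- m[keep, , drop = FALSE]
    fit <- estimate_on(m)
  }
  tilt_a <- fit$a
  cf <- fit$cf
  yp <- m$y_um - tilt_a * m$z_um
  predict_raw <- function(u) {
    X <- matrix(1, length(u), length(pows) + 1)
    for (k in seq_along(pows)) X[, k + 1] <- u^pows[k]
    drop(X %*% cf)
  }
  predict_f <- if (fit_space == "squared") {
    function(u) sqrt(pmax(predict_raw(u), 0))
  } else predict_raw
  rng <- range(fit$u)
  grid <- seq(rng[1], rng[2], length.out = 2001)
  vals <- predict_f(grid)
  i_min <- which.min(vals)
  if (i_min %in% c(1L, length(grid)))
    stop("fitted minimum lies outside the sampled y' range; refusing to extrapolate")
  opt <- stats::optimize(predict_f,
                         interval = grid[c(max(1, i_min - 10),
                                           min(length(grid), i_min + 10))])
  waist <- opt$objective
  y_min <- opt$minimum
  target <- 2 * waist
  half_width <- function(dir) {
    lim <- y_min + dir * 1.5 * max(abs(rng))
    g <- function(u) predict_f(u) - target
    if (g(lim) < 0) return(NA_real_)
    abs(stats::uniroot(g, interval = sort(c(y_min, lim)))$root - y_min)
  }
  hw <- c(half_width(-1), half_width(1))
  fov <- if (any(is.na(hw))) NA_real_ else sum(hw)
  structure(list(tilt_a = tilt_a, coefficients = cf, powers = c(0, pows),
                 fit_space = fit_space,
                 y_center = mean(yp),
                 waist_fwhm_nm = waist,
                 waist_y_um = y_min + mean(yp),
                 fov_length_um = fov,
                 y_corrected_um = yp),
            class = "lightsheet_quant")
}

#' @export
print.lightsheet_quant <- function(x, ...) {
  cat(sprintf("light sheet: waist FWHMz %.0f nm at y' = %.2f um, FOV %.2f um, tilt a = %.4f\n",
              x$waist_fwhm_nm, x$waist_y_um, x$fov_length_um, x$tilt_a))
  invisible(x)
}
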