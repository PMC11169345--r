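# Seeded generators for every input the analyses need, with ground truth:
# bead stacks under a tilted Gaussian light sheet, S/P image pairs,
# parallel-line calibration targets, granule random walks, and dual-color
# volumetric movies with drift and noise.

#' Simulation specification
#'
#' Collects every generator parameter with defaults matching the imaging
#' conditions the analyses characterize: 104 nm lateral pixels, 500 nm
#' axial steps, bead PSF FWHM (570, 666, 924) nm in (X, Y, Z), a Gaussian
#' light-sheet envelope with 850 nm waist FWHM, Rayleigh-like length
#' 2.3 um and Y-per-Z tilt 0.14, sCMOS-like noise (Poisson photons +
#' Gaussian read noise on a 100-count offset), and granule imaging at 8.3
#' volumes/s for 80 volumes.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param shape Volume shape (Z, Y, X) in voxels.
#' @param pitch_um Voxel pitch (z, y, x) in um.
#' @param psf_fwhm_nm PSF FWHM (x, y, z) in nm.
#' @param lightsheet List(`waist_fwhm_nm`, `yR_um`, `tilt`) or NULL to
#'   disable the axial envelope (beads then carry `psf_fwhm_nm[3]` axially).
#' @param noise List(`photon_scale` = expected peak photons,
#'   `read_sd` = Gaussian read noise, `offset` = camera offset counts), or
#'   NULL for a noiseless unit-amplitude render.
#' @param n_beads Bead count for [generate_bead_stack()].
#' @param granules List(`n`, `d_um2_s`, `velocity_um_s` (length-3),
#'   `frame_interval_s`, `n_frames`, `loc_sd_nm`).
#' @param drift_um_per_frame Length-3 (z, y, x) linear stage drift.
#' @param channel_offset_vox Length-3 inter-channel shift (voxels).
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1,
                     shape = c(41, 192, 192),
                     pitch_um = c(0.5, 0.104, 0.104),
                     psf_fwhm_nm = c(x = 570, y = 666, z = 924),
                     lightsheet = NULL,
                     noise = list(photon_scale = 2000, read_sd = 2,
                                  offset = 100),
                     n_beads = 20,
                     granules = list(n = 10, d_um2_s = 0.41,
                                     velocity_um_s = c(0, 0, 0),
                                     frame_interval_s = 1 / 8.3,
                                     n_frames = 80, loc_sd_nm = 30),
                     drift_um_per_frame = c(0, 0, 0),
                     channel_offset_vox = c(0, 0, 0)) {
  stopifnot(all(pitch_um > 0), length(shape) == 3)
  if (!is.null(granules) && granules$d_um2_s < 0) stop("D must be >= 0")
  structure(as.list(environment()), class = "sim_spec")
}

# Add a 3-d Gaussian spot of peak `amp` at physical position (um) into a
# (Z,Y,X) array; sigma_um is (z, y, x).  Local window render.
add_gaussian_spot <- function(vol, pitch, pos_um, sigma_um, amp) {
  d <- dim(vol)
  ctr <- pos_um / pitch + 1
  half <- ceiling(4 * sigma_um / pitch)
  rng <- lapply(1:3, function(k) {
    max(1L, floor(ctr[k] - half[k])):min(d[k], ceiling(ctr[k] + half[k]))
  })
  if (any(vapply(rng, length, integer(1)) == 0)) return(vol)
  gz <- exp(-((rng[[1]] - ctr[1]) * pitch[1])^2 / (2 * sigma_um[1]^2))
  gy <- exp(-((rng[[2]] - ctr[2]) * pitch[2])^2 / (2 * sigma_um[2]^2))
  gx <- exp(-((rng[[3]] - ctr[3]) * pitch[3])^2 / (2 * sigma_um[3]^2))
  spot <- amp * outer(outer(gz, gy), gx)
  dim(spot) <- c(length(gz), length(gy), length(gx))
  cur <- vol[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  vol[rng[[1]], rng[[2]], rng[[3]]] <- cur + spot
  vol
}

apply_camera_noise <- function(vol, noise) {
  if (is.null(noise)) return(vol)
  counts <- stats::rpois(length(vol), lambda = as.numeric(vol))
  counts <- counts + stats::rnorm(length(vol), 0, noise$read_sd) +
    noise$offset
  array(counts, dim(vol))
}

#' Generate a bead stack with ground truth
#'
#' Renders `n_beads` point emitters as 3-d Gaussians with the spec PSF
#' widths.  When a light-sheet envelope is configured, the axial width of
#' each bead is the envelope value at its tilt-corrected sheet coordinate,
#' `FWHMz(y') = W0 sqrt(1 + (y'/yR)^2)` with `y' = y - a z` measured from
#' the sheet waist line through the volume center.  Poisson photon noise
#' plus Gaussian read noise on a camera offset is applied unless the spec
#' disables it.
#'
#' @param spec A [sim_spec()].
#' @param bead_positions_um Optional matrix of (z, y, x) positions (um);
#'   default: seeded uniform positions away from the borders.  Beads
#'   falling outside the volume are dropped with a note.
#' @return List: `stack` (a `volume_stack`), `truth` (data frame: `bead`,
#'   positions (um), true `fwhm_x_nm`, `fwhm_y_nm`, `fwhm_z_nm`).
#' @export
generate_bead_stack <- function(spec, bead_positions_um = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    d <- spec$shape
    pitch <- spec$pitch_um
    ext <- (d - 1) * pitch
    if (is.null(bead_positions_um)) {
      margin <- pmin(0.2 * ext, c(3, 3, 3))
      bead_positions_um <- cbind(
        stats::runif(spec$n_beads, margin[1], ext[1] - margin[1]),
        stats::runif(spec$n_beads, margin[2], ext[2] - margin[2]),
        stats::runif(spec$n_beads, margin[3], ext[3] - margin[3]))
    }
    bead_positions_um <- matrix(bead_positions_um, ncol = 3)
    inside <- bead_positions_um[, 1] >= 0 & bead_positions_um[, 1] <= ext[1] &
      bead_positions_um[, 2] >= 0 & bead_positions_um[, 2] <= ext[2] &
      bead_positions_um[, 3] >= 0 & bead_positions_um[, 3] <= ext[3]
    if (any(!inside))
      message(sum(!inside), " bead(s) outside the volume dropped")
    pos <- bead_positions_um[inside, , drop = FALSE]
    fwhm <- unname(spec$psf_fwhm_nm[c("x", "y", "z")] %||% spec$psf_fwhm_nm)
    n <- nrow(pos)
    fz <- rep(fwhm[3], n)
    if (!is.null(spec$lightsheet)) {
      ls <- spec$lightsheet
      y0 <- ext[2] / 2 ; z0 <- ext[1] / 2
      yp <- (pos[, 2] - y0) - ls$tilt * (pos[, 1] - z0)
      fz <- ls$waist_fwhm_nm * sqrt(1 + (yp / ls$yR_um)^2)
    }
    amp <- if (is.null(spec$noise)) 1 else spec$noise$photon_scale
    vol <- array(0, d)
    for (i in seq_len(n)) {
      sigma_um <- c(fz[i], fwhm[2], fwhm[1]) / 1000 / FWHM_PER_SIGMA
      vol <- add_gaussian_spot(vol, pitch, pos[i, ], sigma_um, amp)
    }
    vol <- apply_camera_noise(vol, spec$noise)
    list(stack = volume_stack(vol, pitch),
         truth = data.frame(bead = seq_len(n), z_um = pos[, 1],
                            y_um = pos[, 2], x_um = pos[, 3],
                            fwhm_x_nm = fwhm[1], fwhm_y_nm = fwhm[2],
                            fwhm_z_nm = fz))
  })
}

#' Generate an S/P polarization image pair with a known offset
#'
#' The P image is a Fourier-shifted, intensity-scaled, independently noised
#' copy of the S image.
#'
#' @param base 2-d base image (the S content).
#' @param offset True (row, col) sub-pixel shift of P relative to S.
#' @param intensity_ratio P/S intensity ratio.
#' @param noise_sd Additive Gaussian noise sd (independent per image).
#' @param seed RNG seed.
#' @return List: `s`, `p` (images), `offset` (the ground truth).
#' @export
generate_sp_pair <- function(base, offset = c(0, 0), intensity_ratio = 1,
                             noise_sd = 0, seed = 1) {
  d <- dim(base)
  if (any(abs(offset) >= d / 4))
    stop("offset too large relative to the image extent")
  with_seed(seed, {
    p <- fourier_shift(base, offset) * intensity_ratio
    s <- base
    if (noise_sd > 0) {
      s <- s + stats::rnorm(length(s), 0, noise_sd)
      p <- p + stats::rnorm(length(p), 0, noise_sd)
    }
    list(s = matrix(s, d[1], d[2]), p = matrix(p, d[1], d[2]),
         offset = offset)
  })
}

#' Generate a parallel-line calibration target
#'
#' Gaussian-profile lines at exact sub-pixel positions with a known
#' spacing; the ground-truth peak spacing in pixels is
#' `line_spacing_um / pixel_size_um`.
#'
#' @param line_spacing_um Physical line spacing (um).
#' @param pixel_size_um Sample-plane pixel size (um).
#' @param shape Image shape (rows, cols).
#' @param line_fwhm_um Line FWHM (um); must be below the spacing.
#' @param orientation 0 (lines run horizontally; intensity varies down the
#'   rows) or 90 (transposed).
#' @param amplitude Peak line intensity above background.
#' @param background Background level.
#' @param noise_sd Additive Gaussian noise sd.
#' @param phase_px Sub-pixel offset of the line comb (px).
#' @param seed RNG seed (noise only).
#' @return List: `image`, `delta_d_px` (true spacing in px),
#'   `positions_px` (true line centers, rows).
#' @export
generate_calibration_target <- function(line_spacing_um = 10,
                                        pixel_size_um = 0.5,
                                        shape = c(256, 256),
                                        line_fwhm_um = 1.5,
                                        orientation = 0,
                                        amplitude = 1000, background = 100,
                                        noise_sd = 0, phase_px = 0.25,
                                        seed = 1) {
  if (line_spacing_um <= line_fwhm_um)
    stop("line spacing must exceed the line width")
  dd <- line_spacing_um / pixel_size_um
  n_lines <- floor((shape[1] - 1) / dd) + 1L
  if (n_lines < 3) stop("fewer than 3 lines fit in the frame")
  first <- (shape[1] - (n_lines - 1) * dd) / 2 + phase_px
  centers <- first + (seq_len(n_lines) - 1) * dd
  sigma_px <- line_fwhm_um / pixel_size_um / FWHM_PER_SIGMA
  rows <- seq_len(shape[1])
  profile <- rep(background, shape[1])
  for (c0 in centers)
    profile <- profile + amplitude * exp(-(rows - c0)^2 / (2 * sigma_px^2))
  img <- matrix(profile, shape[1], shape[2])
  if (noise_sd > 0)
    img <- with_seed(seed, img + stats::rnorm(length(img), 0, noise_sd))
  if (orientation == 90) img <- t(img)
  list(image = img, delta_d_px = dd, positions_px = centers)
}

#' Simulate granule trajectories (Brownian + directed motion)
#'
#' Per-axis Gaussian steps with standard deviation `sqrt(2 D dt)` plus a
#' constant drift velocity, reflected at the volume boundaries (keeping
#' track lengths fixed).  Positions are exact ground truth; add seeded
#' localization noise with [observe_tracks()] to emulate measurement.
#'
#' @param spec A [sim_spec()]; uses `granules`, `shape`, `pitch_um`, `seed`.
#' @return Data frame: `track_id`, `frame`, `t_s`, `x_um`, `y_um`, `z_um`.
#' @export
simulate_granules <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  g <- spec$granules
  ext <- (spec$shape - 1) * spec$pitch_um     # (z, y, x) um
  box <- c(ext[3], ext[2], ext[1])            # work in (x, y, z)
  with_seed(spec$seed, {
    step_sd <- sqrt(2 * g$d_um2_s * g$frame_interval_s)
    v_step <- g$velocity_um_s * g$frame_interval_s
    tracks <- lapply(seq_len(g$n), function(id) {
      p <- stats::runif(3, 0.25 * box, 0.75 * box)
      pos <- matrix(0, g$n_frames, 3)
      pos[1, ] <- p
      for (fr in seq_len(g$n_frames)[-1]) {
        p <- p + stats::rnorm(3, 0, step_sd) + v_step
        # reflecting boundaries
        for (k in 1:3) {
          while (p[k] < 0 || p[k] > box[k]) {
            if (p[k] < 0) p[k] <- -p[k]
            if (p[k] > box[k]) p[k] <- 2 * box[k] - p[k]
          }
        }
        pos[fr, ] <- p
      }
      data.frame(track_id = id, frame = seq_len(g$n_frames),
                 t_s = (seq_len(g$n_frames) - 1) * g$frame_interval_s,
                 x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
    })
    do.call(rbind, tracks)
  })
}

#' Add localization noise to trajectories
#'
#' @param tracks Track table from [simulate_granules()].
#' @param loc_sd_nm Isotropic localization sd (nm).
#' @param seed RNG seed.
#' @return The track table with noised coordinates.
#' @export
observe_tracks <- function(tracks, loc_sd_nm = 30, seed = 1) {
  if (loc_sd_nm <= 0) return(tracks)
  with_seed(seed, {
    s <- loc_sd_nm / 1000
    n <- nrow(tracks)
    tracks$x_um <- tracks$x_um + stats::rnorm(n, 0, s)
    tracks$y_um <- tracks$y_um + stats::rnorm(n, 0, s)
    tracks$z_um <- tracks$z_um + stats::rnorm(n, 0, s)
    tracks
  })
}

#' Render a dual-color granule movie with drift and noise
#'
#' Channel 1 carries the granules (Gaussian spots with the spec PSF);
#' channel 2 carries a membrane-like ellipsoidal shell plus a dim copy of
#' the granule signal (the channels of a real cell share gross structure;
#' without any shared content an inter-channel offset would not be
#' observable), both displaced by the configured inter-channel offset.
#' A global linear drift accumulates per frame, then camera noise is
#' applied.  All ground truth (per-frame drift, channel offset, positions)
#' is returned.
#'
#' @param tracks Track table from [simulate_granules()].
#' @param spec A [sim_spec()].
#' @return List: `series` (`time_series_5d`), `truth` (list: `drift_um`
#'   per-frame matrix, `channel_offset_vox`, `tracks`).
#' @export
render_movie <- function(tracks, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  d <- spec$shape
  pitch <- spec$pitch_um
  frames <- sort(unique(tracks$frame))
  n_t <- length(frames)
  sigma_um <- rev(unname(spec$psf_fwhm_nm[c("x", "y", "z")] %||%
                           spec$psf_fwhm_nm)) / 1000 / FWHM_PER_SIGMA
  amp <- if (is.null(spec$noise)) 1 else spec$noise$photon_scale
  ext <- (d - 1) * pitch
  # membrane surrogate: an ellipsoidal shell around the volume center
  shell <- array(0, d)
  ctr <- ext / 2
  ax <- ext * 0.3
  zz <- ((seq_len(d[1]) - 1) * pitch[1] - ctr[1]) / ax[1]
  yy <- ((seq_len(d[2]) - 1) * pitch[2] - ctr[2]) / ax[2]
  xx <- ((seq_len(d[3]) - 1) * pitch[3] - ctr[3]) / ax[3]
  r2 <- outer(outer(zz^2, yy^2, `+`), xx^2, `+`)
  shell <- amp * 0.25 * exp(-(sqrt(r2) - 1)^2 / (2 * 0.08^2))
  off_um <- spec$channel_offset_vox * pitch
  drift <- outer(seq_len(n_t) - 1, spec$drift_um_per_frame)  # (t, zyx) um
  dat <- array(0, c(n_t, 2, d))
  with_seed(spec$seed + 1L, {
    for (ti in seq_len(n_t)) {
      v1 <- array(0, d)
      v2 <- shift_volume(shell, (drift[ti, ] + off_um) / pitch, fill = 0)
      sub <- tracks[tracks$frame == frames[ti], , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        pos_zyx <- c(sub$z_um[i], sub$y_um[i], sub$x_um[i]) + drift[ti, ]
        v1 <- add_gaussian_spot(v1, pitch, pos_zyx, sigma_um, amp)
        v2 <- add_gaussian_spot(v2, pitch, pos_zyx + off_um, sigma_um, amp)
      }
      dat[ti, 1, , , ] <- apply_camera_noise(v1, spec$noise)
      dat[ti, 2, , , ] <- apply_camera_noise(v2, spec$noise)
    }
  })
  series <- time_series_5d(dat, pitch,
                           frame_interval_s = spec$granules$frame_interval_s)
  list(series = series,
       truth = list(drift_um = drift,
                    channel_offset_vox = spec$channel_offset_vox,
                    tracks = tracks))
}
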