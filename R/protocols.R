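# End-to-end characterization protocols: the standard analyses run by the
# workflow scripts, the test suite and the acceptance script.  Each one
# generates its own synthetic input (seeded), runs the measurement chain,
# and returns both the estimates and the generator truth.

#' Well-separated bead layout
#'
#' Jittered-grid bead positions emulating the selection of isolated beads
#' for resolution measurements (pairwise separation safely above the
#' overlap-rejection floor).
#'
#' @param n Bead count.
#' @param z_center,z_jitter Axial placement (um).
#' @param spacing Grid pitch (um).
#' @param jitter Lateral jitter (um).
#' @param seed RNG seed.
#' @return Matrix of (z, y, x) positions (um).
#' @export
well_separated_positions <- function(n = 20, z_center = 10, z_jitter = 2,
                                     spacing = 5, jitter = 0.4, seed = 1) {
  with_seed(seed, {
    ny <- ceiling(sqrt(n)); nx <- ceiling(n / ny)
    gy <- rep(seq_len(ny), each = nx)[seq_len(n)]
    gx <- rep(seq_len(nx), times = ny)[seq_len(n)]
    cbind(z_center + stats::runif(n, -z_jitter, z_jitter),
          gy * spacing + stats::runif(n, -jitter, jitter),
          gx * spacing + stats::runif(n, -jitter, jitter))
  })
}

#' Bead-based resolution characterization protocol
#'
#' Generates well-separated beads with the given ground-truth FWHM, detects
#' them by PSF-template correlation, and measures per-axis FWHM by the
#' MIP-slab (10 slices at the axial step) + Gaussian-fit procedure.
#'
#' @param seed Seed for both layout and imaging noise.
#' @param fwhm_nm Ground-truth FWHM (x, y, z) in nm.
#' @param n_beads Bead count.
#' @param pitch_um Voxel pitch (z, y, x) in um.
#' @param noise Camera noise spec (see [sim_spec()]).
#' @param n_slices MIP slab thickness.
#' @return List: `measurements`, `mean_fwhm_nm`, `sd_fwhm_nm` (named x/y/z),
#'   `truth_fwhm_nm`, `n_used`.
#' @export
characterize_bead_resolution <- function(seed = 1,
                                         fwhm_nm = c(x = 570, y = 666,
                                                     z = 924),
                                         n_beads = 20,
                                         pitch_um = c(0.5, 0.104, 0.104),
                                         noise = list(photon_scale = 2000,
                                                      read_sd = 2,
                                                      offset = 100),
                                         n_slices = 10) {
  pos <- well_separated_positions(n = n_beads, seed = seed)
  ny <- ceiling(sqrt(n_beads)); nx <- ceiling(n_beads / ny)
  shape <- c(41,
             ceiling((ny + 1) * 5 / pitch_um[2]),
             ceiling((nx + 1) * 5 / pitch_um[3]))
  spec <- sim_spec(seed = seed + 1L, shape = shape, pitch_um = pitch_um,
                   psf_fwhm_nm = fwhm_nm, noise = noise,
                   n_beads = n_beads)
  bs <- generate_bead_stack(spec, bead_positions_um = pos)
  psf <- gaussian_psf_model(fwhm_nm = fwhm_nm, pitch_um = pitch_um)
  det <- detect_beads(bs$stack, psf, min_separation = 2)
  meas <- measure_bead_fwhm(bs$stack, det, mode = "mip",
                            n_slices = n_slices)
  m <- meas[meas$converged, , drop = FALSE]
  list(measurements = meas,
       mean_fwhm_nm = c(x = mean(m$fwhm_x_nm), y = mean(m$fwhm_y_nm),
                        z = mean(m$fwhm_z_nm)),
       sd_fwhm_nm = c(x = stats::sd(m$fwhm_x_nm),
                      y = stats::sd(m$fwhm_y_nm),
                      z = stats::sd(m$fwhm_z_nm)),
       truth_fwhm_nm = fwhm_nm,
       n_used = nrow(m))
}

#' Light-sheet dimension characterization protocol
#'
#' Simulates beads spread across the sheet coordinate under the
#' Gaussian-beam axial envelope (waist `W0`, Rayleigh-like length `yR`,
#' tilt `a`), measures per-bead axial FWHM from the rendered stack, and
#' runs [quantify_lightsheet()].
#'
#' @param seed RNG seed.
#' @param waist_fwhm_nm Envelope waist FWHM (nm).
#' @param yR_um Rayleigh-like length (um).
#' @param tilt Waist Y shift per unit Z (um/um).
#' @param n_beads Bead count (spread over +-`y_span` around the waist).
#' @param y_span Half-range of sheet-coordinate sampling (um).
#' @param noise Camera noise spec.
#' @return List: `quant` (a `lightsheet_quant`), `measurements`,
#'   `analytic_fov_um` (`2 sqrt(3) yR`), `truth`.
#' @export
characterize_lightsheet <- function(seed = 1, waist_fwhm_nm = 850,
                                    yR_um = 2.3, tilt = 0.14,
                                    n_beads = 100, y_span = 6,
                                    noise = list(photon_scale = 2000,
                                                 read_sd = 2,
                                                 offset = 100)) {
  pitch <- c(0.5, 0.104, 0.104)
  n_rows <- 10
  n_cols <- ceiling(n_beads / n_rows)
  shape <- c(41, ceiling((2 * y_span + 7) / pitch[2]),
             ceiling((n_cols + 1) * 4.2 / pitch[3]))
  ext_y <- (shape[2] - 1) * pitch[2]
  pos <- with_seed(seed, {
    yrow <- rep(seq(-y_span, y_span, length.out = n_rows),
                times = n_cols)[seq_len(n_beads)]
    xcol <- rep(seq(3, by = 4.2, length.out = n_cols),
                each = n_rows)[seq_len(n_beads)]
    z <- stats::runif(n_beads, 2, 18)
    cbind(z,
          ext_y / 2 + tilt * (z - 10) + yrow +
            stats::runif(n_beads, -0.2, 0.2),
          xcol + stats::runif(n_beads, -0.2, 0.2))
  })
  spec <- sim_spec(seed = seed + 1L, shape = shape, pitch_um = pitch,
                   noise = noise, n_beads = n_beads,
                   lightsheet = list(waist_fwhm_nm = waist_fwhm_nm,
                                     yR_um = yR_um, tilt = tilt))
  bs <- generate_bead_stack(spec, bead_positions_um = pos)
  det <- data.frame(bead = seq_len(nrow(pos)),
                    z = round(pos[, 1] / pitch[1]) + 1L,
                    y = round(pos[, 2] / pitch[2]) + 1L,
                    x = round(pos[, 3] / pitch[3]) + 1L)
  meas <- measure_bead_fwhm(bs$stack, det)
  m <- meas[meas$converged, , drop = FALSE]
  quant <- quantify_lightsheet(m)
  list(quant = quant, measurements = m,
       analytic_fov_um = 2 * sqrt(3) * yR_um,
       truth = list(waist_fwhm_nm = waist_fwhm_nm, yR_um = yR_um,
                    tilt = tilt))
}

#' Diffusion-coefficient recovery protocol
#'
#' Simulates Brownian granule trajectories at the given imaging rate, adds
#' localization noise, computes time-averaged MSDs and fits the
#' diffusion-plus-transport model.
#'
#' @param seed RNG seed.
#' @param d_um2_s Ground-truth diffusion coefficient (um^2/s).
#' @param velocity_um_s Ground-truth velocity vector (um/s).
#' @param n_tracks Track count.
#' @param frame_interval_s Volume interval (s).
#' @param n_frames Frames per track.
#' @param loc_sd_nm Localization noise (nm).
#' @return List: `fits` (per-track), `median_d`, `median_v`, `truth`.
#' @export
recover_motion_parameters <- function(seed = 1, d_um2_s = 0.41,
                                      velocity_um_s = c(0, 0, 0),
                                      n_tracks = 200,
                                      frame_interval_s = 1 / 8.3,
                                      n_frames = 80, loc_sd_nm = 30) {
  # volume sized so reflections are negligible over the track duration
  sigma_tot <- sqrt(6 * d_um2_s * frame_interval_s * n_frames) +
    sqrt(sum(velocity_um_s^2)) * frame_interval_s * n_frames
  half <- max(20, 10 * sigma_tot)
  shape <- c(ceiling(2 * half / 0.5), ceiling(2 * half / 0.104),
             ceiling(2 * half / 0.104))
  spec <- sim_spec(seed = seed, shape = shape,
                   granules = list(n = n_tracks, d_um2_s = d_um2_s,
                                   velocity_um_s = velocity_um_s,
                                   frame_interval_s = frame_interval_s,
                                   n_frames = n_frames,
                                   loc_sd_nm = loc_sd_nm))
  tracks <- observe_tracks(simulate_granules(spec), loc_sd_nm,
                           seed = seed + 1L)
  fits <- fit_all_tracks(tracks)
  list(fits = fits,
       median_d = stats::median(fits$D),
       median_v = stats::median(fits$v, na.rm = TRUE),
       truth = list(d_um2_s = d_um2_s, velocity_um_s = velocity_um_s))
}
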