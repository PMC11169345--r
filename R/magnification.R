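# Relative and absolute magnification estimation from parallel-line
# calibration-target images across scan positions.

# Bilinear resample of `img` scaled by `s` about its center (s > 1 zooms
# in: features appear s times larger).  Out-of-frame samples clamp to the
# edge.
rescale_about_center <- function(img, s) {
  d <- dim(img)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  ys <- cy + (seq_len(d[1]) - cy) / s
  xs <- cx + (seq_len(d[2]) - cx) / s
  y0 <- pmin(pmax(floor(ys), 1), d[1] - 1)
  x0 <- pmin(pmax(floor(xs), 1), d[2] - 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  a00 <- img[cbind(rep(y0, length(x0)), rep(x0, each = length(y0)))]
  a10 <- img[cbind(rep(y0 + 1, length(x0)), rep(x0, each = length(y0)))]
  a01 <- img[cbind(rep(y0, length(x0)), rep(x0 + 1, each = length(y0)))]
  a11 <- img[cbind(rep(y0 + 1, length(x0)), rep(x0 + 1, each = length(y0)))]
  wy <- rep(fy, length(x0)); wx <- rep(fx, each = length(y0))
  out <- (1 - wy) * (1 - wx) * a00 + wy * (1 - wx) * a10 +
    (1 - wy) * wx * a01 + wy * wx * a11
  matrix(out, d[1], d[2])
}

center_crop <- function(img, size) {
  d <- dim(img)
  size <- min(size, d)
  oy <- (d[1] - size) %/% 2L
  ox <- (d[2] - size) %/% 2L
  img[oy + seq_len(size), ox + seq_len(size)]
}

#' Relative zoom between two images
#'
#' Isotropic scale factor of the best-fit similarity map (scale + shift)
#' taking `image` onto `reference`: the scale is found by golden-section
#' search maximizing the peak scaled cross-correlation between the rescaled
#' image and the reference (the shift is absorbed by the correlation).
#' Returns the factor by which `image` is magnified relative to
#' `reference` (1.05 means 5 % larger).
#'
#' @param image,reference 2-d images containing the same pattern.
#' @param crop Center-crop size applied to both before registration (px).
#' @param bracket Search interval for the zoom factor.
#' @param corr_floor Registration failure threshold on the attained peak
#'   correlation.
#' @return Zoom factor (dimensionless).
#' @export
relative_zoom <- function(image, reference, crop = 700,
                          bracket = c(0.85, 1.18), corr_floor = 0.2) {
  image <- center_crop(image, crop)
  reference <- center_crop(reference, crop)
  score <- function(s) {
    r <- rescale_about_center(image, 1 / s)
    max(scaled_crosscorr(r, reference)$values)
  }
  # periodic targets produce correlation ripples in scale, so a golden
  # section alone can lock onto a sidelobe: coarse grid first, then refine
  grid <- seq(bracket[1], bracket[2], by = 0.0025)
  coarse <- vapply(grid, score, numeric(1))
  s0 <- grid[which.max(coarse)]
  opt <- stats::optimize(score, interval = c(s0 - 0.003, s0 + 0.003),
                         maximum = TRUE, tol = 1e-5)
  if (opt$objective < corr_floor)
    stop("zoom registration failed: peak correlation below floor")
  opt$maximum
}

#' Absolute magnification from a parallel-line target
#'
#' Averages the image over the line direction, smooths the profile with a
#' centered running average (reflected edges), finds all peaks above a
#' prominence floor, refines each peak to sub-pixel precision with a local
#' parabola, and converts the mean consecutive-peak spacing `delta_d` (px)
#' into the sample-plane pixel size `line_spacing / delta_d` and the
#' magnification `camera_pixel / pixel_size`.
#'
#' @param image 2-d image of parallel lines.
#' @param line_spacing_um Physical spacing of consecutive lines (um).
#' @param camera_pixel_um Camera pixel size (um).
#' @param smooth_window Running-average window (px).
#' @param line_axis Direction the lines run: `"h"` (horizontal, profile
#'   taken along columns) or `"v"`.
#' @param min_prominence_frac Peak prominence floor as a fraction of the
#'   profile dynamic range.
#' @return List: `magnification`, `pixel_size_um`, `delta_d_px`, `n_peaks`,
#'   `peak_positions_px`.
#' @export
absolute_magnification <- function(image, line_spacing_um = 10,
                                   camera_pixel_um = 6.5,
                                   smooth_window = 30,
                                   line_axis = c("h", "v"),
                                   min_prominence_frac = 0.1) {
  line_axis <- match.arg(line_axis)
  # "h": lines run along rows, so intensity varies down the image and the
  # profile is the per-row mean; "v" is the transpose case.
  profile <- if (line_axis == "h") rowMeans(image) else colMeans(image)
  sm <- running_mean(profile, smooth_window)
  prom <- min_prominence_frac * diff(range(sm))
  pk <- find_peaks_1d(sm, min_prominence = prom)
  if (length(pk) < 3)
    stop("insufficient pattern: fewer than 3 line peaks found")
  refined <- vapply(pk, function(p) {
    if (p <= 1 || p >= length(sm)) return(as.numeric(p))
    p + subpixel_peak_1d(-1:1, sm[(p - 1):(p + 1)])
  }, numeric(1))
  dd <- mean(diff(refined))
  pixel_size <- line_spacing_um / dd
  list(magnification = camera_pixel_um / pixel_size,
       pixel_size_um = pixel_size,
       delta_d_px = dd,
       n_peaks = length(pk),
       peak_positions_px = refined)
}

#' Magnification curve across scan positions
#'
#' Relative zoom of every image against the reference image, anchored to an
#' absolute magnification measured at the reference via the line-spacing
#' method and propagated by the zoom factors.  Images whose registration or
#' peak finding fails are skipped with a log entry.
#'
#' @param images List of 2-d calibration-target images.
#' @param positions Scan positions (um), same length as `images`.
#' @param reference Index of the reference image; default the position
#'   closest to 0.
#' @param ... Passed to [absolute_magnification()].
#' @param crop Center-crop size for the zoom registration.
#' @return Object of class `magnification_curve`: data frame with
#'   `position_um`, `relative_zoom`, `magnification`, `pixel_size_um`;
#'   skipped positions are recorded in `attr(, "log")`.
#' @export
magnification_curve <- function(images, positions, reference = NULL,
                                crop = 700, ...) {
  stopifnot(length(images) == length(positions), length(images) >= 2)
  if (is.null(reference)) reference <- which.min(abs(positions))
  anchor <- absolute_magnification(images[[reference]], ...)
  log <- character(0)
  rows <- lapply(seq_along(images), function(i) {
    z <- tryCatch({
      if (i == reference) 1
      else relative_zoom(images[[i]], images[[reference]], crop = crop)
    }, error = function(e) {
      log[[length(log) + 1L]] <<- sprintf("position %g: %s", positions[i],
                                          conditionMessage(e))
      NA_real_
    })
    if (is.na(z)) return(NULL)
    mag <- anchor$magnification * z
    data.frame(position_um = positions[i], relative_zoom = z,
               magnification = mag,
               pixel_size_um = anchor$pixel_size_um / z)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position_um), ]
  rownames(out) <- NULL
  attr(out, "log") <- log
  class(out) <- c("magnification_curve", class(out))
  out
}
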