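# Sub-pixel offset estimation between S- and P-polarized images (and
# between stacks) by scaled cross-correlation with per-axis second-order
# polynomial peak interpolation.

#' Scaled cross-correlation surface
#'
#' Mean-subtracted, unit-variance-normalized circular cross-correlation of
#' two equally shaped 2-d or 3-d arrays, computed by FFT.  Identical inputs
#' give a peak of exactly 1 at zero lag; all values lie in `[-1, 1]`.
#' The surface is arranged with zero lag at the central index, and a
#' positive lag on an axis means `b` is displaced toward increasing indices
#' relative to `a`.
#'
#' @param a,b Numeric arrays of identical shape, non-constant.
#' @return Object of class `corr_surface`: `values` (lag-shifted array),
#'   `lags` (list of per-axis lag vectors), `origin` (index of zero lag).
#' @export
scaled_crosscorr <- function(a, b) {
  if (is.null(dim(a))) dim(a) <- length(a)
  if (is.null(dim(b))) dim(b) <- length(b)
  if (!identical(dim(a), dim(b))) stop("images must have identical shape")
  sa <- pop_sd(a); sb <- pop_sd(b)
  if (sa == 0 || sb == 0)
    stop("degenerate input: constant image has no correlation structure")
  a0 <- a - mean(a); b0 <- b - mean(b)
  n <- length(a0)
  cc <- Re(fft(Conj(fft(a0)) * fft(b0), inverse = TRUE)) / n
  cc <- cc / (n * sa * sb)
  cc <- fftshift_nd(array(cc, dim(a)))
  lags <- lapply(dim(a), axis_lags)
  origin <- vapply(dim(a), function(nn) nn %/% 2L + 1L, integer(1))
  structure(list(values = cc, lags = lags, origin = origin),
            class = "corr_surface")
}

# Least-squares quadratic through (x, y) around a peak; fractional vertex.
# Falls back to 0 if the fit has no interior maximum.
subpixel_peak_1d <- function(x, y) {
  v <- quad_vertex(x, y)
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  if (!is.finite(v) || fit$coefficients[3] >= 0) return(0)
  if (abs(v) >= 1) return(0)
  v
}

#' Sub-pixel peak location of a correlation surface
#'
#' Finds the integer argmax (ties broken deterministically toward the
#' smallest absolute lag) and refines each axis by fitting a second-order
#' polynomial through the peak and its `fit_window` neighbours on either
#' side along that axis; the parabola vertex gives the fractional shift.
#'
#' @param surface A `corr_surface` from [scaled_crosscorr()].
#' @param fit_window Half-width of the per-axis fit window (>= 1).
#' @return Object of class `subpixel_offset`: `shift` (fractional lags per
#'   axis), `peak_value`, `fit_window`.
#' @export
find_offset_subpixel <- function(surface, fit_window = 1) {
  stopifnot(inherits(surface, "corr_surface"), fit_window >= 1)
  v <- surface$values
  d <- dim(v)
  mx <- max(v)
  cand <- which(v >= mx - 1e-12, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    lagmat <- vapply(seq_along(d),
                     function(ax) surface$lags[[ax]][cand[, ax]],
                     numeric(nrow(cand)))
    lagmat <- matrix(lagmat, nrow = nrow(cand))
    key <- rowSums(abs(lagmat))
    ord <- do.call(order, c(list(key), lapply(seq_along(d),
                                              function(ax) abs(lagmat[, ax])),
                            lapply(seq_along(d), function(ax) lagmat[, ax])))
    cand <- cand[ord[1], , drop = FALSE]
  }
  peak <- as.integer(cand[1, ])
  if (any(peak - fit_window < 1L) || any(peak + fit_window > d))
    stop("correlation peak on the surface border: shift too large for the fit window")
  shift <- numeric(length(d))
  for (ax in seq_along(d)) {
    idx <- lapply(seq_along(d), function(k) peak[k])
    prof <- vapply(-fit_window:fit_window, function(o) {
      idx[[ax]] <- peak[ax] + o
      do.call(`[`, c(list(v), idx))
    }, numeric(1))
    frac <- subpixel_peak_1d(-fit_window:fit_window, prof)
    shift[ax] <- surface$lags[[ax]][peak[ax]] + frac
  }
  structure(list(shift = shift, peak_value = mx, fit_window = fit_window),
            class = "subpixel_offset")
}

#' Sub-pixel offset between two images
#'
#' Convenience wrapper: scaled cross-correlation followed by polynomial
#' peak interpolation.  Positive shifts mean `b` is displaced toward
#' increasing indices relative to `a`; `register_images(a, b)$shift` is the
#' amount by which `b` must be shifted back to align with `a`.
#'
#' @inheritParams scaled_crosscorr
#' @inheritParams find_offset_subpixel
#' @return A `subpixel_offset`.
#' @export
register_images <- function(a, b, fit_window = 1) {
  find_offset_subpixel(scaled_crosscorr(a, b), fit_window = fit_window)
}

#' 3-axis sub-pixel offset between two stacks
#'
#' The same scaled-correlation + per-axis polynomial peak fit applied to the
#' full 3-d correlation surface.
#'
#' @param stack_a,stack_b 3-d arrays of identical shape.
#' @inheritParams find_offset_subpixel
#' @return A `subpixel_offset` with a length-3 `shift` in (z, y, x) order
#'   (array axis order).
#' @export
find_stack_offset <- function(stack_a, stack_b, fit_window = 1) {
  stopifnot(length(dim(stack_a)) == 3)
  register_images(stack_a, stack_b, fit_window = fit_window)
}

#' Alignment monitor: per-frame offset log against a reference
#'
#' The software analog of the interactive S/P overlay monitor: each incoming
#' frame is registered to the reference and the offset logged; the monitor
#' reports convergence once the offset magnitude stays below `threshold`
#' for `k` consecutive frames.
#'
#' @param reference Reference image.
#' @param stream List of images sharing the reference's shape.
#' @param threshold Convergence threshold on the offset magnitude (px).
#' @param k Number of consecutive in-threshold frames required.
#' @inheritParams find_offset_subpixel
#' @return Data frame with one row per frame: `frame`, per-axis `shift_*`,
#'   `magnitude`, `within_threshold`, `converged` (TRUE from the frame at
#'   which the criterion is first met onward).
#' @export
alignment_monitor <- function(reference, stream, threshold = 0.1, k = 3,
                              fit_window = 1) {
  if (!length(stream))
    return(data.frame(frame = integer(0), magnitude = numeric(0),
                      within_threshold = logical(0), converged = logical(0)))
  offs <- lapply(stream, function(fr) {
    register_images(reference, fr, fit_window = fit_window)$shift
  })
  sh <- do.call(rbind, offs)
  colnames(sh) <- paste0("shift_", seq_len(ncol(sh)))
  mag <- sqrt(rowSums(sh^2))
  within <- mag < threshold
  run <- 0L
  converged <- logical(length(mag))
  met <- FALSE
  for (i in seq_along(mag)) {
    run <- if (within[i]) run + 1L else 0L
    if (run >= k) met <- TRUE
    converged[i] <- met
  }
  cbind(data.frame(frame = seq_along(stream)), as.data.frame(sh),
        data.frame(magnitude = mag, within_threshold = within,
                   converged = converged))
}

#' @export
print.subpixel_offset <- function(x, ...) {
  cat("sub-pixel offset:", paste(sprintf("%+.3f", x$shift), collapse = ", "),
      sprintf("(peak corr %.4f)\n", x$peak_value))
  invisible(x)
}
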