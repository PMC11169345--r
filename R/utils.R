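# Internal numeric helpers shared across modules.

# Population standard deviation (cross-correlation normalization uses the
# n-denominator form so that a perfect autocorrelation peaks at exactly 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Evaluate code with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed without
#' disturbing the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fftshift-style lag vector for an axis of length n: index i of the shifted
# array corresponds to lag lags[i], with lag 0 at floor(n/2) + 1.
axis_lags <- function(n) seq_len(n) - (n %/% 2L) - 1L

# Reorder an n-d array so that zero lag sits at the central index.
fftshift_nd <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) ((seq_len(n) - 1L + (n - n %/% 2L)) %% n) + 1L)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Shift an n-d array by a (possibly fractional) vector using the Fourier
# shift theorem; positive shift moves content toward increasing indices.
fourier_shift <- function(x, shift) {
  d <- dim(x)
  if (is.null(d)) {
    d <- length(x)
    dim(x) <- d
  }
  stopifnot(length(shift) == length(d))
  ph <- array(0, d)
  for (ax in seq_along(d)) {
    k <- c(0:(d[ax] %/% 2), -((d[ax] - 1) %/% 2):-1)[seq_len(d[ax])]
    ramp <- -2i * pi * k * shift[ax] / d[ax]
    perm <- array(ramp, dim = c(d[ax], d[-ax]))
    if (length(d) > 1) perm <- aperm(perm, order(c(ax, seq_along(d)[-ax])))
    ph <- ph + perm
  }
  Re(fft(fft(x) * exp(ph), inverse = TRUE)) / prod(d)
}

# Circular integer roll of an n-d array (test oracle convenience and
# synthetic-shift construction).
roll_nd <- function(x, shift) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  stopifnot(length(shift) == length(d))
  idx <- Map(function(n, s) ((seq_len(n) - 1L - as.integer(s)) %% n) + 1L,
             d, shift)
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  dim(out) <- d
  out
}

# Centered running mean with reflected edges.
running_mean <- function(x, window) {
  stopifnot(window >= 1)
  if (window == 1) return(x)
  n <- length(x)
  half <- window %/% 2
  pad <- c(rev(x[seq_len(min(half, n))]), x,
           rev(x[seq.int(max(1L, n - half + 1L), n)]))
  cs <- cumsum(c(0, pad))
  # x[i] sits at pad index i + half; centered window spans pad[i .. i+window-1]
  lo <- seq_len(n)
  hi <- lo + window - 1L
  (cs[hi + 1L] - cs[lo]) / window
}

# Local maxima of a 1-d profile with a minimum prominence. Prominence of a
# peak is its height above the higher of the two deepest valleys separating
# it from larger neighbours; for these well-separated line profiles the
# simple definition (height minus max of the minima to the nearest larger
# peak or edge) suffices.
find_peaks_1d <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  is_peak <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(is_peak)) return(integer(0))
  keep <- vapply(is_peak, function(p) {
    left <- x[seq_len(p - 1)]
    right <- x[seq.int(p + 1, n)]
    higher_l <- which(left >= x[p])
    higher_r <- which(right >= x[p])
    base_l <- if (length(higher_l)) min(x[seq.int(max(higher_l), p - 1)]) else min(left)
    base_r <- if (length(higher_r)) min(x[seq.int(p + 1, p + min(higher_r))]) else min(right)
    (x[p] - max(base_l, base_r)) >= min_prominence
  }, logical(1))
  is_peak[keep]
}

# Vertex of the least-squares quadratic through points (offsets, values);
# returns the abscissa of the extremum relative to offset 0.
quad_vertex <- function(offsets, values) {
  fit <- stats::lm.fit(cbind(1, offsets, offsets^2), values)
  b <- unname(fit$coefficients)
  if (!is.finite(b[3]) || b[3] == 0) return(0)
  -b[2] / (2 * b[3])
}
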