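# Minimal voxel container used throughout: a 3-d intensity array in fixed
# (Z, Y, X) order plus the physical pitch per axis.  Z is the scan/detection
# axis, Y the light-sheet propagation axis.

#' Volume stack: voxels plus physical pitch
#'
#' @param voxels 3-d numeric array ordered (Z, Y, X).
#' @param pitch Physical voxel pitch per axis in um, named or in (z, y, x)
#'   order.
#' @param channel,time Optional metadata.
#' @return Object of class `volume_stack`.
#' @export
volume_stack <- function(voxels, pitch, channel = NA, time = NA) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  pitch <- unname(pitch[c("z", "y", "x")[seq_along(pitch)]] %||% pitch)
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3 || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("pitch must be three positive values (z, y, x)")
  structure(list(voxels = voxels, pitch = pitch,
                 channel = channel, time = time),
            class = "volume_stack")
}

`%||%` <- function(a, b) if (is.null(a) || any(is.na(a))) b else a

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("volume_stack %d x %d x %d (Z,Y,X), pitch %.3f x %.3f x %.3f um\n",
              d[1], d[2], d[3], x$pitch[1], x$pitch[2], x$pitch[3]))
  invisible(x)
}

#' Read a TIFF stack into a volume_stack
#'
#' Slices of a multi-page TIFF become the Z axis.
#'
#' @param path TIFF file path.
#' @param pitch Voxel pitch (z, y, x) in um.
#' @return A `volume_stack`.
#' @export
read_volume_tiff <- function(path, pitch) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  volume_stack(arr, pitch)
}

#' Write a volume_stack to a multi-page TIFF
#'
#' Intensities are rescaled to the unit range required by the TIFF writer.
#'
#' @param stack A `volume_stack`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_volume_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF requires the 'tiff' package")
  v <- stack$voxels
  rng <- range(v)
  if (diff(rng) > 0) v <- (v - rng[1]) / diff(rng)
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
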