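# Voxel grids and single-channel volume images.
#
# Conventions used throughout the package:
#  * axis order is (z, y, x) everywhere;
#  * voxel indices are 0-based in all physical conversions, so the physical
#    coordinate of voxel i along an axis is i * spacing (voxel centers);
#  * R arrays are 1-based, so array index j corresponds to voxel index j - 1.

#' Create a voxel grid
#'
#' A voxel grid describes the geometry of a 3D image: voxel counts per axis
#' and the physical spacing (micrometres per voxel) along each axis, in
#' (z, y, x) order. Physical coordinate = 0-based voxel index times spacing.
#'
#' @param shape integer vector of length 3, voxel counts along (z, y, x).
#' @param spacing numeric vector of length 3, micrometres per voxel along
#'   (z, y, x). Typical confocal FISH stacks have z spacing (0.3 um) larger
#'   than the xy pixel size (~0.1 um).
#' @return An object of class `voxel_grid`.
#' @examples
#' voxel_grid(c(16, 64, 64), c(0.3, 0.1, 0.1))
#' @export
voxel_grid <- function(shape, spacing) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || length(spacing) != 3L)
    stop("shape and spacing must have length 3 (z, y, x)")
  if (any(shape < 1L)) stop("all shape components must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacings must be finite and > 0")
  structure(list(shape = shape, spacing = spacing), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> shape (z,y,x) = %s; spacing um = %s\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", ")))
  invisible(x)
}

#' Create a volume image
#'
#' Bundles a 3D intensity array with its [voxel_grid()] and acquisition
#' metadata (channel name, optional frame index).
#'
#' @param data numeric 3D array with `dim` equal to `grid$shape` (z, y, x).
#' @param grid a [voxel_grid()].
#' @param channel channel name, e.g. `"ser2p"`.
#' @param frame optional integer frame index for timelapse data.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, grid, channel = "ch0", frame = NA_integer_) {
  if (!inherits(grid, "voxel_grid")) stop("grid must be a voxel_grid")
  data <- as.array(data)
  if (length(dim(data)) != 3L || !all(dim(data) == grid$shape))
    stop("data dimensions must equal grid$shape (z, y, x)")
  if (any(!is.finite(data))) stop("image intensities must be finite")
  structure(list(data = data, grid = grid, channel = as.character(channel),
                 frame = as.integer(frame)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> channel=%s frame=%s %s voxels, range [%g, %g]\n",
              x$channel, ifelse(is.na(x$frame), "-", x$frame),
              paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Convert 0-based voxel coordinates to micrometres
#'
#' @param vox numeric matrix (n x 3) or vector of length 3 of 0-based voxel
#'   coordinates in (z, y, x) order; sub-voxel values allowed.
#' @param grid a [voxel_grid()].
#' @return Matrix (or vector) of physical coordinates in micrometres.
#' @export
voxel_to_um <- function(vox, grid) {
  if (is.null(dim(vox))) return(as.numeric(vox) * grid$spacing)
  sweep(vox, 2L, grid$spacing, `*`)
}

#' Convert micrometre coordinates to 0-based voxel coordinates
#'
#' @inheritParams voxel_to_um
#' @param um physical coordinates in micrometres, (z, y, x).
#' @export
um_to_voxel <- function(um, grid) {
  if (is.null(dim(um))) return(as.numeric(um) / grid$spacing)
  sweep(um, 2L, grid$spacing, `/`)
}

# 0-based (z,y,x) voxel center coordinates for every voxel, as an n x 3
# matrix in array (column-major) order. Used by rasterizers and oracles.
grid_voxel_coords <- function(grid) {
  s <- grid$shape
  z <- rep(seq_len(s[1]) - 1L, times = s[2] * s[3])
  y <- rep(rep(seq_len(s[2]) - 1L, each = s[1]), times = s[3])
  x <- rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  cbind(z = z, y = y, x = x)
}

# Linear (1-based, column-major) index from 1-based (z,y,x) index matrix.
zyx_to_linear <- function(idx, shape) {
  (idx[, 1L]) + (idx[, 2L] - 1L) * shape[1L] +
    (idx[, 3L] - 1L) * shape[1L] * shape[2L]
}

# Inverse of zyx_to_linear: 1-based (z,y,x) from linear indices.
linear_to_zyx <- function(lin, shape) {
  lin0 <- lin - 1L
  z <- lin0 %% shape[1L]
  y <- (lin0 %/% shape[1L]) %% shape[2L]
  x <- lin0 %/% (shape[1L] * shape[2L])
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}
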