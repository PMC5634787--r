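#' 3D intensity stack container
#'
#' A thin wrapper around a 3D numeric array in `(z, y, x)` axis order with an
#' isotropic voxel edge length and an acquisition time.  Voxel centers sit at
#' `(index - 1) * voxel_size` µm (0-based integer grid).
#'
#' @param values 3D non-negative numeric array, axis order `(z, y, x)`.
#' @param voxel_size Voxel edge length in µm (isotropic), `> 0`. Default 3.
#' @param time Acquisition time in hours since the first image.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(values, voxel_size = 3, time = 0) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3D array in (z, y, x) order")
  if (any(dim(values) < 8))
    stop("stack must be at least 8 voxels along every axis")
  if (!all(is.finite(values)))
    stop("stack intensities must be finite")
  if (any(values < 0))
    stop("stack intensities must be non-negative")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a positive scalar")
  structure(list(values = values, voxel_size = voxel_size, time = time),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), %.3g um/voxel, t = %.2f hr\n",
              d[1], d[2], d[3], x$voxel_size, x$time))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Binary voxel mask container
#'
#' @param values 3D logical array, axis order `(z, y, x)`.
#' @param voxel_size Voxel edge length in µm, `> 0`.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(values, voxel_size = 3) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3D array in (z, y, x) order")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1))) stop("mask values must be logical or 0/1")
    values <- array(as.logical(values), dim(values))
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a positive scalar")
  structure(list(values = values, voxel_size = voxel_size),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel_mask: %d x %d x %d voxels, %d foreground (%.3g um/voxel)\n",
              d[1], d[2], d[3], sum(x$values), x$voxel_size))
  invisible(x)
}

# voxel-center coordinates (um) along one axis of a stack of extent n
voxel_centers <- function(n, voxel_size) (seq_len(n) - 1) * voxel_size
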