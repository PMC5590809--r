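#' Image volume with tumor mask
#'
#' The unit of image input for the pipeline: a 3D intensity grid, a binary
#' tumor mask of the same dimensions, and the physical voxel spacing.
#'
#' Axis convention (stated once, used everywhere): arrays are stored in R's
#' native column-major order with dimensions `(x, y, z)`; `spacing` and
#' `origin` are aligned to those axes, in millimetres. Voxel indices used in
#' file I/O are 0-based; voxel `i` (0-based) along an axis with spacing `s`
#' has its center at `origin + i * s`.
#'
#' @param intensities Numeric 3D array.
#' @param mask Logical (or 0/1) 3D array, same dimensions.
#' @param spacing Positive numeric length-3 vector, mm per voxel per axis.
#' @param origin Numeric length-3 vector, mm.
#' @return An object of class `volume_mask`.
#' @export
volume_mask <- function(intensities, mask, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  stop_if_not(is.array(intensities) && length(dim(intensities)) == 3,
              "intensities must be a 3D array")
  stop_if_not(identical(dim(intensities), dim(mask)),
              "intensities and mask must have identical dimensions")
  stop_if_not(length(spacing) == 3 && all(spacing > 0),
              "spacing must be 3 positive lengths (mm)")
  mask <- array(as.logical(mask), dim = dim(mask))
  stop_if_not(!anyNA(mask), "mask must not contain NA")
  structure(list(intensities = intensities, mask = mask,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume_mask> %d x %d x %d voxels, spacing %s mm, %d masked\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

masked_values <- function(v) v$intensities[v$mask]

check_nonempty_mask <- function(v) {
  stop_if_not(any(v$mask), "mask has no voxels inside the analysis region")
}

#' Discretized gray-level volume
#'
#' Holds the gray-level alphabet that the texture matrices (co-occurrence,
#' run-length, size-zone) are built on. Levels are positive integers inside
#' the mask and 0 outside.
#'
#' @param levels Integer 3D array, 0 outside the mask.
#' @param n_levels Number of gray levels (the maximum observed level).
#' @param bin_width Intensity width of one level.
#' @param mask Logical 3D array.
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(levels, n_levels, bin_width, mask) {
  stop_if_not(identical(dim(levels), dim(mask)), "levels/mask dim mismatch")
  stop_if_not(all(levels[mask] >= 1L) && max(levels[mask]) == n_levels,
              "levels must be in 1..n_levels inside the mask")
  structure(list(levels = levels, n_levels = as.integer(n_levels),
                 bin_width = bin_width, mask = mask),
            class = "gray_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  cat(sprintf("<gray_volume> %s voxels, %d levels (bin width %g)\n",
              paste(dim(x$levels), collapse = "x"), x$n_levels, x$bin_width))
  invisible(x)
}
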