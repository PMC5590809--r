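# Geometry and intensity normalization applied before feature extraction.

# Resample one axis by 1D linear interpolation; trilinear interpolation of a
# 3D grid factorizes into three such passes.
resample_axis <- function(a, axis, old_spacing, new_spacing, new_n) {
  n <- dim(a)[axis]
  pos <- (seq_len(new_n) - 1) * new_spacing / old_spacing   # 0-based old units
  i0 <- pmin(pmax(floor(pos), 0), n - 1)
  i1 <- pmin(i0 + 1, n - 1)
  w <- pos - i0
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, nrow = d[1])
  out <- m[i0 + 1, , drop = FALSE] * (1 - w) + m[i1 + 1, , drop = FALSE] * w
  aperm(array(out, dim = c(new_n, d[2], d[3])), order(perm))
}

#' Resample a volume to a target voxel spacing
#'
#' Trilinear interpolation for intensities; the mask is interpolated
#' linearly and re-binarized at 0.5, so it stays a strict binary region.
#' The physical extent of the grid is preserved to within one voxel. The
#' standard pipeline resamples every scan to 1 x 1 x 1 mm before feature
#' extraction so that texture offsets and shape measures are expressed in
#' physical units.
#'
#' @param v A [volume_mask()].
#' @param target_spacing Positive length-3 numeric, mm.
#' @return A [volume_mask()] at the new spacing.
#' @export
resample_volume <- function(v, target_spacing = c(1, 1, 1)) {
  stop_if_not(inherits(v, "volume_mask"), "v must be a volume_mask")
  stop_if_not(all(target_spacing > 0), "target spacing must be positive")
  old <- dim(v$intensities)
  new_n <- pmax(1L, as.integer(round(old * v$spacing / target_spacing)))
  intens <- v$intensities
  maskf <- array(as.numeric(v$mask), dim = old)
  for (ax in 1:3) {
    intens <- resample_axis(intens, ax, v$spacing[ax], target_spacing[ax],
                            new_n[ax])
    maskf <- resample_axis(maskf, ax, v$spacing[ax], target_spacing[ax],
                           new_n[ax])
  }
  mask <- maskf >= 0.5
  if (!any(mask)) {
    stop("mask is empty after resampling to the requested spacing",
         call. = FALSE)
  }
  volume_mask(intens, mask, spacing = target_spacing, origin = v$origin)
}

#' Discretize masked intensities into gray levels
#'
#' Fixed-bin-width discretization relative to the minimum *masked*
#' intensity: `level = floor((I - min_masked) / bin_width) + 1`. This is the
#' gray-level alphabet consumed by the co-occurrence, run-length, and
#' size-zone texture matrices. A fixed width (default 25 intensity units)
#' rather than a fixed level count follows CT-radiomics convention: the
#' level spacing then has a stable physical meaning across tumors.
#'
#' @param v A [volume_mask()].
#' @param bin_width Positive bin width in intensity units.
#' @return A [gray_volume()].
#' @export
discretize_volume <- function(v, bin_width = 25) {
  stop_if_not(inherits(v, "volume_mask"), "v must be a volume_mask")
  stop_if_not(is.numeric(bin_width) && bin_width > 0,
              "bin_width must be positive")
  check_nonempty_mask(v)
  lv <- array(0L, dim = dim(v$intensities))
  x <- v$intensities[v$mask]
  lev <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  lv[v$mask] <- lev
  gray_volume(lv, n_levels = max(lev), bin_width = bin_width, mask = v$mask)
}
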