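#' Specification of a synthetic tumor phantom
#'
#' Describes the geometry and texture of a phantom volume used to exercise
#' the feature-extraction chain with known ground truth.
#'
#' @param shape One of `"sphere"`, `"ellipsoid"`, `"cube"`, `"blob"`.
#' @param size_mm Characteristic size (diameter / edge length) in mm.
#' @param texture One of `"constant"`, `"gaussian_noise"`, `"checkerboard"`,
#'   `"gradient"`.
#' @param texture_params Named list of texture parameters. Recognized names:
#'   `value` (constant), `mean` and `sd` (gaussian_noise), `period`, `low`,
#'   `high`, `sd` (checkerboard; period in voxels), `base` and `slope`
#'   (gradient; slope in intensity units per mm along x).
#' @param spacing Voxel spacing in mm (length 3).
#' @param seed Integer seed; the same spec with the same seed yields a
#'   bit-identical phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("sphere", "ellipsoid", "cube", "blob"),
                         size_mm = 20, texture = c("constant",
                         "gaussian_noise", "checkerboard", "gradient"),
                         texture_params = list(), spacing = c(1, 1, 1),
                         seed = 1L) {
  shape <- match.arg(shape)
  texture <- match.arg(texture)
  stop_if_not(is.numeric(size_mm) && size_mm > 0, "size_mm must be positive")
  stop_if_not(all(spacing > 0), "spacing components must be positive")
  structure(list(shape = shape, size_mm = size_mm, texture = texture,
                 texture_params = texture_params,
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume with mask
#'
#' Builds a 3D intensity volume plus a single connected binary mask from a
#' [phantom_spec()]. Intensities outside the mask are background-filled with
#' zero; masks define the analysis region for every downstream feature.
#'
#' @param spec A [phantom_spec()].
#' @return A [volume_mask()].
#' @examples
#' v <- gen_phantom(phantom_spec("sphere", size_mm = 10,
#'                               texture = "constant",
#'                               texture_params = list(value = 100)))
#' range(v$intensities[v$mask])
#' @export
gen_phantom <- function(spec) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  sp <- spec$spacing
  if (spec$size_mm < min(spec$spacing)) {
    stop("degenerate phantom: size_mm below the voxel resolution ",
         "(mask would be empty)", call. = FALSE)
  }
  margin <- 2L
  half <- spec$size_mm / 2
  dims <- pmax(ceiling(spec$size_mm / sp), 1L) + 2L * margin
  # physical coordinates of voxel centers, origin at the grid corner
  cx <- (seq_len(dims[1]) - 1) * sp[1]
  cy <- (seq_len(dims[2]) - 1) * sp[2]
  cz <- (seq_len(dims[3]) - 1) * sp[3]
  center <- c(mean(range(cx)), mean(range(cy)), mean(range(cz)))
  X <- array(rep(cx - center[1], times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(cy - center[2], each = dims[1]), times = dims[3]),
             dim = dims)
  Z <- array(rep(cz - center[3], each = dims[1] * dims[2]), dim = dims)

  mask <- with_seed(spec$seed + 1L, switch(spec$shape,
    sphere = (X^2 + Y^2 + Z^2) <= half^2,
    ellipsoid = (X / half)^2 + (Y / (0.75 * half))^2 +
      (Z / (0.55 * half))^2 <= 1,
    cube = abs(X) <= half & abs(Y) <= half & abs(Z) <= half,
    blob = {
      # star-shaped perturbation of a sphere: radius modulated by a smooth
      # random trigonometric field, which keeps the mask connected
      a <- stats::runif(3, -1, 1) * 0.25
      ph <- stats::runif(3, 0, 2 * pi)
      r <- sqrt(X^2 + Y^2 + Z^2)
      theta <- atan2(Y, X)
      phi <- atan2(sqrt(X^2 + Y^2), Z)
      rad <- half * (1 + a[1] * cos(2 * theta + ph[1]) +
                       a[2] * cos(3 * phi + ph[2]) +
                       a[3] * cos(theta + 2 * phi + ph[3]))
      r <= pmax(rad, 0.2 * half)
    }))
  if (!any(mask)) {
    stop("degenerate phantom: mask is empty (size_mm too small for spacing)",
         call. = FALSE)
  }

  pr <- spec$texture_params
  vox <- which(mask, arr.ind = TRUE)
  intens <- array(0, dim = dims)
  tex <- with_seed(spec$seed, switch(spec$texture,
    constant = rep((pr$value %||% 100), nrow(vox)),
    gaussian_noise = stats::rnorm(nrow(vox), pr$mean %||% 100,
                                  pr$sd %||% 20),
    checkerboard = {
      period <- pr$period %||% 2
      parity <- (floor((vox[, 1] - 1) / period) +
                 floor((vox[, 2] - 1) / period) +
                 floor((vox[, 3] - 1) / period)) %% 2
      base <- ifelse(parity == 0, pr$low %||% 50, pr$high %||% 150)
      base + stats::rnorm(nrow(vox), 0, pr$sd %||% 0)
    },
    gradient = (pr$base %||% 0) + (pr$slope %||% 10) * X[mask]))
  intens[mask] <- tex
  volume_mask(intens, mask, spacing = sp)
}
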