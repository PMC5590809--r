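# Separable 1D filtering along one axis of a 3D array.
#
# out[i] = sum_t h[t] * a[i + t - center]  (sliding inner product), with
# periodic or edge-replicate padding. All separable filters in the package
# (wavelet bands, Gaussian smoothing, Gaussian second derivatives) reduce to
# repeated calls of this kernel.
conv_axis <- function(a, h, axis, pad = c("periodic", "replicate"),
                      center = NULL) {
  pad <- match.arg(pad)
  n <- dim(a)[axis]
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, nrow = d[1])
  k <- length(h)
  center <- center %||% ((k + 1L) %/% 2L)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_len(k)) {
    idx <- seq_len(n) + (t - center)
    idx <- if (pad == "periodic") ((idx - 1L) %% n) + 1L else
      pmin(pmax(idx, 1L), n)
    out <- out + h[t] * m[idx, , drop = FALSE]
  }
  aperm(array(out, c(n, d[2], d[3])), order(perm))
}

# Coiflet-1 analysis filter pair (orthonormal; high-pass is the quadrature
# mirror of the low-pass).
coif1_filters <- function() {
  lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
          0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
  hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
          0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  list(lo = lo, hi = hi)
}

#' One-level stationary 3D wavelet decomposition
#'
#' Undecimated (stationary) single-level 3D wavelet transform with the
#' Coiflet-1 basis: every combination of low/high-pass along the three axes
#' yields one of 8 same-sized sub-bands, named by the filter letters in
#' `(x, y, z)` axis order (`LLL` ... `HHH`). Periodic boundary handling.
#'
#' @param a Numeric 3D array.
#' @return Named list of 8 arrays, each the size of `a`.
#' @export
swt3 <- function(a) {
  f <- coif1_filters()
  stop_if_not(min(dim(a)) >= length(f$lo),
              "volume smaller than the wavelet filter support")
  bands <- list()
  for (fx in c("L", "H")) {
    ax_x <- conv_axis(a, if (fx == "L") f$lo else f$hi, 1)
    for (fy in c("L", "H")) {
      ax_y <- conv_axis(ax_x, if (fy == "L") f$lo else f$hi, 2)
      for (fz in c("L", "H")) {
        bands[[paste0(fx, fy, fz)]] <-
          conv_axis(ax_y, if (fz == "L") f$lo else f$hi, 3)
      }
    }
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' Wavelet-band features (Group IV)
#'
#' Recomputes the first-order and GLCM/RLGL texture features on each of the
#' 8 stationary Coiflet-1 sub-bands, inside the original tumor mask.
#' Size-zone features are computed on the unfiltered image only, not per
#' band. Feature names carry the band label, e.g. `wavelet.HLL.entropy`.
#'
#' @param v A [volume_mask()].
#' @param bin_width Discretization width for the per-band texture alphabet.
#' @return Named numeric vector of length 8 x 48 = 384.
#' @export
wavelet_features <- function(v, bin_width = 25) {
  check_nonempty_mask(v)
  bands <- swt3(v$intensities)
  out <- numeric(0)
  for (nm in names(bands)) {
    bv <- volume_mask(bands[[nm]], v$mask, spacing = v$spacing)
    g <- discretize_volume(bv, bin_width)
    vals <- c(first_order_features(bv, bin_width),
              glcm_features(g), rlgl_features(g))
    names(vals) <- paste0("wavelet.", nm, ".", names(vals))
    out <- c(out, vals)
  }
  out
}

# Sampled 1D Gaussian (unit sum) and its second derivative (zero sum) on a
# physical grid; radius 4 sigma.
log_kernels_1d <- function(sigma, spacing) {
  r <- max(1L, as.integer(ceiling(4 * sigma / spacing)))
  x <- (-r:r) * spacing
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g2 <- (x^2 - sigma^2) / sigma^4 * exp(-x^2 / (2 * sigma^2))
  g2 <- g2 - mean(g2)   # exact zero response to constants
  list(g = g, g2 = g2)
}

#' Laplacian-of-Gaussian filter response
#'
#' Applies the LoG filter at physical scale `sigma` (mm): the sum over axes
#' of the Gaussian second derivative along that axis and Gaussian smoothing
#' along the other two. Edge-replicate boundary handling; the kernel is
#' corrected to give an exactly zero response to constant input.
#'
#' @param v A [volume_mask()].
#' @param sigma Positive scale in mm.
#' @return Numeric 3D array of filter responses.
#' @export
log_filter <- function(v, sigma) {
  stop_if_not(is.numeric(sigma) && sigma > 0, "sigma must be positive")
  a <- v$intensities
  ks <- lapply(1:3, function(ax) log_kernels_1d(sigma, v$spacing[ax]))
  # share smoothing passes: term_ax = g2 along ax, g along the others
  s3 <- conv_axis(a, ks[[3]]$g, 3, pad = "replicate")
  s23 <- conv_axis(s3, ks[[2]]$g, 2, pad = "replicate")
  term1 <- conv_axis(s23, ks[[1]]$g2, 1, pad = "replicate")
  term2 <- conv_axis(conv_axis(s3, ks[[2]]$g2, 2, pad = "replicate"),
                     ks[[1]]$g, 1, pad = "replicate")
  term3 <- conv_axis(conv_axis(conv_axis(a, ks[[3]]$g2, 3,
                                         pad = "replicate"),
                               ks[[2]]$g, 2, pad = "replicate"),
                     ks[[1]]$g, 1, pad = "replicate")
  term1 + term2 + term3
}

#' Laplacian-of-Gaussian first-order features (Group V)
#'
#' First-order statistics of the LoG response inside the mask, at each
#' scale of `sigmas` (mm). Names carry the scale, e.g.
#' `log.sigma.1.5.mean`.
#'
#' @param v A [volume_mask()].
#' @param sigmas Vector of positive scales in mm.
#' @param bin_width Histogram width for entropy/uniformity of the response.
#' @return Named numeric vector of length `length(sigmas) * 14`.
#' @export
log_features <- function(v, sigmas = seq(1, 7, by = 0.5), bin_width = 25) {
  check_nonempty_mask(v)
  stop_if_not(all(sigmas > 0), "sigmas must be positive")
  out <- numeric(0)
  for (s in sigmas) {
    resp <- log_filter(v, s)
    vals <- first_order_features(volume_mask(resp, v$mask, v$spacing),
                                 bin_width)
    names(vals) <- paste0("log.sigma.", formatC(s, format = "g"), ".",
                          names(vals))
    out <- c(out, vals)
  }
  out
}
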