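first_order_names <- c(
  "energy", "entropy", "kurtosis", "maximum", "mean",
  "mean.absolute.deviation", "median", "minimum", "range",
  "root.mean.square", "skewness", "standard.deviation", "uniformity",
  "variance")

#' First-order intensity statistics (Group I)
#'
#' The 14 first-order statistics of all voxel intensities in the tumor
#' mask. `entropy` and `uniformity` are computed on the fixed-bin-width
#' discretized histogram of the masked intensities (same `bin_width`
#' convention as the texture alphabet); everything else is computed on the
#' raw values. Skewness and kurtosis use population central moments
#' (kurtosis is non-excess, i.e. 3 for a normal distribution); variance and
#' standard deviation use the n-1 denominator. Degenerate cases (constant
#' region, zero variance) return 0 for the moment ratios with a warning, so
#' constant filter sub-bands never abort an extraction.
#'
#' @param v A [volume_mask()].
#' @param bin_width Histogram bin width for entropy/uniformity.
#' @return Named numeric vector of length 14.
#' @export
first_order_features <- function(v, bin_width = 25) {
  check_nonempty_mask(v)
  x <- masked_values(v)
  n <- length(x)
  m2 <- central_moment(x, 2)
  if (m2 > 0) {
    skew <- central_moment(x, 3) / m2^1.5
    kurt <- central_moment(x, 4) / m2^2
  } else {
    warning("constant intensities in mask: skewness/kurtosis set to 0",
            call. = FALSE)
    skew <- 0
    kurt <- 0
  }
  lev <- floor((x - min(x)) / bin_width) + 1
  p <- tabulate(lev) / n
  p <- p[p > 0]
  out <- c(
    energy = sum(x^2),
    entropy = -sum(xlog2(p)),
    kurtosis = kurt,
    maximum = max(x),
    mean = mean(x),
    mean.absolute.deviation = mean(abs(x - mean(x))),
    median = stats::median(x),
    minimum = min(x),
    range = max(x) - min(x),
    root.mean.square = sqrt(mean(x^2)),
    skewness = skew,
    standard.deviation = if (n > 1) stats::sd(x) else 0,
    uniformity = sum(p^2),
    variance = if (n > 1) stats::var(x) else 0)
  out[first_order_names]
}
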