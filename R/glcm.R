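# Gray-level co-occurrence features.

glcm_names <- paste0("glcm.", c(
  "autocorrelation", "cluster.prominence", "cluster.shade",
  "cluster.tendency", "contrast", "correlation", "difference.entropy",
  "dissimilarity", "energy", "entropy", "homogeneity1", "homogeneity2",
  "imc1", "imc2", "idmn", "idn", "inverse.variance",
  "maximum.probability", "sum.average", "sum.entropy", "sum.variance",
  "variance"))

# The 13 unique 3D direction offsets (26-neighborhood up to sign).
texture_directions <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  keep <- d$dz > 0 | (d$dz == 0 & d$dy > 0) |
    (d$dz == 0 & d$dy == 0 & d$dx > 0)
  as.matrix(d[keep, ])
}

# Index range along one axis such that both ends of the offset stay on
# the grid; empty when the axis is shorter than the offset.
axis_range <- function(n, off) {
  lo <- max(1, 1 - off)
  hi <- min(n, n - off)
  if (lo > hi) integer(0) else lo:hi
}

# Pairs of gray levels of adjacent in-mask voxels for one direction offset.
glcm_matrix <- function(g, offset) {
  lv <- g$levels
  d <- dim(lv)
  L <- g$n_levels
  i1 <- axis_range(d[1], offset[1])
  i2 <- axis_range(d[2], offset[2])
  i3 <- axis_range(d[3], offset[3])
  if (!length(i1) || !length(i2) || !length(i3)) {
    return(matrix(0, L, L))
  }
  a <- lv[i1, i2, i3]
  b <- lv[i1 + offset[1], i2 + offset[2], i3 + offset[3]]
  ok <- a > 0L & b > 0L
  counts <- tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
  P <- matrix(counts, L, L, byrow = TRUE)
  P + t(P)   # symmetrize
}

glcm_feature_values <- function(P) {
  L <- nrow(P)
  tot <- sum(P)
  if (tot == 0) return(stats::setNames(rep(NA_real_, 22), glcm_names))
  p <- P / tot
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(L) * px)
  sg2 <- sum((seq_len(L) - mu)^2 * px)
  # diagonal-band distributions p_{x+y}, p_{x-y}
  psum <- vapply(2:(2 * L), function(k) sum(p[i + j == k]), numeric(1))
  kk <- 2:(2 * L)
  pdiff <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  dk <- 0:(L - 1)
  HXY <- -sum(xlog2(p))
  HX <- -sum(xlog2(px))
  pxpy <- outer(px, px)
  HXY1 <- -sum(p * log2(ifelse(pxpy > 0, pxpy, 1)))
  HXY2 <- -sum(xlog2(pxpy))
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  corr <- if (sg2 > 0) (sum(i * j * p) - mu^2) / sg2 else 0
  sa <- sum(kk * psum)
  offdiag <- abs(i - j) > 0
  stats::setNames(c(
    sum(i * j * p),                                   # autocorrelation
    sum((i + j - 2 * mu)^4 * p),                      # cluster prominence
    sum((i + j - 2 * mu)^3 * p),                      # cluster shade
    sum((i + j - 2 * mu)^2 * p),                      # cluster tendency
    sum((i - j)^2 * p),                               # contrast
    corr,                                             # correlation
    -sum(xlog2(pdiff)),                               # difference entropy
    sum(abs(i - j) * p),                              # dissimilarity
    sum(p^2),                                         # energy (ASM)
    HXY,                                              # entropy
    sum(p / (1 + abs(i - j))),                        # homogeneity 1
    sum(p / (1 + (i - j)^2)),                         # homogeneity 2
    imc1, imc2,
    sum(p / (1 + (i - j)^2 / L^2)),                   # IDMN
    sum(p / (1 + abs(i - j) / L)),                    # IDN
    sum(p[offdiag] / (i - j)[offdiag]^2),             # inverse variance
    max(p),                                           # maximum probability
    sa,                                               # sum average
    -sum(xlog2(psum)),                                # sum entropy
    sum((kk - sa)^2 * psum),                          # sum variance
    sum((i - mu)^2 * p)                               # variance
  ), glcm_names)
}

#' Gray-level co-occurrence (GLCM) texture features
#'
#' Builds the distance-1 co-occurrence matrix for each of the 13 unique 3D
#' directions, symmetrizes and normalizes each, computes the 22-feature
#' GLCM set, and averages each feature over directions. Degenerate
#' statistics on a single-level region (correlation, informational measures)
#' are defined as 0, with a warning, rather than failing: constant wavelet
#' sub-bands occur on real masks.
#'
#' @param g A [gray_volume()].
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(g) {
  stop_if_not(inherits(g, "gray_volume"), "g must be a gray_volume")
  if (g$n_levels == 1L) {
    warning("single gray level: correlation-type GLCM features set to 0",
            call. = FALSE)
  }
  dirs <- texture_directions()
  vals <- apply(dirs, 1, function(d) glcm_feature_values(glcm_matrix(g, d)))
  out <- rowMeans(vals, na.rm = TRUE)
  if (anyNA(out) || any(!is.finite(out))) {
    warning("no voxel pairs in any direction: GLCM features set to 0",
            call. = FALSE)
    out[!is.finite(out)] <- 0
  }
  out
}
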