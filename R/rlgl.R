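# Run-length gray-level features.

rlgl_names <- paste0("rlgl.", c(
  "short.run.emphasis", "long.run.emphasis",
  "gray.level.nonuniformity", "run.length.nonuniformity",
  "run.percentage", "low.gray.level.run.emphasis",
  "high.gray.level.run.emphasis", "short.run.low.gray.level.emphasis",
  "short.run.high.gray.level.emphasis", "long.run.low.gray.level.emphasis",
  "long.run.high.gray.level.emphasis", "run.length.variance"))

# Run-length matrix for one direction: counts[g, l] of maximal runs of
# gray level g with length l. Runs are broken by mask boundaries.
rlgl_matrix <- function(g, offset) {
  lv <- g$levels
  d <- dim(lv)
  idx <- which(g$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(0, g$n_levels, 1))
  lev <- lv[g$mask]
  # parametrize each lattice line x = base + t * offset by the step count t
  ax <- which(offset != 0)[1]
  t_step <- idx[, ax] %/% offset[ax]   # offset[ax] is +-1
  base <- idx - outer(t_step, offset)
  # base components lie in [1-d, 2d]; shift and use a radix wide enough to
  # make the line key injective
  r2 <- 3 * d[2] + 5
  r3 <- 3 * d[3] + 5
  key <- ((base[, 1] + d[1]) * r2 + (base[, 2] + d[2])) * r3 +
    (base[, 3] + d[3])
  o <- order(key, t_step)
  key <- key[o]; tt <- t_step[o]; lev <- lev[o]
  brk <- c(TRUE, key[-1] != key[-length(key)] |
             tt[-1] != tt[-length(tt)] + 1L |
             lev[-1] != lev[-length(lev)])
  run_id <- cumsum(brk)
  run_len <- tabulate(run_id)
  run_lev <- lev[brk]
  L <- g$n_levels
  counts <- tabulate((run_lev - 1L) * max(run_len) + run_len,
                     nbins = L * max(run_len))
  matrix(counts, nrow = L, ncol = max(run_len), byrow = TRUE)
}

rlgl_feature_values <- function(R, n_vox) {
  Nr <- sum(R)
  gl <- seq_len(nrow(R))
  ll <- seq_len(ncol(R))
  G <- matrix(gl, nrow(R), ncol(R))
  Lm <- matrix(ll, nrow(R), ncol(R), byrow = TRUE)
  p <- R / Nr
  mu_l <- sum(Lm * p)
  stats::setNames(c(
    sum(R / Lm^2) / Nr,
    sum(R * Lm^2) / Nr,
    sum(rowSums(R)^2) / Nr,
    sum(colSums(R)^2) / Nr,
    Nr / n_vox,
    sum(R / G^2) / Nr,
    sum(R * G^2) / Nr,
    sum(R / (G^2 * Lm^2)) / Nr,
    sum(R * G^2 / Lm^2) / Nr,
    sum(R * Lm^2 / G^2) / Nr,
    sum(R * G^2 * Lm^2) / Nr,
    sum(p * (Lm - mu_l)^2)
  ), rlgl_names)
}

#' Run-length gray-level (RLGL) texture features
#'
#' Counts maximal runs of equal gray level along each of the 13 unique 3D
#' directions and averages the 12-feature run-length set over directions:
#' short/long-run emphasis, gray-level and run-length nonuniformity, run
#' percentage, low/high gray-level run emphasis, the four joint
#' short/long-by-low/high variants, and run-length variance. For every
#' direction the matrix satisfies the conservation identity
#' `sum_g sum_l counts(g, l) * l = number of masked voxels` exactly.
#'
#' @param g A [gray_volume()].
#' @return Named numeric vector of length 12.
#' @export
rlgl_features <- function(g) {
  stop_if_not(inherits(g, "gray_volume"), "g must be a gray_volume")
  n_vox <- sum(g$mask)
  dirs <- texture_directions()
  vals <- apply(dirs, 1, function(d) {
    rlgl_feature_values(rlgl_matrix(g, d), n_vox)
  })
  rowMeans(vals)
}
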