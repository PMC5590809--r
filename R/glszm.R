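# Gray-level size-zone features.

glszm_names <- paste0("glszm.", c(
  "small.area.emphasis", "large.area.emphasis",
  "gray.level.nonuniformity", "size.zone.nonuniformity",
  "zone.percentage", "low.gray.level.zone.emphasis",
  "high.gray.level.zone.emphasis", "small.area.low.gray.level.emphasis",
  "small.area.high.gray.level.emphasis",
  "large.area.low.gray.level.emphasis",
  "large.area.high.gray.level.emphasis", "gray.level.variance",
  "zone.size.variance", "zone.size.entropy"))

# Zones: connected components of equal gray level under 26-connectivity,
# found on the adjacency graph of masked voxels.
glszm_matrix <- function(g) {
  lv <- g$levels
  d <- dim(lv)
  vox <- which(g$mask)
  nvox <- length(vox)
  vid <- array(0L, dim = d)
  vid[vox] <- seq_len(nvox)
  dirs <- texture_directions()
  ef <- integer(0)
  et <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    i1 <- axis_range(d[1], off[1])
    i2 <- axis_range(d[2], off[2])
    i3 <- axis_range(d[3], off[3])
    if (!length(i1) || !length(i2) || !length(i3)) next
    a <- lv[i1, i2, i3]
    b <- lv[i1 + off[1], i2 + off[2], i3 + off[3]]
    ia <- vid[i1, i2, i3]
    ib <- vid[i1 + off[1], i2 + off[2], i3 + off[3]]
    ok <- a > 0L & b > 0L & a == b
    ef <- c(ef, ia[ok])
    et <- c(et, ib[ok])
  }
  gr <- igraph::make_graph(rbind(ef, et), n = nvox, directed = FALSE)
  comp <- igraph::components(gr)
  zone_size <- comp$csize
  zone_level <- lv[vox][match(seq_len(comp$no), comp$membership)]
  L <- g$n_levels
  S <- max(zone_size)
  counts <- tabulate((zone_level - 1L) * S + zone_size, nbins = L * S)
  matrix(counts, nrow = L, ncol = S, byrow = TRUE)
}

#' Gray-level size-zone (GLSZM) texture features
#'
#' Zones are connected components of voxels sharing a gray level under
#' 26-connectivity (direction-free, unlike runs). Emits the 14-feature
#' size-zone set: small/large-area emphasis, gray-level and zone-size
#' nonuniformity, zone percentage, low/high gray-level zone emphasis, the
#' four joint variants, gray-level variance, zone-size variance, and
#' zone-size entropy. The conservation identity
#' `sum counts(g, s) * s = number of masked voxels` holds exactly.
#'
#' @param g A [gray_volume()].
#' @return Named numeric vector of length 14.
#' @export
glszm_features <- function(g) {
  stop_if_not(inherits(g, "gray_volume"), "g must be a gray_volume")
  Z <- glszm_matrix(g)
  Nz <- sum(Z)
  n_vox <- sum(g$mask)
  gl <- seq_len(nrow(Z))
  ss <- seq_len(ncol(Z))
  G <- matrix(gl, nrow(Z), ncol(Z))
  S <- matrix(ss, nrow(Z), ncol(Z), byrow = TRUE)
  p <- Z / Nz
  mu_g <- sum(G * p)
  mu_s <- sum(S * p)
  stats::setNames(c(
    sum(Z / S^2) / Nz,
    sum(Z * S^2) / Nz,
    sum(rowSums(Z)^2) / Nz,
    sum(colSums(Z)^2) / Nz,
    Nz / n_vox,
    sum(Z / G^2) / Nz,
    sum(Z * G^2) / Nz,
    sum(Z / (G^2 * S^2)) / Nz,
    sum(Z * G^2 / S^2) / Nz,
    sum(Z * S^2 / G^2) / Nz,
    sum(Z * G^2 * S^2) / Nz,
    sum(p * (G - mu_g)^2),
    sum(p * (S - mu_s)^2),
    -sum(xlog2(p))
  ), glszm_names)
}
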