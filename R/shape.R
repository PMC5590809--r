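shape_names <- c(
  "volume", "surface.area", "surface.to.volume.ratio", "sphericity",
  "spherical.disproportion", "compactness1", "compactness2",
  "maximum.3d.diameter")

# Count exposed voxel faces along each axis (boundary of the grid counts as
# exposed) and weight by the physical face area.
voxel_surface_area <- function(mask, spacing) {
  d <- dim(mask)
  area <- 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(mask, perm)
    dm <- dim(m)
    ext <- array(FALSE, dim = c(dm[1] + 2, dm[2], dm[3]))
    ext[2:(dm[1] + 1), , ] <- m
    n_exposed <- sum(ext[-1, , ] != ext[-(dm[1] + 2), , ])
    area <- area + n_exposed * face[ax]
  }
  area
}

#' Shape and size features (Group II)
#'
#' 3D morphology of the tumor mask in physical units: volume, surface area,
#' surface-to-volume ratio, sphericity, spherical disproportion, two
#' compactness variants, and the maximum 3D diameter. The surface uses the
#' voxel-face convention (total area of mask faces exposed to background),
#' which makes volume and surface exact for axis-aligned digital solids; a
#' 10 mm cube at 1 mm spacing gives exactly 1000 mm^3 and 600 mm^2.
#' The maximum 3D diameter is the largest pairwise distance between voxel
#' centers of the mask surface; a single-voxel mask has diameter 0 by
#' convention (a point has no extent).
#'
#' @param v A [volume_mask()].
#' @return Named numeric vector of length 8.
#' @export
shape_features <- function(v) {
  check_nonempty_mask(v)
  sp <- v$spacing
  n <- sum(v$mask)
  vol <- n * prod(sp)
  area <- voxel_surface_area(v$mask, sp)
  # surface voxels: at least one exposed face
  idx <- which(v$mask, arr.ind = TRUE)
  surf <- surface_voxels(v$mask, idx)
  pts <- t(t(idx[surf, , drop = FALSE] - 1) * sp)
  maxd <- if (nrow(pts) < 2) 0 else {
    # chunked pairwise search keeps memory bounded on large masks
    best <- 0
    step <- 2000L
    for (s in seq(1, nrow(pts), by = step)) {
      rows <- s:min(s + step - 1, nrow(pts))
      dd <- outer(rowSums(pts[rows, , drop = FALSE]^2), rowSums(pts^2), "+") -
        2 * pts[rows, , drop = FALSE] %*% t(pts)
      best <- max(best, max(dd))
    }
    sqrt(max(best, 0))
  }
  sphericity <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  out <- c(
    volume = vol,
    surface.area = area,
    surface.to.volume.ratio = area / vol,
    sphericity = sphericity,
    spherical.disproportion = area / (4 * pi * r_eq^2),
    compactness1 = vol / (sqrt(pi) * area^1.5),
    compactness2 = 36 * pi * vol^2 / area^3,
    maximum.3d.diameter = maxd)
  out[shape_names]
}

# logical index of voxels with at least one 6-neighbor outside the mask
surface_voxels <- function(mask, idx) {
  d <- dim(mask)
  exposed <- rep(FALSE, nrow(idx))
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + dir
      out_of_grid <- nb[, ax] < 1 | nb[, ax] > d[ax]
      inside <- !out_of_grid
      val <- rep(FALSE, nrow(idx))
      if (any(inside)) {
        val[inside] <- !mask[nb[inside, , drop = FALSE]]
      }
      exposed <- exposed | out_of_grid | val
    }
  }
  exposed
}
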