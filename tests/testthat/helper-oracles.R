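# Independent brute-force oracles: naive loop implementations of the
# feature definitions, kept deliberately separate from the package's
# vectorized code paths.

oracle_directions <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
      out[[length(out) + 1]] <- c(dx, dy, dz)
    }
  }
  out
}

# co-occurrence matrix by exhaustive voxel-pair enumeration
oracle_glcm_matrix <- function(lv, off) {
  d <- dim(lv)
  L <- max(lv)
  P <- matrix(0, L, L)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lv[x, y, z]
    if (a == 0) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
      next
    b <- lv[x2, y2, z2]
    if (b == 0) next
    P[a, b] <- P[a, b] + 1
  }
  P + t(P)
}

xlog2o <- function(p) if (p > 0) p * log2(p) else 0

# all 22 co-occurrence features by naive double loops over the matrix
oracle_glcm_features <- function(P) {
  L <- nrow(P)
  p <- P / sum(P)
  px <- rowSums(p)
  mu <- 0
  for (i in 1:L) mu <- mu + i * px[i]
  sg2 <- 0
  for (i in 1:L) sg2 <- sg2 + (i - mu)^2 * px[i]
  acc <- cpro <- csha <- cten <- con <- dis <- ene <- ent <- h1 <- h2 <-
    idmn <- idn <- invv <- va <- 0
  for (i in 1:L) for (j in 1:L) {
    acc <- acc + i * j * p[i, j]
    cpro <- cpro + (i + j - 2 * mu)^4 * p[i, j]
    csha <- csha + (i + j - 2 * mu)^3 * p[i, j]
    cten <- cten + (i + j - 2 * mu)^2 * p[i, j]
    con <- con + (i - j)^2 * p[i, j]
    dis <- dis + abs(i - j) * p[i, j]
    ene <- ene + p[i, j]^2
    ent <- ent - xlog2o(p[i, j])
    h1 <- h1 + p[i, j] / (1 + abs(i - j))
    h2 <- h2 + p[i, j] / (1 + (i - j)^2)
    idmn <- idmn + p[i, j] / (1 + (i - j)^2 / L^2)
    idn <- idn + p[i, j] / (1 + abs(i - j) / L)
    if (i != j) invv <- invv + p[i, j] / (i - j)^2
    va <- va + (i - mu)^2 * p[i, j]
  }
  corr <- if (sg2 > 0) (acc - mu^2) / sg2 else 0
  psum <- numeric(2 * L)
  pdif <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  sa <- 0
  for (k in 2:(2 * L)) sa <- sa + k * psum[k]
  se <- 0
  for (k in 2:(2 * L)) se <- se - xlog2o(psum[k])
  sv <- 0
  for (k in 2:(2 * L)) sv <- sv + (k - sa)^2 * psum[k]
  de <- 0
  for (k in seq_along(pdif)) de <- de - xlog2o(pdif[k])
  hxy1 <- hxy2 <- hx <- 0
  for (i in 1:L) hx <- hx - xlog2o(px[i])
  for (i in 1:L) for (j in 1:L) {
    q <- px[i] * px[j]
    if (q > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
    hxy2 <- hxy2 - xlog2o(q)
  }
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(glcm.autocorrelation = acc, glcm.cluster.prominence = cpro,
    glcm.cluster.shade = csha, glcm.cluster.tendency = cten,
    glcm.contrast = con, glcm.correlation = corr,
    glcm.difference.entropy = de, glcm.dissimilarity = dis,
    glcm.energy = ene, glcm.entropy = ent, glcm.homogeneity1 = h1,
    glcm.homogeneity2 = h2, glcm.imc1 = imc1, glcm.imc2 = imc2,
    glcm.idmn = idmn, glcm.idn = idn, glcm.inverse.variance = invv,
    glcm.maximum.probability = max(p), glcm.sum.average = sa,
    glcm.sum.entropy = se, glcm.sum.variance = sv, glcm.variance = va)
}

# run-length matrix by walking every lattice line voxel by voxel
oracle_rlgl_matrix <- function(lv, off) {
  d <- dim(lv)
  L <- max(lv)
  runs <- list()
  inside <- function(p) all(p >= 1) && all(p <= d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    v <- lv[x, y, z]
    if (v == 0) next
    prev <- c(x, y, z) - off
    # start of a run: predecessor outside grid, outside mask, or level change
    if (inside(prev) && lv[prev[1], prev[2], prev[3]] == v) next
    len <- 1
    cur <- c(x, y, z) + off
    while (inside(cur) && lv[cur[1], cur[2], cur[3]] == v) {
      len <- len + 1
      cur <- cur + off
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  maxlen <- max(vapply(runs, `[`, numeric(1), 2))
  R <- matrix(0, L, maxlen)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

oracle_rlgl_features <- function(R, n_vox) {
  Nr <- sum(R)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  mu_l <- 0
  for (g in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    sre <- sre + R[g, l] / l^2
    lre <- lre + R[g, l] * l^2
    lgre <- lgre + R[g, l] / g^2
    hgre <- hgre + R[g, l] * g^2
    srlge <- srlge + R[g, l] / (g^2 * l^2)
    srhge <- srhge + R[g, l] * g^2 / l^2
    lrlge <- lrlge + R[g, l] * l^2 / g^2
    lrhge <- lrhge + R[g, l] * g^2 * l^2
    mu_l <- mu_l + l * R[g, l] / Nr
  }
  rlv <- 0
  for (g in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    rlv <- rlv + (l - mu_l)^2 * R[g, l] / Nr
  }
  c(rlgl.short.run.emphasis = sre / Nr, rlgl.long.run.emphasis = lre / Nr,
    rlgl.gray.level.nonuniformity = sum(rowSums(R)^2) / Nr,
    rlgl.run.length.nonuniformity = sum(colSums(R)^2) / Nr,
    rlgl.run.percentage = Nr / n_vox,
    rlgl.low.gray.level.run.emphasis = lgre / Nr,
    rlgl.high.gray.level.run.emphasis = hgre / Nr,
    rlgl.short.run.low.gray.level.emphasis = srlge / Nr,
    rlgl.short.run.high.gray.level.emphasis = srhge / Nr,
    rlgl.long.run.low.gray.level.emphasis = lrlge / Nr,
    rlgl.long.run.high.gray.level.emphasis = lrhge / Nr,
    rlgl.run.length.variance = rlv)
}

# size-zone matrix by explicit breadth-first flood fill, 26-connectivity
oracle_glszm_matrix <- function(lv) {
  d <- dim(lv)
  L <- max(lv)
  seen <- array(FALSE, dim = d)
  zones <- list()
  neigh <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  neigh <- neigh[!(neigh$dx == 0 & neigh$dy == 0 & neigh$dz == 0), ]
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lv[x, y, z] == 0 || seen[x, y, z]) next
    v <- lv[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(neigh))) {
        q <- p + c(neigh$dx[r], neigh$dy[r], neigh$dz[r])
        if (any(q < 1) || any(q > d)) next
        if (seen[q[1], q[2], q[3]] || lv[q[1], q[2], q[3]] != v) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(v, size)
  }
  S <- max(vapply(zones, `[`, numeric(1), 2))
  Z <- matrix(0, L, S)
  for (zn in zones) Z[zn[1], zn[2]] <- Z[zn[1], zn[2]] + 1
  Z
}

oracle_glszm_features <- function(Z, n_vox) {
  Nz <- sum(Z)
  sae <- lae <- lgz <- hgz <- salg <- sahg <- lalg <- lahg <- 0
  mu_g <- mu_s <- 0
  for (g in seq_len(nrow(Z))) for (s in seq_len(ncol(Z))) {
    sae <- sae + Z[g, s] / s^2
    lae <- lae + Z[g, s] * s^2
    lgz <- lgz + Z[g, s] / g^2
    hgz <- hgz + Z[g, s] * g^2
    salg <- salg + Z[g, s] / (g^2 * s^2)
    sahg <- sahg + Z[g, s] * g^2 / s^2
    lalg <- lalg + Z[g, s] * s^2 / g^2
    lahg <- lahg + Z[g, s] * g^2 * s^2
    mu_g <- mu_g + g * Z[g, s] / Nz
    mu_s <- mu_s + s * Z[g, s] / Nz
  }
  glv <- szv <- ze <- 0
  for (g in seq_len(nrow(Z))) for (s in seq_len(ncol(Z))) {
    glv <- glv + (g - mu_g)^2 * Z[g, s] / Nz
    szv <- szv + (s - mu_s)^2 * Z[g, s] / Nz
    ze <- ze - xlog2o(Z[g, s] / Nz)
  }
  c(glszm.small.area.emphasis = sae / Nz,
    glszm.large.area.emphasis = lae / Nz,
    glszm.gray.level.nonuniformity = sum(rowSums(Z)^2) / Nz,
    glszm.size.zone.nonuniformity = sum(colSums(Z)^2) / Nz,
    glszm.zone.percentage = Nz / n_vox,
    glszm.low.gray.level.zone.emphasis = lgz / Nz,
    glszm.high.gray.level.zone.emphasis = hgz / Nz,
    glszm.small.area.low.gray.level.emphasis = salg / Nz,
    glszm.small.area.high.gray.level.emphasis = sahg / Nz,
    glszm.large.area.low.gray.level.emphasis = lalg / Nz,
    glszm.large.area.high.gray.level.emphasis = lahg / Nz,
    glszm.gray.level.variance = glv, glszm.zone.size.variance = szv,
    glszm.zone.size.entropy = ze)
}

oracle_first_order <- function(x, bin_width = 25) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  lev <- floor((x - min(x)) / bin_width) + 1
  p <- as.numeric(table(lev)) / n
  c(energy = sum(x^2),
    entropy = -sum(vapply(p, xlog2o, numeric(1))),
    kurtosis = if (m2 > 0) (sum((x - m)^4) / n) / m2^2 else 0,
    maximum = max(x), mean = m,
    mean.absolute.deviation = sum(abs(x - m)) / n,
    median = stats::median(x), minimum = min(x), range = max(x) - min(x),
    root.mean.square = sqrt(sum(x^2) / n),
    skewness = if (m2 > 0) (sum((x - m)^3) / n) / m2^1.5 else 0,
    standard.deviation = if (n > 1) sqrt(sum((x - m)^2) / (n - 1)) else 0,
    uniformity = sum(p^2),
    variance = if (n > 1) sum((x - m)^2) / (n - 1) else 0)
}

# running-sum enrichment score by walking the whole ranking
oracle_es <- function(scores, hit, weight_exp = 1) {
  N <- length(scores)
  nh <- sum(hit)
  w <- abs(scores)^weight_exp
  tot <- sum(w[hit])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + (if (tot > 0) w[i] / tot else 1 / nh)
    } else {
      run <- run - 1 / (N - nh)
    }
    # earliest extreme wins ties, up to summation round-off
    if (abs(run) > abs(best) + 1e-12) best <- run
  }
  best
}

oracle_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(pos) * length(neg))
}

oracle_ci <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  num / den
}

# small gray volume wrapped from an integer array (0 = outside mask)
gv_from_levels <- function(lv) {
  gray_volume(lv, n_levels = max(lv), bin_width = 1, mask = lv > 0)
}

# random small phantom-derived gray volume for parameterized oracle tests
random_gray_volume <- function(seed, dims = c(4, 4, 4), n_levels = 4) {
  set.seed(seed)
  lv <- array(sample.int(n_levels, prod(dims), replace = TRUE), dim = dims)
  mask <- array(stats::runif(prod(dims)) < 0.85, dim = dims)
  if (!any(mask)) mask[1] <- TRUE
  lv[!mask] <- 0L
  lv
}
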