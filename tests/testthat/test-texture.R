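# Texture features against exhaustive brute-force enumeration oracles.

test_that("co-occurrence features match exhaustive pair enumeration", {
  lv_small <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  cases <- c(list(lv_small), lapply(1:4, random_gray_volume))
  dirs <- oracle_directions()
  for (lv in cases) {
    g <- gv_from_levels(lv)
    got <- suppressWarnings(glcm_features(g))
    per_dir <- vapply(dirs, function(off) {
      P <- oracle_glcm_matrix(lv, off)
      if (sum(P) == 0) return(rep(NA_real_, 22))
      oracle_glcm_features(P)
    }, numeric(22))
    want <- rowMeans(per_dir, na.rm = TRUE)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("entropy-type co-occurrence features are label-permutation invariant", {
  lv <- random_gray_volume(11, n_levels = 4)
  g1 <- glcm_features(gv_from_levels(lv))
  perm <- c(3L, 1L, 4L, 2L)
  lv2 <- lv
  lv2[lv > 0] <- perm[lv[lv > 0]]
  g2 <- glcm_features(gv_from_levels(lv2))
  for (nm in c("glcm.entropy", "glcm.energy",
               "glcm.maximum.probability")) {
    expect_equal(g1[[nm]], g2[[nm]], tolerance = 1e-9)
  }
})

test_that("a single gray level gives zero contrast and sentinel correlation", {
  lv <- array(1L, c(3, 3, 3))
  f <- suppressWarnings(glcm_features(gv_from_levels(lv)))
  expect_equal(unname(f["glcm.contrast"]), 0)
  expect_equal(unname(f["glcm.correlation"]), 0)
})

test_that("run-length features match the line-walking oracle", {
  for (lv in lapply(5:8, random_gray_volume)) {
    g <- gv_from_levels(lv)
    got <- rlgl_features(g)
    dirs <- oracle_directions()
    per_dir <- vapply(dirs, function(off) {
      oracle_rlgl_features(oracle_rlgl_matrix(lv, off), sum(lv > 0))
    }, numeric(12))
    expect_equal(unname(got), unname(rowMeans(per_dir)), tolerance = 1e-9)
  }
})

test_that("run conservation holds exactly in every direction", {
  lv <- random_gray_volume(21, dims = c(5, 5, 5), n_levels = 3)
  g <- gv_from_levels(lv)
  for (i in seq_len(13)) {
    R <- radiopath:::rlgl_matrix(g, texture_directions()[i, ])
    expect_identical(sum(R %*% seq_len(ncol(R))), as.numeric(sum(lv > 0)))
  }
})

test_that("a constant line volume has one run along its axis", {
  lv <- array(1L, c(6, 1, 1))
  R <- radiopath:::rlgl_matrix(gv_from_levels(lv), c(1L, 0L, 0L))
  expect_equal(sum(R), 1)            # one run
  expect_equal(R[1, 6], 1)           # of length N
  f <- oracle_rlgl_features(R, 6)
  expect_equal(unname(f["rlgl.run.percentage"]), 1 / 6)
})

test_that("alternating levels give all-unit runs and short-run emphasis 1", {
  lv <- array(rep(c(1L, 2L), 4), c(8, 1, 1))
  R <- radiopath:::rlgl_matrix(gv_from_levels(lv), c(1L, 0L, 0L))
  expect_true(all(R[, -1] == 0))
  f <- oracle_rlgl_features(R, 8)
  expect_equal(unname(f["rlgl.short.run.emphasis"]), 1)
})

test_that("size-zone features match the flood-fill oracle", {
  for (lv in lapply(9:12, random_gray_volume)) {
    got <- glszm_features(gv_from_levels(lv))
    want <- oracle_glszm_features(oracle_glszm_matrix(lv), sum(lv > 0))
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("zones merge when bridged and the conservation identity holds", {
  lv <- array(0L, c(5, 3, 1))
  lv[1, 1, 1] <- 1L; lv[5, 1, 1] <- 1L          # two distant blobs
  Z <- radiopath:::glszm_matrix(gv_from_levels(lv))
  expect_equal(sum(Z), 2)
  lv[2:4, 1, 1] <- 1L                           # bridge them
  Z2 <- radiopath:::glszm_matrix(gv_from_levels(lv))
  expect_equal(sum(Z2), 1)
  expect_identical(sum(Z2 %*% seq_len(ncol(Z2))), as.numeric(sum(lv > 0)))
})

test_that("a constant volume is a single zone with percentage 1/N", {
  lv <- array(2L, c(3, 3, 2))
  lv[lv > 0] <- 1L
  f <- glszm_features(gv_from_levels(lv))
  expect_equal(unname(f["glszm.zone.percentage"]), 1 / 18)
})

test_that("direction-averaged texture is invariant to 90-degree rotation", {
  lv <- random_gray_volume(31, dims = c(4, 4, 4))
  rot <- aperm(lv[, dim(lv)[2]:1, ], c(2, 1, 3))   # 90 deg about z
  g1 <- suppressWarnings(glcm_features(gv_from_levels(lv)))
  g2 <- suppressWarnings(glcm_features(gv_from_levels(rot)))
  expect_equal(g1, g2, tolerance = 1e-9)
  r1 <- rlgl_features(gv_from_levels(lv))
  r2 <- rlgl_features(gv_from_levels(rot))
  expect_equal(r1, r2, tolerance = 1e-9)
})
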