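rank_df <- function(genes, scores) {
  structure(data.frame(gene = genes, score = scores,
                       stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"))
}

test_that("enrichment score hits the documented extremes", {
  r <- rank_df(c("a", "b", "c"), c(3, 2, 1))
  expect_equal(enrichment_score(r, "a"), 1)
  expect_equal(enrichment_score(r, "c"), -1)
})

test_that("the running-sum statistic matches the walking oracle", {
  set.seed(5)
  for (rep in 1:20) {
    N <- sample(8:12, 1)
    scores <- sort(round(rnorm(N, 0, 2), 2), decreasing = TRUE)
    genes <- paste0("g", seq_len(N))
    k <- sample(1:(N - 1), 1)
    set <- sample(genes, k)
    for (w in c(0, 1)) {
      got <- enrichment_score(rank_df(genes, scores), set, weight_exp = w)
      want <- oracle_es(scores, genes %in% set, weight_exp = w)
      expect_equal(got, want, tolerance = 1e-12)
      expect_lte(abs(got), 1)
    }
  }
})

test_that("a set equal to the whole universe is rejected", {
  r <- rank_df(c("a", "b"), c(1, -1))
  expect_error(enrichment_score(r, c("a", "b")), "universe")
})

test_that("unweighted ES of a set and its complement have opposite signs", {
  set.seed(6)
  for (rep in 1:10) {
    N <- 10
    genes <- paste0("g", 1:N)
    scores <- sort(rnorm(N), decreasing = TRUE)
    set <- sample(genes, 4)
    a <- enrichment_score(rank_df(genes, scores), set, weight_exp = 0)
    b <- enrichment_score(rank_df(genes, scores), setdiff(genes, set),
                          weight_exp = 0)
    expect_lte(a * b, 0)
  }
})

test_that("preranked enrichment is deterministic and sign-consistent", {
  set.seed(7)
  N <- 200
  genes <- paste0("g", 1:N)
  scores <- sort(rnorm(N), decreasing = TRUE)
  r <- rank_df(genes, scores)
  coll <- list(top = genes[1:15], mid = genes[90:110],
               rnd = sample(genes, 20))
  g1 <- preranked_gsea(r, coll, n_perm = 200, seed = 3)
  g2 <- preranked_gsea(r, coll, n_perm = 200, seed = 3)
  expect_identical(g1, g2)
  expect_true(all(sign(g1$NES) == sign(g1$ES)))
  expect_true(all(g1$q_value >= g1$p_value - 1e-12))
})

test_that("a planted top set gets a positive NES at the permutation floor", {
  set.seed(8)
  N <- 300
  genes <- paste0("g", 1:N)
  scores <- sort(abs(rnorm(N)) + 0.01, decreasing = TRUE)
  r <- rank_df(genes, scores)
  g <- preranked_gsea(r, list(planted = genes[1:15]), n_perm = 500,
                      seed = 4)
  expect_gt(g$NES[1], 1)
  expect_lte(g$p_value[1], 1 / 250)
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(9)
  ps <- replicate(100, {
    N <- 100
    genes <- paste0("g", 1:N)
    scores <- sort(rnorm(N), decreasing = TRUE)
    set <- sample(genes, 10)
    preranked_gsea(rank_df(genes, scores), list(s = set), n_perm = 100,
                   seed = sample.int(1e6, 1))$p_value
  })
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.11)
})

test_that("enrichment scores agree with an independent preranked implementation", {
  set.seed(77)
  N <- 400
  genes <- paste0("g", 1:N)
  scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
  r <- rank_df(genes, scores)
  coll <- list(a = sample(genes, 25), b = genes[1:20],
               c = sample(genes, 40))
  stats <- stats::setNames(scores, genes)
  fg <- suppressWarnings(fgsea::fgseaSimple(pathways = coll, stats = stats,
                                            nperm = 100,
                                            scoreType = "std"))
  ours <- vapply(coll, function(s) enrichment_score(r, s), numeric(1))
  expect_equal(unname(ours[fg$pathway]), fg$ES, tolerance = 1e-9)
})

test_that("per-patient scores follow the rank sign convention", {
  expr <- cbind(p_top = c(10, 9, 1, 2, 3, 4, 0.5, 0.2),
                p_bot = c(0.1, 0.2, 5, 6, 7, 8, 9, 10))
  rownames(expr) <- paste0("g", 1:8)
  s <- per_patient_enrichment(expr, c("g1", "g2"))
  expect_gt(s["p_top"], 0)
  expect_lt(s["p_bot"], 0)
})

test_that("per-patient scores are invariant to monotone transforms", {
  set.seed(10)
  expr <- matrix(rnorm(50 * 6), 50, 6,
                 dimnames = list(paste0("g", 1:50), paste0("p", 1:6)))
  set <- paste0("g", c(2, 7, 9, 30))
  s1 <- per_patient_enrichment(expr, set)
  s2 <- per_patient_enrichment(exp(expr) + 5, set)
  expect_equal(s1, s2)
  expr2 <- cbind(expr, dup = expr[, 1])
  s3 <- per_patient_enrichment(expr2, set)
  expect_equal(unname(s3["p1"]), unname(s3["dup"]))
})

test_that("the association matrix recovers a planted link as the row maximum", {
  d <- planted_design(n_patients = 120, n_features = 5, n_genes = 300,
                      n_sets = 6, set_size = 15,
                      links = data.frame(feature = "feat_3", set = "SET_5",
                                         strength = 0.9), seed = 12)
  b <- gen_cohort(d)
  coll <- filter_gene_sets(b$gene_sets, rownames(b$expr))
  am <- build_association_matrix(b$features, b$expr, coll, n_perm = 150,
                                 seed = 5, weight_exp = 0.25)
  expect_s3_class(am, "association_matrix")
  expect_false(anyNA(am$nes))
  expect_equal(colnames(am$nes)[which.max(abs(am$nes["feat_3", ]))],
               "SET_5")
})

test_that("association rows are invariant to monotone feature transforms", {
  d <- planted_design(n_patients = 60, n_features = 2, n_genes = 150,
                      n_sets = 4, set_size = 16, seed = 13)
  b <- gen_cohort(d)
  coll <- filter_gene_sets(b$gene_sets, rownames(b$expr))
  f1 <- b$features
  f2 <- f1
  f2[, 1] <- exp(f2[, 1] / 2)
  a1 <- build_association_matrix(f1, b$expr, coll, n_perm = 120, seed = 2)
  a2 <- build_association_matrix(f2, b$expr, coll, n_perm = 120, seed = 2)
  expect_equal(a1$nes, a2$nes)
})
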