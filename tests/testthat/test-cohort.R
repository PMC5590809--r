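base_design <- function(...) {
  planted_design(n_patients = 200, n_features = 6, n_genes = 300,
                 n_sets = 6, set_size = 20, seed = 1, ...)
}

test_that("cohort generation is seed-deterministic", {
  d <- base_design()
  expect_identical(gen_cohort(d), gen_cohort(d))
})

test_that("zero link strength leaves set-mean expression uncorrelated", {
  d <- base_design(links = data.frame(feature = "feat_1", set = "SET_1",
                                      strength = 0))
  b <- gen_cohort(d)
  sm <- colMeans(b$expr[d$gene_sets$SET_1, ])
  rho <- cor(sm, b$features[, "feat_1"], method = "spearman")
  expect_lt(abs(rho), 0.15)
})

test_that("strong links give the requested per-gene correlation", {
  d <- base_design(links = data.frame(feature = "feat_2", set = "SET_2",
                                      strength = 0.8))
  b <- gen_cohort(d)
  rhos <- apply(b$expr[d$gene_sets$SET_2, ], 1, function(g) {
    cor(g, b$features[, "feat_2"], method = "spearman")
  })
  expect_true(all(rhos >= 0.5))
})

test_that("null survival link gives chance-level concordance", {
  d <- base_design(survival_link = list(feature = "feat_1", coef = 0))
  b <- gen_cohort(d)
  ci <- concordance_index(b$features[, "feat_1"], b$clinical$os_time,
                          b$clinical$os_event)$ci
  expect_lt(abs(ci - 0.5), 0.05)
})

test_that("censoring fraction tracks the design rate", {
  d <- planted_design(n_patients = 500, n_features = 3, n_genes = 100,
                      n_sets = 3, set_size = 15, censor_rate = 0.3,
                      seed = 9)
  b <- gen_cohort(d)
  expect_lt(abs(mean(1 - b$clinical$os_event) - 0.3), 0.05)
})

test_that("planted correlation strength is recovered in rank order", {
  strengths <- c(0.3, 0.6, 0.9)
  reps <- 50
  obs <- sapply(strengths, function(s) {
    mean(sapply(seq_len(reps), function(r) {
      d <- planted_design(n_patients = 60, n_features = 2, n_genes = 40,
                          gene_sets = list(S = paste0("gene_", 1:10)),
                          links = data.frame(feature = "feat_1", set = "S",
                                             strength = s),
                          seed = 1000 * s + r)
      b <- gen_cohort(d)
      cor(colMeans(b$expr[1:10, ]), b$features[, "feat_1"],
          method = "spearman")
    }))
  })
  expect_true(all(diff(obs) > 0))
})

test_that("feature blocks share the requested pairwise correlation", {
  d <- planted_design(n_patients = 400, n_features = 6, n_genes = 50,
                      n_sets = 2, set_size = 15,
                      feature_blocks = list(list(
                        features = paste0("feat_", 1:3), rho = 0.7)),
                      seed = 4)
  b <- gen_cohort(d)
  cm <- cor(b$features[, 1:3])
  expect_lt(max(abs(cm[upper.tri(cm)] - 0.7)), 0.12)
})

test_that("inconsistent design ids are rejected", {
  expect_error(base_design(links = data.frame(feature = "nope",
                                              set = "SET_1",
                                              strength = 0.5)),
               "unknown feature")
  expect_error(base_design(links = data.frame(feature = "feat_1",
                                              set = "nope",
                                              strength = 0.5)),
               "unknown set")
  expect_error(base_design(censor_rate = 1.2), "censor_rate")
})

test_that("bundle alignment drops patients missing from a block", {
  d <- base_design()
  b <- gen_cohort(d)
  clin <- b$clinical[-1, ]
  expect_message(
    b2 <- cohort_bundle(b$features, b$expr, b$gene_sets, clin, "t"),
    "dropped 1")
  expect_equal(length(b2$patients), 199)
  expect_identical(rownames(b2$features), colnames(b2$expr))
})
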