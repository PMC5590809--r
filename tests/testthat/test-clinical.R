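test_that("concordance hits its closed-form extremes", {
  tt <- c(2, 4, 6, 8)
  ev <- c(1, 1, 1, 1)
  expect_equal(concordance_index(c(4, 3, 2, 1), tt, ev)$ci, 1)
  expect_equal(concordance_index(rep(5, 4), tt, ev)$ci, 0.5)
})

test_that("the worked censored example matches exhaustive pair enumeration", {
  tt <- c(2, 4, 6, 8)
  ev <- c(1, 1, 0, 1)
  rk <- c(10, 8, 9, 1)
  got <- concordance_index(rk, tt, ev)
  expect_equal(got$ci, oracle_ci(rk, tt, ev))
  expect_equal(got$se, sqrt(got$ci * (1 - got$ci) / got$n_pairs))
})

test_that("concordance agrees with the survival package on random data", {
  set.seed(1)
  for (rep in 1:5) {
    n <- 60
    risk <- rnorm(n)
    tt <- rexp(n, exp(0.5 * risk) / 20)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) < 2) next
    ours <- concordance_index(risk, tt, ev)$ci
    ref <- survival::concordance(survival::Surv(tt, ev) ~ risk,
                                 reverse = TRUE)$concordance
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("concordance is monotone-invariant and antisymmetric in risk", {
  set.seed(2)
  n <- 50
  risk <- rnorm(n)
  tt <- rexp(n, exp(risk) / 10)
  ev <- rbinom(n, 1, 0.8)
  a <- concordance_index(risk, tt, ev)$ci
  expect_equal(concordance_index(exp(risk), tt, ev)$ci, a)
  expect_equal(concordance_index(-risk, tt, ev)$ci + a, 1)
})

test_that("no comparable pairs is an explicit error", {
  expect_error(concordance_index(c(1, 2), c(5, 3), c(0, 0)), "comparable")
})

test_that("Kruskal-Wallis reproduces the worked rank-sum example", {
  h <- kruskal_wallis_stat(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(h, 27 / 7, tolerance = 1e-9)   # 3.857
  expect_equal(kruskal_wallis_stat(rep(4, 6), rep(c("a", "b"), each = 3)), 0)
  expect_error(kruskal_wallis_stat(1:5, rep("a", 5)), "two")
})

test_that("Kruskal-Wallis H has its chi-square mean under the null", {
  set.seed(3)
  h <- replicate(300, kruskal_wallis_stat(rnorm(60),
                                          rep(c("a", "b", "c"), 20)))
  expect_lt(abs(mean(h) - 2), 0.35)   # E[H] = k - 1 = 2
})

test_that("weighted-Z meta-combination matches closed forms", {
  expect_equal(meta_combine(0.5, 100, 0.5, 100), 0.5, tolerance = 1e-12)
  got <- meta_combine(0.05, 80, 0.05, 80)
  want <- pnorm(qnorm(0.95) * 2 / sqrt(2), lower.tail = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(round(got, 4), 0.0100)
  # degenerate weight limit recovers the first cohort
  expect_equal(meta_combine(0.03, 100, 0.8, 1e-9), 0.03, tolerance = 1e-6)
  expect_warning(meta_combine(0, 10, 0.5, 10), "clamp")
})

test_that("meta p is monotone in each input", {
  ps <- seq(0.05, 0.9, by = 0.05)
  out <- vapply(ps, function(p) meta_combine(p, 50, 0.3, 70), numeric(1))
  expect_true(all(diff(out) > 0))
})

test_that("a module holding a prognostic feature is flagged against OS", {
  d <- planted_design(n_patients = 150, n_features = 40, n_genes = 60,
                      n_sets = 3, set_size = 15,
                      survival_link = list(feature = "feat_1",
                                           coef = log(2.5)),
                      censor_rate = 0.3, seed = 21)
  b <- gen_cohort(d)
  mod <- radiomic_module("feat_1", "SET_1")
  res <- module_os_association(mod, b$features, b$clinical, n_perm = 200,
                               seed = 3)
  expect_lte(res$p, 0.05)
  null_mod <- radiomic_module(c("feat_7", "feat_8"), "SET_1")
  res0 <- module_os_association(null_mod, b$features, b$clinical,
                                n_perm = 200, seed = 4)
  expect_gte(res0$p, 0.05)
})

test_that("two-cohort clinical results combine into meta p-values", {
  d <- planted_design(n_patients = 100, n_features = 30, n_genes = 60,
                      n_sets = 3, set_size = 15,
                      survival_link = list(feature = "feat_1",
                                           coef = log(2.5)), seed = 31)
  b1 <- gen_cohort(d)
  d$seed <- 32L
  b2 <- gen_cohort(d)
  mods <- list(radiomic_module("feat_1", "SET_1"))
  out <- module_clinical_results(mods, b1, b2, n_perm = 100, seed = 5)
  expect_equal(nrow(out), 3)
  expect_setequal(out$endpoint, c("OS", "stage", "histology"))
  expect_true(all(out$p_meta >= 0 & out$p_meta <= 1))
  os <- out[out$endpoint == "OS", ]
  expect_lte(os$p_meta, 0.05)
})
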