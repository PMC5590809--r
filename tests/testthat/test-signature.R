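sim_surv <- function(n, lp, censor = 0.3, seed = 1) {
  set.seed(seed)
  t_ev <- rexp(n, exp(lp) / 36)
  cens <- rbinom(n, 1, censor) == 1
  list(time = ifelse(cens, runif(n) * t_ev, t_ev),
       event = as.integer(!cens))
}

test_that("mRMR puts an exact copy last and respects relevance", {
  set.seed(1)
  n <- 120
  f1 <- rnorm(n)
  f3 <- rnorm(n)
  X <- cbind(f1 = f1, f2 = f1, f3 = f3)   # f2 duplicates f1
  sv <- sim_surv(n, 1.2 * f1 + 0.4 * f3, seed = 2)
  rk <- mrmr_rank(X, sv$time, sv$event, k = 3)
  expect_equal(rk[1], "f1")
  expect_equal(rk[2], "f3")
  expect_equal(mrmr_rank(X, sv$time, sv$event, k = 1), "f1")
})

test_that("zero redundancy weight reduces mRMR to a relevance sort", {
  set.seed(3)
  n <- 150
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  sv <- sim_surv(n, 0.8 * X[, 4] + 0.4 * X[, 2], seed = 4)
  rk0 <- mrmr_rank(X, sv$time, sv$event, k = 6, redundancy_weight = 0)
  mart <- residuals(survival::coxph(survival::Surv(sv$time, sv$event) ~ 1),
                    type = "martingale")
  rel <- abs(apply(X, 2, function(f) cor(rank(f), rank(mart))))
  expect_identical(rk0, names(sort(-rel)))
})

test_that("constant features are excluded with a warning", {
  set.seed(5)
  X <- cbind(f1 = rnorm(50), flat = rep(2, 50))
  sv <- sim_surv(50, X[, 1], seed = 6)
  expect_warning(rk <- mrmr_rank(X, sv$time, sv$event, k = 2), "constant")
  expect_identical(rk, "f1")
})

test_that("incremental Cox selects a prognostic signature deterministically", {
  set.seed(7)
  n <- 150
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  sv <- sim_surv(n, log(2) * X[, 1], seed = 8)
  rk <- mrmr_rank(X, sv$time, sv$event, k = 6)
  s1 <- incremental_cox(rk, X, sv$time, sv$event, n_cv = 30, seed = 9)
  s2 <- incremental_cox(rk, X, sv$time, sv$event, n_cv = 30, seed = 9)
  expect_identical(s1$feature_ids, s2$feature_ids)
  expect_true("f1" %in% s1$feature_ids)
  expect_gt(s1$cv_best_ci, 0.55)
})

test_that("pure-noise features give chance-level cross-validated concordance", {
  set.seed(10)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  sv <- sim_surv(n, rep(0, n), seed = 11)
  rk <- mrmr_rank(X, sv$time, sv$event, k = 5)
  sig <- incremental_cox(rk, X, sv$time, sv$event, n_cv = 40, seed = 12)
  # out-of-split concordance of pure noise hovers at (or slightly below,
  # through overfitting) chance, and growing the model does not help
  expect_lt(abs(mean(sig$cv_mean_ci) - 0.5), 0.08)
  expect_lt(max(sig$cv_mean_ci) - sig$cv_mean_ci[1], 0.08)
})

test_that("signature risk prediction is the fitted linear predictor", {
  set.seed(13)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  sv <- sim_surv(50, X[, 2], seed = 14)
  sig <- incremental_cox(paste0("f", 1:4), X, sv$time, sv$event,
                         n_cv = 20, seed = 15)
  pr <- predict(sig, X)
  expect_equal(pr, as.numeric(X[, sig$feature_ids, drop = FALSE] %*%
                                sig$coefficients))
})

test_that("a single fused component reduces to that component's concordance", {
  set.seed(16)
  n <- 100
  z <- matrix(rnorm(n * 1), n, 1, dimnames = list(NULL, "clinical"))
  sv <- sim_surv(n, 0.8 * z[, 1], seed = 17)
  sv2 <- sim_surv(n, 0.8 * z[, 1], seed = 18)
  tab <- combine_signatures(z, sv$time, sv$event, z, sv2$time, sv2$event)
  expect_equal(nrow(tab), 1)
  direct <- concordance_index(z[, 1], sv2$time, sv2$event)$ci
  expect_equal(tab$ci, direct, tolerance = 1e-9)
})

test_that("model comparison returns p = 1 for identical models", {
  set.seed(19)
  n <- 80
  risk <- rnorm(n)
  sv <- sim_surv(n, risk, seed = 20)
  out <- compare_models_permutation(risk, risk, sv$time, sv$event,
                                    n_perm = 50, seed = 21)
  expect_equal(out$p, 1)
  expect_equal(out$stat, 0)
})

test_that("adding a real prognostic component is flagged, noise is not", {
  set.seed(22)
  n <- 150
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  sv <- sim_surv(n, 0.8 * z1 + 0.8 * z2, censor = 0, seed = 23)
  sig <- compare_models_permutation(0.8 * z1 + 0.8 * z2, 0.8 * z1,
                                    sv$time, sv$event, n_perm = 200,
                                    seed = 24)
  expect_lte(sig$p, 0.05)
  noise <- compare_models_permutation(0.8 * z1 + 0.05 * rnorm(n), 0.8 * z1,
                                      sv$time, sv$event, n_perm = 200,
                                      seed = 25)
  expect_gt(noise$p, 0.05)
})
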