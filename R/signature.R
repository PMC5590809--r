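# Prognostic signature construction: mRMR ranking, incremental Cox with
# repeated cross-validation, and Cox-level fusion of data types.

#' Minimum-redundancy maximum-relevance feature ranking for survival
#'
#' Greedy mRMR: relevance of a feature is the absolute Spearman
#' correlation with the martingale residuals of a null Cox model (the
#' standard continuous-survival surrogate for the censored outcome);
#' redundancy is the mean absolute Spearman correlation with the features
#' already selected. Each step picks the feature maximizing
#' `relevance - redundancy_weight * mean_redundancy` (ties by feature
#' name). Constant columns are excluded with a warning. With
#' `redundancy_weight = 0` the ranking reduces to a pure relevance sort.
#'
#' @param features Patients x features matrix.
#' @param time,event Survival outcome aligned to the rows.
#' @param k Number of features to rank.
#' @param redundancy_weight Weight on the redundancy penalty (default 1).
#' @return Character vector of `k` feature names in selection order.
#' @export
mrmr_rank <- function(features, time, event, k = min(15, ncol(features)),
                      redundancy_weight = 1) {
  features <- as.matrix(features)
  stop_if_not(k >= 1 && k <= ncol(features),
              "k must be between 1 and the feature count")
  keep <- apply(features, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sprintf("excluding %d constant feature column(s)",
                    sum(!keep)), call. = FALSE)
    features <- features[, keep, drop = FALSE]
    k <- min(k, ncol(features))
  }
  mart <- stats::residuals(
    survival::coxph(survival::Surv(time, event) ~ 1), type = "martingale")
  rmat <- apply(features, 2, rank)
  rmart <- rank(mart)
  rel <- abs(stats::cor(rmat, rmart))[, 1]
  cmat <- abs(stats::cor(rmat))
  nm <- colnames(features)
  sel <- character(0)
  avail <- nm
  for (step in seq_len(k)) {
    if (length(sel) == 0 || redundancy_weight == 0) {
      score <- rel[avail]
    } else {
      red <- rowMeans(cmat[avail, sel, drop = FALSE])
      score <- rel[avail] - redundancy_weight * red
    }
    pick <- avail[order(-score, avail)[1]]
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  sel
}

#' Incremental Cox signature with repeated cross-validation
#'
#' Walks down an mRMR-style ranking, fitting proportional-hazards models
#' of size 1, 2, ..., and estimates each size's out-of-split concordance
#' over `n_cv` random 70/30 resamples; the size with the highest mean CI
#' is retained and refitted on the full cohort. Sizes whose fit fails to
#' converge on a split are skipped for that split; a size with no usable
#' split is dropped.
#'
#' @param ranked Character vector of feature names in rank order.
#' @param features Patients x features matrix.
#' @param time,event Survival outcome.
#' @param n_cv Number of random splits (>= 10; the reference analysis
#'   used 1000).
#' @param train_frac Training fraction per split.
#' @param seed Integer seed.
#' @return Object of class `survival_signature`: `feature_ids`,
#'   `coefficients`, `cv_mean_ci` (per size and selected), `size`.
#' @export
incremental_cox <- function(ranked, features, time, event, n_cv = 1000,
                            train_frac = 0.7, seed = NULL) {
  stop_if_not(n_cv >= 10, "n_cv must be at least 10")
  stop_if_not(all(ranked %in% colnames(features)),
              "ranked features missing from the table")
  features <- as.matrix(features)
  n <- nrow(features)
  k <- length(ranked)
  cv_ci <- matrix(NA_real_, n_cv, k)
  with_seed(seed, {
    for (s in seq_len(n_cv)) {
      tr <- sample.int(n, round(train_frac * n))
      te <- setdiff(seq_len(n), tr)
      if (sum(event[te]) == 0 || sum(event[tr]) < 2) next
      for (sz in seq_len(k)) {
        X <- features[, ranked[seq_len(sz)], drop = FALSE]
        fit <- tryCatch(
          survival::coxph(survival::Surv(time[tr], event[tr]) ~ X[tr, ]),
          error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit)) next
        lp <- X[te, , drop = FALSE] %*% stats::coef(fit)
        ci <- tryCatch(
          concordance_index(as.numeric(lp), time[te], event[te])$ci,
          error = function(e) NA_real_)
        cv_ci[s, sz] <- ci
      }
    }
  })
  mean_ci <- colMeans(cv_ci, na.rm = TRUE)
  if (all(!is.finite(mean_ci))) {
    stop("no signature size produced a usable cross-validated fit",
         call. = FALSE)
  }
  best <- which.max(mean_ci)
  X <- features[, ranked[seq_len(best)], drop = FALSE]
  fit <- survival::coxph(survival::Surv(time, event) ~ X)
  structure(list(feature_ids = ranked[seq_len(best)],
                 coefficients = stats::setNames(as.numeric(stats::coef(fit)),
                                                ranked[seq_len(best)]),
                 size = best, cv_mean_ci = mean_ci,
                 cv_best_ci = mean_ci[best]),
            class = "survival_signature")
}

#' @export
print.survival_signature <- function(x, ...) {
  cat(sprintf("<survival_signature> %d feature(s), CV mean CI %.3f\n",
              x$size, x$cv_best_ci))
  invisible(x)
}

#' Per-patient risk score of a survival signature
#'
#' @param object A `survival_signature`.
#' @param newdata Patients x features matrix containing the signature's
#'   columns.
#' @param ... Unused.
#' @return Numeric linear-predictor risk per patient.
#' @export
predict.survival_signature <- function(object, newdata, ...) {
  stop_if_not(all(object$feature_ids %in% colnames(newdata)),
              "newdata is missing signature features")
  as.numeric(as.matrix(newdata[, object$feature_ids, drop = FALSE]) %*%
               object$coefficients)
}

#' Fuse clinical, gene, and radiomic risk components in a Cox model
#'
#' Fits a proportional-hazards model on per-patient scalar risk components
#' in the training cohort and reports the validation concordance of every
#' component subset (each single component, clinical+radiomic,
#' clinical+gene, and the full combination). Degenerate collinear inputs
#' fall back to a ridge-penalized fit with a warning.
#'
#' @param components_train Data frame / matrix of per-patient risk
#'   components (e.g. columns `clinical`, `gene`, `radiomic`).
#' @param time_train,event_train Training outcome.
#' @param components_val,time_val,event_val Validation cohort.
#' @return data.frame: one row per component subset with the validation
#'   `ci` and `se`.
#' @export
combine_signatures <- function(components_train, time_train, event_train,
                               components_val, time_val, event_val) {
  components_train <- as.matrix(components_train)
  components_val <- as.matrix(components_val)
  nm <- colnames(components_train)
  stop_if_not(identical(nm, colnames(components_val)),
              "component columns must match between cohorts")
  subsets <- c(as.list(nm),
               if (all(c("clinical", "radiomic") %in% nm))
                 list(c("clinical", "radiomic")),
               if (all(c("clinical", "gene") %in% nm))
                 list(c("clinical", "gene")),
               if (length(nm) > 1) list(nm))
  rows <- lapply(subsets, function(ss) {
    X <- components_train[, ss, drop = FALSE]
    fit <- tryCatch(
      survival::coxph(survival::Surv(time_train, event_train) ~ X),
      warning = function(w) NULL, error = function(e) NULL)
    beta <- if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
      stats::coef(fit)
    } else {
      warning("degenerate component fit: using ridge-penalized Cox",
              call. = FALSE)
      stats::coef(survival::coxph(
        survival::Surv(time_train, event_train) ~ ridge(X, theta = 1)))
    }
    risk <- as.numeric(components_val[, ss, drop = FALSE] %*% beta)
    ci <- concordance_index(risk, time_val, event_val)
    data.frame(model = paste(ss, collapse = "+"), ci = ci$ci, se = ci$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Permutation comparison of two risk models
#'
#' Tests whether model A outperforms model B in concordance on the same
#' patients. The statistic is `CI(A) - CI(B)`; the null permutes the
#' component distinguishing A from B across patients (by default the
#' risk difference `preds_a - preds_b`, exact for nested linear
#' predictors) and recomputes the statistic; plus-one p-value. Identical
#' models return p = 1.
#'
#' @param preds_a,preds_b Per-patient risk predictions of the two models.
#' @param time,event Outcome on the same patients.
#' @param component The distinguishing component to permute (default
#'   `preds_a - preds_b`).
#' @param n_perm,seed Permutation parameters.
#' @return List with `stat` (CI difference) and `p`.
#' @export
compare_models_permutation <- function(preds_a, preds_b, time, event,
                                       component = NULL, n_perm = 1000,
                                       seed = NULL) {
  component <- component %||% (preds_a - preds_b)
  if (all(component == 0)) return(list(stat = 0, p = 1))
  ci_b <- concordance_index(preds_b, time, event)$ci
  obs <- concordance_index(preds_a, time, event)$ci - ci_b
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    concordance_index(preds_b + sample(component), time, event)$ci - ci_b
  }, numeric(1)))
  list(stat = obs, p = (1 + sum(null >= obs)) / (n_perm + 1))
}
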