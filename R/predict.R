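# Radiomic prediction of per-patient pathway activation.

#' Binary pathway-activation labels from enrichment scores
#'
#' Label 1 when a patient's single-sample enrichment score is positive
#' (pathway activated), 0 otherwise. A score of exactly 0 maps to 0 with a
#' warning.
#'
#' @param scores Numeric vector of per-patient enrichment scores.
#' @return Integer vector of 0/1 labels.
#' @export
pathway_activation_labels <- function(scores) {
  stop_if_not(all(is.finite(scores)), "scores must be finite")
  if (any(scores == 0)) {
    warning("enrichment score exactly 0 treated as not activated",
            call. = FALSE)
  }
  as.integer(scores > 0)
}

# Newton-iterated ridge logistic regression on one predictor; the tiny L2
# penalty keeps the slope finite under perfect separation.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  pen <- diag(c(0, lambda))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Univariate logistic predictor of pathway activation
#'
#' Maximum-likelihood logistic regression of a binary activation label on
#' one radiomic feature. Under perfect separation (where the ML slope
#' diverges) the fit falls back to a lightly ridge-penalized estimate with
#' a warning, so predicted probabilities stay monotone in the feature with
#' a finite slope.
#'
#' @param f Numeric feature values.
#' @param labels 0/1 labels, both classes present.
#' @param feature_id,set_id Optional identifiers stored on the result.
#' @return Object of class `pathway_predictor`: intercept, slope,
#'   training AUC and its Noether p-value.
#' @export
fit_univariate_predictor <- function(f, labels, feature_id = NA_character_,
                                     set_id = NA_character_) {
  labels <- as.integer(labels)
  stop_if_not(length(unique(labels)) == 2,
              "both classes must be present to fit a predictor")
  glm_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(labels ~ f, family = stats::binomial()),
    warning = function(w) {
      glm_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  separated <- max(f[labels == 0]) < min(f[labels == 1]) ||
    max(f[labels == 1]) < min(f[labels == 0])
  if (!fit$converged || glm_warned || separated || any(!is.finite(beta))) {
    warning("separation detected: using ridge-penalized logistic fit",
            call. = FALSE)
    beta <- ridge_logistic(f, labels)
  }
  probs <- 1 / (1 + exp(-(beta[1] + beta[2] * f)))
  an <- auc_with_noether(probs, labels)
  structure(list(feature_id = feature_id, set_id = set_id,
                 intercept = unname(beta[1]), slope = unname(beta[2]),
                 auc_train = an$auc, p_noether = an$p,
                 auc_val = NA_real_),
            class = "pathway_predictor")
}

#' Predict activation probabilities from a fitted predictor
#'
#' @param object A `pathway_predictor`.
#' @param newdata Numeric feature values.
#' @param ... Unused.
#' @return Predicted probabilities.
#' @export
predict.pathway_predictor <- function(object, newdata, ...) {
  1 / (1 + exp(-(object$intercept + object$slope * newdata)))
}

#' AUC with Noether significance
#'
#' Area under the ROC curve as the normalized Mann-Whitney U (ties count
#' 1/2), with a one-sided test against AUC = 0.5. Large samples use the
#' Noether normal approximation with the null Mann-Whitney variance
#' `(n + 1) / (12 n_pos n_neg)`; when `n_pos * n_neg < 50` the null is
#' built exactly by enumerating (or, above 20000 arrangements, sampling)
#' label permutations.
#'
#' @param probs Predicted scores.
#' @param labels 0/1 labels, both classes present.
#' @return List with `auc` and one-sided `p`.
#' @export
auc_with_noether <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  stop_if_not(n1 > 0 && n0 > 0, "both classes must be present")
  auc_of <- function(lab) {
    r <- rank(probs)
    (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(labels)
  if (n1 * n0 >= 50) {
    v0 <- (n1 + n0 + 1) / (12 * n1 * n0)
    p <- stats::pnorm((auc - 0.5) / sqrt(v0), lower.tail = FALSE)
  } else {
    n <- n1 + n0
    if (choose(n, n1) <= 20000) {
      combs <- utils::combn(n, n1)
      null <- apply(combs, 2, function(ix) {
        lab <- integer(n)
        lab[ix] <- 1L
        auc_of(lab)
      })
      p <- mean(null >= auc)
    } else {
      null <- vapply(seq_len(2000), function(i) {
        auc_of(sample(labels))
      }, numeric(1))
      p <- (1 + sum(null >= auc)) / (2000 + 1)
    }
  }
  list(auc = auc, p = p)
}

#' Strongest predictor of a module
#'
#' Among a module's fitted predictors, the one with the highest training
#' AUC (ties broken by feature id, then set id).
#'
#' @param predictors List of `pathway_predictor` objects.
#' @return The selected `pathway_predictor`.
#' @export
strongest_predictor <- function(predictors) {
  stop_if_not(length(predictors) >= 1, "no predictors supplied")
  auc <- vapply(predictors, `[[`, numeric(1), "auc_train")
  fid <- vapply(predictors, `[[`, character(1), "feature_id")
  sid <- vapply(predictors, `[[`, character(1), "set_id")
  predictors[[order(-auc, fid, sid)[1]]]
}

#' Fit and validate a module's pathway predictors
#'
#' For every (feature, pathway) pair of a module: labels are the signs of
#' the per-patient enrichment scores in the training cohort, a univariate
#' logistic predictor is fitted on the training features, and the
#' strongest predictor by training AUC is evaluated on the validation
#' cohort (validation labels from the validation cohort's own enrichment
#' scores).
#'
#' @param mod A [radiomic_module()].
#' @param d1,d2 Training and validation [cohort_bundle()] objects.
#' @return The strongest `pathway_predictor`, with `auc_val` and
#'   `p_noether_val` filled in; `NULL` when no pair has both classes in
#'   training.
#' @export
module_pathway_predictors <- function(mod, d1, d2) {
  preds <- list()
  for (set_id in mod$pathway_ids) {
    lab1 <- pathway_activation_labels(
      per_patient_enrichment(d1$expr, d1$gene_sets[[set_id]]))
    if (length(unique(lab1)) < 2) next
    for (fid in mod$feature_ids) {
      preds[[length(preds) + 1]] <- fit_univariate_predictor(
        d1$features[, fid], lab1, feature_id = fid, set_id = set_id)
    }
  }
  if (length(preds) == 0) return(NULL)
  best <- strongest_predictor(preds)
  lab2 <- pathway_activation_labels(
    per_patient_enrichment(d2$expr, d2$gene_sets[[best$set_id]]))
  if (length(unique(lab2)) == 2) {
    pv <- predict(best, d2$features[, best$feature_id])
    an <- auc_with_noether(pv, lab2)
    best$auc_val <- an$auc
    best$p_noether_val <- an$p
  }
  best
}
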