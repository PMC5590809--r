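# Clinical associations of modules: survival concordance, group tests,
# and the two-cohort meta-analysis.

#' Harrell's concordance index with Noether standard error
#'
#' Probability that, of a comparable patient pair, the one with the higher
#' risk score fails first. Pairs are comparable when the shorter observed
#' time carries an observed event; risk ties count 1/2. The standard error
#' is the Noether-type large-sample estimate
#' `sqrt(CI * (1 - CI) / n_pairs)` and the reported p-value is the
#' one-sided normal test against CI = 0.5.
#'
#' @param risk Numeric risk score per patient (higher = worse prognosis).
#' @param time Observed follow-up time.
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @return List with `ci`, `se`, `n_pairs`, `p`.
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  stop_if_not(length(time) == n && length(event) == n,
              "risk, time and event must have equal length")
  event <- as.integer(event)
  conc <- 0
  npair <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    j <- which(time > time[i])
    npair <- npair + length(j)
    conc <- conc + sum(risk[i] > risk[j]) + 0.5 * sum(risk[i] == risk[j])
  }
  if (npair == 0) stop("no comparable pairs", call. = FALSE)
  ci <- conc / npair
  se <- sqrt(ci * (1 - ci) / npair)
  p <- if (se == 0) as.numeric(ci <= 0.5) else
    stats::pnorm((ci - 0.5) / se, lower.tail = FALSE)
  list(ci = ci, se = se, n_pairs = npair, p = p)
}

#' Module association with overall survival
#'
#' The module statistic is the mean over its features of `|CI - 0.5|`, the
#' direction-free univariate prognostic strength (features within a module
#' may be prognostic in opposite directions, so signed concordances would
#' cancel). The permutation null redraws random feature sets of the same
#' size from the full bank; `p` uses the plus-one convention.
#'
#' @param mod A [radiomic_module()].
#' @param feature_table Patients x features matrix.
#' @param clinical Clinical table with `os_time`, `os_event` aligned to
#'   the feature table rows.
#' @param n_perm Number of null draws.
#' @param seed Integer seed.
#' @return List with `stat` (mean |CI - 0.5|) and `p`.
#' @export
module_os_association <- function(mod, feature_table, clinical,
                                  n_perm = 1000, seed = NULL) {
  stop_if_not(all(mod$feature_ids %in% colnames(feature_table)),
              "module features missing from the table")
  dev_one <- function(f) {
    abs(concordance_index(feature_table[, f], clinical$os_time,
                          clinical$os_event)$ci - 0.5)
  }
  obs <- mean(vapply(mod$feature_ids, dev_one, numeric(1)))
  k <- length(mod$feature_ids)
  all_dev <- vapply(colnames(feature_table), dev_one, numeric(1))
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    mean(all_dev[sample.int(length(all_dev), k)])
  }, numeric(1)))
  list(stat = obs, p = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Kruskal-Wallis chi-square statistic
#'
#' Rank-based H statistic with ties correction for a continuous value
#' against a categorical grouping (stage, histology). Thin wrapper over
#' [stats::kruskal.test()], kept as the pipeline's named entry point.
#'
#' @param values Numeric vector.
#' @param groups Factor or character grouping.
#' @return The H statistic (chi-square scale).
#' @export
kruskal_wallis_stat <- function(values, groups) {
  groups <- factor(groups)
  stop_if_not(nlevels(droplevels(groups)) >= 2,
              "need at least two non-empty groups")
  if (stats::var(values) == 0) return(0)
  unname(stats::kruskal.test(values, groups)$statistic)
}

#' Module association with a categorical clinical factor
#'
#' Mean Kruskal-Wallis H over the module's features, with the same
#' random-feature-set permutation null as [module_os_association()].
#'
#' @param mod A [radiomic_module()].
#' @param feature_table Patients x features matrix.
#' @param groups Categorical vector aligned to the rows (stage or
#'   histology).
#' @param n_perm,seed Permutation parameters.
#' @return List with `stat` and `p`.
#' @export
module_group_association <- function(mod, feature_table, groups,
                                     n_perm = 1000, seed = NULL) {
  stop_if_not(all(mod$feature_ids %in% colnames(feature_table)),
              "module features missing from the table")
  all_h <- vapply(colnames(feature_table), function(f) {
    kruskal_wallis_stat(feature_table[, f], groups)
  }, numeric(1))
  obs <- mean(all_h[mod$feature_ids])
  k <- length(mod$feature_ids)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    mean(all_h[sample.int(length(all_h), k)])
  }, numeric(1)))
  list(stat = obs, p = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Weighted-Z meta-combination of two cohort p-values
#'
#' Fisher Z (Stouffer) combination with sample-size weights:
#' `z_i = qnorm(1 - p_i)`, `z = (n1 z1 + n2 z2) / sqrt(n1^2 + n2^2)`,
#' `p_meta = 1 - pnorm(z)`. One-sided upper-tail convention: small input
#' p-values mean a strong association in that cohort. Inputs of exactly 0
#' or 1 are clamped with a warning.
#'
#' @param p1,p2 Cohort p-values in `(0, 1)`.
#' @param n1,n2 Cohort sample sizes (positive weights).
#' @return Combined p-value.
#' @export
meta_combine <- function(p1, n1, p2, n2) {
  stop_if_not(n1 > 0 && n2 > 0, "weights must be positive")
  clamp <- function(p) {
    if (p <= 0 || p >= 1) {
      warning("p-value clamped away from {0, 1} for the Z transform",
              call. = FALSE)
    }
    min(max(p, 1e-15), 1 - 1e-15)
  }
  z1 <- stats::qnorm(1 - clamp(p1))
  z2 <- stats::qnorm(1 - clamp(p2))
  z <- (n1 * z1 + n2 * z2) / sqrt(n1^2 + n2^2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Clinical associations of modules across two cohorts
#'
#' For every module and endpoint (overall survival, stage, histology):
#' the cohort-level statistic and permutation p in each cohort, combined
#' by the sample-size-weighted Z meta-analysis.
#'
#' @param modules List of [radiomic_module()].
#' @param d1,d2 [cohort_bundle()] objects (discovery, validation).
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return data.frame: one row per module x endpoint with `stat_d1`,
#'   `p_d1`, `stat_d2`, `p_d2`, `p_meta`.
#' @export
module_clinical_results <- function(modules, d1, d2, n_perm = 1000,
                                    seed = NULL) {
  endpoints <- c("OS", "stage", "histology")
  seeds <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max %/% 2, 2 * 3 * length(modules)),
    nrow = length(modules)))
  rows <- list()
  for (i in seq_along(modules)) {
    mod <- modules[[i]]
    for (e in seq_along(endpoints)) {
      ep <- endpoints[e]
      one <- function(bundle, sd) {
        if (ep == "OS") {
          module_os_association(mod, bundle$features, bundle$clinical,
                                n_perm = n_perm, seed = sd)
        } else {
          module_group_association(mod, bundle$features,
                                   bundle$clinical[[tolower(ep)]],
                                   n_perm = n_perm, seed = sd)
        }
      }
      a <- one(d1, seeds[i, e])
      b <- one(d2, seeds[i, 3 + e])
      rows[[length(rows) + 1]] <- data.frame(
        module = i, endpoint = ep, stat_d1 = a$stat, p_d1 = a$p,
        stat_d2 = b$stat, p_d2 = b$p,
        p_meta = meta_combine(a$p, length(d1$patients), b$p,
                              length(d2$patients)))
    }
  }
  do.call(rbind, rows)
}
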