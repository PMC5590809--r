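# Radiomic-pathway modules: coherence, validation, size and overlap.

#' Radiomic-pathway module
#'
#' A validated bicluster: a set of radiomic features and a set of
#' pathways whose associations are coherent across patients, with the
#' coherence statistic and its permutation significance.
#'
#' @param feature_ids,pathway_ids Nonempty character vectors.
#' @param r_stat Coherence statistic (see [coherence_r()]).
#' @param p_perm,q_fdr Permutation p-value and FDR-adjusted q-value.
#' @param cohort_of_origin Id of the discovery cohort.
#' @return Object of class `radiomic_module`.
#' @export
radiomic_module <- function(feature_ids, pathway_ids, r_stat = NA_real_,
                            p_perm = NA_real_, q_fdr = NA_real_,
                            cohort_of_origin = NA_character_) {
  stop_if_not(length(feature_ids) >= 1 && length(pathway_ids) >= 1,
              "modules need at least one feature and one pathway")
  structure(list(feature_ids = as.character(feature_ids),
                 pathway_ids = as.character(pathway_ids),
                 r_stat = r_stat, p_perm = p_perm, q_fdr = q_fdr,
                 cohort_of_origin = cohort_of_origin),
            class = "radiomic_module")
}

#' @export
print.radiomic_module <- function(x, ...) {
  cat(sprintf("<radiomic_module> %d features x %d pathways, r = %.3f, p = %s, q = %s\n",
              length(x$feature_ids), length(x$pathway_ids), x$r_stat,
              format.pval(x$p_perm), format.pval(x$q_fdr)))
  invisible(x)
}

#' Module coherence statistic
#'
#' `r = mean(C_X) + mean(C_Y)`, where `C_X` are the Spearman correlations
#' of all pairs of the module's feature columns across patients and `C_Y`
#' the same among the module's per-patient pathway score columns. Computed
#' on patient-level data so it can be re-evaluated on an independent
#' cohort. A singleton side contributes 1 (perfect self-coherence), so
#' one-feature or one-pathway modules remain scorable; `r` ranges over
#' `[-2, 2]`.
#'
#' @param mod A [radiomic_module()] (or list with `feature_ids`,
#'   `pathway_ids`).
#' @param feature_table Patients x features matrix.
#' @param pathway_scores Patients x pathways matrix (per-patient
#'   enrichment scores, see [pathway_score_matrix()]).
#' @return Numeric coherence r.
#' @export
coherence_r <- function(mod, feature_table, pathway_scores) {
  stop_if_not(all(mod$feature_ids %in% colnames(feature_table)),
              "feature table is missing module feature columns")
  stop_if_not(all(mod$pathway_ids %in% colnames(pathway_scores)),
              "pathway score matrix is missing module pathway columns")
  cx <- mean_pairwise_spearman(
    feature_table[, mod$feature_ids, drop = FALSE])
  cy <- mean_pairwise_spearman(
    pathway_scores[, mod$pathway_ids, drop = FALSE])
  cx + cy
}

#' Permutation validation of a module on an independent cohort
#'
#' The observed statistic is the module's coherence `r` computed on the
#' validation cohort. The null preserves the module's dimensions: random
#' modules with the same number of features and pathways are drawn
#' (columns sampled without replacement) from the validation cohort, and
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param mod A [radiomic_module()].
#' @param feature_table Validation patients x features matrix.
#' @param pathway_scores Validation patients x pathways matrix.
#' @param n_perm Number of null draws.
#' @param seed Integer seed.
#' @return List with `r_val` (observed validation coherence) and `p_perm`.
#' @export
permutation_validate <- function(mod, feature_table, pathway_scores,
                                 n_perm = 1000, seed = NULL) {
  nf <- length(mod$feature_ids)
  np <- length(mod$pathway_ids)
  stop_if_not(ncol(feature_table) >= nf && ncol(pathway_scores) >= np,
              "validation cohort has too few columns to sample the null")
  obs <- coherence_r(mod, feature_table, pathway_scores)
  rft <- apply(feature_table, 2, rank)
  rps <- apply(pathway_scores, 2, rank)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    fs <- sample.int(ncol(rft), nf)
    ps <- sample.int(ncol(rps), np)
    mean_pairwise_spearman(rft[, fs, drop = FALSE], method = "pearson") +
      mean_pairwise_spearman(rps[, ps, drop = FALSE], method = "pearson")
  }, numeric(1)))
  list(r_val = obs, p_perm = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control; a thin wrapper over
#' [stats::p.adjust()] kept as the single named FDR entry point of the
#' pipeline.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
fdr_adjust <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Relative module size
#'
#' `n/N + m/M`: the module's feature count relative to the feature bank
#' plus its pathway count relative to the pathway collection; ranges over
#' `(0, 2]`.
#'
#' @param mod A [radiomic_module()].
#' @param n_features_total,n_pathways_total Bank and collection sizes.
#' @return Numeric size.
#' @export
module_size <- function(mod, n_features_total, n_pathways_total) {
  stop_if_not(n_features_total > 0 && n_pathways_total > 0,
              "totals must be positive")
  length(mod$feature_ids) / n_features_total +
    length(mod$pathway_ids) / n_pathways_total
}

#' Feature overlap of two modules
#'
#' Jaccard index `|intersection| / |union|` of the modules' feature sets
#' after collapsing transformed feature names to their base names
#' (wavelet-band and LoG-scale variants of a statistic count as the same
#' feature).
#'
#' @param a,b [radiomic_module()] objects.
#' @return Overlap in `[0, 1]`.
#' @export
module_overlap <- function(a, b) {
  fa <- unique(base_feature_name(a$feature_ids))
  fb <- unique(base_feature_name(b$feature_ids))
  length(intersect(fa, fb)) / length(union(fa, fb))
}

#' Discover modules in a discovery cohort
#'
#' Runs ISA biclustering on the NES association matrix, removes candidates
#' that plain noise can produce with [isa_robustness_filter()], scores
#' every surviving candidate's coherence on the discovery cohort, and
#' prunes redundancy greedily in decreasing |r| order with the 0.3
#' membership-correlation cap. Pruning runs before cross-cohort
#' validation.
#'
#' @param assoc An `association_matrix` (or plain NES matrix with
#'   dimnames).
#' @param feature_table Discovery patients x features matrix.
#' @param pathway_scores Discovery patients x pathways matrix.
#' @param row_thresholds,col_thresholds,n_seeds,max_corr ISA and pruning
#'   parameters.
#' @param seed Integer seed.
#' @param cohort_id Discovery cohort id recorded on each module.
#' @return List of [radiomic_module()] (p/q not yet filled).
#' @export
discover_modules <- function(assoc, feature_table, pathway_scores,
                             row_thresholds = c(1.5, 2, 2.5),
                             col_thresholds = c(1.5, 2, 2.5),
                             n_seeds = 100, max_corr = 0.3, seed = NULL,
                             cohort_id = "discovery") {
  nes <- if (inherits(assoc, "association_matrix")) assoc$nes else assoc
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2, 2))
  cands <- isa_bicluster(nes, row_thresholds, col_thresholds,
                         n_seeds = n_seeds, seed = seeds[1])
  cands <- isa_robustness_filter(nes, cands, row_thresholds,
                                 col_thresholds, n_seeds = n_seeds,
                                 seed = seeds[2])
  if (length(cands) == 0) return(list())
  mods <- lapply(cands, function(cd) {
    radiomic_module(rownames(nes)[cd$rows], colnames(nes)[cd$cols],
                    cohort_of_origin = cohort_id)
  })
  r <- vapply(mods, coherence_r, numeric(1), feature_table, pathway_scores)
  for (i in seq_along(mods)) mods[[i]]$r_stat <- r[i]
  key <- function(x) paste(paste(x$rows, collapse = ","),
                           paste(x$cols, collapse = ","), sep = "|")
  keep <- deduplicate_modules(cands, max_corr = max_corr,
                              robustness = abs(r))
  mods[match(vapply(keep, key, character(1)),
             vapply(cands, key, character(1)))]
}

#' Validate a module list on an independent cohort
#'
#' Applies [permutation_validate()] to every module and attaches
#' Benjamini-Hochberg q-values across the list.
#'
#' @param modules List of [radiomic_module()].
#' @param feature_table,pathway_scores Validation cohort data.
#' @param n_perm Permutations per module.
#' @param seed Integer seed.
#' @return The module list with `r_stat` (validation r), `p_perm` and
#'   `q_fdr` filled in.
#' @export
validate_modules <- function(modules, feature_table, pathway_scores,
                             n_perm = 1000, seed = NULL) {
  if (length(modules) == 0) return(modules)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                      length(modules)))
  ps <- numeric(length(modules))
  for (i in seq_along(modules)) {
    v <- permutation_validate(modules[[i]], feature_table, pathway_scores,
                              n_perm = n_perm, seed = seeds[i])
    modules[[i]]$r_val <- v$r_val
    ps[i] <- v$p_perm
  }
  qs <- fdr_adjust(ps)
  for (i in seq_along(modules)) {
    modules[[i]]$p_perm <- ps[i]
    modules[[i]]$q_fdr <- qs[i]
  }
  modules
}
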