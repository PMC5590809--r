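# End-to-end orchestration of the two-cohort analysis.

#' Pipeline configuration
#'
#' Bundles every stage's tunable parameters with one global seed; the
#' configuration is serializable to YAML and hashed into all artifacts so
#' a run is reproducible bit-exact from its config.
#'
#' @param extraction An [extraction_config()] (used when images are
#'   extracted upstream; cohort bundles carry extracted features).
#' @param n_perm_gsea Permutations per feature in the enrichment stage.
#' @param weight_exp Ranking weight exponent used when building the NES
#'   matrix. The pipeline default is 0.25 rather than the classic 1: the
#'   rho * (-log10 p) ranking metric is unbounded (its extremes grow with
#'   cohort size), and with exponent 1 the running sum is dominated by a
#'   handful of top genes, which saturates the gene-permutation null and
#'   compresses the NES scale until coherent blocks become invisible to
#'   biclustering on compact gene universes. A sub-unit exponent tempers
#'   the weights while preserving the weighted statistic; set 1 to
#'   reproduce the classic behavior.
#' @param set_min,set_max Gene-set size filter bounds.
#' @param isa_thresholds Row/column threshold grid for biclustering.
#' @param isa_seeds Random seeds per threshold pair.
#' @param max_corr Redundancy-pruning membership-correlation cap.
#' @param n_perm_validate Permutations for module validation.
#' @param n_perm_clinical Permutations for clinical association tests.
#' @param q_threshold Module FDR acceptance threshold.
#' @param signature_k Maximum signature size ranked by mRMR.
#' @param n_cv Cross-validation resamples for the incremental Cox stage.
#' @param seed Global integer seed; every stage's draws flow from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(extraction = extraction_config(),
                            n_perm_gsea = 1000, weight_exp = 0.25,
                            set_min = 15, set_max = 500,
                            isa_thresholds = c(1.5, 2, 2.5),
                            isa_seeds = 100, max_corr = 0.3,
                            n_perm_validate = 1000,
                            n_perm_clinical = 1000, q_threshold = 0.05,
                            signature_k = 15, n_cv = 1000, seed = 1L) {
  cfg <- structure(list(extraction = extraction, n_perm_gsea = n_perm_gsea,
                        weight_exp = weight_exp, set_min = set_min,
                        set_max = set_max, isa_thresholds = isa_thresholds,
                        isa_seeds = isa_seeds, max_corr = max_corr,
                        n_perm_validate = n_perm_validate,
                        n_perm_clinical = n_perm_clinical,
                        q_threshold = q_threshold,
                        signature_k = signature_k, n_cv = n_cv,
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  cfg$hash <- config_hash(unclass(cfg))
  cfg
}

#' Run the full two-cohort radiogenomic pipeline
#'
#' Executes the analysis chain on a discovery and a validation cohort:
#' gene-set filtering, the feature x pathway NES association matrix on the
#' discovery cohort, ISA module discovery with redundancy pruning,
#' cross-cohort permutation validation under FDR control, clinical
#' associations with two-cohort meta-analysis, the strongest pathway
#' predictor per validated module, and the mRMR + incremental Cox
#' prognostic signature trained on discovery and validated on the second
#' cohort. Discovery/validation roles are explicit arguments, never
#' inferred.
#'
#' @param d1 Discovery [cohort_bundle()].
#' @param d2 Validation [cohort_bundle()].
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, artifacts are written
#'   (`association_nes.csv`, `modules.json`, `module_network.csv`,
#'   `clinical_results.csv`, `signature.json`, `config.yaml`).
#' @return List with elements `assoc`, `modules` (validated, q below the
#'   configured threshold), `all_modules`, `clinical`, `predictors`,
#'   `signature`, `signature_validation_ci`, `config`.
#' @export
run_pipeline <- function(d1, d2, cfg = pipeline_config(),
                         out_dir = NULL) {
  stop_if_not(inherits(d1, "cohort_bundle") && inherits(d2, "cohort_bundle"),
              "d1 and d2 must be cohort bundles")
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max %/% 2, 6))
  universe <- intersect(rownames(d1$expr), rownames(d2$expr))
  collection <- filter_gene_sets(d1$gene_sets, universe,
                                 min_size = cfg$set_min,
                                 max_size = cfg$set_max)
  stop_if_not(length(collection) >= 1,
              "no gene sets usable in both cohorts")
  message(sprintf("stage associate: %d features x %d pathways",
                  ncol(d1$features), length(collection)))
  assoc <- build_association_matrix(d1$features, d1$expr, collection,
                                    n_perm = cfg$n_perm_gsea,
                                    seed = seeds[1],
                                    weight_exp = cfg$weight_exp)
  ps1 <- pathway_score_matrix(d1$expr, collection)
  cand <- discover_modules(assoc, d1$features, ps1,
                           row_thresholds = cfg$isa_thresholds,
                           col_thresholds = cfg$isa_thresholds,
                           n_seeds = cfg$isa_seeds,
                           max_corr = cfg$max_corr, seed = seeds[2],
                           cohort_id = d1$cohort_id)
  message(sprintf("stage modules: %d pruned candidate(s)", length(cand)))
  ps2 <- pathway_score_matrix(d2$expr, collection)
  cand <- validate_modules(cand, d2$features, ps2,
                           n_perm = cfg$n_perm_validate, seed = seeds[3])
  qv <- vapply(cand, `[[`, numeric(1), "q_fdr")
  modules <- cand[which(qv < cfg$q_threshold)]
  message(sprintf("stage validate: %d module(s) at q < %g",
                  length(modules), cfg$q_threshold))
  clinical <- if (length(modules)) {
    module_clinical_results(modules, d1, d2,
                            n_perm = cfg$n_perm_clinical, seed = seeds[4])
  } else {
    NULL
  }
  predictors <- lapply(modules, module_pathway_predictors, d1 = d1,
                       d2 = d2)
  ranked <- mrmr_rank(d1$features, d1$clinical$os_time,
                      d1$clinical$os_event,
                      k = min(cfg$signature_k, ncol(d1$features)))
  signature <- incremental_cox(ranked, d1$features, d1$clinical$os_time,
                               d1$clinical$os_event, n_cv = cfg$n_cv,
                               seed = seeds[5])
  val_ci <- concordance_index(predict(signature, d2$features),
                              d2$clinical$os_time,
                              d2$clinical$os_event)$ci
  res <- list(assoc = assoc, modules = modules, all_modules = cand,
              clinical = clinical, predictors = predictors,
              signature = signature, signature_validation_ci = val_ci,
              config = cfg)
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$assoc$nes,
                   file.path(out_dir, "association_nes.csv"))
  mods <- lapply(res$all_modules, function(m) {
    list(feature_ids = m$feature_ids, pathway_ids = m$pathway_ids,
         r_stat = m$r_stat, r_val = m$r_val %||% NA_real_,
         p_perm = m$p_perm, q_fdr = m$q_fdr)
  })
  jsonlite::write_json(list(config_hash = res$config$hash, modules = mods),
                       file.path(out_dir, "modules.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(res$modules) > 1) {
    pairs <- utils::combn(length(res$modules), 2)
    net <- data.frame(
      module_a = pairs[1, ], module_b = pairs[2, ],
      overlap = apply(pairs, 2, function(ix) {
        module_overlap(res$modules[[ix[1]]], res$modules[[ix[2]]])
      }))
    utils::write.csv(net, file.path(out_dir, "module_network.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$clinical)) {
    utils::write.csv(res$clinical,
                     file.path(out_dir, "clinical_results.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(config_hash = res$config$hash,
         feature_ids = res$signature$feature_ids,
         coefficients = as.list(res$signature$coefficients),
         cv_mean_ci = res$signature$cv_best_ci,
         validation_ci = res$signature_validation_ci),
    file.path(out_dir, "signature.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(res$config), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
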