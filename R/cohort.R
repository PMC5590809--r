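#' Aligned cohort bundle
#'
#' One cohort's worth of aligned data: a patients x features radiomic
#' table, a genes x patients expression matrix, a gene-set collection, and
#' a clinical table (overall-survival time and event, TNM stage grouped as
#' I/II/III/other, histology grouped as adenocarcinoma/squamous/other).
#' All blocks are aligned to an identical, duplicate-free patient id set.
#'
#' @param features Data frame or matrix, patients x features, rownames =
#'   patient ids.
#' @param expr Numeric matrix, genes x patients.
#' @param gene_sets Named list of character vectors of gene ids.
#' @param clinical Data frame with columns `patient_id`, `os_time`,
#'   `os_event`, `stage`, `histology`.
#' @param cohort_id Identifier string.
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(features, expr, gene_sets, clinical,
                          cohort_id = "cohort") {
  features <- as.matrix(features)
  stop_if_not(!is.null(rownames(features)), "features need patient rownames")
  stop_if_not(!is.null(colnames(expr)), "expr needs patient colnames")
  stop_if_not(all(c("patient_id", "os_time", "os_event", "stage",
                    "histology") %in% names(clinical)),
              "clinical table is missing required columns")
  ids <- rownames(features)
  stop_if_not(!anyDuplicated(ids), "duplicated patient ids in features")
  stop_if_not(!anyDuplicated(colnames(expr)), "duplicated patient ids in expr")
  stop_if_not(!anyDuplicated(clinical$patient_id),
              "duplicated patient ids in clinical table")
  common <- Reduce(intersect, list(ids, colnames(expr),
                                   as.character(clinical$patient_id)))
  if (length(common) == 0) stop("no patients shared across blocks",
                                call. = FALSE)
  dropped <- length(unique(c(ids, colnames(expr),
                             as.character(clinical$patient_id)))) -
    length(common)
  if (dropped > 0) {
    message(sprintf("cohort %s: dropped %d patient(s) missing in some block",
                    cohort_id, dropped))
  }
  clinical <- clinical[match(common, clinical$patient_id), ]
  stop_if_not(all(clinical$os_time >= 0), "os_time must be nonnegative")
  structure(list(features = features[common, , drop = FALSE],
                 expr = expr[, common, drop = FALSE],
                 gene_sets = gene_sets,
                 clinical = clinical,
                 cohort_id = cohort_id,
                 patients = common),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0("<cohort_bundle> %s: %d patients, %d radiomic features,",
                     " %d genes, %d gene sets\n"),
              x$cohort_id, length(x$patients), ncol(x$features),
              nrow(x$expr), length(x$gene_sets)))
  invisible(x)
}

#' Design of a synthetic cohort with planted structure
#'
#' Declares the ground truth that [gen_cohort()] realizes: cohort size,
#' gene universe, gene sets, feature-set correlation links, correlated
#' feature blocks, a prognostic feature, and the censoring fraction. The
#' generator's defaults emulate a desk-scale lung-cancer cohort: a 2,000
#' gene universe, standard-normal log-expression, and exponential baseline
#' survival with median about 2 years.
#'
#' @param n_patients Number of patients.
#' @param n_features Number of radiomic feature columns (named
#'   `feat_1 ...`).
#' @param n_genes Gene universe size (named `gene_1 ...`).
#' @param gene_sets Named list of gene id vectors; `NULL` generates
#'   `n_sets` random disjoint sets of size `set_size`.
#' @param n_sets,set_size Used when `gene_sets` is `NULL`.
#' @param links Data frame with columns `feature`, `set`, `strength`
#'   (correlation in `[-1, 1]` between the feature and each member gene).
#' @param feature_blocks List of `list(features =, rho =)` giving groups of
#'   feature columns sharing a latent factor at pairwise correlation `rho`.
#' @param survival_link `list(feature =, coef =)`: log-hazard per unit of
#'   the (standardized) feature. `coef = 0` gives null survival.
#' @param censor_rate Expected fraction of censored patients in `[0, 1)`.
#' @param baseline_hazard Exponential event rate per month at covariate 0.
#' @param stage_probs,histology_probs Categorical mixtures for stage
#'   (I/II/III/other) and histology (adenocarcinoma/squamous/other).
#' @param seed Integer seed (same design + seed = identical cohort).
#' @return An object of class `planted_design`.
#' @export
planted_design <- function(n_patients = 100, n_features = 20,
                           n_genes = 2000, gene_sets = NULL, n_sets = 10,
                           set_size = 20, links = NULL,
                           feature_blocks = list(),
                           survival_link = list(feature = "feat_1",
                                                coef = 0),
                           censor_rate = 0.3, baseline_hazard = 1 / 36,
                           stage_probs = c(I = 0.45, II = 0.2, III = 0.25,
                                           other = 0.1),
                           histology_probs = c(adenocarcinoma = 0.5,
                                               squamous = 0.35,
                                               other = 0.15),
                           seed = 1L) {
  genes <- paste0("gene_", seq_len(n_genes))
  if (is.null(gene_sets)) {
    stop_if_not(n_sets * set_size <= n_genes,
                "gene universe too small for the requested sets")
    gene_sets <- split(genes[seq_len(n_sets * set_size)],
                       rep(seq_len(n_sets), each = set_size))
    names(gene_sets) <- paste0("SET_", seq_len(n_sets))
  }
  feats <- paste0("feat_", seq_len(n_features))
  if (is.null(links)) {
    links <- data.frame(feature = character(), set = character(),
                        strength = numeric())
  }
  stop_if_not(all(links$feature %in% feats),
              "links reference unknown feature ids")
  stop_if_not(all(links$set %in% names(gene_sets)),
              "links reference unknown set ids")
  stop_if_not(all(abs(links$strength) <= 1),
              "link strengths must lie in [-1, 1]")
  stop_if_not(censor_rate >= 0 && censor_rate < 1,
              "censor_rate must be in [0, 1)")
  stop_if_not(survival_link$feature %in% feats,
              "survival_link references an unknown feature")
  for (b in feature_blocks) {
    stop_if_not(all(b$features %in% feats),
                "feature_blocks reference unknown feature ids")
    stop_if_not(b$rho >= 0 && b$rho <= 1, "block rho must be in [0, 1]")
  }
  structure(list(n_patients = n_patients, n_features = n_features,
                 n_genes = n_genes, genes = genes, gene_sets = gene_sets,
                 links = links, feature_blocks = feature_blocks,
                 survival_link = survival_link, censor_rate = censor_rate,
                 baseline_hazard = baseline_hazard,
                 stage_probs = stage_probs,
                 histology_probs = histology_probs,
                 seed = as.integer(seed)),
            class = "planted_design")
}

#' Generate a synthetic cohort with planted structure
#'
#' Realizes a [planted_design()] as a [cohort_bundle()] with known ground
#' truth. Feature columns are standard normal; columns named in a feature
#' block share a latent factor at the block's pairwise correlation.
#' Expression follows a Gaussian-copula construction: every member gene of
#' a linked set is `s * feature + sqrt(1 - s^2) * noise`, so the
#' feature-gene correlation is `s` in expectation. Survival times are drawn
#' from an exponential proportional-hazards model on the designated
#' feature; a `Bernoulli(censor_rate)` subset of patients is censored at a
#' uniform fraction of the event time, which delivers the requested
#' censoring fraction in expectation regardless of covariate effects.
#'
#' @param design A [planted_design()].
#' @return A [cohort_bundle()].
#' @examples
#' d <- planted_design(n_patients = 40, n_features = 8, n_genes = 300,
#'                     n_sets = 5, set_size = 15, seed = 2)
#' gen_cohort(d)
#' @export
gen_cohort <- function(design) {
  stop_if_not(inherits(design, "planted_design"),
              "design must be a planted_design")
  d <- design
  with_seed(d$seed, {
    n <- d$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    feats <- paste0("feat_", seq_len(d$n_features))
    X <- matrix(stats::rnorm(n * d$n_features), n, d$n_features,
                dimnames = list(ids, feats))
    for (b in d$feature_blocks) {
      z <- stats::rnorm(n)
      for (f in b$features) {
        X[, f] <- sqrt(b$rho) * z + sqrt(1 - b$rho) * stats::rnorm(n)
      }
    }
    E <- matrix(stats::rnorm(d$n_genes * n), d$n_genes, n,
                dimnames = list(d$genes, ids))
    if (nrow(d$links)) {
      for (k in seq_len(nrow(d$links))) {
        s <- d$links$strength[k]
        f <- scale(X[, d$links$feature[k]])[, 1]
        for (gn in d$gene_sets[[d$links$set[k]]]) {
          E[gn, ] <- s * f + sqrt(1 - s^2) * stats::rnorm(n)
        }
      }
    }
    beta <- d$survival_link$coef
    z <- scale(X[, d$survival_link$feature])[, 1]
    rate <- d$baseline_hazard * exp(beta * z)
    t_event <- stats::rexp(n, rate)
    cens <- stats::rbinom(n, 1, d$censor_rate) == 1
    os_time <- ifelse(cens, stats::runif(n) * t_event, t_event)
    clinical <- data.frame(
      patient_id = ids,
      os_time = os_time,
      os_event = as.integer(!cens),
      stage = sample(names(d$stage_probs), n, TRUE, d$stage_probs),
      histology = sample(names(d$histology_probs), n, TRUE,
                         d$histology_probs),
      stringsAsFactors = FALSE)
    cohort_bundle(X, E, d$gene_sets, clinical,
                  cohort_id = sprintf("synthetic_seed%d", d$seed))
  })
}
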