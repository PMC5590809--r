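# radiopath

Radiomic–pathway association modules for tumor imaging genomics.

Lung tumors (and solid tumors generally) vary in CT-visible phenotype —
density, shape, texture — and in the molecular pathways active in the
tissue. `radiopath` implements the full inference chain that connects
the two across a discovery and a validation cohort:

1. **Radiomics** — a 636-feature bank per tumor volume + mask:
   first-order intensity statistics, 3D shape, GLCM / run-length /
   size-zone texture, the same statistics on 8 stationary Coiflet-1
   wavelet bands, and first-order statistics of Laplacian-of-Gaussian
   responses at 13 scales. A 440-feature previously published core is
   flagged inside the bank.
2. **Pathway scoring** — for each feature, genes are ranked by
   `rho · (−log10 p)` (Spearman correlation with the feature and its
   significance) and every gene set (15–500 genes) is scored by
   preranked enrichment with a gene-permutation null, giving a
   feature × pathway matrix of normalized enrichment scores (NES).
3. **Module discovery** — the NES matrix is biclustered with the
   Iterative Signature Algorithm (thresholds 1.5–2.5 by 0.5), filtered
   against permuted-matrix noise, pruned for redundancy (membership
   correlation ≤ 0.3), and each module's coherence
   `r = mean(C_X) + mean(C_Y)` (mean pairwise Spearman correlation of
   its features, plus the same for its per-patient pathway scores) is
   validated on the independent cohort by permutation (N = 1000) under
   Benjamini–Hochberg FDR control.
4. **Clinical association** — per module: mean |CI − 0.5| against
   overall survival (Harrell's concordance, Noether standard error),
   mean Kruskal–Wallis H against stage and histology, permutation
   tests in both cohorts, and a sample-size-weighted Z meta-analysis
   `z = (n₁z₁ + n₂z₂)/√(n₁² + n₂²)`.
5. **Prediction and signatures** — univariate logistic predictors of
   per-patient pathway activation (AUC with Noether significance),
   mRMR + incremental Cox prognostic signatures selected by repeated
   random cross-validation, and Cox-level fusion of clinical, gene,
   and radiomic risk with permutation model comparisons.

A synthetic-cohort generator (`gen_phantom()`, `planted_design()`,
`gen_cohort()`) plants known image, expression, and survival structure
so that every stage is testable end to end.

## Worked example

Extract the feature bank from a synthetic tumor phantom:

```r
library(radiopath)

v <- gen_phantom(phantom_spec("blob", size_mm = 14,
                              texture = "gaussian_noise",
                              texture_params = list(mean = 120, sd = 35),
                              seed = 8))
v
#> <volume_mask> 18 x 18 x 18 voxels, spacing 1x1x1 mm, 1639 masked

f <- extract_features(v)
round(f[c("mean", "sphericity", "glcm.contrast",
          "wavelet.HHH.entropy", "log.sigma.3.standard.deviation")], 3)
#>                           mean                     sphericity
#>                        119.857                          0.588
#>                  glcm.contrast            wavelet.HHH.entropy
#>                          4.188                          2.760
#> log.sigma.3.standard.deviation
#>                         15.063
```

`length(f)` is 636; `sum(feature_bank()$prior)` is 440. The mean sits
at the phantom's texture mean, the blob's sphericity (0.59) is well
below a sphere's, and the high-pass wavelet band still carries entropy
because the texture is noise.

Run the full two-cohort pipeline on synthetic cohorts with one planted
feature–pathway block (five correlated features, four linked gene
sets) and a planted prognostic feature:

```r
d <- planted_design(
  n_patients = 150, n_features = 50, n_genes = 500, n_sets = 20,
  set_size = 15,
  links = data.frame(feature = c("feat_1", "feat_2", "feat_3", "feat_1"),
                     set = paste0("SET_", 1:4), strength = 0.35),
  feature_blocks = list(list(features = paste0("feat_", 1:5), rho = 0.85)),
  survival_link = list(feature = "feat_1", coef = log(2)), seed = 1)
d1 <- gen_cohort(d); d$seed <- 2L; d2 <- gen_cohort(d)

cfg <- pipeline_config(n_perm_gsea = 200, isa_seeds = 100,
                       n_perm_validate = 1000, n_perm_clinical = 200,
                       n_cv = 50, signature_k = 8, seed = 42)
res <- run_pipeline(d1, d2, cfg)
#> stage associate: 50 features x 20 pathways
#> stage modules: 1 pruned candidate(s)
#> stage validate: 1 module(s) at q < 0.05

res$modules[[1]]
#> <radiomic_module> 7 features x 4 pathways, r = 0.774, p = 0.000999, q = 0.000999
res$clinical[res$clinical$endpoint == "OS", ]
#>   module endpoint stat_d1    p_d1 stat_d2    p_d2   p_meta
#> 1      1       OS    0.15 0.00498   0.118 0.00498 0.000134
res$signature
#> <survival_signature> 4 feature(s), CV mean CI 0.711
round(res$signature_validation_ci, 3)
#> [1] 0.665
```

The single validated module contains all five planted features and all
four linked sets (plus two diluting features); its coherence validates
on the second cohort at the permutation floor. The module's features
associate with overall survival in both cohorts (meta p = 1.3e-4), and
the mRMR + incremental-Cox signature — which selects the planted
prognostic feature — validates at concordance 0.665 on the independent
cohort.

A thin command-line front-end over the same functions lives at
`inst/cli/radiopath.R` (subcommands `simulate`, `extract`, `associate`,
`run-all`).

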