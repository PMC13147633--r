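# DCNfuse

Multi-layer network analysis for small immuno-oncology cohorts profiled
with a targeted tumour gene-expression panel (GEP) and circulating immune
phenotyping (CIP). The package is aimed at translational researchers who
want to ask, on a few dozen patients: *which gene–gene and immune–immune
relationships differ between therapy responders and non-responders, and
does integrating the two data layers stratify patients prognostically?*

## What it computes

* **Group-wise correlation networks.** Spearman correlation networks of
  the immune subsets per response group and timepoint (edges at
  |ρ| > 0.55, BH-FDR < 0.05) and co-expression networks per group
  (|ρ| > 0.7, FDR < 0.05).
* **A differential co-expression network (DCN).** For gene pairs that are
  edges in at least one group network, the correlation difference is
  tested with the Fisher z-statistic

  $$Z = \frac{\mathrm{atanh}\,\rho_A - \mathrm{atanh}\,\rho_B}
  {\sqrt{1/(n_A-3) + 1/(n_B-3)}},$$

  retaining |Z| > 2. Positive edges mark pairs more strongly co-expressed
  in responders. Hubs are the genes above the 95th percentile of the
  nonzero degree distribution; communities come from Louvain modularity
  optimisation; hub neighbourhoods and communities are tested for
  over-representation against user-supplied GMT gene sets with the
  hypergeometric tail on the panel-restricted background.
* **Similarity Network Fusion (SNF).** Patient-affinity matrices from the
  hub-gene expression layer and the immune layer are fused by nonlinear
  cross-diffusion; the cluster count is picked by the Laplacian eigengap
  and patients are grouped by seeded spectral clustering.
* **Survival stratification.** Kaplan–Meier curves, log-rank tests, and
  univariate plus covariate-adjusted Cox models (Efron ties) for the
  fused clusters, cluster composition and accuracy against response,
  per-variable Mann–Whitney comparisons and baseline-balance tests.
* **Internal validation.** Leave-one-out cross-validation of the entire
  pipeline and a hub-percentile sensitivity analysis.
* **A synthetic-cohort generator** with planted hubs, group-specific
  co-expression, immune correlation blocks, cluster-linked survival and
  full ground truth, used by the recovery tests and the acceptance
  script. No patient data ship with the package.

## Worked example

```r
library(DCNfuse)
cohort <- generateCohort(cohortConfig(seed = 1))
clin <- cohortClinical(cohort)
response <- factor(setNames(clin$response, clin$patient_id),
                   levels = c("R", "NR"))

dcn <- buildDCN(cohortExpression(cohort),
                response[colnames(cohortExpression(cohort))])
dcn
#> DifferentialNetwork: 438 genes, 668 edges (537 positive, 131 negative), |Z| > 2
hubs <- selectHubs(dcn, percentile = 95)
length(hubs$genes)
#> [1] 21

immune <- cohortImmune(cohort, "pre")
gep_features <- t(log1p(cohortExpression(cohort)[hubs$genes, rownames(immune)]))
fused <- snfFuse(list(GEP = affinityMatrix(gep_features),
                      CIP = affinityMatrix(as.matrix(immune))))
eigengapK(fused)$k
#> [1] 2
clusters <- spectralCluster(fused, k = 2, seed = 1)$labels
clusterAccuracy(clusters, response[names(clusters)])$confusion
#>        label
#> cluster NR  R
#>       1  1 17
#>       2 17  3

surv <- clin[match(names(clusters), clin$patient_id), ]
logrankTest(surv$time_months, surv$event, clusters)$p
#> [1] 0.0007946005
coxPH(cbind(surv, cluster = factor(clusters)), "cluster")$hazard_ratios
#> cluster2
#> 4.115183
```

Reading the output: the DCN finds 668 gene pairs whose co-expression
differs between response groups; 21 of the 23 planted hub genes sit above
the 95th degree percentile. Fusing the hub-gene and immune similarity
layers splits the 38 common patients into two clusters that track
response (34/38 concordant here) and separate overall survival sharply
(log-rank p ≈ 8·10⁻⁴, cluster hazard ratio ≈ 4.1 against a planted 4.5).

`runPipeline(cohort, "out/")` runs every stage in order — four CIP
networks, co-expression networks, DCN/hubs/communities, enrichment,
PSN fusion with single-layer ablations, survival reports, LOOCV and the
percentile sensitivity — and writes TSV/CSV/JSON artifacts plus a
manifest of content hashes.

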