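test_that("cohort dimensions follow the configuration", {
  ch <- generateCohort(cohortConfig(seed = 1))
  expect_equal(dim(cohortExpression(ch)), c(438L, 44L))
  expect_equal(dim(cohortImmune(ch, "pre")), c(38L, 31L))
  expect_equal(dim(cohortImmune(ch, "post")), c(38L, 31L))
  clin <- cohortClinical(ch)
  expect_equal(sum(clin$common & clin$response == "R"), 20L)
  expect_equal(sum(clin$common & clin$response == "NR"), 18L)
  expect_length(cohortTruth(ch)$planted_hub_genes, 23L)
  expect_true(validObject(ch))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generateCohort(smallConfig(seed = 99))
  b <- generateCohort(smallConfig(seed = 99))
  expect_identical(cohortExpression(a), cohortExpression(b))
  expect_identical(cohortImmune(a, "pre"), cohortImmune(b, "pre"))
  expect_identical(cohortClinical(a), cohortClinical(b))
  expect_identical(cohortTruth(a), cohortTruth(b))
  c2 <- generateCohort(smallConfig(seed = 100))
  expect_false(identical(cohortExpression(a), cohortExpression(c2)))
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(n_responders_common = 40,
                            n_patients_common = 38), "exceed")
  expect_error(cohortConfig(n_patients_common = 50), "exceed")
  expect_error(cohortConfig(rho_within_module = 1), "\\[0, 1\\)")
  expect_error(cohortConfig(n_genes = 100, n_backbone_genes = 95),
               "fit in the panel")
  expect_error(cohortConfig(censoring_rate = 1.2), "censoring")
})

test_that("planted pairs are strongly correlated in responders only", {
  ch <- generateCohort(cohortConfig(seed = 2))
  expr <- cohortExpression(ch)
  tr <- cohortTruth(ch)
  clin <- cohortClinical(ch)
  isR <- clin$response[match(colnames(expr), clin$patient_id)] == "R"
  pairs <- tr$planted_differential_pairs
  set.seed(1)
  pairs <- pairs[sample(nrow(pairs), 150), ]
  rhoOf <- function(cols) {
    vapply(seq_len(nrow(pairs)), function(i) {
      cor(expr[pairs[i, 1], cols], expr[pairs[i, 2], cols],
          method = "spearman")
    }, 1)
  }
  expect_gte(mean(abs(rhoOf(isR))), 0.6)
  expect_lte(mean(abs(rhoOf(!isR))), 0.3)
  # every planted pair touches a planted hub
  expect_true(all(pairs[, 1] %in% tr$planted_hub_genes |
                    pairs[, 2] %in% tr$planted_hub_genes))
})

test_that("immune percentages are bounded and expression is count-like", {
  ch <- generateCohort(smallConfig(seed = 3))
  for (tp in c("pre", "post")) {
    v <- unlist(cohortImmune(ch, tp))
    expect_true(all(v > 0 & v < 100))
  }
  ex <- cohortExpression(ch)
  expect_true(all(is.finite(ex)) && all(ex >= 0))
  expect_true(all(ex == round(ex)))
})

test_that("survival generation carries the planted hazard ratio", {
  set.seed(30)
  ests <- vapply(1:50, function(s) {
    ch <- generateCohort(cohortConfig(seed = s))
    clin <- cohortClinical(ch)
    clin <- clin[clin$common, ]
    lat <- cohortTruth(ch)$latent_cluster[clin$patient_id]
    fit <- coxPH(cbind(clin, lat = factor(lat, levels = c("C1", "C2"))),
                 "lat")
    fit$coefficients[[1]]
  }, 1)
  truth <- log(4.5)
  expect_lt(abs(mean(ests) - truth) / truth, 0.5)
})

test_that("the censoring fraction tracks the configured rate", {
  evs <- vapply(1:20, function(s) {
    mean(cohortClinical(generateCohort(cohortConfig(seed = s)))$event)
  }, 1)
  expect_equal(1 - mean(evs), 0.2, tolerance = 0.08)
  nocens <- generateCohort(cohortConfig(seed = 1, censoring_rate = 0))
  expect_true(all(cohortClinical(nocens)$event == 1))
})

test_that("cohorts round-trip losslessly through the writers and readers", {
  ch <- generateCohort(smallConfig(seed = 4))
  d <- file.path(tempfile("cohort"))
  expect_error(writeCohort(ch, d), d)
  dir.create(d)
  files <- writeCohort(ch, d)
  expect_true(all(file.exists(files)))
  back <- readCohort(d)
  expect_equal(cohortExpression(back), cohortExpression(ch))
  expect_equal(as.matrix(cohortImmune(back, "pre")),
               as.matrix(cohortImmune(ch, "pre")), tolerance = 1e-12)
  expect_equal(cohortClinical(back)$response, cohortClinical(ch)$response)
  tr <- jsonlite::read_json(file.path(d, "truth.json"),
                            simplifyVector = TRUE)
  expect_length(tr$planted_hub_genes, ch@config$n_planted_hubs)
  expect_true(file.exists(file.path(d, "manifest.json")))
  # synthetic gene sets align with the panel
  gmt <- readGMT(file.path(d, "gene_sets.gmt"))
  expect_setequal(gmt$sets$HUB_MODULE, cohortTruth(ch)$planted_hub_genes)
})

test_that("baseline covariates are balanced across latent clusters", {
  set.seed(31)
  ps <- vapply(1:40, function(s) {
    ch <- generateCohort(smallConfig(seed = s))
    clin <- cohortClinical(ch)
    lat <- cohortTruth(ch)$latent_cluster[clin$patient_id]
    if (length(unique(lat)) < 2) return(NA_real_)
    bb <- baselineBalance(clin, setNames(lat, clin$patient_id),
                          covariates = "age")
    bb$p
  }, 1)
  ps <- ps[!is.na(ps)]
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
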