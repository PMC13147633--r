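test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kmCurve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  allc <- kmCurve(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(allc$survival == 1))
  expect_true(is.na(allc$median))
  one <- kmCurve(3, 1)
  expect_equal(one$survival, 0)
  expect_equal(one$median, 3)
  expect_error(kmCurve(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank reduces to zero on identical groups and matches hand O/E/V", {
  t2 <- rep(c(2, 5, 8), 2)
  e2 <- rep(1, 6)
  g2 <- rep(c("a", "b"), each = 3)
  lr0 <- logrankTest(t2, e2, g2)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  # group1 events at 1,2; group2 at 3,4: O1=2, E1=5/6, V=17/36
  lr <- logrankTest(c(1, 2, 3, 4), rep(1, 4), c(1, 1, 2, 2))
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-9)
  expect_error(logrankTest(c(1, 2), c(1, 1), c("a", "a")), "2 non-empty")
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(20)
  ps <- replicate(500, {
    tm <- rexp(38, 0.05)
    gr <- rep(c("a", "b"), c(20, 18))
    logrankTest(tm, rbinom(38, 1, 0.8), gr)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Cox fits report Wald intervals and flag problems", {
  set.seed(21)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.05 * exp(log(2) * x))
  tab <- data.frame(time_months = tm, event = 1, arm = factor(x))
  fit <- coxPH(tab, "arm")
  expect_true(fit$converged)
  expect_equal(unname(fit$hazard_ratios), unname(exp(fit$coefficients)))
  expect_true(fit$ci_lower[1] <= fit$hazard_ratios[1] &&
              fit$hazard_ratios[1] <= fit$ci_upper[1])
  expect_gt(fit$coefficients[1], 0)      # direction of harm
  expect_error(coxPH(data.frame(time_months = 1:3, event = 0, x = 1:3),
                     "x"), "event")
  # complete separation is flagged, not silently reported
  sep <- data.frame(time_months = c(1, 2, 3, 10, 11, 12),
                    event = c(1, 1, 1, 0, 0, 0),
                    g = factor(c("a", "a", "a", "b", "b", "b")))
  expect_false(coxPH(sep, "g")$converged)
})

test_that("null Cox intervals cover one at the nominal rate", {
  set.seed(22)
  cover <- replicate(60, {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    tab <- data.frame(time_months = rexp(n, 0.1), event = 1,
                      x = factor(x))
    fit <- coxPH(tab, "x")
    fit$ci_lower[1] <= 1 && 1 <= fit$ci_upper[1]
  })
  expect_gt(mean(cover), 0.85)
})

test_that("cluster composition recovers the exact hypergeometric tails", {
  asg <- setNames(rep(c(1, 2), each = 5), paste0("P", 1:10))
  resp <- setNames(rep(c("R", "NR"), each = 5), paste0("P", 1:10))
  ce <- clusterEnrichment(asg, resp)
  expect_equal(ce$p, rep(1 / 252, 2))
  one <- clusterEnrichment(setNames(rep(1, 10), paste0("P", 1:10)), resp)
  expect_equal(one$p, 1)
  expect_error(clusterEnrichment(asg, setNames(rep("R", 10),
                                               paste0("P", 1:10))),
               "binary")
})

test_that("two-cluster accuracy uses the better label mapping", {
  asg <- setNames(rep(c("c1", "c2"), c(22, 16)), sprintf("P%02d", 1:38))
  resp <- setNames(c(rep("R", 16), rep("NR", 6), rep("R", 4),
                     rep("NR", 12)), sprintf("P%02d", 1:38))
  ca <- clusterAccuracy(asg, resp)
  expect_equal(ca$accuracy, 28 / 38)
  expect_equal(round(ca$accuracy, 2), 0.74)
  # swapping cluster names changes nothing
  swapped <- setNames(ifelse(asg == "c1", "c2", "c1"), names(asg))
  expect_equal(clusterAccuracy(swapped, resp)$accuracy, 28 / 38)
  perfect <- clusterAccuracy(setNames(resp, names(resp)), resp)
  expect_equal(perfect$accuracy, 1)
  set.seed(23)
  for (i in 1:5) {
    a <- setNames(sample(1:2, 12, TRUE), paste0("P", 1:12))
    r <- setNames(sample(c("R", "NR"), 12, TRUE), paste0("P", 1:12))
    if (length(unique(a)) == 2 && length(unique(r)) == 2)
      expect_gte(clusterAccuracy(a, r)$accuracy, 0.5)
  }
})

test_that("Mann-Whitney comparisons match exact enumeration on small groups", {
  vars <- matrix(c(1, 2, 3, 4, 5, 6,
                   2, 2, 2, 2, 2, 2), ncol = 2,
                 dimnames = list(paste0("P", 1:6), c("sep", "flat")))
  asg <- setNames(rep(c(1, 2), each = 3), paste0("P", 1:6))
  res <- compareClusters(vars, asg)
  expect_equal(res$p[res$variable == "sep"], 0.1)
  expect_equal(res$p[res$variable == "sep"], mwOracle(1:3, 4:6))
  expect_equal(res$p[res$variable == "flat"], 1)
  expect_true(res$U[res$variable == "sep"] %in% c(0, 9))
  expect_error(compareClusters(vars, setNames(c(1, 1, 1, 1, 1, 2),
                                              paste0("P", 1:6))),
               "at least 2")
})

test_that("a 1.5-SD shift is detected by the cluster comparison", {
  set.seed(24)
  hits <- replicate(50, {
    v <- matrix(c(rnorm(19), rnorm(19, mean = 1.5)), ncol = 1,
                dimnames = list(paste0("P", 1:38), "v"))
    asg <- setNames(rep(1:2, each = 19), paste0("P", 1:38))
    compareClusters(v, asg)$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("baseline balance chooses Fisher or Wilcoxon appropriately", {
  clin <- data.frame(
    patient_id = paste0("P", 1:20),
    age = c(rnorm(10, 60), rnorm(10, 61)),
    sex = rep(c("M", "F"), 10),
    stringsAsFactors = FALSE)
  asg <- setNames(rep(1:2, each = 10), paste0("P", 1:20))
  bb <- baselineBalance(clin, asg, covariates = c("age", "sex"))
  expect_equal(bb$test, c("wilcoxon", "fisher"))
  expect_equal(bb$p[bb$covariate == "sex"], 1)
  # 2x2 table (8,2 / 2,8) against the enumeration oracle
  clin2 <- data.frame(patient_id = paste0("P", 1:20),
                      grp = rep(c("x", "y"), c(10, 10))[c(1:8, 11:12,
                                                          9:10, 13:20)])
  bb2 <- baselineBalance(clin2, asg, covariates = "grp")
  expect_equal(bb2$p, fisherOracle(8, 2, 2, 8), tolerance = 1e-9)
})
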