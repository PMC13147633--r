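test_that("Fisher z-transform is atanh with domain checks", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.76159), 1.0000, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_error(fisherZ(1), "< 1")
  expect_error(fisherZ(-1.2), "< 1")
})

test_that("differential z-score follows the two-group Fisher formula", {
  expect_equal(differentialZ(0.5, 0.5, 20, 18), 0)
  expect_equal(differentialZ(0.9, 0, 20, 18), 4.155925, tolerance = 1e-5)
  expect_equal(differentialZ(0.7, 0.2, 25, 19),
               -differentialZ(0.2, 0.7, 19, 25))
  expect_error(differentialZ(0.5, 0.1, 3, 18), "exceed 3")
  # variance inflation option rescales by sqrt(1.06)
  expect_equal(differentialZ(0.9, 0, 20, 18, variance_inflation = 1.06),
               4.155925 / sqrt(1.06), tolerance = 1e-5)
})

test_that("identical groups give identical co-expression nets and empty DCN", {
  set.seed(11)
  base <- matrix(rnorm(12 * 15), 12, 15,
                 dimnames = list(sprintf("g%02d", 1:12),
                                 sprintf("s%02d", 1:15)))
  expr <- cbind(base, base)
  colnames(expr) <- sprintf("s%02d", 1:30)
  groups <- rep(c("A", "B"), each = 15)
  nets <- buildCoexpressionNetworks(expr, groups, rho_min = 0.5)
  expect_equal(networkEdges(nets$A), networkEdges(nets$B))
  expect_equal(nets$A@params$rho_min, 0.5)
  expect_equal(nets$A@params$q_max, 0.05)
  dcn <- buildDCN(expr, groups, rho_min = 0.5)
  expect_equal(nrow(networkEdges(dcn)), 0L)
})

test_that("the DCN is invariant to gene and sample order", {
  ch <- generateCohort(smallConfig(seed = 21))
  expr <- cohortExpression(ch)
  clin <- cohortClinical(ch)
  resp <- factor(setNames(clin$response, clin$patient_id),
                 levels = c("R", "NR"))
  d1 <- buildDCN(expr, resp[colnames(expr)])
  pg <- sample(nrow(expr)); ps <- sample(ncol(expr))
  d2 <- buildDCN(expr[pg, ps], resp[colnames(expr)[ps]])
  expect_equal(networkEdges(d1), networkEdges(d2))
  expect_setequal(networkNodes(d1), networkNodes(d2))
})

test_that("perfectly correlated pairs are excluded with a warning", {
  set.seed(12)
  x <- rnorm(16)
  expr <- rbind(g1 = c(x, rnorm(8)), g2 = c(2 * x, rnorm(8)),
                g3 = rnorm(24))
  colnames(expr) <- sprintf("s%02d", 1:24)
  groups <- rep(c("A", "B"), each = 12)
  expect_warning(dcn <- buildDCN(expr, groups, rho_min = 0.5),
                 "perfect correlation")
  ed <- networkEdges(dcn)
  expect_false(any(ed$gene_a == "g1" & ed$gene_b == "g2"))
})

test_that("hub selection takes the strict right tail with boundary ties", {
  set.seed(8)
  # random sparse graph plus a dense hub: compare against the rule applied
  # directly to the degree distribution
  nodes <- sprintf("n%02d", 1:40)
  edges <- t(utils::combn(nodes, 2))
  edges <- edges[runif(nrow(edges)) < 0.08 | edges[, 1] == "n01", ]
  net <- makeNet(nodes, edges)
  for (pct in c(75, 90, 95)) {
    hubs <- selectHubs(net, percentile = pct)
    deg <- networkSummary(net)$degree
    nz <- deg[deg >= 1]
    thr <- unname(quantile(nz, pct / 100))
    expected <- names(nz)[nz > thr]
    if (length(expected))
      expected <- names(nz)[nz >= min(nz[expected])]
    expect_setequal(hubs$genes, expected)
    expect_equal(hubs$degree_threshold, thr)
    expect_false(is.unsorted(rev(hubs$degree)))
  }
  # all-equal degrees: nothing strictly above the percentile
  clq <- twoCliques(4)
  expect_length(selectHubs(clq, 95)$genes, 0)
  empty <- makeNet(c("a", "b"), matrix(character(0), 0, 2))
  expect_error(selectHubs(empty), "empty")
})

test_that("hub selection on 100 distinct degrees returns the top five", {
  # simple independent check of the percentile semantics on a degree list
  deg <- 1:100
  thr <- unname(quantile(deg, 0.95))
  expect_equal(sum(deg > thr), 5)
  expect_equal(deg[deg > thr], 96:100)
})

test_that("Louvain and modularity recover clique structure exactly", {
  net <- twoCliques(5)
  cm <- louvainCommunities(net, seed = 3)
  expect_equal(length(unique(cm$membership)), 2L)
  expect_equal(cm$modularity_Q, 0.5)
  split <- cm$membership
  expect_equal(modularityQ(net, split), 0.5)

  one <- makeNet(paste0("v", 1:5), t(utils::combn(paste0("v", 1:5), 2)))
  cm1 <- louvainCommunities(one, seed = 3)
  expect_equal(length(unique(cm1$membership)), 1L)
  expect_equal(cm1$modularity_Q, 0)
  expect_equal(modularityQ(one, setNames(rep(1, 5), paste0("v", 1:5))), 0)

  set.seed(9)
  rnd <- setNames(sample(1:2, 5, replace = TRUE), paste0("v", 1:5))
  expect_lte(modularityQ(one, rnd), 0)
  expect_error(modularityQ(one, rnd[1:3]), "missing")
})

test_that("Louvain is deterministic under a fixed seed", {
  ch <- generateCohort(smallConfig(seed = 5))
  clin <- cohortClinical(ch)
  resp <- setNames(clin$response, clin$patient_id)
  dcn <- buildDCN(cohortExpression(ch), resp[colnames(cohortExpression(ch))])
  c1 <- louvainCommunities(dcn, seed = 42)
  c2 <- louvainCommunities(dcn, seed = 42)
  expect_identical(c1, c2)
})

test_that("fully differential pairs are detected at the oracle-fixed rate", {
  # population Spearman ~0.785 vs 0 at n=20/18: exact-sampling MC puts
  # P(|Z|>2) near 0.82; assert the band around it
  set.seed(31)
  B <- 400
  hits <- replicate(B, {
    x <- rnorm(20); yA <- 0.8 * x + sqrt(1 - 0.64) * rnorm(20)
    zA <- atanh(cor(x, yA, method = "spearman"))
    zB <- atanh(cor(rnorm(18), rnorm(18), method = "spearman"))
    abs((zA - zB) / sqrt(1 / 17 + 1 / 15)) > 2
  })
  expect_gt(mean(hits), 0.75)
  expect_lt(mean(hits), 0.90)
})
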