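test_that("Spearman correlation is rank-based and handles ties by midranks", {
  set.seed(1)
  x <- rnorm(20)
  tab <- cbind(x = x, expx = exp(x), negx = -x)
  cr <- spearmanMatrix(tab)
  expect_equal(cr$rho["x", "expx"], 1)
  expect_lt(cr$pvalue["x", "expx"], 1e-12)
  expect_equal(cr$rho["x", "negx"], -1)

  tx <- c(1, 2, 2, 3); ty <- c(1, 2, 3, 4)
  crt <- spearmanMatrix(cbind(a = tx, b = ty))
  expect_equal(crt$rho["a", "b"], cor(rank(tx), rank(ty)))
  expect_equal(crt$rho["a", "b"], 0.9486833, tolerance = 1e-6)
})

test_that("constant variables are flagged, not dropped, and small n errors", {
  tab <- cbind(a = c(1, 2, 3, 4, 5), b = rep(2, 5), c = c(5, 3, 1, 4, 2))
  cr <- spearmanMatrix(tab)
  expect_identical(cr$constant_variables, "b")
  expect_true(all(is.na(cr$rho["b", ])))
  expect_false(is.na(cr$rho["a", "c"]))
  expect_error(spearmanMatrix(tab[1:3, ]), "4 samples")
})

test_that("BH adjustment matches the step-up oracle and input checks hold", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(7)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, bhOracle(p))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("correlation networks keep only strong significant edges", {
  set.seed(2)
  x <- rnorm(30)
  tab <- cbind(v1 = x, v2 = x + 1, v3 = rnorm(30))
  net <- buildCorrelationNetwork(tab, rho_min = 0.55, q_max = 0.05)
  ed <- networkEdges(net)
  expect_true(any(ed$node_a == "v1" & ed$node_b == "v2" & ed$weight == 1))
  expect_true(all(abs(ed$weight) > 0.55))
  expect_true(all(ed$q < 0.05))
})

test_that("independent variables yield mostly empty networks at study thresholds", {
  # exact-sampling MC puts the empty-network rate near 0.92 (one of the
  # 465 null pairs slips past |rho| > 0.55 and the BH cut ~8% of the time)
  set.seed(3)
  emptyCount <- 0
  edgeTotal <- 0
  for (i in 1:100) {
    tab <- matrix(rnorm(38 * 31), 38, 31)
    net <- buildCorrelationNetwork(tab, rho_min = 0.55, q_max = 0.05)
    ne <- nrow(networkEdges(net))
    if (ne == 0) emptyCount <- emptyCount + 1
    edgeTotal <- edgeTotal + ne
  }
  expect_gte(emptyCount, 86)
  expect_lte(edgeTotal / 100, 0.5)       # far below one edge per network
})

test_that("network summaries count nodes, signs, degrees and components", {
  empty <- makeNet(paste0("v", 1:31), matrix(character(0), 0, 2))
  s <- networkSummary(empty)
  expect_equal(s[c("n_nodes", "n_edges", "n_components")],
               list(n_nodes = 31L, n_edges = 0L, n_components = 31L))

  tri <- makeNet(c("a", "b", "c"),
                 rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                 weights = c(0.9, 0.8, -0.7))
  s <- networkSummary(tri)
  expect_equal(s$n_edges, 3L)
  expect_equal(s$n_positive, 2L)
  expect_equal(s$n_negative, 1L)
  expect_equal(unname(s$degree), c(2, 2, 2))
  expect_equal(s$n_components, 1L)
  expect_equal(sum(s$degree), 2 * s$n_edges)

  two <- makeNet(c("a", "b", "c", "d"), rbind(c("a", "b"), c("c", "d")))
  expect_equal(networkSummary(two)$n_components, 2L)
})

test_that("edge sets are invariant to sample reordering", {
  set.seed(4)
  tab <- matrix(rnorm(25 * 8), 25, 8,
                dimnames = list(NULL, paste0("v", 1:8)))
  tab[, 2] <- tab[, 1] * 2 + rnorm(25, sd = 0.1)
  n1 <- buildCorrelationNetwork(tab, 0.5, 0.1)
  n2 <- buildCorrelationNetwork(tab[sample(25), ], 0.5, 0.1)
  expect_equal(networkEdges(n1)[, c("node_a", "node_b")],
               networkEdges(n2)[, c("node_a", "node_b")])
})

test_that("cross-correlation agrees with the square form and checks samples", {
  set.seed(5)
  a <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(paste0("s", 1:20), paste0("x", 1:3)))
  cc <- crossCorrelation(a, a)
  expect_equal(unname(diag(cc$rho)), rep(1, 3))
  sq <- spearmanMatrix(a)
  expect_equal(cc$rho, sq$rho)
  onecol <- crossCorrelation(a[, 1, drop = FALSE], a[, 2, drop = FALSE])
  expect_equal(onecol$rho[1, 1], sq$rho["x1", "x2"])
  b <- a
  rownames(b)[3] <- "zzz"
  expect_error(crossCorrelation(a, b), "zzz")
})

test_that("under independence few cross-correlation pairs pass the FDR cut", {
  set.seed(6)
  hits <- replicate(30, {
    a <- matrix(rnorm(38 * 10), 38, 10)
    b <- matrix(rnorm(38 * 8), 38, 8)
    mean(crossCorrelation(a, b)$qvalue < 0.05)
  })
  expect_lte(mean(hits), 0.05)
})

test_that("edge lists and GraphML exports round-trip through igraph", {
  net <- twoCliques(3)
  f1 <- tempfile(fileext = ".tsv")
  writeEdgeList(net, f1)
  ed <- read.delim(f1)
  expect_equal(nrow(ed), nrow(networkEdges(net)))
  f2 <- tempfile(fileext = ".graphml")
  writeGraphML(net, f2)
  g <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::gorder(g), 6)
  expect_equal(igraph::gsize(g), nrow(networkEdges(net)))
})
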