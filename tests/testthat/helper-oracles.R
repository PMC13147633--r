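# brute-force oracles and small fixtures shared across test files

# step-up BH by direct definition
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# hypergeometric upper tail by direct summation of binomial coefficients
hyperOracle <- function(k, K, n, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# two-sided Mann-Whitney p by enumerating all rank splits (no ties)
mwOracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  Uobs <- sum(outer(x, y, ">"))
  n <- length(pooled)
  splits <- utils::combn(n, n1)
  Us <- apply(splits, 2, function(idx) {
    sum(outer(pooled[idx], pooled[-idx], ">"))
  })
  mu <- n1 * (n - n1) / 2
  mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9)
}

# two-sided Fisher exact p for a 2x2 table by enumerating fixed margins
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  av <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(av, c1, n - c1, r1)
  pobs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# adjusted Rand index by explicit pair counting
ariOracle <- function(a, b) {
  n <- length(a)
  sameA <- outer(a, a, "==")[upper.tri(diag(n))]
  sameB <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(sameA & sameB); n00 <- sum(!sameA & !sameB)
  n10 <- sum(sameA & !sameB); n01 <- sum(!sameA & sameB)
  np <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / np
  maxidx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxidx == expected) return(if (n11 == maxidx) 1 else 0)
  (n11 - expected) / (maxidx - expected)
}

# reduced cohort geometry so pipeline-level tests stay fast
smallConfig <- function(seed = 1L, ...) {
  cohortConfig(n_patients_gep = 30, n_patients_common = 26,
               n_responders_common = 13, n_responders_gep = 15,
               n_genes = 80, n_immune_vars = 15, n_planted_hubs = 8,
               n_backbone_genes = 72, seed = seed, ...)
}

# build a CorrelationNetwork from an explicit edge list (weights default 1)
makeNet <- function(nodes, edges, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  ed <- data.frame(node_a = as.character(edges[, 1]),
                   node_b = as.character(edges[, 2]),
                   weight = weights, q = rep(0, nrow(edges)),
                   stringsAsFactors = FALSE)
  new("CorrelationNetwork", nodes = nodes, edges = ed,
      params = list(rho_min = 0, q_max = 1, n_samples = NA))
}

# union of two disjoint k-cliques as a network fixture
twoCliques <- function(k = 5) {
  nodes <- c(paste0("a", seq_len(k)), paste0("b", seq_len(k)))
  e1 <- t(utils::combn(paste0("a", seq_len(k)), 2))
  e2 <- t(utils::combn(paste0("b", seq_len(k)), 2))
  makeNet(nodes, rbind(e1, e2))
}

# block-diagonal similarity matrix with optional off-block noise
blockMatrix <- function(sizes, within = 1, noise = 0) {
  n <- sum(sizes)
  W <- matrix(noise, n, n)
  start <- cumsum(c(1, sizes))
  for (i in seq_along(sizes)) {
    idx <- start[i]:(start[i] + sizes[i] - 1)
    W[idx, idx] <- within
  }
  diag(W) <- 1
  dimnames(W) <- list(paste0("P", seq_len(n)), paste0("P", seq_len(n)))
  W
}
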