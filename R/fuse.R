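#' Patient affinity matrix from a feature table
#'
#' Builds the scaled-exponential similarity kernel used by Similarity
#' Network Fusion: features are standardised per variable (zero mean, unit
#' variance; constant variables dropped with a warning), pairwise Euclidean
#' distances are computed, and
#' \deqn{W(i,j) = \exp\left(-\frac{d^2(i,j)}{\mu\,\varepsilon_{ij}}\right)}
#' with \eqn{\varepsilon_{ij} = (\bar d_i + \bar d_j + d(i,j))/3}, where
#' \eqn{\bar d_i} is the mean distance of patient i to its K nearest
#' neighbours.
#'
#' @param features numeric matrix/data.frame, patients in rows (with ids as
#'   row names), variables in columns.
#' @param K neighbourhood size (capped at N - 1).
#' @param mu kernel bandwidth multiplier.
#' @param standardize z-score each variable first (default TRUE).
#' @return list: \code{W} (N x N symmetric affinity, unit diagonal),
#'   \code{patient_ids}, \code{params}.
#' @export
affinityMatrix <- function(features, K = 20, mu = 0.5, standardize = TRUE) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  stopIfNot(nrow(x) >= 3, "at least 3 patients are required (got %d)", nrow(x))
  stopIfNot(!anyNA(x), "features contain missing values")
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping %d constant feature(s)", sum(sds == 0)))
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    stopIfNot(ncol(x) > 0, "no non-constant features left")
    x <- scale(x)
  }
  N <- nrow(x)
  K <- min(K, N - 1)
  d2 <- as.matrix(stats::dist(x))^2
  # mean squared distance to the K nearest neighbours (excluding self);
  # the bandwidth term is kept on the squared-distance scale so the kernel
  # argument is scale-free, as in the reference SNF implementation
  dbar <- apply(d2, 1, function(row) {
    others <- sort(row)[-1]          # drop the self 0
    mean(others[seq_len(K)])
  })
  eps <- (outer(dbar, dbar, "+") + d2) / 3
  eps[eps == 0] <- .Machine$double.eps
  W <- exp(-d2 / (mu * eps))
  W <- (W + t(W)) / 2
  dimnames(W) <- list(rownames(x), rownames(x))
  list(W = W, patient_ids = rownames(x),
       params = list(K = K, mu = mu, standardized = standardize))
}

# full-kernel transition matrix: off-diagonal rows sum to 1/2, diagonal 1/2
snfNormalize <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# local K-NN kernel: row-normalised over each patient's K nearest neighbours
snfLocal <- function(W, K) {
  N <- nrow(W)
  K <- min(K, N - 1)
  S <- matrix(0, N, N, dimnames = dimnames(W))
  for (i in seq_len(N)) {
    w <- W[i, ]
    nb <- order(w, decreasing = TRUE)
    nb <- setdiff(nb, i)[seq_len(K)]
    S[i, c(i, nb)] <- w[c(i, nb)] / sum(w[c(i, nb)])
  }
  S
}

#' Similarity Network Fusion
#'
#' Iterative nonlinear cross-diffusion of two or more patient affinity
#' layers. Each layer is normalised into a full transition kernel P (rows
#' sum to one with half the mass on the diagonal) and a sparse local K-NN
#' kernel S; each iteration updates
#' \eqn{P_v \leftarrow S_v \cdot \mathrm{mean}_{u \ne v}(P_u) \cdot S_v^T}
#' followed by renormalisation, for \code{t} iterations. The output is the
#' symmetrised average of the final layer kernels.
#'
#' @param affinities list of affinity layers (outputs of
#'   \code{\link{affinityMatrix}}, or bare matrices with patient dimnames),
#'   identical patient sets and order. Optionally named.
#' @param K local-neighbourhood size.
#' @param t diffusion iterations.
#' @return a \code{\link{FusedNetwork-class}} object.
#' @export
snfFuse <- function(affinities, K = 20, t = 20) {
  Ws <- lapply(affinities, function(a) if (is.list(a)) a$W else a)
  stopIfNot(length(Ws) >= 1, "at least one affinity layer is required")
  ids <- rownames(Ws[[1]])
  for (W in Ws) {
    stopIfNot(identical(rownames(W), ids) && identical(colnames(W), ids),
              "affinity layers must share one patient set and order")
  }
  if (length(Ws) == 1)
    warning("single layer supplied: returning its diffused kernel")
  nm <- names(Ws)
  if (is.null(nm)) nm <- paste0("layer", seq_along(Ws))

  Ps <- lapply(Ws, snfNormalize)
  Ss <- lapply(Ws, snfLocal, K = K)
  maxDev <- 0
  for (it in seq_len(t)) {
    newPs <- vector("list", length(Ps))
    for (v in seq_along(Ps)) {
      others <- Ps[-v]
      meanP <- Reduce(`+`, others) / max(length(others), 1)
      if (length(Ps) == 1) meanP <- Ps[[1]]
      P <- Ss[[v]] %*% meanP %*% t(Ss[[v]])
      P <- snfNormalize((P + t(P)) / 2)
      maxDev <- max(maxDev, max(abs(rowSums(P) - 1)))
      newPs[[v]] <- P
    }
    Ps <- newPs
  }
  fused <- Reduce(`+`, Ps) / length(Ps)
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(ids, ids)
  new("FusedNetwork", fused = fused, layers = nm, iterations = as.integer(t),
      params = list(K = K, t = t, max_rowsum_dev = maxDev))
}

# symmetric normalized Laplacian eigen-decomposition of a similarity matrix
normalizedLaplacianEigen <- function(W) {
  stopIfNot(isSymmetric(unname(W), tol = 1e-8), "W must be symmetric")
  stopIfNot(all(W >= 0), "W must be nonnegative")
  d <- rowSums(W)
  d[d == 0] <- .Machine$double.eps
  Dhalf <- 1 / sqrt(d)
  L <- diag(nrow(W)) - (Dhalf * W) %*% diag(Dhalf)
  L <- (L + t(L)) / 2
  eigen(L, symmetric = TRUE)
}

#' Eigengap selection of the cluster count
#'
#' Eigenvalues of the symmetric normalised Laplacian are sorted ascending;
#' the returned k maximises the gap \eqn{\lambda_{k+1} - \lambda_k} over
#' \code{k_min..k_max}.
#'
#' @param W symmetric nonnegative similarity matrix.
#' @param k_min,k_max search range (defaults 2 and 5).
#' @return list: \code{k}, and \code{eigengap_values} (named gap per
#'   candidate k).
#' @export
eigengapK <- function(W, k_min = 2, k_max = 5) {
  if (is(W, "FusedNetwork")) W <- fusedMatrix(W)
  ev <- rev(normalizedLaplacianEigen(W)$values)  # ascending
  k_max <- min(k_max, length(ev) - 1)
  ks <- k_min:k_max
  gaps <- stats::setNames(ev[ks + 1] - ev[ks], ks)
  ncomp <- sum(ev < 1e-10)
  if (ncomp > k_max)
    warning(sprintf("graph has %d components, more than k_max = %d", ncomp, k_max))
  list(k = ks[which.max(gaps)], eigengap_values = gaps)
}

# k-means++ initial centres under the current RNG stream
kmeansPPCenters <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(0)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Spectral clustering of a similarity matrix
#'
#' Embeds patients in the eigenvectors of the k smallest eigenvalues of the
#' symmetric normalised Laplacian, row-normalises the embedding, and runs
#' k-means with k-means++ initialisation over seeded restarts, keeping the
#' solution with the lowest within-cluster sum of squares (ties broken by
#' lexicographically smallest label vector). Deterministic under a fixed
#' seed.
#'
#' @param W symmetric nonnegative similarity matrix (or a
#'   \code{FusedNetwork}).
#' @param k number of clusters, \code{2 <= k < N}.
#' @param seed RNG seed.
#' @param restarts k-means restarts (default 50).
#' @return list: \code{labels} (named integer vector, clusters numbered by
#'   first appearance), \code{k}, \code{inertia}.
#' @export
spectralCluster <- function(W, k, seed = 1L, restarts = 50) {
  if (is(W, "FusedNetwork")) W <- fusedMatrix(W)
  N <- nrow(W)
  stopIfNot(k >= 2 && k < N, "need 2 <= k < N (k = %s, N = %d)", k, N)
  eg <- normalizedLaplacianEigen(W)
  U <- eg$vectors[, N - seq_len(k) + 1, drop = FALSE]  # smallest k eigenvalues
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(restarts)) {
      ctr <- kmeansPPCenters(U, k)
      km <- suppressWarnings(
        stats::kmeans(U, centers = ctr, iter.max = 100, algorithm = "Lloyd"))
      cand <- list(labels = km$cluster, inertia = km$tot.withinss)
      if (is.null(best) || cand$inertia < best$inertia - 1e-12 ||
          (abs(cand$inertia - best$inertia) <= 1e-12 &&
           paste(cand$labels, collapse = ",") <
           paste(best$labels, collapse = ","))) {
        best <- cand
      }
    }
  })
  lab <- as.integer(factor(best$labels, levels = unique(best$labels)))
  names(lab) <- rownames(W)
  list(labels = lab, k = k, inertia = best$inertia)
}
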