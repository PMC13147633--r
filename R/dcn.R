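#' Fisher z-transformation of a correlation coefficient
#'
#' \code{atanh(rho)}; variance-stabilising for correlation coefficients,
#' with approximate variance \eqn{1/(n-3)} for bivariate-normal data.
#'
#' @param rho correlation coefficient(s), strictly inside (-1, 1).
#' @return transformed value(s).
#' @export
fisherZ <- function(rho) {
  stopIfNot(all(is.finite(rho)) && all(abs(rho) < 1),
            "|rho| must be < 1 (clip or exclude perfect correlations)")
  atanh(rho)
}

#' Differential correlation z-score
#'
#' Tests whether a correlation differs between two conditions A and B:
#' \deqn{Z = \frac{z_A - z_B}{\sqrt{1/(n_A-3) + 1/(n_B-3)}}}
#' with \eqn{z_x = \mathrm{atanh}(\rho_x)}. The \eqn{1/(n-3)} variance of
#' the Fisher transform is used even when the input correlations are
#' Spearman, mirroring common differential-correlation practice; setting
#' \code{variance_inflation = 1.06} applies the Fieller-Hartley-Pearson
#' correction for rank correlations.
#'
#' @param rho_A,rho_B correlations in the two conditions (|rho| < 1).
#' @param n_A,n_B group sample sizes, both > 3.
#' @param variance_inflation multiplier on the 1/(n-3) variances (default 1).
#' @return the z-score Z (vectorised over the rho arguments).
#' @export
differentialZ <- function(rho_A, rho_B, n_A, n_B, variance_inflation = 1) {
  stopIfNot(n_A > 3 && n_B > 3, "both group sizes must exceed 3")
  (fisherZ(rho_A) - fisherZ(rho_B)) /
    sqrt(variance_inflation * (1 / (n_A - 3) + 1 / (n_B - 3)))
}

# split an expression matrix (genes x samples) by a two-level group factor;
# factor level order (or "R" before "NR", else first appearance) fixes
# which group is condition A
splitByGroup <- function(expr, groups) {
  stopIfNot(!is.null(colnames(expr)), "expression matrix must have sample ids")
  stopIfNot(length(groups) == ncol(expr),
            "groups must have one label per sample")
  lev <- if (is.factor(groups)) levels(droplevels(groups))
         else unique(as.character(groups))
  if (setequal(lev, c("R", "NR"))) lev <- c("R", "NR")
  groups <- as.character(groups)
  stopIfNot(length(lev) == 2, "exactly two groups are required (got %d)",
            length(lev))
  lapply(stats::setNames(lev, lev), function(g) expr[, groups == g, drop = FALSE])
}

#' Group-wise co-expression networks
#'
#' Builds one thresholded Spearman co-expression network per response
#' group from a genes x samples expression matrix, at the gene-panel
#' thresholds (|rho| > 0.7, FDR < 0.05 by default).
#'
#' @param expr numeric matrix, genes in rows, samples in columns.
#' @param groups two-level vector of per-sample group labels; the first
#'   level encountered is condition A.
#' @param rho_min,q_max thresholds passed to
#'   \code{\link{buildCorrelationNetwork}}.
#' @return named list of two \code{CorrelationNetwork} objects.
#' @export
buildCoexpressionNetworks <- function(expr, groups, rho_min = 0.7,
                                      q_max = 0.05) {
  parts <- splitByGroup(expr, groups)
  stopIfNot(all(vapply(parts, ncol, 1L) > 3),
            "each group needs more than 3 samples")
  lapply(names(parts), function(g) {
    buildCorrelationNetwork(t(parts[[g]]), rho_min = rho_min, q_max = q_max,
                            group = g)
  }) |> stats::setNames(names(parts))
}

#' Differential co-expression network
#'
#' For every candidate gene pair, computes the Fisher z-score for the
#' difference between the group A and group B Spearman correlations and
#' retains pairs with \eqn{|Z| >} \code{z_min}. Positive edges mark pairs
#' more strongly co-expressed in group A. By default the candidate set is
#' the union of the edge sets of the two group co-expression networks
#' (the group networks are built first, then tested); \code{pair_universe
#' = "all_pairs"} tests every gene pair. Pairs with a perfect sample
#' correlation in either group are excluded with a warning, since the
#' Fisher transform is undefined there.
#'
#' @inheritParams buildCoexpressionNetworks
#' @param z_min |Z| retention threshold (default 2).
#' @param pair_universe \code{"union_of_networks"} or \code{"all_pairs"}.
#' @param variance_inflation passed to \code{\link{differentialZ}}.
#' @return a \code{\link{DifferentialNetwork-class}} object; condition A is
#'   the first group level.
#' @export
buildDCN <- function(expr, groups, z_min = 2,
                     pair_universe = c("union_of_networks", "all_pairs"),
                     rho_min = 0.7, q_max = 0.05, variance_inflation = 1) {
  pair_universe <- match.arg(pair_universe)
  parts <- splitByGroup(expr, groups)
  nA <- ncol(parts[[1]]); nB <- ncol(parts[[2]])
  stopIfNot(nA > 3 && nB > 3, "each group needs more than 3 samples")
  genes <- rownames(expr)
  stopIfNot(!is.null(genes) && !anyDuplicated(genes),
            "expression matrix needs unique gene ids as row names")

  crA <- spearmanMatrix(t(parts[[1]]))
  crB <- spearmanMatrix(t(parts[[2]]))

  if (pair_universe == "union_of_networks") {
    netA <- buildCorrelationNetwork(t(parts[[1]]), rho_min, q_max,
                                    group = names(parts)[1])
    netB <- buildCorrelationNetwork(t(parts[[2]]), rho_min, q_max,
                                    group = names(parts)[2])
    pairKey <- function(net) {
      ed <- networkEdges(net)
      if (!nrow(ed)) return(character(0))
      paste(pmin(ed$node_a, ed$node_b), pmax(ed$node_a, ed$node_b), sep = "\r")
    }
    keys <- union(pairKey(netA), pairKey(netB))
    if (!length(keys)) {
      pairs <- matrix(character(0), 0, 2)
    } else {
      pairs <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    }
  } else {
    idx <- which(upper.tri(crA$rho), arr.ind = TRUE)
    pairs <- cbind(genes[idx[, 1]], genes[idx[, 2]])
  }

  if (nrow(pairs)) {
    i <- match(pairs[, 1], genes); j <- match(pairs[, 2], genes)
    rA <- crA$rho[cbind(i, j)]
    rB <- crB$rho[cbind(i, j)]
    ok <- !is.na(rA) & !is.na(rB)
    perfect <- ok & (abs(rA) >= 1 - 1e-12 | abs(rB) >= 1 - 1e-12)
    if (any(perfect))
      warning(sprintf("%d pair(s) with perfect correlation excluded from the differential test", sum(perfect)))
    ok <- ok & !perfect
    Z <- rep(NA_real_, length(rA))
    Z[ok] <- differentialZ(rA[ok], rB[ok], nA, nB, variance_inflation)
    keep <- ok & abs(Z) > z_min
    ed <- data.frame(
      gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
      rho_A = rA[keep], rho_B = rB[keep],
      z_A = atanh(rA[keep]), z_B = atanh(rB[keep]),
      n_A = rep(nA, sum(keep)), n_B = rep(nB, sum(keep)),
      Z = Z[keep], stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(gene_a = character(0), gene_b = character(0),
                     rho_A = numeric(0), rho_B = numeric(0),
                     z_A = numeric(0), z_B = numeric(0),
                     n_A = integer(0), n_B = integer(0), Z = numeric(0))
  }
  ord <- order(ed$gene_a, ed$gene_b)
  ed <- ed[ord, , drop = FALSE]
  rownames(ed) <- NULL
  new("DifferentialNetwork", nodes = genes, edges = ed, zMin = z_min,
      params = list(group_A = names(parts)[1], group_B = names(parts)[2],
                    n_A = nA, n_B = nB, pair_universe = pair_universe,
                    rho_min = rho_min, q_max = q_max,
                    variance_inflation = variance_inflation))
}

#' Select hub genes from the degree distribution
#'
#' The degree threshold is the requested percentile (linear interpolation)
#' of the degree distribution over nodes with degree >= 1. Hubs are the
#' nodes with degree strictly greater than the threshold, plus all nodes
#' tied at the smallest degree among those included.
#'
#' @param net a \code{DifferentialNetwork} (or \code{CorrelationNetwork}).
#' @param percentile percentile of the nonzero-degree distribution
#'   (default 95).
#' @return list: \code{genes} (hub ids sorted by decreasing degree),
#'   \code{degree} (named degrees of the hubs), \code{percentile_used},
#'   \code{degree_threshold}.
#' @export
selectHubs <- function(net, percentile = 95) {
  ed <- networkEdges(net)
  stopIfNot(nrow(ed) > 0, "cannot select hubs from an empty network")
  deg <- networkSummary(net)$degree
  nz <- deg[deg >= 1]
  thr <- as.numeric(stats::quantile(nz, percentile / 100, type = 7))
  hubs <- names(nz)[nz > thr]
  if (length(hubs)) {
    minDeg <- min(nz[hubs])
    hubs <- names(nz)[nz >= minDeg]
  }
  hubs <- hubs[order(-nz[hubs], hubs)]
  list(genes = hubs, degree = nz[hubs], percentile_used = percentile,
       degree_threshold = thr)
}

#' Louvain community detection
#'
#' Two-phase greedy modularity optimisation (local moves, then
#' aggregation) via igraph's Louvain implementation; deterministic under a
#' fixed seed. Edges are treated as unweighted by default; \code{weighted =
#' TRUE} uses |Z| (or |rho|) edge weights.
#'
#' @param net a network object.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed controlling tie-breaking order.
#' @param weighted use absolute edge weights.
#' @return list: \code{membership} (named node -> community id) and
#'   \code{modularity_Q}.
#' @export
louvainCommunities <- function(net, resolution = 1, seed = 1L,
                               weighted = FALSE) {
  g <- asIgraph(net, weighted = weighted)
  stopIfNot(length(networkEdges(net)[[1]]) >= 0 &&
              length(net@nodes) > 0, "empty network")
  cl <- withSeed(seed,
    igraph::cluster_louvain(g, weights = if (weighted) igraph::E(g)$weight,
                            resolution = resolution))
  mem <- stats::setNames(igraph::membership(cl), igraph::V(g)$name)
  list(membership = mem[net@nodes],
       modularity_Q = modularityQ(net, mem, weighted = weighted))
}

#' Newman modularity of a partition
#'
#' @param net a network object.
#' @param membership named vector assigning every node a community id.
#' @param weighted use absolute edge weights.
#' @return modularity Q.
#' @export
modularityQ <- function(net, membership, weighted = FALSE) {
  miss <- setdiff(net@nodes, names(membership))
  stopIfNot(length(miss) == 0, "membership missing for node(s): %s",
            paste(utils::head(miss, 5), collapse = ", "))
  g <- asIgraph(net, weighted = weighted)
  m <- membership[igraph::V(g)$name]
  igraph::modularity(g, as.integer(factor(m)),
                     weights = if (weighted) igraph::E(g)$weight)
}
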