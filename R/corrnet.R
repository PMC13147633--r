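#' Spearman correlation matrix with pairwise tests
#'
#' Computes all pairwise Spearman rank correlations for a samples x
#' variables table, with two-sided p-values from the t-approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom
#' and Benjamini-Hochberg q-values over the \eqn{V(V-1)/2} unordered pairs.
#' Midranks are used for ties. Variables that are constant across samples
#' have undefined correlations: their entries are \code{NA} and the
#' variable is reported in \code{constant_variables}, not dropped.
#'
#' The t-approximation is accurate for the sample sizes this package
#' targets (n of 18-44). For very small n an exact permutation p-value is
#' available via \code{method = "permutation"} (seeded, pairwise).
#'
#' @param table numeric matrix or data.frame, samples in rows, variables in
#'   columns (at least 4 samples).
#' @param method \code{"t"} (default) or \code{"permutation"}.
#' @param n_perm permutations when \code{method = "permutation"}.
#' @param seed RNG seed for the permutation method.
#' @return list with components \code{rho}, \code{pvalue}, \code{qvalue}
#'   (symmetric V x V matrices), \code{n_samples}, and
#'   \code{constant_variables}.
#' @export
spearmanMatrix <- function(table, method = c("t", "permutation"),
                           n_perm = 2000, seed = NULL) {
  method <- match.arg(method)
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  stopIfNot(nrow(x) >= 4, "at least 4 samples are required (got %d)", nrow(x))
  stopIfNot(!anyNA(x), "input table contains missing values")
  n <- nrow(x)
  v <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(v))
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  r <- apply(x, 2, rank)                      # midranks for ties
  rho <- suppressWarnings(stats::cor(r))       # Pearson on ranks = Spearman
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- ifelse(const, NA_real_, 1)

  if (method == "t") {
    rr <- pmin(pmax(rho, -1), 1)
    tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    p[abs(rr) >= 1 - 1e-12] <- 0
  } else {
    p <- matrix(NA_real_, v, v)
    withSeed(seed, {
      for (i in seq_len(v - 1)) for (j in (i + 1):v) {
        if (const[i] || const[j]) next
        obs <- abs(rho[i, j])
        perm <- replicate(n_perm,
          abs(stats::cor(r[, i], sample(r[, j]))))
        p[i, j] <- p[j, i] <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
      }
    })
  }
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho)

  ut <- upper.tri(p)
  q <- matrix(NA_real_, v, v, dimnames = dimnames(rho))
  pv <- p[ut]
  ok <- !is.na(pv)
  qv <- rep(NA_real_, length(pv))
  qv[ok] <- bhAdjust(pv[ok])
  q[ut] <- qv
  q[lower.tri(q)] <- t(q)[lower.tri(q)]

  list(rho = rho, pvalue = p, qvalue = q, n_samples = n,
       constant_variables = colnames(x)[const])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with enforced monotonicity; output
#' order matches input order. Thin validated wrapper over
#' \code{\link[stats]{p.adjust}}.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
  stopIfNot(is.numeric(pvalues), "p-values must be numeric")
  stopIfNot(all(pvalues >= 0 & pvalues <= 1, na.rm = FALSE) && !anyNA(pvalues),
            "all p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Build a thresholded Spearman correlation network
#'
#' An edge joins variables i and j iff \eqn{|\rho_{ij}| >} \code{rho_min}
#' and the BH q-value is below \code{q_max}; the edge weight is the signed
#' correlation. Constant variables stay in the node set as isolates.
#'
#' @inheritParams spearmanMatrix
#' @param rho_min absolute-correlation threshold in [0, 1).
#' @param q_max FDR threshold.
#' @param group,timepoint optional labels stored in the network metadata.
#' @return a \code{\link{CorrelationNetwork-class}} object.
#' @export
buildCorrelationNetwork <- function(table, rho_min = 0.55, q_max = 0.05,
                                    group = NULL, timepoint = NULL) {
  stopIfNot(rho_min >= 0 && rho_min < 1, "rho_min must lie in [0, 1)")
  cr <- spearmanMatrix(table)
  v <- ncol(cr$rho)
  nodes <- colnames(cr$rho)
  ut <- which(upper.tri(cr$rho), arr.ind = TRUE)
  keep <- !is.na(cr$rho[ut]) &
    abs(cr$rho[ut]) > rho_min & cr$qvalue[ut] < q_max
  ed <- data.frame(
    node_a = nodes[ut[keep, 1]],
    node_b = nodes[ut[keep, 2]],
    weight = cr$rho[ut][keep],
    q = cr$qvalue[ut][keep],
    stringsAsFactors = FALSE)
  new("CorrelationNetwork", nodes = nodes, edges = ed,
      params = list(rho_min = rho_min, q_max = q_max,
                    n_samples = cr$n_samples, group = group,
                    timepoint = timepoint,
                    constant_variables = cr$constant_variables))
}

#' Summary statistics of a correlation network
#'
#' @param net a \code{CorrelationNetwork} or \code{DifferentialNetwork}.
#' @return list: \code{n_nodes}, \code{n_edges}, \code{n_positive},
#'   \code{n_negative}, \code{degree} (named, every node), and
#'   \code{n_components}.
#' @export
networkSummary <- function(net) {
  ed <- networkEdges(net)
  w <- if (is(net, "CorrelationNetwork")) ed$weight else ed$Z
  g <- asIgraph(net)
  deg <- igraph::degree(g)
  list(n_nodes = length(net@nodes),
       n_edges = nrow(ed),
       n_positive = sum(w > 0),
       n_negative = sum(w < 0),
       degree = deg[net@nodes],
       n_components = igraph::components(g)$no)
}

#' Rectangular Spearman cross-correlation
#'
#' Spearman correlations between every variable of \code{table_a} and every
#' variable of \code{table_b} over the same sample set, with BH adjustment
#' across all A x B pairs.
#'
#' @param table_a,table_b numeric tables, samples in rows, with identical
#'   row names in identical order.
#' @return list with A x B matrices \code{rho}, \code{pvalue},
#'   \code{qvalue}, and \code{n_samples}.
#' @export
crossCorrelation <- function(table_a, table_b) {
  a <- as.matrix(table_a); b <- as.matrix(table_b)
  if (!is.null(rownames(a)) || !is.null(rownames(b))) {
    bad <- union(setdiff(rownames(a), rownames(b)),
                 setdiff(rownames(b), rownames(a)))
    stopIfNot(length(bad) == 0 && identical(rownames(a), rownames(b)),
              "sample sets differ or are misaligned: %s",
              paste(utils::head(bad, 10), collapse = ", "))
  }
  stopIfNot(nrow(a) == nrow(b), "tables must share the sample dimension")
  stopIfNot(nrow(a) >= 4, "at least 4 samples are required")
  n <- nrow(a)
  ra <- apply(a, 2, rank); rb <- apply(b, 2, rank)
  rho <- suppressWarnings(stats::cor(ra, rb))
  rr <- pmin(pmax(rho, -1), 1)
  tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(rr) >= 1 - 1e-12] <- 0
  q <- matrix(bhAdjust(as.vector(p)), nrow(p), ncol(p),
              dimnames = dimnames(p))
  list(rho = rho, pvalue = p, qvalue = q, n_samples = n)
}

#' Write a network edge list as TSV
#'
#' @param net a network object.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(net, path) {
  ed <- networkEdges(net)
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' Node and edge attributes (weights, group/timepoint metadata) are carried
#' into the GraphML file via igraph.
#'
#' @param net a network object.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGraphML <- function(net, path) {
  g <- asIgraph(net, weighted = TRUE)
  if (is(net, "DifferentialNetwork"))
    igraph::E(g)$sign <- ifelse(net@edges$Z > 0, "positive", "negative")
  p <- net@params
  for (nm in c("group", "timepoint"))
    if (!is.null(p[[nm]])) g <- igraph::set_graph_attr(g, nm, p[[nm]])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
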