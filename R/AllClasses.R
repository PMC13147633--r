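#' @import methods
NULL

#' Thresholded correlation network
#'
#' An undirected, node-labelled network whose edges are significant Spearman
#' correlations. Nodes with no significant partner (including variables that
#' were constant in the input) are retained as isolated nodes so that the
#' variable universe is stable across groups and timepoints.
#'
#' @slot nodes character vector of unique node identifiers, in input order.
#' @slot edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{weight} (signed correlation) and \code{q} (BH-adjusted p-value).
#' @slot params list of construction metadata: \code{rho_min}, \code{q_max},
#'   \code{n_samples}, and optional \code{group} / \code{timepoint} labels.
#' @exportClass CorrelationNetwork
setClass("CorrelationNetwork",
  slots = c(nodes = "character", edges = "data.frame", params = "list"))

setValidity("CorrelationNetwork", function(object) {
  ed <- object@edges
  need <- c("node_a", "node_b", "weight")
  if (!all(need %in% names(ed)))
    return("edges must have columns node_a, node_b, weight")
  if (anyDuplicated(object@nodes))
    return("node ids must be unique")
  if (nrow(ed)) {
    if (any(ed$node_a == ed$node_b)) return("self-loops are not allowed")
    if (!all(c(ed$node_a, ed$node_b) %in% object@nodes))
      return("edge endpoints must be listed in nodes")
    rm <- object@params$rho_min
    if (!is.null(rm) && any(abs(ed$weight) <= rm))
      return("every |weight| must exceed the correlation threshold")
  }
  TRUE
})

#' Differential co-expression network
#'
#' Gene pairs whose Spearman correlation differs between two sample groups
#' (A = responders, B = non-responders by convention), tested with the
#' Fisher z-statistic for a correlation difference. An edge is retained when
#' the absolute z-score exceeds \code{zMin}; positive edges mark pairs more
#' strongly co-expressed in group A.
#'
#' @slot nodes character vector of gene ids (the full panel universe).
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{rho_A}, \code{rho_B}, \code{z_A}, \code{z_B}, \code{n_A},
#'   \code{n_B}, \code{Z}.
#' @slot zMin numeric scalar, the |Z| retention threshold.
#' @slot params list: group labels, candidate-pair policy, thresholds used.
#' @exportClass DifferentialNetwork
setClass("DifferentialNetwork",
  slots = c(nodes = "character", edges = "data.frame", zMin = "numeric",
            params = "list"))

setValidity("DifferentialNetwork", function(object) {
  ed <- object@edges
  need <- c("gene_a", "gene_b", "rho_A", "rho_B", "z_A", "z_B",
            "n_A", "n_B", "Z")
  if (!all(need %in% names(ed)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(object@nodes)) return("gene ids must be unique")
  if (nrow(ed)) {
    if (any(ed$gene_a == ed$gene_b)) return("self-loops are not allowed")
    if (any(abs(ed$Z) <= object@zMin))
      return("every |Z| must exceed zMin")
    if (!all(c(ed$gene_a, ed$gene_b) %in% object@nodes))
      return("edge endpoints must be listed in nodes")
  }
  TRUE
})

#' Fused patient-similarity network
#'
#' The result of Similarity Network Fusion across two or more per-data-type
#' patient affinity layers: a symmetric, nonnegative similarity matrix over
#' a common patient set.
#'
#' @slot fused numeric N x N symmetric matrix, dimnames = patient ids.
#' @slot layers character vector naming the input layers.
#' @slot iterations integer, diffusion iterations run.
#' @slot params list: K, mu, t, and the maximum row-sum deviation observed
#'   after each renormalisation step (\code{max_rowsum_dev}).
#' @exportClass FusedNetwork
setClass("FusedNetwork",
  slots = c(fused = "matrix", layers = "character", iterations = "integer",
            params = "list"))

setValidity("FusedNetwork", function(object) {
  W <- object@fused
  if (nrow(W) != ncol(W)) return("fused matrix must be square")
  if (is.null(rownames(W)) || !identical(rownames(W), colnames(W)))
    return("fused matrix must carry identical row/column patient ids")
  if (any(!is.finite(W))) return("fused matrix must be finite")
  if (any(W < 0)) return("fused matrix must be nonnegative")
  if (max(abs(W - t(W))) > 1e-8) return("fused matrix must be symmetric")
  TRUE
})

#' Synthetic multi-layer cohort
#'
#' A generated cohort with the data structure the pipeline consumes: panel
#' gene expression (genes x samples, count scale), circulating immune
#' profiles at two timepoints (samples x variables, percentages), a clinical
#' table (response, overall survival, baseline covariates), and the ground
#' truth used to plant recoverable structure.
#'
#' @slot expression numeric matrix, genes in rows, samples in columns.
#' @slot immunePre,immunePost data.frame, common patients x immune subsets,
#'   values in [0, 100].
#' @slot clinical data.frame with one row per expression sample: patient_id,
#'   response, common (flag), time_months, event, age, sex, smoking,
#'   histology, pdl1, ecog.
#' @slot truth list: planted_hub_genes, planted_module_genes,
#'   planted_differential_pairs (two-column matrix), latent_cluster (named),
#'   true_log_hazard_ratio.
#' @slot config the \code{\link{cohortConfig}} used.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  slots = c(expression = "matrix", immunePre = "data.frame",
            immunePost = "data.frame", clinical = "data.frame",
            truth = "list", config = "list"))

setValidity("SyntheticCohort", function(object) {
  ex <- object@expression
  if (any(!is.finite(ex)) || any(ex < 0))
    return("expression must be finite and nonnegative (count scale)")
  for (nm in c("immunePre", "immunePost")) {
    im <- slot(object, nm)
    v <- unlist(im)
    if (length(v) && (any(!is.finite(v)) || any(v < 0) || any(v > 100)))
      return(sprintf("%s values must lie in [0, 100]", nm))
  }
  common <- object@clinical$patient_id[object@clinical$common]
  if (!all(common %in% colnames(ex)) ||
      !all(common %in% rownames(object@immunePre)) ||
      !all(common %in% rownames(object@immunePost)))
    return("every common patient must appear in all tables")
  hubs <- object@truth$planted_hub_genes
  if (!all(hubs %in% rownames(ex)))
    return("planted hubs must be members of the gene panel")
  pairs <- object@truth$planted_differential_pairs
  if (!is.null(pairs) && nrow(pairs) &&
      !all(pairs[, 1] %in% hubs | pairs[, 2] %in% hubs))
    return("every planted differential pair must touch a planted hub")
  TRUE
})

setMethod("show", "CorrelationNetwork", function(object) {
  s <- networkSummary(object)
  cat(sprintf("CorrelationNetwork: %d nodes, %d edges (%d+/%d-), %d components\n",
              s$n_nodes, s$n_edges, s$n_positive, s$n_negative,
              s$n_components))
  p <- object@params
  if (!is.null(p$rho_min))
    cat(sprintf("  thresholds: |rho| > %g, q < %g (n = %s)\n",
                p$rho_min, p$q_max, p$n_samples))
  if (!is.null(p$group))
    cat(sprintf("  group: %s%s\n", p$group,
                if (is.null(p$timepoint)) "" else paste0(" / ", p$timepoint)))
  invisible(NULL)
})

setMethod("show", "DifferentialNetwork", function(object) {
  ed <- object@edges
  cat(sprintf(
    "DifferentialNetwork: %d genes, %d edges (%d positive, %d negative), |Z| > %g\n",
    length(object@nodes), nrow(ed), sum(ed$Z > 0), sum(ed$Z < 0),
    object@zMin))
  invisible(NULL)
})

setMethod("show", "FusedNetwork", function(object) {
  cat(sprintf("FusedNetwork: %d patients, layers [%s], %d iterations\n",
              nrow(object@fused), paste(object@layers, collapse = ", "),
              object@iterations))
  invisible(NULL)
})

setMethod("show", "SyntheticCohort", function(object) {
  cl <- object@clinical
  cat(sprintf("SyntheticCohort: %d genes x %d samples; %d common patients (%d R / %d NR)\n",
              nrow(object@expression), ncol(object@expression),
              sum(cl$common),
              sum(cl$common & cl$response == "R"),
              sum(cl$common & cl$response == "NR")))
  invisible(NULL)
})

#' Accessors for network and cohort objects
#'
#' @param x a \code{CorrelationNetwork}, \code{DifferentialNetwork},
#'   \code{FusedNetwork} or \code{SyntheticCohort}.
#' @return \code{networkNodes}: character vector of node ids.
#'   \code{networkEdges}: the edge data.frame. \code{fusedMatrix}: the fused
#'   similarity matrix. \code{cohortTruth}: the ground-truth list.
#' @name accessors
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "CorrelationNetwork") || is(x, "DifferentialNetwork"))
  x@nodes
}

#' @rdname accessors
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "CorrelationNetwork") || is(x, "DifferentialNetwork"))
  x@edges
}

#' @rdname accessors
#' @export
fusedMatrix <- function(x) {
  stopifnot(is(x, "FusedNetwork"))
  x@fused
}

#' @rdname accessors
#' @export
cohortTruth <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@truth
}

#' @rdname accessors
#' @export
cohortExpression <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@expression
}

#' @rdname accessors
#' @export
cohortClinical <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@clinical
}

#' @rdname accessors
#' @param timepoint \code{"pre"} or \code{"post"} therapy.
#' @export
cohortImmune <- function(x, timepoint = c("pre", "post")) {
  stopifnot(is(x, "SyntheticCohort"))
  timepoint <- match.arg(timepoint)
  if (timepoint == "pre") x@immunePre else x@immunePost
}
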