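# internal helpers shared across modules

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. All exported stochastic entry points funnel through this.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# seed < 2^31 derived from a base seed and a stage/iteration tag
deriveSeed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

stopIfNot <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

# convert a network object to igraph, keeping isolated nodes
asIgraph <- function(net, weighted = FALSE) {
  if (is(net, "CorrelationNetwork")) {
    ed <- net@edges[, c("node_a", "node_b"), drop = FALSE]
    w <- net@edges$weight
  } else if (is(net, "DifferentialNetwork")) {
    ed <- net@edges[, c("gene_a", "gene_b"), drop = FALSE]
    w <- net@edges$Z
  } else stop("unsupported network class")
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(ed[[1]]), to = as.character(ed[[2]])),
    directed = FALSE,
    vertices = data.frame(name = net@nodes))
  if (weighted) igraph::E(g)$weight <- abs(w)
  g
}
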