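#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate genes
#' within a line are collapsed.
#'
#' @param path GMT file.
#' @return list with \code{sets} (named list of character vectors),
#'   \code{descriptions} (named character) and \code{source}.
#' @export
readGMT <- function(path) {
  stopIfNot(file.exists(path), "GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  stopIfNot(length(lines) > 0, "GMT file is empty: %s", path)
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d (fewer than 3 fields): %s",
                   i, path), call. = FALSE)
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  stopIfNot(!anyDuplicated(names(sets)), "duplicate set names in %s", path)
  list(sets = sets, descriptions = desc, source = path)
}

#' Write a GMT gene-set collection
#'
#' @param collection list as returned by \code{\link{readGMT}}, or a named
#'   list of gene vectors.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGMT <- function(collection, path) {
  sets <- if (!is.null(collection$sets)) collection$sets else collection
  desc <- collection$descriptions
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the
#' probability of observing at least \code{k} annotated genes in a draw of
#' \code{n} from a background of \code{N} containing \code{K} annotated
#' genes. Computed with \code{\link[stats]{phyper}} (exact tail in log
#' space internally). \code{strict = TRUE} gives \eqn{P(X > k)}.
#'
#' @param k observed overlap.
#' @param K annotated genes in the background.
#' @param n query size.
#' @param N background size.
#' @param strict use the strict-inequality convention.
#' @return upper-tail probability.
#' @export
hypergeomUpper <- function(k, K, n, N, strict = FALSE) {
  stopIfNot(all(c(k, K, n, N) >= 0) && k <= min(n, K) && K <= N && n <= N,
            "inconsistent counts: need 0 <= k <= min(n, K) and K, n <= N")
  stats::phyper(if (strict) k else k - 1, m = K, n = N - K, k = n,
                lower.tail = FALSE)
}

#' First-neighbour set of a hub
#'
#' The hub plus its first neighbours in the differential network,
#' restricted to edges of the requested sign (positive: stronger
#' co-expression in group A; negative: weaker).
#'
#' @param dcn a \code{DifferentialNetwork}.
#' @param hub gene id present in the network.
#' @param sign \code{"both"}, \code{"positive"} or \code{"negative"}.
#' @return character vector of gene ids (hub first).
#' @export
hubNeighborhood <- function(dcn, hub, sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  stopIfNot(hub %in% dcn@nodes, "unknown hub gene: %s", hub)
  ed <- networkEdges(dcn)
  if (sign == "positive") ed <- ed[ed$Z > 0, , drop = FALSE]
  if (sign == "negative") ed <- ed[ed$Z < 0, , drop = FALSE]
  nb <- c(ed$gene_b[ed$gene_a == hub], ed$gene_a[ed$gene_b == hub])
  unique(c(hub, nb))
}

#' Over-representation analysis against a restricted background
#'
#' Hypergeometric upper-tail test of each collection set against the query,
#' with every set first intersected with the background (here typically the
#' gene panel, not the whole transcriptome). Sets with fewer than
#' \code{min_set_size} background genes, or zero overlap with the query,
#' are excluded before BH adjustment. One BH family per call (i.e. per
#' query).
#'
#' @param query character vector of gene ids.
#' @param collection GMT collection (\code{\link{readGMT}} result or named
#'   list of gene vectors).
#' @param background character vector: the gene universe.
#' @param min_set_size minimum background-intersected set size (default 3).
#' @param strict strict-inequality tail convention (see
#'   \code{\link{hypergeomUpper}}).
#' @return data.frame with columns term, k, n, K, N, p, q, sorted by q then
#'   p.
#' @export
enrichTest <- function(query, collection, background, min_set_size = 3,
                       strict = FALSE) {
  sets <- if (!is.null(collection$sets)) collection$sets else collection
  background <- unique(background)
  query <- intersect(unique(query), background)
  stopIfNot(length(query) > 0,
            "query is empty after intersection with the background")
  N <- length(background); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    Kset <- intersect(sets[[nm]], background)
    K <- length(Kset)
    k <- length(intersect(query, Kset))
    if (K < min_set_size || k == 0) return(NULL)
    data.frame(term = nm, k = k, n = n, K = K, N = N,
               p = hypergeomUpper(k, K, n, N, strict = strict),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
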