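#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' from the pair-counting contingency table. Symmetric and invariant to
#' label permutation; 1 for identical partitions, about 0 for independent
#' ones.
#'
#' @param labels_a,labels_b label vectors over the same items (aligned, or
#'   both named).
#' @return the ARI.
#' @export
adjustedRandIndex <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    stopIfNot(setequal(names(labels_a), names(labels_b)),
              "partitions must cover the same items")
    labels_b <- labels_b[names(labels_a)]
  }
  stopIfNot(length(labels_a) == length(labels_b),
            "partitions must have equal length (%d vs %d)",
            length(labels_a), length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sumIJ <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expected <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(if (sumIJ == maxIdx) 1 else 0)
  (sumIJ - expected) / (maxIdx - expected)
}

# one full stratification fit: DCN -> hubs -> two-layer SNF -> spectral
# clustering, on the given patient subset. The workhorse shared by the
# pipeline, LOOCV and the percentile sensitivity analysis.
fitStratification <- function(expr, response, immune, params,
                              hub_percentile = NULL, seed = NULL,
                              dcn = NULL) {
  if (is.null(hub_percentile)) hub_percentile <- params$hub_percentile
  if (is.null(seed)) seed <- params$seed
  if (is.null(dcn))
    dcn <- buildDCN(expr, response[colnames(expr)], z_min = params$z_min,
                    pair_universe = params$pair_universe,
                    rho_min = params$gep_rho, q_max = params$q_max)
  hubs <- selectHubs(dcn, percentile = hub_percentile)
  commonIds <- rownames(immune)
  gepFeat <- t(log1p(expr[hubs$genes, commonIds, drop = FALSE]))
  affG <- affinityMatrix(gepFeat, K = params$snf_K, mu = params$snf_mu)
  affC <- affinityMatrix(as.matrix(immune), K = params$snf_K,
                         mu = params$snf_mu)
  fused <- snfFuse(list(GEP = affG, CIP = affC), K = params$snf_K,
                   t = params$snf_t)
  k <- if (!is.null(params$n_clusters)) params$n_clusters
       else eigengapK(fused, params$k_min, params$k_max)$k
  cl <- spectralCluster(fused, k = k, seed = seed,
                        restarts = params$restarts)
  list(dcn = dcn, hubs = hubs, affinities = list(GEP = affG, CIP = affC),
       fused = fused, k = k, labels = cl$labels)
}

#' Leave-one-out cross-validation of the stratification pipeline
#'
#' Each common patient is removed in turn and the entire process — DCN
#' construction, hub selection, two-layer SNF, spectral clustering (k = 2)
#' — is refit on the remaining N-1 patients. Per iteration the cluster
#' accuracy against clinical response and the log-rank p-value between the
#' two clusters are computed on the retained patients (the held-out
#' patient is not assigned a cluster). Iteration seeds are derived
#' deterministically from the base seed and the left-out patient id.
#'
#' @param cohort a \code{SyntheticCohort} (or list with elements
#'   \code{expression}, \code{immune}, \code{clinical}).
#' @param params pipeline parameters, see \code{\link{pipelineParams}}.
#' @return list: \code{per_iteration} data.frame (left_out_id, accuracy,
#'   logrank_p, failed), \code{mean_accuracy}, \code{sd_accuracy},
#'   \code{fraction_significant_logrank}.
#' @export
loocv <- function(cohort, params = pipelineParams()) {
  inp <- asPipelineInput(cohort)
  ids <- rownames(inp$immune)
  stopIfNot(length(ids) >= 10, "LOOCV needs at least 10 patients")
  params$n_clusters <- 2L
  rows <- lapply(ids, function(pid) {
    res <- tryCatch({
      keepG <- setdiff(colnames(inp$expression), pid)
      keepC <- setdiff(ids, pid)
      fit <- fitStratification(
        inp$expression[, keepG, drop = FALSE], inp$response,
        inp$immune[keepC, , drop = FALSE], params,
        seed = deriveSeed(params$seed, pid))
      acc <- clusterAccuracy(fit$labels, inp$response[keepC])$accuracy
      surv <- inp$clinical[match(keepC, inp$clinical$patient_id), ]
      lr <- logrankTest(surv$time_months, surv$event, fit$labels[keepC])
      data.frame(left_out_id = pid, accuracy = acc, logrank_p = lr$p,
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(left_out_id = pid, accuracy = NA_real_,
                 logrank_p = NA_real_, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    res
  })
  per <- do.call(rbind, rows)
  ok <- !per$failed
  list(per_iteration = per,
       mean_accuracy = mean(per$accuracy[ok]),
       sd_accuracy = stats::sd(per$accuracy[ok]),
       fraction_significant_logrank = mean(per$logrank_p[ok] < 0.05),
       n_failed = sum(per$failed))
}

#' Hub-percentile sensitivity analysis
#'
#' Reruns hub selection, the two-layer SNF and spectral clustering for a
#' grid of degree percentiles, reporting the hub count, the adjusted Rand
#' index against the reference partition (the 95th percentile by default)
#' and the cluster accuracy against response.
#'
#' @inheritParams loocv
#' @param percentiles degree percentiles to scan (default
#'   \code{c(75, 90, 95, 98, 99)}).
#' @param reference_percentile percentile defining the reference partition.
#' @return data.frame: percentile, n_hubs, ari_vs_reference, accuracy,
#'   failed.
#' @export
percentileSensitivity <- function(cohort, params = pipelineParams(),
                                  percentiles = c(75, 90, 95, 98, 99),
                                  reference_percentile = 95) {
  inp <- asPipelineInput(cohort)
  params$n_clusters <- 2L
  dcn <- buildDCN(inp$expression, inp$response[colnames(inp$expression)],
                  z_min = params$z_min,
                  pair_universe = params$pair_universe,
                  rho_min = params$gep_rho, q_max = params$q_max)
  fitAt <- function(p) {
    fitStratification(inp$expression, inp$response, inp$immune, params,
                      hub_percentile = p,
                      seed = deriveSeed(params$seed, paste0("pct", p)),
                      dcn = dcn)
  }
  ref <- fitAt(reference_percentile)
  rows <- lapply(percentiles, function(p) {
    out <- tryCatch({
      fit <- if (p == reference_percentile) ref else fitAt(p)
      data.frame(
        percentile = p, n_hubs = length(fit$hubs$genes),
        ari_vs_reference = adjustedRandIndex(fit$labels, ref$labels),
        accuracy = clusterAccuracy(
          fit$labels, inp$response[names(fit$labels)])$accuracy,
        failed = FALSE)
    }, error = function(e) {
      data.frame(percentile = p, n_hubs = 0L, ari_vs_reference = NA_real_,
                 accuracy = NA_real_, failed = TRUE)
    })
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
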