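#' Pipeline parameters
#'
#' Every published threshold of the analysis is a default here, not a
#' constant: immune-network correlation cutoff 0.55, co-expression cutoff
#' 0.7, FDR 0.05, differential z cutoff 2, hub degree percentile 95, SNF
#' neighbourhood 20 / bandwidth 0.5 / 20 iterations, eigengap search 2..5.
#'
#' @param cip_rho immune-network |rho| threshold.
#' @param gep_rho co-expression |rho| threshold.
#' @param q_max FDR threshold for both network families.
#' @param z_min differential-correlation |Z| threshold.
#' @param hub_percentile hub degree percentile.
#' @param snf_K,snf_mu,snf_t SNF neighbourhood size, kernel bandwidth and
#'   iteration count.
#' @param k_min,k_max eigengap search range.
#' @param n_clusters fixed cluster count; \code{NULL} selects by eigengap.
#' @param restarts k-means restarts in spectral clustering.
#' @param pair_universe DCN candidate-pair policy.
#' @param weighted_louvain use |Z| weights in community detection.
#' @param cip_timepoint immune timepoint feeding the CIP similarity layer.
#' @param seed base RNG seed.
#' @return named list of parameters.
#' @export
pipelineParams <- function(cip_rho = 0.55, gep_rho = 0.7, q_max = 0.05,
                           z_min = 2, hub_percentile = 95, snf_K = 20,
                           snf_mu = 0.5, snf_t = 20, k_min = 2, k_max = 5,
                           n_clusters = NULL, restarts = 50,
                           pair_universe = c("union_of_networks",
                                             "all_pairs"),
                           weighted_louvain = FALSE,
                           cip_timepoint = c("pre", "post"), seed = 1L) {
  stopIfNot(cip_rho >= 0 && cip_rho < 1 && gep_rho >= 0 && gep_rho < 1,
            "correlation thresholds must lie in [0, 1)")
  stopIfNot(q_max > 0 && q_max <= 1, "q_max must lie in (0, 1]")
  stopIfNot(z_min >= 0, "z_min must be nonnegative")
  stopIfNot(hub_percentile > 0 && hub_percentile < 100,
            "hub_percentile must lie in (0, 100)")
  params <- as.list(environment())
  params$pair_universe <- match.arg(pair_universe)
  params$cip_timepoint <- match.arg(cip_timepoint)
  params
}

# normalise a cohort-like object into the tables the pipeline consumes
asPipelineInput <- function(cohort, params = NULL) {
  tp <- if (!is.null(params)) params$cip_timepoint else "pre"
  if (is(cohort, "SyntheticCohort")) {
    clin <- cohortClinical(cohort)
    list(expression = cohortExpression(cohort),
         immune = cohortImmune(cohort, tp),
         immune_pre = cohortImmune(cohort, "pre"),
         immune_post = cohortImmune(cohort, "post"),
         clinical = clin,
         response = stats::setNames(clin$response, clin$patient_id))
  } else {
    stopIfNot(is.list(cohort) &&
                all(c("expression", "immune", "clinical") %in%
                      names(cohort)),
              "cohort must be a SyntheticCohort or a list with expression, immune and clinical")
    clin <- cohort$clinical
    list(expression = cohort$expression, immune = cohort$immune,
         immune_pre = cohort$immune, immune_post = cohort$immune_post,
         clinical = clin,
         response = stats::setNames(clin$response, clin$patient_id))
  }
}

#' Read a gene-expression matrix from TSV
#'
#' Expects gene ids in the first column and sample ids in the header.
#' Duplicate gene ids, missing cells and non-numeric cells are errors that
#' name the offending gene or cell.
#'
#' @param path TSV file.
#' @return numeric matrix, genes in rows.
#' @export
readExpression <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  stopIfNot(ncol(df) >= 2, "expression table needs gene ids plus samples")
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  stopIfNot(length(dup) == 0, "duplicate gene id(s): %s",
            paste(utils::head(dup, 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing cell(s): %s",
                 paste(sprintf("%s/%s", genes[bad[, 1]],
                               colnames(m)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
                       collapse = ", ")), call. = FALSE)
  }
  rownames(m) <- genes
  m
}

#' Read an immune-profile table from CSV
#'
#' @param path CSV with a \code{patient_id} column; remaining columns are
#'   immune-subset percentages.
#' @return data.frame with patient ids as row names.
#' @export
readImmuneTable <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  im <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot("patient_id" %in% names(im),
            "immune table needs a patient_id column: %s", path)
  rownames(im) <- im$patient_id
  im$patient_id <- NULL
  stopIfNot(all(vapply(im, is.numeric, TRUE)),
            "immune table has non-numeric columns: %s", path)
  im
}

#' Read a clinical table from CSV
#'
#' @param path CSV with at least \code{patient_id}, \code{response},
#'   \code{time_months} and \code{event} columns.
#' @return data.frame.
#' @export
readClinicalTable <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  clin <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "response", "time_months", "event")
  miss <- setdiff(need, names(clin))
  stopIfNot(length(miss) == 0, "clinical table missing column(s): %s",
            paste(miss, collapse = ", "))
  if (!"common" %in% names(clin)) clin$common <- TRUE
  clin
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full multi-layer analysis
#'
#' Orchestrates, on one cohort: the four group/timepoint immune correlation
#' networks, the two co-expression networks and the differential
#' co-expression network with hub selection and Louvain communities,
#' enrichment of hub neighbourhoods and communities against a gene-set
#' collection, the GEP/CIP/fused patient-similarity layers with
#' eigengap-selected spectral clustering (plus single-layer ablations),
#' survival stratification (Kaplan-Meier, log-rank, univariate and
#' covariate-adjusted Cox), cluster characterisation (composition,
#' accuracy, per-variable Mann-Whitney, baseline balance), and, optionally,
#' LOOCV and hub-percentile sensitivity. All artifacts are written under
#' \code{output_dir} with a manifest of content hashes at its root.
#'
#' @param cohort a \code{SyntheticCohort}, or a cohort directory path as
#'   written by \code{\link{writeCohort}}.
#' @param output_dir output directory (created if missing).
#' @param params \code{\link{pipelineParams}}.
#' @param gene_sets optional collection (see \code{\link{readGMT}});
#'   defaults to the cohort's synthetic collection when available.
#' @param run_loocv,run_sensitivity include the validation stages (both
#'   TRUE by default).
#' @return invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(cohort, output_dir, params = pipelineParams(),
                        gene_sets = NULL, run_loocv = TRUE,
                        run_sensitivity = TRUE) {
  if (is.character(cohort)) {
    if (is.null(gene_sets) &&
        file.exists(file.path(cohort, "gene_sets.gmt")))
      gene_sets <- readGMT(file.path(cohort, "gene_sets.gmt"))
    cohort <- readCohort(cohort)
  }
  if (is.null(gene_sets) && is(cohort, "SyntheticCohort"))
    gene_sets <- cohortGeneSets(cohort)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- asPipelineInput(cohort, params)
  art <- character(0)
  warningsLog <- character(0)
  stage <- function(name, code) {
    tryCatch(withCallingHandlers(code, warning = function(w) {
      warningsLog <<- c(warningsLog,
                        sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(file) art <<- c(art, file)
  p <- function(f) file.path(output_dir, f)

  ## 1. immune (CIP) correlation networks per group and timepoint
  cipSummaries <- list()
  stage("cip_networks", {
    commonResp <- inp$response[rownames(inp$immune_pre)]
    for (tp in c("pre", "post")) {
      im <- if (tp == "pre") inp$immune_pre else inp$immune_post
      if (is.null(im)) next
      for (g in c("R", "NR")) {
        net <- buildCorrelationNetwork(
          im[commonResp[rownames(im)] == g, , drop = FALSE],
          rho_min = params$cip_rho, q_max = params$q_max,
          group = g, timepoint = tp)
        f <- sprintf("cip_network_%s_%s.tsv", g, tp)
        emit(writeTsv(networkEdges(net), p(f)))
        s <- networkSummary(net)
        cipSummaries[[paste(g, tp, sep = "_")]] <-
          s[c("n_nodes", "n_edges", "n_positive", "n_negative",
              "n_components")]
      }
    }
    jsonlite::write_json(cipSummaries, p("cip_network_summaries.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    emit(p("cip_network_summaries.json"))
  })

  ## 2. co-expression networks, DCN, hubs, communities
  dcnFit <- stage("dcn", {
    coex <- buildCoexpressionNetworks(inp$expression,
                                      inp$response[colnames(inp$expression)],
                                      rho_min = params$gep_rho,
                                      q_max = params$q_max)
    dcn <- buildDCN(inp$expression, inp$response[colnames(inp$expression)],
                    z_min = params$z_min,
                    pair_universe = params$pair_universe,
                    rho_min = params$gep_rho, q_max = params$q_max)
    hubs <- selectHubs(dcn, percentile = params$hub_percentile)
    comm <- louvainCommunities(dcn, seed = deriveSeed(params$seed, "louvain"),
                               weighted = params$weighted_louvain)
    for (g in names(coex))
      emit(writeTsv(networkEdges(coex[[g]]),
                    p(sprintf("coexpression_%s.tsv", g))))
    emit(writeTsv(networkEdges(dcn)[, c("gene_a", "gene_b", "rho_A",
                                        "rho_B", "Z")],
                  p("dcn_edges.tsv")))
    emit(writeGraphML(dcn, p("dcn.graphml")))
    emit(writeTsv(data.frame(gene = hubs$genes, degree = hubs$degree),
                  p("dcn_hubs.tsv")))
    emit(writeTsv(data.frame(gene = names(comm$membership),
                             community = as.integer(comm$membership)),
                  p("dcn_communities.tsv")))
    list(dcn = dcn, hubs = hubs, communities = comm)
  })

  ## 3. enrichment of hub neighbourhoods and communities
  if (!is.null(gene_sets)) stage("enrichment", {
    background <- rownames(inp$expression)
    enr <- list()
    for (h in dcnFit$hubs$genes) {
      q <- hubNeighborhood(dcnFit$dcn, h, sign = "both")
      enr[[paste0("hub_", h)]] <- enrichTest(q, gene_sets, background)
    }
    mem <- dcnFit$communities$membership
    for (cm in unique(mem)) {
      gs <- names(mem)[mem == cm]
      gs <- intersect(gs, unique(unlist(
        networkEdges(dcnFit$dcn)[, c("gene_a", "gene_b")])))
      if (length(gs) >= 5)
        enr[[paste0("community_", cm)]] <-
          enrichTest(gs, gene_sets, background)
    }
    tab <- do.call(rbind, lapply(names(enr), function(nm) {
      if (!nrow(enr[[nm]])) return(NULL)
      cbind(query = nm, enr[[nm]])
    }))
    if (is.null(tab)) tab <- data.frame(query = character(0))
    emit(writeTsv(tab, p("enrichment.tsv")))
  })

  ## 4. patient-similarity layers, fusion, clustering (+ ablations)
  psn <- stage("fusion", {
    commonIds <- rownames(inp$immune)
    gepFeat <- t(log1p(inp$expression[dcnFit$hubs$genes, commonIds,
                                      drop = FALSE]))
    affG <- affinityMatrix(gepFeat, K = params$snf_K, mu = params$snf_mu)
    affC <- affinityMatrix(as.matrix(inp$immune), K = params$snf_K,
                           mu = params$snf_mu)
    fused <- snfFuse(list(GEP = affG, CIP = affC), K = params$snf_K,
                     t = params$snf_t)
    eg <- eigengapK(fused, params$k_min, params$k_max)
    k <- if (!is.null(params$n_clusters)) params$n_clusters else eg$k
    labels <- spectralCluster(fused, k = k,
                              seed = deriveSeed(params$seed, "spectral"),
                              restarts = params$restarts)$labels
    single <- lapply(list(gep_only = affG$W, cip_only = affC$W),
                     function(W) {
                       spectralCluster(W, k = 2,
                                       seed = deriveSeed(params$seed, "ablation"),
                                       restarts = params$restarts)$labels
                     })
    fm <- fusedMatrix(fused)
    emit(writeTsv(data.frame(patient_id = rownames(fm), fm,
                             check.names = FALSE), p("fused_matrix.tsv")))
    asg <- data.frame(patient_id = names(labels), cluster = labels,
                      gep_only = single$gep_only[names(labels)],
                      cip_only = single$cip_only[names(labels)])
    utils::write.csv(asg, p("cluster_assignment.csv"), row.names = FALSE)
    emit(p("cluster_assignment.csv"))
    jsonlite::write_json(
      list(k = k, eigengap_values = as.list(eg$eigengap_values),
           snf = list(K = params$snf_K, mu = params$snf_mu,
                      t = params$snf_t),
           iterations_run = fused@iterations,
           max_rowsum_dev = fused@params$max_rowsum_dev),
      p("fusion_report.json"), auto_unbox = TRUE, pretty = TRUE)
    emit(p("fusion_report.json"))
    list(fused = fused, labels = labels, single = single, k = k,
         gepFeat = gepFeat)
  })

  ## 5. survival and cluster characterisation
  stage("survival", {
    commonIds <- names(psn$labels)
    surv <- inp$clinical[match(commonIds, inp$clinical$patient_id), ]
    res <- list()
    labs <- psn$labels
    if (psn$k == 2) {
      res$accuracy <- clusterAccuracy(labs, inp$response[commonIds])$accuracy
      res$confusion <- as.data.frame(
        clusterAccuracy(labs, inp$response[commonIds])$confusion)
      for (nm in names(psn$single))
        res[[paste0("accuracy_", nm)]] <-
          clusterAccuracy(psn$single[[nm]],
                          inp$response[commonIds])$accuracy
      lr <- logrankTest(surv$time_months, surv$event, labs)
      res$logrank <- lr
      surv2 <- cbind(surv, cluster = factor(labs[surv$patient_id]))
      res$cox_univariate <- coxPH(surv2, "cluster")
      adjCov <- intersect(c("age", "smoking", "histology", "pdl1", "ecog"),
                          names(surv2))
      res$cox_adjusted <- coxPH(surv2, c("cluster", adjCov))
      res$cluster_composition <-
        clusterEnrichment(labs, inp$response[commonIds])
      mw <- rbind(
        cbind(layer = "GEP",
              compareClusters(psn$gepFeat[commonIds, , drop = FALSE],
                              labs)),
        cbind(layer = "CIP",
              compareClusters(inp$immune[commonIds, , drop = FALSE],
                              labs)))
      emit(writeTsv(mw, p("cluster_variable_tests.tsv")))
      bb <- baselineBalance(
        surv, labs,
        covariates = intersect(c("age", "sex", "smoking", "histology",
                                 "pdl1", "ecog"), names(surv)))
      emit(writeTsv(bb, p("baseline_balance.tsv")))
    }
    kmRows <- do.call(rbind, lapply(sort(unique(labs)), function(cl) {
      sel <- labs[surv$patient_id] == cl
      km <- kmCurve(surv$time_months[sel], surv$event[sel])
      data.frame(cluster = cl, time = km$times, survival = km$survival,
                 n_risk = km$n_risk, n_events = km$n_events)
    }))
    emit(writeTsv(kmRows, p("km_curves.tsv")))
    res$km_median <- vapply(sort(unique(labs)), function(cl) {
      sel <- labs[surv$patient_id] == cl
      kmCurve(surv$time_months[sel], surv$event[sel])$median
    }, 1)
    jsonlite::write_json(res, p("survival_report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
    emit(p("survival_report.json"))
  })

  ## 6. validation stages
  if (run_loocv) stage("loocv", {
    lc <- loocv(cohort, params)
    emit(writeTsv(lc$per_iteration, p("loocv_iterations.tsv")))
    jsonlite::write_json(lc[c("mean_accuracy", "sd_accuracy",
                              "fraction_significant_logrank", "n_failed")],
                         p("loocv_report.json"), auto_unbox = TRUE,
                         digits = NA)
    emit(p("loocv_report.json"))
  })
  if (run_sensitivity) stage("sensitivity", {
    sens <- percentileSensitivity(cohort, params)
    emit(writeTsv(sens, p("percentile_sensitivity.tsv")))
  })

  ## manifest
  art <- unique(basename(art))
  manifest <- list(
    package_version = as.character(utils::packageVersion("DCNfuse")),
    params = params[!vapply(params, is.null, TRUE)],
    files = art,
    md5 = as.list(tools::md5sum(file.path(output_dir, art))),
    warnings = warningsLog,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  names(manifest$md5) <- art
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
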