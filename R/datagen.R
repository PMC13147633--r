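#' Configuration for a synthetic cohort
#'
#' Collects the knobs of the synthetic-cohort generator: cohort geometry
#' (44 gene-expression patients, 38 of them with immune profiling, 20
#' responders among the common set), panel geometry (438 genes, 23 planted
#' hubs), the planted co-expression strength, and the survival model.
#'
#' The expression model is a latent-program Gaussian on the log scale:
#' each planted hub anchors an independent co-regulated program whose
#' backbone cohort tracks the hub's latent activity in responders
#' (pairwise correlation \code{rho_within_module}) but tracks a ghost copy
#' of the program in non-responders, where the hub itself is decoupled.
#' Hub-touching module pairs are therefore differentially co-expressed
#' while backbone-backbone pairs are equally correlated in both groups.
#'
#' @param n_patients_gep patients with gene expression (default 44).
#' @param n_patients_common patients with both layers (default 38).
#' @param n_responders_common responders among the common set (default 20).
#' @param n_responders_gep responders among all GEP patients (default 23).
#' @param n_genes panel size (default 438).
#' @param n_immune_vars circulating immune subsets (default 31).
#' @param n_planted_hubs planted hub genes (default 23).
#' @param n_backbone_genes co-regulated non-hub genes (default 415, i.e. the
#'   whole panel outside the hubs; genes beyond hubs+backbone are noise).
#' @param rho_within_module pairwise correlation of the planted module in
#'   responders, in [0, 1) (default 0.8).
#' @param hazard_ratio hazard ratio of the poor-prognosis latent cluster
#'   (default 4.5).
#' @param median_survival_good median overall survival, in months, of the
#'   good-prognosis cluster (default 32).
#' @param censoring_rate expected fraction of censored patients (default
#'   0.2; independent uniform censoring).
#' @param flip_prob probability that a patient's latent cluster disagrees
#'   with their response label (default 0.2).
#' @param immune_cluster_shift latent-scale mean shift of the NK (cluster
#'   1) and myeloid (cluster 2) immune subsets (default 1.6).
#' @param gep_cluster_shift log-scale mean shift of hub genes in cluster-1
#'   patients (default 0.8).
#' @param seed RNG seed.
#' @return a validated list of class \code{cohort_config}.
#' @export
cohortConfig <- function(n_patients_gep = 44, n_patients_common = 38,
                         n_responders_common = 20, n_responders_gep = 23,
                         n_genes = 438, n_immune_vars = 31,
                         n_planted_hubs = 23, n_backbone_genes = 415,
                         rho_within_module = 0.8, hazard_ratio = 4.5,
                         median_survival_good = 32, censoring_rate = 0.2,
                         flip_prob = 0.2, immune_cluster_shift = 1.6,
                         gep_cluster_shift = 0.8, seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_patients_gep", "n_patients_common", "n_responders_common",
              "n_responders_gep", "n_genes", "n_immune_vars",
              "n_planted_hubs")
  for (nm in counts)
    stopIfNot(cfg[[nm]] >= 1 && cfg[[nm]] == round(cfg[[nm]]),
              "%s must be a positive count", nm)
  stopIfNot(n_responders_common <= n_patients_common,
            "n_responders_common must not exceed n_patients_common")
  stopIfNot(n_patients_common <= n_patients_gep,
            "n_patients_common must not exceed n_patients_gep")
  stopIfNot(n_responders_gep >= n_responders_common &&
              n_responders_gep <= n_patients_gep -
                (n_patients_common - n_responders_common),
            "n_responders_gep incompatible with the common-patient split")
  stopIfNot(rho_within_module >= 0 && rho_within_module < 1,
            "rho_within_module must lie in [0, 1)")
  stopIfNot(n_planted_hubs + n_backbone_genes <= n_genes,
            "hubs plus backbone genes must fit in the panel")
  stopIfNot(hazard_ratio > 0, "hazard_ratio must be positive")
  stopIfNot(censoring_rate >= 0 && censoring_rate < 1,
            "censoring_rate must lie in [0, 1)")
  stopIfNot(flip_prob >= 0 && flip_prob <= 0.5,
            "flip_prob must lie in [0, 0.5]")
  class(cfg) <- "cohort_config"
  cfg
}

# immune-subset variable names; first 8 myeloid, next 5 NK, rest lymphoid
immuneVarNames <- function(n) {
  base <- c("monocytes_classical", "monocytes_intermediate",
            "monocytes_nonclassical", "neutrophils", "g_mdsc", "m_mdsc",
            "granulo_hladr_dim", "eosinophils",
            "nk_cd56dim_cd16pos", "nk_cd56bright", "nk_total", "nkt_like",
            "nk_cd57pos",
            "t_cd3", "t_cd4", "t_cd8", "treg", "t_naive_cd4",
            "t_memory_cd4", "t_naive_cd8", "t_memory_cd8", "t_pd1_cd4",
            "t_pd1_cd8", "b_total", "b_naive", "b_memory", "plasmablasts",
            "dc_myeloid", "dc_plasmacytoid", "basophils", "gd_t")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("subset_", seq_len(n - length(base))))
}

# latent immune values for one patient stratum: myeloid + NK factor model
# with an NK-myeloid bridge only when `bridge` is TRUE
immuneLatent <- function(n_pat, n_vars, bridge) {
  nMy <- min(8, n_vars)
  nNk <- if (n_vars > 8) min(5, n_vars - 8) else 0
  nT <- if (n_vars > 13) min(9, n_vars - 13) else 0
  z <- matrix(stats::rnorm(n_pat * n_vars), n_pat, n_vars)
  m <- stats::rnorm(n_pat)
  k0 <- stats::rnorm(n_pat)
  k <- if (bridge) 0.77 * m + sqrt(1 - 0.77^2) * k0 else k0
  tf <- stats::rnorm(n_pat)
  if (nMy > 0)
    z[, seq_len(nMy)] <- sqrt(0.7) * m + sqrt(0.3) * z[, seq_len(nMy)]
  if (nNk > 0)
    z[, 8 + seq_len(nNk)] <- sqrt(0.6) * k + sqrt(0.4) * z[, 8 + seq_len(nNk)]
  if (nT > 0)
    z[, 13 + seq_len(nT)] <- sqrt(0.4) * tf + sqrt(0.6) * z[, 13 + seq_len(nT)]
  z
}

# uniform-censoring upper bound giving the requested censoring fraction
censoringBound <- function(rates, target) {
  pc <- function(u) mean((1 - exp(-rates * u)) / (rates * u)) - target
  stats::uniroot(pc, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Generate a synthetic multi-layer cohort
#'
#' Draws a cohort with the planted structure described in
#' \code{\link{cohortConfig}}: group-specific gene co-expression centred on
#' the planted hubs, immune-subset correlation blocks with a responder-only
#' pre-therapy NK-myeloid bridge, cluster-linked immune mean shifts, and
#' exponential survival whose hazard depends on the latent cluster.
#' Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \code{\link{SyntheticCohort-class}} object.
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopIfNot(inherits(config, "cohort_config"),
            "config must come from cohortConfig()")
  c0 <- config
  withSeed(c0$seed, {
    nP <- c0$n_patients_gep
    nC <- c0$n_patients_common
    ids <- sprintf("P%02d", seq_len(nP))
    common <- c(rep(TRUE, nC), rep(FALSE, nP - nC))

    response <- character(nP)
    response[seq_len(nC)] <-
      sample(rep(c("R", "NR"), c(c0$n_responders_common,
                                 nC - c0$n_responders_common)))
    if (nP > nC) {
      extraR <- c0$n_responders_gep - c0$n_responders_common
      response[(nC + 1):nP] <-
        sample(rep(c("R", "NR"), c(extraR, nP - nC - extraR)))
    }

    flip <- stats::runif(nP) < c0$flip_prob
    cluster <- ifelse(xor(response == "R", flip), "C1", "C2")
    names(cluster) <- ids

    ## expression: per-hub latent programs on the log scale. Each planted
    ## hub anchors an independent co-regulated program: in responders its
    ## backbone cohort tracks the hub's latent activity (pairwise backbone
    ## correlation = rho_within_module); in non-responders the cohort
    ## tracks a ghost copy of the program while the hub itself is
    ## decoupled. Hub-touching module pairs are therefore differentially
    ## co-expressed; backbone-backbone pairs are equally co-expressed in
    ## both groups.
    nG <- c0$n_genes
    genes <- sprintf("G%03d", seq_len(nG))
    hubs <- sort(sample(genes, c0$n_planted_hubs))
    backbone <- sort(sample(setdiff(genes, hubs), c0$n_backbone_genes))
    beta <- sqrt(c0$rho_within_module)
    isR <- response == "R"
    y <- matrix(stats::rnorm(nG * nP), nG, nP, dimnames = list(genes, ids))
    cohort_of <- rep(seq_along(hubs), length.out = length(backbone))
    for (k in seq_along(hubs)) {
      t_live <- stats::rnorm(nP)     # program activity (responders)
      t_ghost <- stats::rnorm(nP)    # ghost activity (non-responders)
      hubRow <- y[hubs[k], ]
      hubRow[isR] <- t_live[isR]     # hub tracks its program in responders
      y[hubs[k], ] <- hubRow
      drive <- ifelse(isR, t_live, t_ghost)
      bb <- backbone[cohort_of == k]
      y[bb, ] <- beta * matrix(drive, length(bb), nP, byrow = TRUE) +
        sqrt(1 - beta^2) * y[bb, , drop = FALSE]
    }
    # hub-expression shift in cluster-1 patients (patient-similarity signal)
    isHub <- genes %in% hubs
    y[isHub, ] <- y[isHub, ] +
      c0$gep_cluster_shift * matrix(cluster == "C1", sum(isHub), nP,
                                    byrow = TRUE)
    mu <- stats::runif(nG, 3, 7)
    expr <- round(exp(mu + y))
    dimnames(expr) <- list(genes, ids)

    ## immune profiles for common patients, two timepoints
    nV <- c0$n_immune_vars
    vnames <- immuneVarNames(nV)
    alpha <- stats::runif(nV, -2.5, -0.5)
    cid <- ids[common]
    cresp <- response[common]
    ccl <- cluster[common]
    makeImmune <- function(timepoint) {
      z <- matrix(NA_real_, nC, nV, dimnames = list(cid, vnames))
      for (g in c("R", "NR")) {
        sel <- cresp == g
        z[sel, ] <- immuneLatent(sum(sel), nV,
                                 bridge = (g == "R" && timepoint == "pre"))
      }
      myeloid <- seq_len(min(8, nV))
      nk <- if (nV > 8) 8 + seq_len(min(5, nV - 8)) else integer(0)
      z[, nk] <- z[, nk] + c0$immune_cluster_shift * (ccl == "C1")
      z[, myeloid] <- z[, myeloid] + c0$immune_cluster_shift * (ccl == "C2")
      pct <- 100 * stats::plogis(matrix(alpha, nC, nV, byrow = TRUE) +
                                   0.6 * z)
      as.data.frame(pct)
    }
    immunePre <- makeImmune("pre")
    immunePost <- makeImmune("post")

    ## survival: exponential with cluster hazard, uniform censoring
    rateGood <- log(2) / c0$median_survival_good
    rates <- ifelse(cluster == "C1", rateGood, rateGood * c0$hazard_ratio)
    tEvent <- stats::rexp(nP, rates)
    if (c0$censoring_rate > 0) {
      u <- censoringBound(rates, c0$censoring_rate)
      cTime <- stats::runif(nP, 0, u)
      time <- pmin(tEvent, cTime)
      event <- as.integer(tEvent <= cTime)
    } else {
      time <- tEvent
      event <- rep(1L, nP)
    }

    clinical <- data.frame(
      patient_id = ids,
      response = response,
      common = common,
      time_months = round(time, 2) + 0.01,
      event = event,
      age = pmin(pmax(round(stats::rnorm(nP, 67, 8)), 35), 88),
      sex = sample(c("M", "F"), nP, replace = TRUE, prob = c(0.7, 0.3)),
      smoking = sample(c("never", "former", "current"), nP, replace = TRUE,
                       prob = c(0.15, 0.5, 0.35)),
      histology = sample(c("squamous", "non-squamous"), nP, replace = TRUE,
                         prob = c(0.3, 0.7)),
      pdl1 = sample(c("<1%", "1-49%"), nP, replace = TRUE,
                    prob = c(0.4, 0.6)),
      ecog = sample(c("0-1", "2"), nP, replace = TRUE, prob = c(0.85, 0.15)),
      stringsAsFactors = FALSE)

    pairs <- cbind(gene_a = hubs[cohort_of], gene_b = backbone)

    truth <- list(
      planted_hub_genes = hubs,
      planted_module_genes = c(hubs, backbone),
      planted_differential_pairs = pairs,
      latent_cluster = cluster,
      true_log_hazard_ratio = log(c0$hazard_ratio))

    new("SyntheticCohort", expression = expr, immunePre = immunePre,
        immunePost = immunePost, clinical = clinical, truth = truth,
        config = unclass(c0))
  })
}

#' Deterministic synthetic gene-set collection for a cohort
#'
#' Builds a GMT-style collection aligned with the cohort's planted
#' structure: one term for the planted hub module, one for a slice of the
#' co-regulated backbone, plus random panel subsets. Deterministic given
#' the cohort's seed.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param n_random number of random terms (default 18).
#' @return collection list usable with \code{\link{enrichTest}} /
#'   \code{\link{writeGMT}}.
#' @export
cohortGeneSets <- function(cohort, n_random = 18) {
  genes <- rownames(cohortExpression(cohort))
  tr <- cohortTruth(cohort)
  withSeed(deriveSeed(cohort@config$seed, "gmt"), {
    sets <- list(
      HUB_MODULE = tr$planted_hub_genes,
      BACKBONE_PROGRAM = sort(sample(
        setdiff(tr$planted_module_genes, tr$planted_hub_genes),
        min(50, length(tr$planted_module_genes) -
              length(tr$planted_hub_genes)))))
    for (i in seq_len(n_random)) {
      sets[[sprintf("RANDOM_SET_%02d", i)]] <-
        sort(sample(genes, sample(10:40, 1)))
    }
    list(sets = sets,
         descriptions = stats::setNames(rep("synthetic", length(sets)),
                                        names(sets)),
         source = "synthetic")
  })
}

#' Write a cohort to a directory
#'
#' Writes the expression matrix as TSV (genes in rows), immune and clinical
#' tables as CSV, ground truth as JSON, a synthetic GMT collection, and a
#' manifest listing every file. Round-trips losslessly through
#' \code{\link{readCohort}}.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param directory existing writable directory.
#' @return invisibly, the file paths written.
#' @export
writeCohort <- function(cohort, directory) {
  stopIfNot(dir.exists(directory), "directory does not exist: %s", directory)
  p <- function(f) file.path(directory, f)
  ex <- data.frame(gene_id = rownames(cohort@expression),
                   cohort@expression, check.names = FALSE)
  utils::write.table(ex, p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (tp in c("pre", "post")) {
    im <- cohortImmune(cohort, tp)
    utils::write.csv(data.frame(patient_id = rownames(im), im,
                                check.names = FALSE),
                     p(sprintf("immune_%s.csv", tp)), row.names = FALSE,
                     quote = FALSE)
  }
  utils::write.csv(cohort@clinical, p("clinical.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- cohort@truth
  tr$planted_differential_pairs <-
    as.data.frame(tr$planted_differential_pairs)
  jsonlite::write_json(
    c(tr, list(config = cohort@config)), p("truth.json"),
    auto_unbox = TRUE, digits = NA)
  writeGMT(cohortGeneSets(cohort), p("gene_sets.gmt"))
  files <- c("expression.tsv", "immune_pre.csv", "immune_post.csv",
             "clinical.csv", "truth.json", "gene_sets.gmt")
  jsonlite::write_json(
    list(files = files,
         md5 = as.list(tools::md5sum(vapply(files, p, "")))),
    p("manifest.json"), auto_unbox = TRUE)
  invisible(vapply(files, p, ""))
}

#' Read a cohort directory written by \code{writeCohort}
#'
#' @param directory cohort directory.
#' @return a \code{\link{SyntheticCohort-class}} object.
#' @export
readCohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  stopIfNot(file.exists(p("expression.tsv")),
            "no expression.tsv under %s", directory)
  expr <- readExpression(p("expression.tsv"))
  readIm <- function(f) {
    im <- utils::read.csv(p(f), check.names = FALSE,
                          stringsAsFactors = FALSE)
    rownames(im) <- im$patient_id
    im$patient_id <- NULL
    im
  }
  clin <- utils::read.csv(p("clinical.csv"), stringsAsFactors = FALSE)
  tr <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  cfg <- tr$config
  tr$config <- NULL
  tr$planted_differential_pairs <-
    as.matrix(tr$planted_differential_pairs)
  tr$latent_cluster <- unlist(tr$latent_cluster)
  new("SyntheticCohort", expression = expr,
      immunePre = readIm("immune_pre.csv"),
      immunePost = readIm("immune_post.csv"),
      clinical = clin, truth = tr, config = as.list(cfg))
}
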