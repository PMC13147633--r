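#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function, via
#' \code{\link[survival]{survfit}}. The median is the smallest observed
#' time with \eqn{S(t) \le 0.5} (no interpolation), \code{NA} if the curve
#' never reaches 0.5.
#'
#' @param times positive follow-up times (months).
#' @param events event indicator (1 death, 0 censored).
#' @return list: \code{times} (sorted unique times), \code{survival},
#'   \code{n_risk}, \code{n_events}, \code{median}.
#' @export
kmCurve <- function(times, events) {
  stopIfNot(length(times) >= 1 && all(times > 0),
            "all times must be positive")
  stopIfNot(all(events %in% c(0, 1)), "events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- summary(fit, censored = TRUE)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  list(times = fit$time, survival = fit$surv, n_risk = fit$n.risk,
       n_events = fit$n.event, median = med)
}

#' Two-group log-rank test
#'
#' Standard (O - E)^2 / V chi-square statistic on 1 df, via
#' \code{\link[survival]{survdiff}}.
#'
#' @param times,events as in \code{\link{kmCurve}}.
#' @param groups two-level grouping vector, both levels non-empty.
#' @return list: \code{statistic}, \code{p}.
#' @export
logrankTest <- function(times, events, groups) {
  g <- factor(groups)
  stopIfNot(nlevels(g) == 2 && all(table(g) > 0),
            "exactly 2 non-empty groups are required")
  if (all(events == 0)) return(list(statistic = 0, p = 1))
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Efron-tie partial likelihood maximised by Newton-Raphson, via
#' \code{\link[survival]{coxph}}; categorical covariates enter as
#' reference-level dummies. Wald 95% confidence intervals and p-values per
#' coefficient. Non-convergence or an infinite coefficient (complete
#' separation) is flagged, never returned silently.
#'
#' @param table data.frame with columns \code{time_months}, \code{event},
#'   plus the covariates.
#' @param covariates character vector of covariate column names.
#' @return list: \code{coefficients}, \code{hazard_ratios},
#'   \code{ci_lower}, \code{ci_upper}, \code{p} (all named per
#'   coefficient), \code{converged}, \code{n}, \code{n_events}.
#' @export
coxPH <- function(table, covariates) {
  stopIfNot(all(c("time_months", "event") %in% names(table)),
            "table needs time_months and event columns")
  stopIfNot(sum(table$event) >= 1, "at least one event is required")
  miss <- setdiff(covariates, names(table))
  stopIfNot(length(miss) == 0, "unknown covariate(s): %s",
            paste(miss, collapse = ", "))
  df <- table
  for (cv in covariates)
    if (is.character(df[[cv]])) df[[cv]] <- factor(df[[cv]])
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(covariates, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  conf <- sm$conf.int
  converged <- !warned && all(is.finite(co[, "coef"])) &&
    all(abs(co[, "coef"]) < 15)
  list(coefficients = stats::setNames(co[, "coef"], rownames(co)),
       hazard_ratios = stats::setNames(exp(co[, "coef"]), rownames(co)),
       ci_lower = stats::setNames(conf[, "lower .95"], rownames(conf)),
       ci_upper = stats::setNames(conf[, "upper .95"], rownames(conf)),
       p = stats::setNames(co[, "Pr(>|z|)"], rownames(co)),
       converged = converged, n = sm$n, n_events = sm$nevent)
}

#' Response composition of each cluster
#'
#' For each cluster, the 2x2 composition against the binary response label
#' and the one-sided hypergeometric upper-tail p-value for the
#' over-representation of the cluster's majority label.
#'
#' @param assignment named cluster labels per patient.
#' @param response_labels named binary labels (e.g. "R"/"NR"), same
#'   patients.
#' @param strict strict-inequality tail convention (see
#'   \code{\link{hypergeomUpper}}).
#' @return data.frame with one row per cluster: cluster, size,
#'   majority_label, k (majority-label count in cluster), K (majority-label
#'   total), p.
#' @export
clusterEnrichment <- function(assignment, response_labels, strict = FALSE) {
  ids <- names(assignment)
  stopIfNot(!is.null(ids) && all(ids %in% names(response_labels)),
            "assignment and response labels must cover the same patients")
  resp <- response_labels[ids]
  lev <- sort(unique(as.character(resp)))
  stopIfNot(length(lev) == 2, "response labels must be binary (got: %s)",
            paste(lev, collapse = ", "))
  N <- length(ids)
  rows <- lapply(sort(unique(assignment)), function(cl) {
    inCl <- assignment == cl
    n <- sum(inCl)
    counts <- table(factor(as.character(resp[inCl]), levels = lev))
    maj <- lev[which.max(counts)]
    k <- max(counts)
    K <- sum(resp == maj)
    data.frame(cluster = cl, size = n, majority_label = maj,
               k = as.integer(k), K = as.integer(K), N = N,
               p = hypergeomUpper(k, K, n, N, strict = strict),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accuracy of a two-cluster assignment against binary labels
#'
#' Clusters are mapped to labels by the better of the two possible
#' mappings (majority matching); accuracy is the concordant fraction under
#' that mapping. Invariant to cluster relabelling; always >= 0.5.
#'
#' @inheritParams clusterEnrichment
#' @return list: \code{accuracy}, \code{confusion} (2x2 table, rows =
#'   clusters, columns = labels), \code{mapping} (cluster -> label).
#' @export
clusterAccuracy <- function(assignment, response_labels) {
  ids <- names(assignment)
  if (!is.null(ids) && !is.null(names(response_labels)))
    response_labels <- response_labels[ids]
  cl <- factor(assignment)
  stopIfNot(nlevels(cl) == 2, "exactly 2 clusters are required (got %d)",
            nlevels(cl))
  resp <- factor(as.character(response_labels))
  stopIfNot(nlevels(resp) == 2, "labels must be binary")
  tab <- table(cluster = cl, label = resp)
  accA <- (tab[1, 1] + tab[2, 2]) / sum(tab)
  accB <- (tab[1, 2] + tab[2, 1]) / sum(tab)
  if (accA >= accB) {
    mapping <- stats::setNames(colnames(tab), rownames(tab))
    acc <- accA
  } else {
    mapping <- stats::setNames(rev(colnames(tab)), rownames(tab))
    acc <- accB
  }
  list(accuracy = as.numeric(acc), confusion = tab, mapping = mapping)
}

#' Per-variable Mann-Whitney comparison between two clusters
#'
#' Two-sided Mann-Whitney U test of every variable between the two
#' clusters, BH-adjusted across variables. Exact enumeration is used when
#' both groups have at most 10 samples and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param variables samples x variables table, sample ids as row names.
#' @param assignment named two-level cluster labels.
#' @return data.frame: variable, U, p, q.
#' @export
compareClusters <- function(variables, assignment) {
  x <- as.matrix(variables)
  ids <- names(assignment)
  if (!is.null(ids) && !is.null(rownames(x))) x <- x[ids, , drop = FALSE]
  cl <- factor(assignment)
  stopIfNot(nlevels(cl) == 2, "exactly 2 clusters are required")
  stopIfNot(all(table(cl) >= 2), "each cluster needs at least 2 samples")
  g1 <- cl == levels(cl)[1]
  rows <- lapply(colnames(x), function(v) {
    a <- x[g1, v]; b <- x[!g1, v]
    exact <- length(a) <= 10 && length(b) <= 10 &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    p <- wt$p.value
    if (!is.finite(p)) p <- 1            # zero-variance variable
    data.frame(variable = v, U = unname(wt$statistic), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}

#' Baseline covariate balance between clusters
#'
#' Categorical covariates are compared with the two-sided Fisher exact
#' test (full enumeration, via \code{\link[stats]{fisher.test}}); numeric
#' covariates with the Wilcoxon rank-sum test. Levels absent from the data
#' are dropped with a warning.
#'
#' @param clinical data.frame of covariates, sample ids as row names (or a
#'   patient_id column).
#' @param assignment named two-level cluster labels.
#' @param covariates columns to test (default: all except patient_id).
#' @return data.frame: covariate, test ("fisher" or "wilcoxon"), p.
#' @export
baselineBalance <- function(clinical, assignment, covariates = NULL) {
  df <- as.data.frame(clinical)
  if ("patient_id" %in% names(df)) rownames(df) <- df$patient_id
  ids <- names(assignment)
  stopIfNot(all(ids %in% rownames(df)),
            "assignment patients missing from the clinical table")
  df <- df[ids, , drop = FALSE]
  cl <- factor(assignment)
  stopIfNot(nlevels(cl) == 2, "exactly 2 clusters are required")
  if (is.null(covariates))
    covariates <- setdiff(names(df), "patient_id")
  rows <- lapply(covariates, function(cv) {
    v <- df[[cv]]
    if (is.numeric(v)) {
      p <- suppressWarnings(
        stats::wilcox.test(v[cl == levels(cl)[1]],
                           v[cl == levels(cl)[2]])$p.value)
      test <- "wilcoxon"
    } else {
      f <- factor(as.character(v))
      empty <- setdiff(levels(f), unique(as.character(v)))
      if (length(empty)) {
        warning(sprintf("dropping empty level(s) of %s: %s", cv,
                        paste(empty, collapse = ", ")))
        f <- droplevels(f)
      }
      if (nlevels(f) < 2) return(NULL)
      p <- stats::fisher.test(table(cl, f))$p.value
      test <- "fisher"
    }
    data.frame(covariate = cv, test = test, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
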