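#' Construct a survival cohort
#'
#' Sample-level follow-up times and event indicators paired with a
#' gene x sample expression z-score matrix (as used for TCGA-style cohorts,
#' where z-scores of RNA-seq expression drive the gene-wise and signature
#' survival analyses).
#'
#' @param time Positive follow-up times (units are caller-defined, typically
#'   months).
#' @param event Event indicators in \{0, 1\} (1 = death observed).
#' @param z Gene x sample numeric matrix of expression z-scores; column names
#'   must match `sample_id`.
#' @param sample_id Sample identifiers (default: colnames of `z`).
#' @return A `survival_cohort`: list with `samples` (data frame `sample_id`,
#'   `time`, `event`) and `z`.
#' @export
survival_cohort <- function(time, event, z, sample_id = colnames(z)) {
  if (any(time <= 0) || any(!is.finite(time))) {
    stop("times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicators must be 0 or 1", call. = FALSE)
  }
  if (is.null(sample_id) || anyDuplicated(sample_id)) {
    stop("sample IDs must be present and unique", call. = FALSE)
  }
  if (!is.matrix(z) || ncol(z) != length(time) ||
      length(event) != length(time)) {
    stop("'z' must be a gene x sample matrix aligned with time/event",
         call. = FALSE)
  }
  colnames(z) <- sample_id
  structure(list(samples = data.frame(sample_id = sample_id, time = time,
                                      event = as.integer(event),
                                      stringsAsFactors = FALSE),
                 z = z),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("<survival_cohort> %d samples (%d events), %d genes\n",
              nrow(x$samples), sum(x$samples$event), nrow(x$z)))
  invisible(x)
}

#' Gene-wise z-scores
#'
#' Standardizes each gene row to mean 0 and SD 1 (n - 1 denominator).
#' Zero-variance genes are dropped with a warning; if nothing remains an
#' error is raised.
#'
#' @param expr Gene x sample numeric matrix (>= 2 samples).
#' @return The z-score matrix (possibly with fewer rows).
#' @export
zscore_matrix <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 2L) {
    stop("'expr' must be a matrix with at least 2 samples", call. = FALSE)
  }
  sds <- sqrt(row_vars(expr))
  drop <- sds == 0 | !is.finite(sds)
  if (all(drop)) stop("all genes have zero variance", call. = FALSE)
  if (any(drop)) {
    warning(sprintf("%d zero-variance gene(s) dropped", sum(drop)))
    expr <- expr[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  (expr - rowMeans(expr)) / sds
}

#' Quartile expression groups for one gene
#'
#' Splits samples into a low-expression group (`z < Q1`) and a
#' high-expression group (`z > Q3`), strict inequalities; samples between the
#' quartiles are excluded. Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 7). With 180 distinct values this gives
#' the 45-low / 45-high split used for gene-wise cohort screens.
#'
#' @param z Named numeric vector of one gene's z-scores (>= 8 samples).
#' @param label Optional gene label used in error messages.
#' @param type Quantile algorithm (see [stats::quantile()]).
#' @return List with `low` and `high` (sample names or indices), `q1`, `q3`.
#' @export
quartile_groups <- function(z, label = "gene", type = 7) {
  if (length(z) < 8L) stop("at least 8 samples are required", call. = FALSE)
  q <- stats::quantile(z, c(0.25, 0.75), names = FALSE, type = type)
  ids <- names(z) %||% seq_along(z)
  low <- ids[z < q[1]]
  high <- ids[z > q[2]]
  if (length(low) == 0L || length(high) == 0L) {
    stop(sprintf("degenerate expression distribution for %s: empty quartile group",
                 label), call. = FALSE)
  }
  list(low = low, high = high, q1 = q[1], q3 = q[2])
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`,
#' right-continuous and non-increasing with `S(0) = 1`. Computed via
#' [survival::survfit()].
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A `km_estimate` data frame with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (one row per distinct observed time).
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("at least one observation required", call. = FALSE)
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       survival = fit$surv),
            class = c("km_estimate", "data.frame"))
}

#' Log-rank test between two survival groups
#'
#' Mantel-Haenszel log-rank: at every distinct event time a 2x2 risk table
#' contributes observed-minus-expected events and a hypergeometric variance;
#' the statistic is `(sum(O - E))^2 / sum(V)`, chi-square with 1 df. Computed
#' via [survival::survdiff()].
#'
#' @param time,event Follow-up times and event indicators for all samples.
#' @param group Two-level grouping vector.
#' @return List with `statistic`, `df` (= 1), `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2L || any(table(group) == 0L)) {
    stop("exactly two non-empty groups are required", call. = FALSE)
  }
  if (sum(event) < 1L) stop("log-rank is undefined with zero events",
                            call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd_$chisq), df = 1L,
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Count-based gene-signature risk score
#'
#' The signature procedure: each signature gene is binarized per sample at its
#' upper quartile (indicator 1 iff `z > Q3` of that gene across the cohort);
#' the per-sample score is the number of highly expressed signature genes; the
#' cutoff is the median of these counts, and samples with
#' `count >= cutoff` form the high-risk group (so a median of 6 means "at
#' least six highly expressed genes" is high risk). Kaplan-Meier curves per
#' group and the log-rank test are attached.
#'
#' @param cohort A [survival_cohort()].
#' @param genes Signature gene IDs; genes absent from the matrix are dropped
#'   with a warning (at least one must remain).
#' @param quantile_type Quantile algorithm for the per-gene Q3.
#' @return A `signature_result`: list with `genes`, `indicator` (gene x
#'   sample 0/1 matrix), `counts`, `cutoff`, `risk` (named "high"/"low"
#'   vector), `km` (list of [km_estimate()] per group, `NULL` if a group is
#'   empty), `logrank` (list or `NULL`).
#' @export
signature_score <- function(cohort, genes, quantile_type = 7) {
  stopifnot(inherits(cohort, "survival_cohort"))
  present <- intersect(genes, rownames(cohort$z))
  missing <- setdiff(genes, present)
  if (length(missing) > 0L) {
    warning(sprintf("%d signature gene(s) not in the matrix dropped: %s",
                    length(missing),
                    paste(head(missing, 5), collapse = ", ")))
  }
  if (length(present) == 0L) {
    stop("no signature gene present in the expression matrix", call. = FALSE)
  }
  z <- cohort$z[present, , drop = FALSE]
  q3 <- apply(z, 1L, stats::quantile, probs = 0.75, names = FALSE,
              type = quantile_type)
  indicator <- (z > q3) * 1L
  counts <- colSums(indicator)
  cutoff <- stats::median(counts)
  risk <- ifelse(counts >= cutoff, "high", "low")
  names(risk) <- colnames(z)
  km <- list(high = NULL, low = NULL)
  lr <- NULL
  if (all(c("high", "low") %in% risk)) {
    for (g in c("high", "low")) {
      sel <- risk == g
      km[[g]] <- km_estimate(cohort$samples$time[sel],
                             cohort$samples$event[sel])
    }
    if (sum(cohort$samples$event) >= 1L) {
      lr <- logrank_test(cohort$samples$time, cohort$samples$event, risk)
    }
  } else {
    warning("all samples fall in one risk group; KM/log-rank skipped")
  }
  structure(list(genes = present, indicator = indicator, counts = counts,
                 cutoff = cutoff, risk = risk, km = km, logrank = lr),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result> %d genes, cutoff %.1f: %d high / %d low risk\n",
              length(x$genes), x$cutoff, sum(x$risk == "high"),
              sum(x$risk == "low")))
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank chi-square %.3f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p))
  }
  invisible(x)
}

#' Co-occurrence grouping of highly expressed genes
#'
#' Pairwise gene similarity is the Jaccard index of the high-expression
#' indicator vectors; average-linkage hierarchical clustering on
#' `1 - Jaccard` gives a leaf ordering and a k-cluster cut (default `k = 2`,
#' matching the two main co-occurrence groups reported for the immune
#' signature). The pairwise co-occurrence count matrix is returned alongside.
#'
#' @param indicator Gene x sample 0/1 matrix (e.g. from [signature_score()]).
#' @param k Number of clusters to cut (default 2).
#' @return List with `order` (gene IDs in dendrogram leaf order), `clusters`
#'   (named integer vector), `cooccurrence` (gene x gene count matrix),
#'   `jaccard`, and the `hclust` object.
#' @export
cooccurrence_groups <- function(indicator, k = 2) {
  if (!is.matrix(indicator) || nrow(indicator) < 2L) {
    stop("'indicator' must be a matrix with at least 2 genes", call. = FALSE)
  }
  if (all(indicator == 0)) stop("all-zero indicator matrix", call. = FALSE)
  co <- indicator %*% t(indicator)
  rs <- rowSums(indicator)
  uni <- outer(rs, rs, `+`) - co
  jac <- ifelse(uni > 0, co / uni, 0)
  diag(jac) <- 1
  hc <- stats::hclust(stats::as.dist(1 - jac), method = "average")
  k <- min(k, nrow(indicator))
  list(order = rownames(indicator)[hc$order],
       clusters = stats::cutree(hc, k = k),
       cooccurrence = co, jaccard = jac, hclust = hc)
}

#' Cox proportional-hazards fit
#'
#' Multivariate Cox regression maximizing the partial likelihood with Breslow
#' tie handling by default (Efron available), via [survival::coxph()] with a
#' relative log-likelihood convergence tolerance of 1e-9 and at most 50
#' iterations. Non-convergence or infinite coefficients (monotone likelihood
#' / perfect separation) are flagged, with estimates still returned.
#'
#' @param cohort A [survival_cohort()] (only `time`/`event` are used), or a
#'   data frame with columns `time` and `event`.
#' @param covariates Data frame of per-sample covariates (numeric or factor),
#'   aligned with the cohort samples.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `cox_fit`: list with `coefficients` (data frame `term`, `coef`,
#'   `hr`, `se`, `z`, `p`, `ci_lower`, `ci_upper` with HR-scale CI
#'   `exp(coef +/- 1.96 se)`), `loglik`, `score_test`, `n`, `n_event`,
#'   `converged`.
#' @export
cox_fit <- function(cohort, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  tab <- if (inherits(cohort, "survival_cohort")) cohort$samples else cohort
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 1L) stop("at least one covariate required",
                                  call. = FALSE)
  if (nrow(covariates) != nrow(tab)) {
    stop("covariates must align with the cohort samples", call. = FALSE)
  }
  if (sum(tab$event) < ncol(covariates)) {
    stop("fewer events than covariates", call. = FALSE)
  }
  dat <- cbind(tab[, c("time", "event")], covariates)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ ., data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  co <- sm$coefficients
  res <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hr = exp(co[, "coef"]), se = co[, "se(coef)"],
                    z = co[, "z"], p = co[, "Pr(>|z|)"],
                    ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!converged) warning("Cox fit did not converge cleanly; estimates flagged")
  structure(list(coefficients = res, loglik = fit$loglik[2],
                 score_test = unname(fit$score), n = fit$n,
                 n_event = fit$nevent, converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d (%d events), converged: %s\n",
              x$n, x$n_event, x$converged))
  print(x$coefficients, digits = 4)
  invisible(x)
}
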