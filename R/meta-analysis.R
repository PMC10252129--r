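#' Meta-analysis configuration
#'
#' Thresholds controlling gene evaluation and the significance call. A gene is
#' evaluated if measured in at least `min_presence` studies; it is flagged
#' significant when `FDR < fdr_max`, `|pooled log2FC| > lfc_min` (strict
#' inequalities) and it was measured in at least `min_studies` studies.
#'
#' @param fdr_max FDR threshold (default 0.05).
#' @param lfc_min Absolute pooled log2FC threshold (default 0.6).
#' @param min_studies Minimum number of contributing studies for significance
#'   (default 11).
#' @param min_presence Minimum number of studies for a gene to be evaluated at
#'   all (default 2).
#' @return A `meta_config` list.
#' @export
meta_config <- function(fdr_max = 0.05, lfc_min = 0.6,
                        min_studies = 11, min_presence = 2) {
  if (fdr_max <= 0 || lfc_min <= 0) {
    stop("'fdr_max' and 'lfc_min' must be positive", call. = FALSE)
  }
  if (min_studies < min_presence) {
    stop("'min_studies' must be >= 'min_presence'", call. = FALSE)
  }
  structure(list(fdr_max = fdr_max, lfc_min = lfc_min,
                 min_studies = as.integer(min_studies),
                 min_presence = as.integer(min_presence)),
            class = "meta_config")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-study effects `y_j` with within-study variances `v_j`.
#' Fixed-effect weights `w_j = 1/v_j` give the fixed-effect mean and Cochran's
#' `Q = sum w_j (y_j - ybar_FE)^2`; the moment estimator of the between-study
#' variance is `tau2 = max(0, (Q - (k - 1)) / C)` with
#' `C = sum(w) - sum(w^2)/sum(w)` (and `tau2 = 0` when `k = 1`). Random-effects
#' weights `1/(v_j + tau2)` yield the pooled estimate, its standard error
#' `SE = (sum w*)^(-1/2)`, the normal z statistic, a two-sided p-value and the
#' 95% CI `pooled +/- 1.96 SE`. `I2 = max(0, (Q - (k - 1)) / Q)`.
#'
#' @param effects Numeric vector of per-study effects (log2FC).
#' @param variances Positive per-study variances (squared standard errors).
#' @return List of class `dl_pool` with `k`, `pooled`, `se`, `tau2`, `Q`,
#'   `I2`, `z`, `p`, `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' dl_pool(c(1.0, 0.5, 1.5), c(0.04, 0.04, 0.04))
dl_pool <- function(effects, variances) {
  k <- length(effects)
  if (k < 1L) stop("at least one study is required", call. = FALSE)
  if (length(variances) != k) {
    stop("'effects' and 'variances' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    stop("variances must be positive and finite", call. = FALSE)
  }
  w <- 1 / variances
  y_fe <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - y_fe)^2)
  if (k == 1L) {
    tau2 <- 0
  } else {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
  }
  ws <- 1 / (variances + tau2)
  pooled <- sum(ws * effects) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- pooled / se
  p <- 2 * stats::pnorm(-abs(z))
  i2 <- if (k > 1L && Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  structure(list(k = k, pooled = pooled, se = se, tau2 = tau2, Q = Q,
                 I2 = i2, z = z, p = p,
                 ci_lower = pooled - 1.96 * se,
                 ci_upper = pooled + 1.96 * se),
            class = "dl_pool")
}

#' Gene-wise random-effects meta-analysis across studies
#'
#' Collects per-study `(log2fc, se)` pairs for every gene measured in at least
#' `config$min_presence` studies, pools them with [dl_pool()], adjusts the
#' pooled p-values by Benjamini-Hochberg across all evaluated genes, and flags
#' significance per [meta_config()]. Rows are sorted by FDR, then by
#' decreasing `|pooled|`.
#'
#' @param dge_results List of `dge_result` objects (one per study), as
#'   returned by [fit_dge()] or [read_dge_table()].
#' @param config A [meta_config()].
#' @return A `meta_result` data frame with columns `gene`, `k`, `pooled`,
#'   `se`, `ci_lower`, `ci_upper`, `z`, `p`, `fdr`, `Q`, `tau2`, `I2`,
#'   `significant`, `loo_stable` (NA until [add_loo_stability()] is run).
#'   Attribute `study_data` holds the per-gene study-level effects; attribute
#'   `config` echoes the thresholds.
#' @export
run_meta <- function(dge_results, config = meta_config()) {
  if (length(dge_results) < 2L) {
    stop("at least two studies are required", call. = FALSE)
  }
  long <- do.call(rbind, lapply(dge_results, function(d) {
    data.frame(study = attr(d, "study_id") %||% "?",
               gene = d$gene, y = d$log2fc, v = d$se^2,
               stringsAsFactors = FALSE)
  }))
  spl <- split(long, long$gene)
  spl <- spl[vapply(spl, nrow, integer(1)) >= config$min_presence]
  if (length(spl) == 0L) {
    stop("no gene is present in the required minimum number of studies",
         call. = FALSE)
  }
  rows <- vapply(spl, function(g) {
    pl <- dl_pool(g$y, g$v)
    c(k = pl$k, pooled = pl$pooled, se = pl$se, ci_lower = pl$ci_lower,
      ci_upper = pl$ci_upper, z = pl$z, p = pl$p, Q = pl$Q, tau2 = pl$tau2,
      I2 = pl$I2)
  }, numeric(10))
  res <- as.data.frame(t(rows))
  res$gene <- names(spl)
  res$fdr <- bh_adjust(res$p)
  res$significant <- res$fdr < config$fdr_max &
    abs(res$pooled) > config$lfc_min &
    res$k >= config$min_studies
  res$loo_stable <- NA
  ord <- order(res$fdr, -abs(res$pooled))
  res <- res[ord, c("gene", "k", "pooled", "se", "ci_lower", "ci_upper",
                    "z", "p", "fdr", "Q", "tau2", "I2", "significant",
                    "loo_stable")]
  rownames(res) <- NULL
  structure(res, class = c("meta_result", "data.frame"),
            study_data = spl[res$gene], config = config)
}

#' Per-gene study-level effects behind a meta-analysis row
#'
#' @param meta A `meta_result` from [run_meta()].
#' @param gene Gene identifier.
#' @return Data frame with columns `study`, `gene`, `y`, `v`.
#' @export
gene_studies <- function(meta, gene) {
  sd_ <- attr(meta, "study_data")
  if (is.null(sd_[[gene]])) stop(sprintf("gene '%s' was not evaluated", gene),
                                 call. = FALSE)
  sd_[[gene]]
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools a gene's effects `k` times, omitting one study each time. The gene
#' is called `loo_stable` when every rerun keeps the sign of the full pooled
#' estimate, keeps `|pooled| > lfc_min`, and keeps the unadjusted pooled
#' p-value below `fdr_max` (used as the nominal level; global FDR is not
#' recomputed per rerun since it would entangle the other genes).
#'
#' @param effects,variances Per-study effects and variances (`k >= 2`).
#' @param config A [meta_config()] supplying `lfc_min` and `fdr_max`.
#' @param study_ids Optional study labels.
#' @return Data frame with one row per omitted study (`omitted`, `k`,
#'   `pooled`, `se`, `tau2`, `p`); attribute `loo_stable` (logical).
#' @export
loo_sensitivity <- function(effects, variances, config = meta_config(),
                            study_ids = NULL) {
  k <- length(effects)
  if (k < 2L) stop("leave-one-out requires at least 2 studies", call. = FALSE)
  full <- dl_pool(effects, variances)
  reruns <- lapply(seq_len(k), function(j) dl_pool(effects[-j], variances[-j]))
  out <- data.frame(
    omitted = study_ids %||% sprintf("study_%d", seq_len(k)),
    k = k - 1L,
    pooled = vapply(reruns, `[[`, numeric(1), "pooled"),
    se = vapply(reruns, `[[`, numeric(1), "se"),
    tau2 = vapply(reruns, `[[`, numeric(1), "tau2"),
    p = vapply(reruns, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  stable <- all(sign(out$pooled) == sign(full$pooled)) &&
    all(abs(out$pooled) > config$lfc_min) &&
    all(out$p < config$fdr_max)
  structure(out, loo_stable = stable)
}

#' Flag leave-one-out stability for significant genes
#'
#' Runs [loo_sensitivity()] for every significant gene of a meta-analysis
#' result and fills the `loo_stable` column (non-significant genes keep `NA`).
#'
#' @param meta A `meta_result` from [run_meta()].
#' @return The `meta_result` with `loo_stable` filled in.
#' @export
add_loo_stability <- function(meta) {
  config <- attr(meta, "config")
  sig <- which(meta$significant & meta$k >= 2)
  for (i in sig) {
    g <- gene_studies(meta, meta$gene[i])
    meta$loo_stable[i] <- attr(
      loo_sensitivity(g$y, g$v, config = config, study_ids = g$study),
      "loo_stable")
  }
  meta
}

#' Forest- and funnel-plot data for one gene
#'
#' Pure data export. The forest component lists each study's effect with its
#' 95% CI (`y_j +/- 1.96 sqrt(v_j)`) plus the pooled diamond; the funnel
#' component gives `(y_j, sqrt(v_j))` points, the pooled center line, and the
#' pseudo-confidence cone whose half-width at precision level `s` is
#' `1.96 * s`.
#'
#' @param effects,variances Per-study effects and variances (`k >= 1`).
#' @param study_ids Optional study labels.
#' @param cone_levels Standard-error grid for the funnel cone.
#' @return List with data frames `forest` (columns `label`, `y`, `ci_lower`,
#'   `ci_upper`, `type`) and `funnel_points` (`y`, `se`), plus `funnel_center`
#'   and `funnel_cone` (`se`, `lower`, `upper`).
#' @export
forest_funnel_data <- function(effects, variances, study_ids = NULL,
                               cone_levels = seq(0, max(sqrt(variances)),
                                                 length.out = 25)) {
  pl <- dl_pool(effects, variances)
  se_j <- sqrt(variances)
  forest <- data.frame(
    label = c(study_ids %||% sprintf("study_%d", seq_along(effects)),
              "pooled"),
    y = c(effects, pl$pooled),
    ci_lower = c(effects - 1.96 * se_j, pl$ci_lower),
    ci_upper = c(effects + 1.96 * se_j, pl$ci_upper),
    type = c(rep("study", length(effects)), "pooled"),
    stringsAsFactors = FALSE
  )
  list(
    forest = forest,
    funnel_points = data.frame(y = effects, se = se_j),
    funnel_center = pl$pooled,
    funnel_cone = data.frame(se = cone_levels,
                             lower = pl$pooled - 1.96 * cone_levels,
                             upper = pl$pooled + 1.96 * cone_levels)
  )
}

#' Read / write per-study DGE tables
#'
#' TSV with columns `gene`, `log2fc`, `se`, `df`, `t`, `p`, `fdr` as written
#' by [write_dge_table()].
#'
#' @param path File path.
#' @param dge A `dge_result`.
#' @return `read_dge_table` returns a `dge_result`; `write_dge_table` returns
#'   the path invisibly.
#' @export
write_dge_table <- function(dge, path) {
  df <- as.data.frame(dge)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dge_table
#' @param study_id Study label attached to the result (defaults to the file
#'   name without extension).
#' @export
read_dge_table <- function(path, study_id = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "log2fc", "se", "p")
  if (!all(needed %in% names(df))) {
    stop("DGE table must contain columns gene, log2fc, se, p", call. = FALSE)
  }
  structure(df, class = c("dge_result", "data.frame"),
            study_id = study_id %||% sub("\\.[^.]+$", "", basename(path)))
}
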