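#' Construct an expression study
#'
#' Bundles one study's gene-by-sample expression matrix with its sample
#' annotation. Matrices hold either normalized log2 intensities (microarray or
#' normalized RNA-seq) or raw RNA-seq counts; the `normalization_state` field
#' records which. Studies must have at least five samples per group, mirroring
#' the compendium inclusion rule (sample size > 4 in both the case and the
#' control group).
#'
#' @param matrix Numeric gene x sample matrix with unique rownames (gene IDs)
#'   and colnames (sample IDs).
#' @param group Character/factor vector, one of `"control"`/`"case"` per
#'   sample, aligned with the matrix columns.
#' @param study_id Single string identifying the study.
#' @param platform `"array"` or `"rnaseq"`.
#' @param pair_id Optional pairing identifier per sample (for paired designs);
#'   `NA` for unpaired samples.
#' @param normalization_state `"normalized_log2"` or `"raw_counts"`.
#' @return An object of class `expression_study`: a list with elements
#'   `study_id`, `matrix`, `samples` (data frame with `sample_id`, `group`,
#'   `pair_id`), `platform`, `normalization_state`.
#' @export
#' @examples
#' m <- matrix(rnorm(60, 8), 6, 10,
#'             dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
#' st <- expression_study(m, rep(c("control", "case"), each = 5), "demo")
expression_study <- function(matrix, group, study_id,
                             platform = c("array", "rnaseq"),
                             pair_id = NULL,
                             normalization_state = c("normalized_log2",
                                                     "raw_counts")) {
  platform <- match.arg(platform)
  normalization_state <- match.arg(normalization_state)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("'matrix' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    stop("gene IDs (rownames) must be present and unique", call. = FALSE)
  }
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- sprintf("S%03d", seq_len(ncol(matrix)))
  }
  group <- as.character(group)
  if (length(group) != ncol(matrix)) {
    stop("'group' must have one entry per sample", call. = FALSE)
  }
  if (!all(group %in% c("control", "case"))) {
    stop("'group' values must be 'control' or 'case'", call. = FALSE)
  }
  if (any(table(factor(group, c("control", "case"))) < 5L)) {
    stop("each group needs at least 5 samples (inclusion rule: n > 4 per group)",
         call. = FALSE)
  }
  if (platform == "rnaseq" && normalization_state == "raw_counts") {
    if (any(matrix < 0) || any(matrix != floor(matrix))) {
      stop("raw RNA-seq counts must be non-negative integers", call. = FALSE)
    }
  }
  if (!is.null(pair_id) && length(pair_id) != ncol(matrix)) {
    stop("'pair_id' must have one entry per sample", call. = FALSE)
  }
  structure(list(
    study_id = as.character(study_id)[1],
    matrix = matrix,
    samples = data.frame(sample_id = colnames(matrix),
                         group = group,
                         pair_id = if (is.null(pair_id)) NA_character_ else
                           as.character(pair_id),
                         stringsAsFactors = FALSE),
    platform = platform,
    normalization_state = normalization_state
  ), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  tab <- table(x$samples$group)
  cat(sprintf("<expression_study> %s: %d genes x %d samples (%s, %s)\n",
              x$study_id, nrow(x$matrix), ncol(x$matrix), x$platform,
              x$normalization_state))
  cat(sprintf("  control: %d, case: %d, paired: %s\n",
              tab[["control"]], tab[["case"]],
              !all(is.na(x$samples$pair_id))))
  invisible(x)
}

#' TMM scaling factors for RNA-seq count matrices
#'
#' Trimmed mean of M-values normalization factors. The reference sample is the
#' one whose 75th-percentile count fraction is closest to the mean of that
#' quantity across samples. For each sample, M (log2 ratio) and A (average
#' log2 abundance) values versus the reference are computed on library-size
#' scaled counts, genes with a zero in either sample are excluded, the M and A
#' values are doubly trimmed (`trim_m` on M, `trim_a` on A), and the factor is
#' 2 to the weighted mean of the surviving M-values with inverse asymptotic
#' binomial variance weights. Factors are rescaled to geometric mean 1.
#'
#' @param counts Non-negative integer gene x sample matrix (>= 2 samples).
#' @param trim_m Two-sided trim fraction applied to M-values (default 0.30).
#' @param trim_a Two-sided trim fraction applied to A-values (default 0.05).
#' @return Named numeric vector of positive per-sample scaling factors with
#'   geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (!is.matrix(counts) || ncol(counts) < 2L) {
    stop("'counts' must be a matrix with at least 2 samples", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs a positive library size", call. = FALSE)
  f75 <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample's TMM log2 factor versus the reference column.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) < 2L) {
    warning("fewer than 2 genes survive zero-filtering; factor set to 1")
    return(1)
  }
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # asymptotic variance of M under binomial sampling
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra_ <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) {
    warning("trimming removed all genes; factor set to 1")
    return(1)
  }
  2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' Log2 counts per million
#'
#' `log2((count + prior_count) / (library_size * factor) * 1e6)`, monotone in
#' the count. Library sizes are the column sums of `counts`.
#'
#' @param counts Non-negative count matrix, genes as rows.
#' @param factors Positive per-sample scaling factors (e.g. [tmm_factors()]).
#' @param prior_count Pseudo-count stabilizing the log at zero (default 0.5).
#' @return Gene x sample matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, factors = rep(1, ncol(counts)), prior_count = 0.5) {
  if (any(factors <= 0)) stop("'factors' must be positive", call. = FALSE)
  if (length(factors) != ncol(counts)) {
    stop("'factors' must have one entry per sample", call. = FALSE)
  }
  eff <- colSums(counts) * factors
  t(log2(t(counts + prior_count) / eff * 1e6))
}

#' Normalize a study to the log2 scale
#'
#' Raw RNA-seq counts are TMM-normalized and converted to log2-CPM. Microarray
#' matrices are assumed pre-normalized; a scale heuristic (maximum value > 30)
#' triggers a `log2(x + 1)` transform, with a message recording the action.
#'
#' @param study An [expression_study()].
#' @param prior_count Pseudo-count for [log_cpm()].
#' @param trim_m,trim_a TMM trim fractions, see [tmm_factors()].
#' @return The study with `matrix` on log2 scale and
#'   `normalization_state = "normalized_log2"`.
#' @export
normalize_study <- function(study, prior_count = 0.5,
                            trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  if (study$normalization_state == "raw_counts") {
    f <- tmm_factors(study$matrix, trim_m = trim_m, trim_a = trim_a)
    study$matrix <- log_cpm(study$matrix, f, prior_count = prior_count)
    study$normalization_state <- "normalized_log2"
  } else if (max(study$matrix) > 30) {
    message(sprintf("study %s: values exceed 30, applying log2(x + 1)",
                    study$study_id))
    study$matrix <- log2(study$matrix + 1)
  }
  study
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-down FDR adjustment: with sorted p-values, the i-th adjusted value is
#' `min over j >= i of min(1, p_(j) * m / j)`, mapped back to the input order.
#' Delegates to [stats::p.adjust()] after validation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear (Smyth's parametrization).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-9) break
  }
  y
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-gene residual variances toward a common prior under a scaled-F
#' model: the prior degrees of freedom `d0` and prior variance `s0_2` are
#' estimated by method of moments on `log(s2)` (matching the distribution of
#' log chi-square variates), and the posterior variance is
#' `(d0 * s0_2 + df * s2) / (d0 + df)`.
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar or per gene).
#' @param d0,s0_2 Optional prior values overriding the moment estimates
#'   (useful to force the `d0 = 0` unmoderated and `d0 = Inf` full-shrinkage
#'   limits).
#' @return List with `s2_post`, `d0`, `s0_2`, `df_total = df + d0`.
#' @export
squeeze_variances <- function(s2, df, d0 = NULL, s0_2 = NULL) {
  df <- rep_len(df, length(s2))
  if (is.null(d0) || is.null(s0_2)) {
    ok <- s2 > 0 & df > 0
    if (sum(ok) < 2L) {
      d0 <- d0 %||% 0
      s0_2 <- s0_2 %||% stats::median(s2[ok])
    } else {
      z <- log(s2[ok])
      e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
      emean <- mean(e)
      evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
      if (is.null(d0)) {
        d0 <- if (evar > 0) 2 * trigamma_inverse(evar) else Inf
      }
      if (is.null(s0_2)) {
        s0_2 <- if (is.finite(d0) && d0 > 0) {
          exp(emean + digamma(d0 / 2) - log(d0 / 2))
        } else {
          exp(emean)
        }
      }
    }
  }
  s2_post <- if (is.infinite(d0)) {
    rep_len(s0_2, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_2 + df * s2) / (d0 + df)
  }
  list(s2_post = s2_post, d0 = d0, s0_2 = s0_2, df_total = df + d0)
}

#' Per-study differential expression
#'
#' Two-group differential expression on a log2-scale study. Unpaired designs
#' fit the per-gene two-sample model (effect = mean(case) - mean(control),
#' pooled residual variance, `df = n - 2`); paired designs model within-pair
#' case-minus-control differences (`df = n_pairs - 1`). With
#' `moderated = TRUE` the residual variances are shrunk by
#' [squeeze_variances()] and the t-test uses `df + d0` degrees of freedom.
#' Genes with zero residual variance get a floored SE (machine-epsilon scale)
#' and a warning. FDR is the Benjamini-Hochberg adjustment of the p-values.
#'
#' @param study An [expression_study()] with `normalization_state =
#'   "normalized_log2"` (see [normalize_study()]).
#' @param paired Use the paired design? Requires every `pair_id` to have
#'   exactly one case and one control.
#' @param moderated Moderate variances across genes (default `TRUE`).
#' @param d0,s0_2 Optional prior overrides passed to [squeeze_variances()].
#' @return A `dge_result`: data frame with columns `gene`, `log2fc`, `se`,
#'   `df`, `t`, `p`, `fdr`; attributes `study_id`, `paired`, `moderated`,
#'   `d0`, `s0_2`.
#' @export
fit_dge <- function(study, paired = FALSE, moderated = TRUE,
                    d0 = NULL, s0_2 = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (study$normalization_state != "normalized_log2") {
    stop("study must be normalized to log2 scale first (normalize_study)",
         call. = FALSE)
  }
  x <- study$matrix
  grp <- study$samples$group
  if (paired) {
    pid <- study$samples$pair_id
    if (anyNA(pid)) stop("paired design requires pair_id for every sample",
                         call. = FALSE)
    tab <- table(pid, grp)
    if (!all(tab == 1L)) {
      stop("each pair_id must have exactly one case and one control",
           call. = FALSE)
    }
    pairs <- sort(unique(pid))
    # explicit column matching: case column and control column per pair
    case_cols <- vapply(pairs, function(p) which(pid == p & grp == "case"),
                        integer(1))
    ctrl_cols <- vapply(pairs, function(p) which(pid == p & grp == "control"),
                        integer(1))
    d <- x[, case_cols, drop = FALSE] - x[, ctrl_cols, drop = FALSE]
    fc <- rowMeans(d)
    s2 <- row_vars(d)
    n_eff <- length(pairs)
    df <- n_eff - 1
    c2 <- 1 / n_eff
  } else {
    is_case <- grp == "case"
    n1 <- sum(!is_case); n2 <- sum(is_case)
    m1 <- rowMeans(x[, !is_case, drop = FALSE])
    m2 <- rowMeans(x[, is_case, drop = FALSE])
    fc <- m2 - m1
    ss <- rowSums((x[, !is_case, drop = FALSE] - m1)^2) +
      rowSums((x[, is_case, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2
    s2 <- ss / df
    c2 <- 1 / n1 + 1 / n2
  }
  zero <- s2 <= 0
  if (any(zero)) {
    floor_val <- .Machine$double.eps * max(c(s2[!zero], 1))
    s2[zero] <- floor_val
    warning(sprintf("study %s: %d gene(s) with zero residual variance; SE floored",
                    study$study_id, sum(zero)))
  }
  if (moderated) {
    sq <- squeeze_variances(s2, df, d0 = d0, s0_2 = s0_2)
    s2_use <- sq$s2_post
    df_use <- df + sq$d0
    prior <- sq[c("d0", "s0_2")]
  } else {
    s2_use <- s2
    df_use <- df
    prior <- list(d0 = 0, s0_2 = NA_real_)
  }
  se <- sqrt(s2_use * c2)
  tstat <- fc / se
  p <- 2 * stats::pt(-abs(tstat), df = df_use)
  res <- data.frame(gene = rownames(x), log2fc = fc, se = se,
                    df = rep_len(df_use, length(fc)), t = tstat, p = p,
                    fdr = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(res, class = c("dge_result", "data.frame"),
            study_id = study$study_id, paired = paired,
            moderated = moderated, d0 = prior$d0, s0_2 = prior$s0_2)
}
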