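# Default per-study (control, case) sample sizes for a 21-study compendium.
# Totals: 320 controls, 602 cases across 922 samples, matching the scale of
# the multi-study PDAC compendium the generator emulates; the individual
# study sizes are invented but span the typical GEO range (5 to ~120).
default_sample_sizes <- function() {
  data.frame(
    n_control = c(8L, 61L, 13L, 5L, 6L, 5L, 9L, 7L, 45L, 8L, 6L,
                  5L, 16L, 39L, 10L, 10L, 19L, 9L, 15L, 18L, 6L),
    n_case = c(14L, 69L, 28L, 12L, 8L, 6L, 26L, 6L, 45L, 12L, 25L,
               7L, 118L, 39L, 14L, 36L, 52L, 10L, 36L, 24L, 15L)
  )
}

#' Simulation configuration for a multi-study compendium
#'
#' Describes a synthetic compendium of case-control expression studies with
#' per-gene between-study heterogeneity, mixed platforms and incomplete gene
#' coverage. The defaults emulate the structure of a 21-study compendium with
#' 922 samples (320 controls / 602 cases), 19 array-like and 2 count-based
#' studies, ~50% of genes passing an 11-study coverage filter, 10% DE genes
#' of mean absolute effect 1 log2 unit, and between-study SD 0.2.
#'
#' @param n_studies Number of studies.
#' @param n_genes Number of simulated genes.
#' @param de_fraction Fraction of genes differentially expressed.
#' @param effect_size_mean Absolute true mean effect of DE genes (log2 units);
#'   signs are random.
#' @param tau Between-study SD of the per-study effects of DE genes (log2).
#' @param coverage_fraction Probability that a (non-core) gene is measured by
#'   a given study; must be positive.
#' @param core_fraction Fraction of genes measured in every study (guarantees
#'   passers of the coverage filter).
#' @param sample_sizes Data frame with columns `n_control`, `n_case` (>= 5
#'   each); defaults to the built-in 21-study table, recycled if `n_studies`
#'   differs.
#' @param platform_mix Character vector (`"array"`/`"rnaseq"`) per study;
#'   default all-array with the last two studies count-based when
#'   `n_studies >= 21`.
#' @param noise_sd Residual SD of array log2 intensities.
#' @param nb_dispersion Negative-binomial dispersion of RNA-seq counts.
#' @param baseline_mean,baseline_sd Mean/SD of per-gene baseline log2
#'   expression.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_studies = 21, n_genes = 2000,
                              de_fraction = 0.1, effect_size_mean = 1.0,
                              tau = 0.2, coverage_fraction = 0.5,
                              core_fraction = 0.2, sample_sizes = NULL,
                              platform_mix = NULL, noise_sd = 1.0,
                              nb_dispersion = 0.1, baseline_mean = 7,
                              baseline_sd = 2, seed = 1) {
  stop_if_not_scalar_count(n_studies, "n_studies")
  stop_if_not_scalar_count(n_genes, "n_genes")
  check_proportion(de_fraction, "de_fraction")
  check_proportion(coverage_fraction, "coverage_fraction", allow_zero = FALSE)
  check_proportion(core_fraction, "core_fraction")
  if (tau < 0) stop("'tau' must be non-negative", call. = FALSE)
  if (noise_sd <= 0 || nb_dispersion <= 0) {
    stop("'noise_sd' and 'nb_dispersion' must be positive", call. = FALSE)
  }
  if (is.null(sample_sizes)) {
    base <- default_sample_sizes()
    idx <- rep_len(seq_len(nrow(base)), n_studies)
    sample_sizes <- base[idx, , drop = FALSE]
    rownames(sample_sizes) <- NULL
  }
  sample_sizes <- as.data.frame(sample_sizes)
  if (!all(c("n_control", "n_case") %in% names(sample_sizes)) ||
      nrow(sample_sizes) != n_studies) {
    stop("'sample_sizes' needs n_control/n_case columns, one row per study",
         call. = FALSE)
  }
  if (any(sample_sizes$n_control < 5) || any(sample_sizes$n_case < 5)) {
    stop("sample sizes must be at least 5 per group (inclusion rule n > 4)",
         call. = FALSE)
  }
  if (is.null(platform_mix)) {
    platform_mix <- rep("array", n_studies)
    if (n_studies >= 21) {
      platform_mix[(n_studies - 1):n_studies] <- "rnaseq"
    }
  }
  if (length(platform_mix) != n_studies ||
      !all(platform_mix %in% c("array", "rnaseq"))) {
    stop("'platform_mix' must label each study 'array' or 'rnaseq'",
         call. = FALSE)
  }
  structure(list(n_studies = as.integer(n_studies),
                 n_genes = as.integer(n_genes),
                 de_fraction = de_fraction,
                 effect_size_mean = effect_size_mean, tau = tau,
                 coverage_fraction = coverage_fraction,
                 core_fraction = core_fraction,
                 sample_sizes = sample_sizes,
                 platform_mix = platform_mix, noise_sd = noise_sd,
                 nb_dispersion = nb_dispersion,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-study expression compendium with known ground truth
#'
#' Gene-level truths are drawn once from the global seed: a random DE subset
#' receives true mean effects `mu_g = +/- effect_size_mean` with per-gene
#' heterogeneity `tau_g = tau` (null genes have `mu_g = 0`, `tau_g = 0`), and
#' per-gene baseline log2 intensities are Normal(`baseline_mean`,
#' `baseline_sd`). Each study then draws from its own derived seed stream (so
#' adding studies never reshuffles earlier ones): a Bernoulli coverage mask
#' (core genes always covered), realized per-study effects
#' `delta_gj ~ Normal(mu_g, tau_g^2)`, and data. Array studies are Gaussian
#' log2 intensities with the case/control shift `delta_gj`; RNA-seq studies
#' are negative-binomial counts with log-normal library sizes around 1e6
#' whose case/control log2 mean ratio equals `delta_gj`.
#'
#' @param config A [simulation_config()].
#' @return List with `studies` (list of [expression_study()]) and `truth`, a
#'   `truth_manifest`: list with `genes`, `mu`, `tau` (per-gene), `de`
#'   (logical), `coverage` (gene x study logical matrix), `delta` (realized
#'   per-study effects, `NA` where unmeasured), `n_measured`,
#'   `never_measured` (flag for genes covered by no study), `config`.
#' @export
simulate_multistudy <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  G <- config$n_genes
  genes <- sprintf("G%05d", seq_len(G))
  set.seed(config$seed)
  n_de <- round(config$de_fraction * G)
  de_idx <- if (n_de > 0) sample(G, n_de) else integer(0)
  mu <- numeric(G)
  if (n_de > 0) {
    mu[de_idx] <- config$effect_size_mean * sample(c(-1, 1), n_de,
                                                   replace = TRUE)
  }
  tau_g <- ifelse(mu != 0, config$tau, 0)
  baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  core <- sample(G, round(config$core_fraction * G))

  coverage <- matrix(FALSE, G, config$n_studies,
                     dimnames = list(genes, sprintf("study_%02d",
                                                    seq_len(config$n_studies))))
  delta <- matrix(NA_real_, G, config$n_studies,
                  dimnames = dimnames(coverage))
  studies <- vector("list", config$n_studies)
  for (j in seq_len(config$n_studies)) {
    set.seed(derive_seed(config$seed, j))
    cov_j <- stats::runif(G) < config$coverage_fraction
    cov_j[core] <- TRUE
    d_j <- stats::rnorm(G, mu, tau_g)
    coverage[, j] <- cov_j
    delta[cov_j, j] <- d_j[cov_j]
    nc <- config$sample_sizes$n_control[j]
    nt <- config$sample_sizes$n_case[j]
    id <- sprintf("study_%02d", j)
    grp <- rep(c("control", "case"), c(nc, nt))
    snames <- sprintf("%s_%s%02d", id, ifelse(grp == "case", "T", "C"),
                      c(seq_len(nc), seq_len(nt)))
    gsub <- genes[cov_j]
    if (config$platform_mix[j] == "array") {
      m <- baseline[cov_j] +
        matrix(stats::rnorm(sum(cov_j) * (nc + nt), 0, config$noise_sd),
               sum(cov_j), nc + nt)
      m[, grp == "case"] <- m[, grp == "case"] + d_j[cov_j]
      dimnames(m) <- list(gsub, snames)
      studies[[j]] <- expression_study(m, grp, id, platform = "array",
                                       normalization_state = "normalized_log2")
    } else {
      p_g <- 2^baseline[cov_j]
      p_g <- p_g / sum(p_g)
      lib <- stats::rlnorm(nc + nt, meanlog = log(1e6), sdlog = 0.3)
      mu_mat <- outer(p_g, lib)
      mu_mat[, grp == "case"] <- mu_mat[, grp == "case"] * 2^d_j[cov_j]
      cnt <- matrix(stats::rnbinom(length(mu_mat),
                                   size = 1 / config$nb_dispersion,
                                   mu = mu_mat),
                    nrow(mu_mat), ncol(mu_mat), dimnames = list(gsub, snames))
      studies[[j]] <- expression_study(cnt, grp, id, platform = "rnaseq",
                                       normalization_state = "raw_counts")
    }
  }
  n_measured <- rowSums(coverage)
  truth <- structure(list(genes = genes, mu = setNames(mu, genes),
                          tau = setNames(tau_g, genes),
                          de = setNames(mu != 0, genes),
                          coverage = coverage, delta = delta,
                          n_measured = setNames(n_measured, genes),
                          never_measured = setNames(n_measured == 0, genes),
                          config = config),
                     class = "truth_manifest")
  list(studies = studies, truth = truth)
}

#' Simulate an expression-linked survival cohort
#'
#' A balanced latent high-/low-risk label is drawn; signature-gene expression
#' is `signal_shift * label + Normal(0, 1)` (then z-scored per gene) so that
#' z-scores correlate with the latent risk, and noise genes are independent
#' standard normals. Event times are exponential with rate
#' `baseline_rate * hazard_ratio^label`; censoring is independent exponential
#' with rate `censoring_rate` (none when 0). The defaults mirror a
#' TCGA-PAAD-sized cohort: 180 samples, a 28-gene signature, hazard ratio
#' 2.36 for the high-risk class, and a baseline rate of 0.035 events/month
#' (median survival near 20 months).
#'
#' @param n_samples Number of samples (>= 8).
#' @param signature_size Number of risk-linked signature genes.
#' @param hazard_ratio Hazard multiplier (> 0) for the high-risk class.
#' @param baseline_rate Baseline exponential event rate (events per time
#'   unit, > 0).
#' @param censoring_rate Exponential censoring rate (>= 0; 0 = no censoring).
#' @param signal_shift Mean expression shift of signature genes in high-risk
#'   samples (SD units).
#' @param n_noise_genes Unrelated genes added to the matrix.
#' @param seed Integer seed.
#' @return List with `cohort` (a [survival_cohort()]) and `truth` (list with
#'   `label` (1 = latent high risk), `signature` gene IDs, `hazard_ratio`,
#'   `baseline_rate`, `censoring_rate`).
#' @export
simulate_survival_cohort <- function(n_samples = 180, signature_size = 28,
                                     hazard_ratio = 2.36,
                                     baseline_rate = 0.035,
                                     censoring_rate = 0.01,
                                     signal_shift = 1.5,
                                     n_noise_genes = 72, seed = 1) {
  if (n_samples < 8) stop("'n_samples' must be at least 8", call. = FALSE)
  if (hazard_ratio <= 0) stop("'hazard_ratio' must be positive", call. = FALSE)
  if (baseline_rate <= 0) stop("'baseline_rate' must be positive", call. = FALSE)
  if (censoring_rate < 0) stop("'censoring_rate' must be non-negative",
                               call. = FALSE)
  set.seed(seed)
  label <- sample(rep(c(0L, 1L), length.out = n_samples))
  sig_genes <- sprintf("SIG%03d", seq_len(signature_size))
  noise_genes <- sprintf("NOISE%03d", seq_len(n_noise_genes))
  expr <- rbind(
    matrix(stats::rnorm(signature_size * n_samples), signature_size,
           n_samples) + matrix(signal_shift * label, signature_size,
                               n_samples, byrow = TRUE),
    matrix(stats::rnorm(n_noise_genes * n_samples), n_noise_genes, n_samples)
  )
  rownames(expr) <- c(sig_genes, noise_genes)
  colnames(expr) <- sprintf("S%03d", seq_len(n_samples))
  z <- zscore_matrix(expr)
  rate <- baseline_rate * hazard_ratio^label
  t_event <- stats::rexp(n_samples, rate)
  t_cens <- if (censoring_rate > 0) {
    stats::rexp(n_samples, censoring_rate)
  } else {
    rep(Inf, n_samples)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  cohort <- survival_cohort(time, event, z)
  truth <- list(label = setNames(label, colnames(z)), signature = sig_genes,
                hazard_ratio = hazard_ratio, baseline_rate = baseline_rate,
                censoring_rate = censoring_rate)
  list(cohort = cohort, truth = truth)
}
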