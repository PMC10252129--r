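# In-code fixture builders shared across tests.

# Small array-like study with optional case-vs-control shift on some genes.
make_array_study <- function(n_genes = 40, n_control = 6, n_case = 6,
                             effect = 0, de_genes = integer(0), seed = 1,
                             id = "study_x", noise_sd = 0.5) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  grp <- rep(c("control", "case"), c(n_control, n_case))
  m <- matrix(rnorm(n_genes * (n_control + n_case), mean = 8, sd = noise_sd),
              n_genes, n_control + n_case,
              dimnames = list(genes, sprintf("%s_s%02d", id,
                                             seq_len(n_control + n_case))))
  if (length(de_genes) > 0) {
    m[de_genes, grp == "case"] <- m[de_genes, grp == "case"] + effect
  }
  expression_study(m, grp, id, platform = "array",
                   normalization_state = "normalized_log2")
}

# Hand-built per-study DGE table (for meta-analysis inputs with controlled
# coverage and effects).
make_dge <- function(study_id, genes, log2fc, se) {
  structure(data.frame(gene = genes, log2fc = log2fc, se = se,
                       df = 10, t = log2fc / se,
                       p = 2 * pt(-abs(log2fc / se), df = 10),
                       fdr = NA_real_, stringsAsFactors = FALSE),
            class = c("dge_result", "data.frame"), study_id = study_id)
}

# Three-study simulation used by pipeline tests.
small_sim_config <- function(seed = 11) {
  simulation_config(
    n_studies = 3, n_genes = 120, de_fraction = 0.15,
    effect_size_mean = 1.2, tau = 0.15, coverage_fraction = 0.9,
    core_fraction = 0.3,
    sample_sizes = data.frame(n_control = c(6, 8, 7),
                              n_case = c(7, 9, 8)),
    platform_mix = c("array", "array", "array"), seed = seed)
}

small_pipeline_config <- function(out_dir, seed = 11, gmt = NULL) {
  pipeline_config(
    out_dir = out_dir,
    sim = small_sim_config(seed),
    meta = meta_config(min_studies = 3, min_presence = 2),
    gmt = gmt, min_overlap = 3,
    cohort = list(n_samples = 60, signature_size = 6, n_noise_genes = 20,
                  hazard_ratio = 2.5, censoring_rate = 0.01),
    seed = seed)
}

# GMT file covering genes of the small simulation, with one set enriched in
# the true DE genes.
write_small_gmt <- function(truth, path) {
  genes <- truth$genes
  de <- names(truth$de)[truth$de]
  set.seed(5)
  sets <- list(
    DE_HEAVY = unique(c(de, sample(genes, 5))),
    RANDOM_A = sample(genes, 25),
    RANDOM_B = sample(genes, 30),
    SMALL = sample(genes, 4)
  )
  coll <- gene_set_collection(sets)
  write_gmt(coll, path)
  path
}
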