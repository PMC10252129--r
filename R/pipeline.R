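#' Pipeline configuration
#'
#' Validates and bundles everything [run_pipeline()] needs: the simulation
#' settings (or pre-built studies), meta-analysis thresholds, optional
#' gene-set collection, survival-cohort settings and the output directory.
#' Referenced files are checked at validation time so configuration errors
#' surface before any compute.
#'
#' @param out_dir Output directory (created if needed; must be writable).
#' @param sim A [simulation_config()] describing the synthetic compendium.
#' @param meta A [meta_config()].
#' @param gmt Optional path to a GMT file for the enrichment stage (skipped
#'   when `NULL`).
#' @param min_overlap,ora_fdr_max ORA reporting thresholds (see [ora()]).
#' @param cohort Named list of arguments for [simulate_survival_cohort()]
#'   (`seed` is supplied by the pipeline).
#' @param signature Optional signature gene IDs for the survival stage;
#'   default: the cohort's true signature genes.
#' @param seed Master seed; feeds the simulation and the survival cohort.
#' @param moderated Use moderated t-statistics in the DGE stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = simulation_config(),
                            meta = meta_config(), gmt = NULL,
                            min_overlap = 10, ora_fdr_max = 0.05,
                            cohort = list(), signature = NULL, seed = 1,
                            moderated = TRUE) {
  if (!is.null(gmt) && !file.exists(gmt)) {
    stop(sprintf("configuration error: GMT file not found: %s", gmt),
         call. = FALSE)
  }
  stopifnot(inherits(sim, "simulation_config"), inherits(meta, "meta_config"))
  structure(list(out_dir = out_dir, sim = sim, meta = meta, gmt = gmt,
                 min_overlap = min_overlap, ora_fdr_max = ora_fdr_max,
                 cohort = cohort, signature = signature,
                 seed = as.integer(seed), moderated = isTRUE(moderated)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The YAML may contain top-level keys `out_dir`, `seed`, `gmt`,
#' `min_overlap`, `ora_fdr_max`, `moderated`, `signature`, and nested maps
#' `sim` (arguments of [simulation_config()]), `meta` (arguments of
#' [meta_config()]) and `cohort` (arguments of
#' [simulate_survival_cohort()]).
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path, out_dir = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("configuration error: file not found: %s", path),
         call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, y$sim %||% list())
  meta <- do.call(meta_config, y$meta %||% list())
  pipeline_config(out_dir = out_dir %||% y$out_dir %||%
                    stop("configuration error: out_dir missing", call. = FALSE),
                  sim = sim, meta = meta, gmt = y$gmt,
                  min_overlap = y$min_overlap %||% 10,
                  ora_fdr_max = y$ora_fdr_max %||% 0.05,
                  cohort = y$cohort %||% list(),
                  signature = unlist(y$signature),
                  seed = y$seed %||% 1,
                  moderated = y$moderated %||% TRUE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full synthetic meta-analysis pipeline
#'
#' Executes simulate -> per-study DGE -> random-effects meta-analysis (with
#' leave-one-out stability for significant genes) -> optional ORA -> survival
#' signature, each stage consuming the previous stage's outputs, and writes a
#' JSON run manifest echoing every threshold used plus per-stage row counts.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest` (also written to
#'   `manifest.json`), `files`, `meta` (the `meta_result`), `signature` (the
#'   `signature_result`) and `cox` (risk-group Cox fit).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  ok <- dir.exists(out) || dir.create(out, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok) stop(sprintf("configuration error: cannot create '%s'", out),
                call. = FALSE)

  # stage 1: simulate
  sim_cfg <- config$sim
  sim_cfg$seed <- config$seed
  sim <- run_stage("simulate", {
    sim <- simulate_multistudy(sim_cfg)
    coh_args <- config$cohort
    coh_args$seed <- derive_seed(config$seed, 7777)
    coh <- do.call(simulate_survival_cohort, coh_args)
    sim$truth$survival <- list(hazard_ratio = coh$truth$hazard_ratio,
                               baseline_rate = coh$truth$baseline_rate,
                               censoring_rate = coh$truth$censoring_rate,
                               signature = coh$truth$signature)
    data_dir <- file.path(out, "data")
    files <- write_fixtures(sim$studies, coh$cohort, data_dir,
                            truth = sim$truth)
    list(studies = sim$studies, truth = sim$truth, cohort = coh$cohort,
         cohort_truth = coh$truth, files = files)
  })
  message(sprintf("simulate: %d studies, %d genes, cohort of %d samples",
                  length(sim$studies), sim_cfg$n_genes,
                  nrow(sim$cohort$samples)))

  # stage 2: per-study differential expression
  dge <- run_stage("dge", {
    lapply(sim$studies, function(st) {
      fit_dge(normalize_study(st), moderated = config$moderated)
    })
  })
  dge_files <- vapply(dge, function(d) {
    p <- file.path(out, sprintf("dge_%s.tsv", attr(d, "study_id")))
    write_dge_table(d, p)
    p
  }, character(1))
  names(dge_files) <- vapply(dge, attr, character(1), "study_id")
  message(sprintf("dge: %d studies fitted", length(dge)))

  # stage 3: meta-analysis
  meta <- run_stage("meta", {
    m <- run_meta(dge, config = config$meta)
    add_loo_stability(m)
  })
  meta_file <- file.path(out, "meta.tsv")
  write.table(as.data.frame(meta), meta_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  n_sig <- sum(meta$significant)
  message(sprintf("meta: %d genes evaluated, %d significant", nrow(meta),
                  n_sig))

  # stage 4: over-representation analysis (optional)
  ora_counts <- NULL
  ora_files <- character(0)
  if (!is.null(config$gmt)) {
    ora_res <- run_stage("ora", {
      coll <- read_gmt(config$gmt)
      universe <- intersect(meta$gene, coll$universe)
      up <- meta$gene[meta$significant & meta$pooled > 0]
      down <- meta$gene[meta$significant & meta$pooled < 0]
      list(up = ora(up, coll, universe = universe,
                    min_overlap = config$min_overlap,
                    fdr_max = config$ora_fdr_max),
           down = ora(down, coll, universe = universe,
                      min_overlap = config$min_overlap,
                      fdr_max = config$ora_fdr_max))
    })
    for (dir_ in c("up", "down")) {
      p <- file.path(out, sprintf("ora_%s.tsv", dir_))
      write.table(as.data.frame(ora_res[[dir_]]), p, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ora_files[paste0("ora_", dir_)] <- p
    }
    ora_counts <- list(up = nrow(ora_res$up), down = nrow(ora_res$down))
    message(sprintf("ora: %d up / %d down terms reported", ora_counts$up,
                    ora_counts$down))
  }

  # stage 5: survival signature
  surv <- run_stage("survival", {
    genes <- config$signature %||% sim$cohort_truth$signature
    sc <- signature_score(sim$cohort, genes)
    cox <- cox_fit(sim$cohort,
                   data.frame(risk_high = as.integer(sc$risk == "high")))
    list(signature = sc, cox = cox)
  })
  km_file <- file.path(out, "km.tsv")
  km_tab <- do.call(rbind, lapply(c("high", "low"), function(g) {
    k <- surv$signature$km[[g]]
    if (is.null(k)) return(NULL)
    cbind(group = g, as.data.frame(k))
  }))
  write.table(km_tab, km_file, sep = "\t", quote = FALSE, row.names = FALSE)
  assign_file <- file.path(out, "signature_assignments.csv")
  write.csv(data.frame(sample_id = names(surv$signature$risk),
                       count = surv$signature$counts,
                       risk = surv$signature$risk, row.names = NULL),
            assign_file, row.names = FALSE, quote = FALSE)
  surv_json <- file.path(out, "survival_summary.json")
  jsonlite::write_json(list(
    n_genes = length(surv$signature$genes),
    cutoff = surv$signature$cutoff,
    n_high = sum(surv$signature$risk == "high"),
    n_low = sum(surv$signature$risk == "low"),
    logrank_statistic = surv$signature$logrank$statistic,
    logrank_p = surv$signature$logrank$p,
    cox_hr = surv$cox$coefficients$hr[1],
    cox_p = surv$cox$coefficients$p[1]
  ), surv_json, auto_unbox = TRUE, digits = NA)
  message(sprintf("survival: cutoff %g, log-rank p = %.3g",
                  surv$signature$cutoff, surv$signature$logrank$p))

  files <- c(sim$files, setNames(dge_files, paste0("dge_", names(dge_files))),
             meta = meta_file, ora_files, km = km_file,
             assignments = assign_file, survival_summary = surv_json)
  # paths relative to out_dir: manifests of identical runs are byte-identical
  rel_files <- substring(files, nchar(out) + 2L)
  manifest <- list(
    parameters = list(
      seed = config$seed,
      n_studies = sim_cfg$n_studies, n_genes = sim_cfg$n_genes,
      de_fraction = sim_cfg$de_fraction, tau = sim_cfg$tau,
      coverage_fraction = sim_cfg$coverage_fraction,
      core_fraction = sim_cfg$core_fraction,
      moderated = config$moderated,
      fdr_max = config$meta$fdr_max, lfc_min = config$meta$lfc_min,
      min_studies = config$meta$min_studies,
      min_presence = config$meta$min_presence,
      ora_min_overlap = config$min_overlap,
      ora_fdr_max = config$ora_fdr_max
    ),
    counts = list(
      studies = length(sim$studies),
      genes_evaluated = nrow(meta),
      genes_significant = n_sig,
      loo_stable = sum(meta$loo_stable, na.rm = TRUE),
      ora = ora_counts,
      cohort_samples = nrow(sim$cohort$samples),
      cohort_events = sum(sim$cohort$samples$event)
    ),
    files = as.list(setNames(rel_files, names(files)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, files = files, meta = meta,
                 signature = surv$signature, cox = surv$cox))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  hdr <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                               collapse = ""), "</tr>")
  rows <- apply(df, 1L, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(format(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  paste0("<table border='1' cellpadding='3'>", hdr,
         paste(rows, collapse = "\n"), "</table>")
}

#' Export a static HTML report for a completed run
#'
#' Renders significant-gene counts, the top of the meta-analysis table, ORA
#' term counts and the survival-signature summary from the TSV/JSON outputs
#' of [run_pipeline()] (every number in the report is traceable to those
#' files). KM and forest plots are attempted with base graphics; if no
#' graphics device is available the report notes it and the tables stand.
#'
#' @param run_dir Output directory of a completed [run_pipeline()] run.
#' @param top_n Number of top genes to tabulate.
#' @return Path of the written `report.html`, invisibly.
#' @export
export_report <- function(run_dir, top_n = 20) {
  manifest_path <- file.path(run_dir, "manifest.json")
  meta_path <- file.path(run_dir, "meta.tsv")
  missing <- c(manifest = manifest_path, meta = meta_path)
  missing <- missing[!file.exists(missing)]
  if (length(missing) > 0L) {
    stop(sprintf("incomplete run: missing %s",
                 paste(names(missing), collapse = ", ")), call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  n_sig <- sum(meta$significant)
  top <- head(meta[, c("gene", "k", "pooled", "se", "p", "fdr",
                       "significant")], top_n)
  top[, c("pooled", "se")] <- round(top[, c("pooled", "se")], 3)
  top[, c("p", "fdr")] <- signif(top[, c("p", "fdr")], 3)

  parts <- c(
    "<html><head><title>txmeta run report</title></head><body>",
    "<h1>Multi-study expression meta-analysis report</h1>",
    sprintf("<p>%d studies; %d genes evaluated; <b>%d significant genes</b> (FDR &lt; %s, |log2FC| &gt; %s, k &ge; %s).</p>",
            manifest$counts$studies, manifest$counts$genes_evaluated, n_sig,
            manifest$parameters$fdr_max, manifest$parameters$lfc_min,
            manifest$parameters$min_studies),
    sprintf("<h2>Top %d genes</h2>", nrow(top)),
    html_table(top)
  )
  if (!is.null(manifest$counts$ora)) {
    parts <- c(parts, sprintf(
      "<p>ORA: %d over-expressed / %d under-expressed terms reported (overlap &ge; %s, FDR &lt; %s).</p>",
      manifest$counts$ora$up, manifest$counts$ora$down,
      manifest$parameters$ora_min_overlap, manifest$parameters$ora_fdr_max))
  }
  surv_path <- file.path(run_dir, "survival_summary.json")
  if (file.exists(surv_path)) {
    ss <- jsonlite::read_json(surv_path)
    parts <- c(parts, sprintf(
      "<p>Survival signature (%s genes): cutoff %s highly expressed genes; %s high-risk vs %s low-risk; log-rank p = %.3g; risk-group HR = %.2f.</p>",
      ss$n_genes, ss$cutoff, ss$n_high, ss$n_low, ss$logrank_p, ss$cox_hr))
    km_png <- file.path(run_dir, "km.png")
    km_ok <- tryCatch({
      km <- read.delim(file.path(run_dir, "km.tsv"))
      grDevices::png(km_png, width = 640, height = 480)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot(NA, xlim = c(0, max(km$time)), ylim = c(0, 1),
           xlab = "time", ylab = "S(t)", main = "Signature risk groups")
      for (g in unique(km$group)) {
        kk <- km[km$group == g, ]
        graphics::lines(stats::stepfun(kk$time, c(1, kk$survival)),
                        do.points = FALSE,
                        col = if (g == "high") "red" else "blue")
      }
      graphics::legend("topright", legend = c("high", "low"),
                       col = c("red", "blue"), lty = 1)
      TRUE
    }, error = function(e) FALSE)
    parts <- c(parts, if (km_ok) "<p><img src='km.png'/></p>" else
      "<p>(KM plot unavailable: no graphics device.)</p>")
  }
  if (n_sig == 0L) {
    parts <- c(parts, "<p><b>0 significant genes</b> at the configured thresholds.</p>")
  }
  parts <- c(parts, "</body></html>")
  report <- file.path(run_dir, "report.html")
  writeLines(parts, report)
  invisible(report)
}
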