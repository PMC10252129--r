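#' Read and write expression matrices and sample sheets
#'
#' TSV expression matrices have genes as rows, a header row of sample IDs and
#' gene IDs in the first column. Count matrices use MatrixMarket (`.mtx`)
#' coordinate format with plain-text row (gene) and column (sample) name
#' files. Sample sheets are CSV with columns `sample_id,group,pair_id`;
#' survival tables are CSV with columns `sample_id,time,event`.
#'
#' @param x Numeric matrix to write.
#' @param path Output/input path.
#' @return Readers return the parsed object; writers return the path
#'   invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
}

#' @rdname write_expression_matrix
#' @param counts Integer count matrix.
#' @param path_mtx,path_genes,path_samples Paths for the MatrixMarket file and
#'   the row/column name files.
#' @export
write_count_matrix <- function(counts, path_mtx, path_genes, path_samples) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path_mtx)
  writeLines(rownames(counts), path_genes)
  writeLines(colnames(counts), path_samples)
  invisible(path_mtx)
}

#' @rdname write_expression_matrix
#' @export
read_count_matrix <- function(path_mtx, path_genes, path_samples) {
  m <- as.matrix(Matrix::readMM(path_mtx))
  storage.mode(m) <- "double"
  m <- round(m)
  dimnames(m) <- list(readLines(path_genes), readLines(path_samples))
  m
}

#' @rdname write_expression_matrix
#' @param samples Sample sheet data frame (`sample_id`, `group`, `pair_id`).
#' @export
write_sample_sheet <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_sample_sheet <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(pair_id = "character"))
}

#' @rdname write_expression_matrix
#' @param table Survival table data frame (`sample_id`, `time`, `event`).
#' @export
write_survival_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_survival_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a simulated compendium to disk
#'
#' Array studies produce `<id>_expr.tsv` + `<id>_samples.csv`; RNA-seq
#' studies produce `<id>_counts.mtx`, `<id>_genes.txt`, `<id>_colnames.txt` +
#' `<id>_samples.csv`. A survival cohort adds `survival.csv` and
#' `survival_expr.tsv`; a truth manifest adds `truth.json` (gene-level truths
#' and the coverage mask; the realized per-study effect matrix stays
#' in-memory). All files round-trip through the package readers (float
#' formatting tolerance 1e-9; counts integer-exact).
#'
#' @param studies List of [expression_study()] objects.
#' @param cohort Optional [survival_cohort()].
#' @param out_dir Output directory (created if missing).
#' @param truth Optional `truth_manifest` from [simulate_multistudy()], with
#'   optional element `survival` merged from the cohort truth.
#' @return Named character vector of written file paths (the file manifest).
#' @export
write_fixtures <- function(studies, cohort = NULL, out_dir, truth = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L) {
    stop(sprintf("cannot write to directory '%s'", out_dir), call. = FALSE)
  }
  files <- character(0)
  for (st in studies) {
    id <- st$study_id
    if (st$platform == "rnaseq" && st$normalization_state == "raw_counts") {
      p <- file.path(out_dir, paste0(id, c("_counts.mtx", "_genes.txt",
                                           "_colnames.txt")))
      write_count_matrix(st$matrix, p[1], p[2], p[3])
      files <- c(files, setNames(p, paste0(id, c("_counts", "_genes",
                                                 "_colnames"))))
    } else {
      p <- file.path(out_dir, paste0(id, "_expr.tsv"))
      write_expression_matrix(st$matrix, p)
      files <- c(files, setNames(p, paste0(id, "_expr")))
    }
    ps <- file.path(out_dir, paste0(id, "_samples.csv"))
    write_sample_sheet(st$samples, ps)
    files <- c(files, setNames(ps, paste0(id, "_samples")))
  }
  if (!is.null(cohort)) {
    p1 <- file.path(out_dir, "survival.csv")
    write_survival_table(cohort$samples, p1)
    p2 <- file.path(out_dir, "survival_expr.tsv")
    write_expression_matrix(cohort$z, p2)
    files <- c(files, survival = p1, survival_expr = p2)
  }
  if (!is.null(truth)) {
    p <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(
      genes = truth$genes,
      mu = unname(truth$mu),
      tau = unname(truth$tau),
      de = unname(truth$de),
      n_measured = unname(truth$n_measured),
      never_measured = unname(truth$never_measured),
      coverage = unname(apply(truth$coverage, 2L, as.integer)),
      survival = truth$survival
    ), p, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth = p)
  }
  files
}

#' Read a study back from fixture files
#'
#' Reconstructs an [expression_study()] written by [write_fixtures()].
#'
#' @param dir Fixture directory.
#' @param study_id Study identifier (file prefix).
#' @param platform `"array"` or `"rnaseq"`.
#' @return An [expression_study()].
#' @export
read_study <- function(dir, study_id, platform = c("array", "rnaseq")) {
  platform <- match.arg(platform)
  samples <- read_sample_sheet(file.path(dir, paste0(study_id,
                                                     "_samples.csv")))
  if (platform == "array") {
    m <- read_expression_matrix(file.path(dir, paste0(study_id, "_expr.tsv")))
    state <- "normalized_log2"
  } else {
    m <- read_count_matrix(file.path(dir, paste0(study_id, "_counts.mtx")),
                           file.path(dir, paste0(study_id, "_genes.txt")),
                           file.path(dir, paste0(study_id, "_colnames.txt")))
    state <- "raw_counts"
  }
  m <- m[, samples$sample_id, drop = FALSE]
  pid <- samples$pair_id
  if (all(is.na(pid) | pid == "")) pid <- NULL
  expression_study(m, samples$group, study_id, platform = platform,
                   pair_id = pid, normalization_state = state)
}
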