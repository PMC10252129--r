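#' Gene-set collection
#'
#' A named list of gene sets with descriptions and a gene universe. The
#' default universe is the union of all set members; in a meta-analysis
#' context it should be restricted to the evaluated genes (see [ora()]).
#'
#' @param sets Named list of character vectors (gene IDs). Duplicate genes
#'   within a set are removed; duplicate set names are an error.
#' @param descriptions Optional named character vector of set descriptions.
#' @param universe Optional character vector defining the gene universe.
#' @return A `gene_set_collection` list with `sets`, `descriptions`,
#'   `universe`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (length(sets) > 0 &&
      (is.null(names(sets)) || anyDuplicated(names(sets)))) {
    stop("gene sets must have unique names", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited GMT dialect: each line is
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are deduplicated; duplicate set names or lines with fewer than three
#' fields raise an error naming the offending line. An empty file yields an
#' empty (valid) collection.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 bad[1]), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate gene-set name '%s'", nm[duplicated(nm)][1]),
         call. = FALSE)
  }
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), nm)
  sets <- setNames(lapply(fields, function(f) unique(f[-(1:2)])), nm)
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "",
            collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis (hypergeometric test)
#'
#' For each gene set, tests whether the significant list overlaps the set more
#' than expected by chance: with a universe of `N` genes of which `K` are in
#' the set and a significant list of `n` genes with `k` in the set, the
#' p-value is the hypergeometric upper tail `P(X >= k)`. P-values are
#' BH-adjusted across all tested terms (every term with `K >= 1` in the
#' universe); the reported table keeps terms with `overlap >= min_overlap` and
#' `FDR < fdr_max`, sorted by FDR. Filtering happens after the adjustment so
#' the FDR is not biased by the size filter.
#'
#' @param significant Character vector of significant gene IDs. Genes outside
#'   the universe are dropped (a message reports how many).
#' @param collection A [gene_set_collection()].
#' @param universe Optional universe override (e.g. the genes evaluated in the
#'   meta-analysis); intersected with nothing else, must be non-empty.
#' @param min_overlap Minimum overlap for a term to be reported (default 10,
#'   the "at least ten differentially expressed genes in the set" rule).
#' @param fdr_max FDR threshold for reported terms (default 0.05).
#' @param report_all Return all tested terms instead of the filtered table.
#' @return An `ora_result` data frame with columns `term`, `description`,
#'   `k`, `K`, `n`, `N`, `p`, `fdr`, `genes` (comma-separated overlap).
#'   Attribute `tested` holds the unfiltered table.
#' @export
ora <- function(significant, collection, universe = NULL,
                min_overlap = 10, fdr_max = 0.05, report_all = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe %||% collection$universe)
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  significant <- unique(as.character(significant))
  dropped <- sum(!significant %in% universe)
  if (dropped > 0L) {
    message(sprintf("ora: %d significant gene(s) outside the universe dropped",
                    dropped))
  }
  sig <- intersect(significant, universe)
  N <- length(universe)
  n <- length(sig)
  rows <- lapply(names(collection$sets), function(nm) {
    set_u <- intersect(collection$sets[[nm]], universe)
    K <- length(set_u)
    if (K < 1L) return(NULL)
    hits <- intersect(sig, set_u)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm,
               description = collection$descriptions[[nm]] %||% "",
               k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    tested <- data.frame(term = character(), description = character(),
                         k = integer(), K = integer(), n = integer(),
                         N = integer(), p = numeric(), fdr = numeric(),
                         genes = character(), stringsAsFactors = FALSE)
  } else {
    tested <- do.call(rbind, rows)
    tested$fdr <- bh_adjust(tested$p)
    tested <- tested[order(tested$fdr, tested$p),
                     c("term", "description", "k", "K", "n", "N",
                       "p", "fdr", "genes")]
    rownames(tested) <- NULL
  }
  out <- if (report_all) tested else
    tested[tested$k >= min_overlap & tested$fdr < fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ora_result", "data.frame"), tested = tested)
}
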