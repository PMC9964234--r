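#' Load gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene symbols. Duplicate genes within a line are collapsed, keeping first
#' occurrence order.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> genes).
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(stats::setNames(list(), character(0)))
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line ", i, ": need name, description and >=1 gene")
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      stop("malformed GMT line ", i, ": empty gene list")
    out[[parts[1]]] <- unique(genes)
  }
  out
}

#' Extract the expression rows of one gene set
#'
#' Rows are matched on gene symbol (the `gene_symbol` annotation, falling
#' back to rownames), keeping original row order; several probes of the same
#' gene all stay.
#'
#' @param m Expression matrix.
#' @param genes Character vector of gene symbols (one gene set).
#' @param missing_policy `"warn"` (default) logs genes with no matching row;
#'   `"error"` makes them fatal.
#' @return The row subset of `m`.
#' @export
subset_matrix <- function(m, genes, missing_policy = c("warn", "error")) {
  missing_policy <- match.arg(missing_policy)
  gs <- gene_symbols(m)
  hit <- which(unname(gs) %in% genes)
  absent <- setdiff(genes, gs)
  if (length(absent) > 0) {
    msg <- paste0("gene(s) not in matrix: ", paste(absent, collapse = ", "))
    if (missing_policy == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  if (length(hit) == 0) stop("no genes of the set found in the matrix")
  subset_rows(m, hit)
}

#' Distinct-gene union over gene sets
#'
#' @param sets List of character vectors (as from [load_gene_sets()]).
#' @return Sorted distinct union of all genes.
#' @export
sets_gene_union <- function(sets) {
  sort(unique(unlist(sets, use.names = FALSE)))
}

#' Packaged pathway gene sets of the astronaut study
#'
#' The 11 pathway memberships (differentially expressed genes per enriched
#' pathway) published for dataset E-GEOD-74708, shipped as a GMT fixture.
#'
#' @return Named list of gene symbol vectors.
#' @export
astro_pathway_sets <- function() {
  load_gene_sets(system.file("extdata", "egeod74708_pathways.gmt",
                             package = "ccrewire", mustWork = TRUE))
}

#' Packaged pair-correlation table of the astronaut study
#'
#' The published per-pathway gene-pair Pearson correlations (pre-flight and
#' in-flight) for every pair whose differential passed the 0.70 cut in
#' dataset E-GEOD-74708, plus the published differential. This table is the
#' package's executable worked example: feeding it through
#' [classify_pairs()] and [select_panel()] reproduces the published
#' biomarker panel.
#'
#' @return data.frame with columns `pathway`, `gene_a`, `gene_b`, `cc_pre`,
#'   `cc_in`, `dcc_printed`.
#' @export
astro_pair_cc <- function() {
  utils::read.delim(system.file("extdata", "egeod74708_pair_cc.tsv",
                                package = "ccrewire", mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
}
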