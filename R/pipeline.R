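#' Load a pipeline configuration file
#'
#' Flat YAML or JSON mirroring the arguments of [run_pipeline()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML configs")
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is needed for JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json: ", path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the differential-correlation pipeline end to end
#'
#' Two input modes:
#' \describe{
#'   \item{expression mode}{`expression_paths` + `sample_sheet` (path or
#'     data.frame): profiles are assembled, null rows dropped, probes
#'     annotated, the matrix split by condition; DEGs are called for the
#'     contrast, per-pathway correlation and differential matrices computed,
#'     and the pair screen plus panel assembly applied.}
#'   \item{precomputed-CC mode}{`pair_cc` (path or data.frame with columns
#'     `gene_a`, `gene_b`, `cc_a`, `cc_b` and optional `pathway`): the
#'     correlation stage is bypassed and the screen runs directly on the
#'     given values — this makes a published pair-correlation table an
#'     executable input.}
#' }
#' Outputs are written as TSV in `out_dir` with deterministic ordering, plus
#' a `manifest.tsv` recording configuration, package version, seed and the
#' row count of every output.
#'
#' @param cfg Named list (or path loadable by [read_pipeline_config()]) with
#'   fields: `out_dir`; expression mode: `expression_paths`, `sample_sheet`,
#'   optional `probe_map`, `gene_sets` (GMT path), `scale` ("log2"/"linear");
#'   precomputed mode: `pair_cc`; shared thresholds `lfc_cut` (3.00),
#'   `p_cut` (0.05), `delta_cut` (0.70); contrast `from`/`to` (default
#'   "Pre"/"In"); `quiet`.
#' @return Invisibly, a list with the in-memory results (`pairs`,
#'   `selected`, `panel`, and in expression mode `degs`, `correlations`,
#'   `deltas`) and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) cfg <- read_pipeline_config(cfg)
  quiet <- isTRUE(cfg$quiet)
  say <- function(...) if (!quiet) message("[ccrewire] ", ...)
  out_dir <- cfg$out_dir %||% stop("cfg$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  delta_cut <- cfg$delta_cut %||% 0.70
  from <- cfg$from %||% "Pre"; to <- cfg$to %||% "In"
  if (!all(c(from, to) %in% c("Pre", "In", "Post")))
    stop("unknown condition label in contrast: ", from, " vs ", to)
  manifest <- list(package = "ccrewire",
                   version = as.character(utils::packageVersion("ccrewire")),
                   delta_cut = delta_cut, contrast = paste(to, "vs", from))
  res <- list()

  if (!is.null(cfg$pair_cc)) {
    say("stage: precomputed-CC screen")
    pc <- cfg$pair_cc
    if (is.character(pc)) pc <- utils::read.delim(pc, comment.char = "#",
                                                  stringsAsFactors = FALSE)
    if (!"cc_a" %in% names(pc) && "cc_pre" %in% names(pc)) pc$cc_a <- pc$cc_pre
    if (!"cc_b" %in% names(pc) && "cc_in" %in% names(pc)) pc$cc_b <- pc$cc_in
    blocks <- if ("pathway" %in% names(pc)) split(pc, pc$pathway) else list(all = pc)
    pairs <- do.call(rbind, lapply(names(blocks), function(nm) {
      b <- blocks[[nm]]
      rec <- classify_pairs(b$gene_a, b$gene_b, b$cc_a, b$cc_b, delta_cut)
      with_pathway(rec, nm)
    }))
    rownames(pairs) <- NULL
    res$pairs <- pairs
  } else {
    say("stage: assemble expression")
    sheet <- cfg$sample_sheet
    if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
    m <- read_expression_profiles(cfg$expression_paths, sheet,
                                  scale = cfg$scale %||% "log2")
    m <- drop_null_rows(m)
    if (!is.null(cfg$probe_map)) {
      pm <- cfg$probe_map
      if (is.character(pm)) pm <- utils::read.delim(pm, stringsAsFactors = FALSE)
      m <- map_probe_ids(m, pm)
    }
    say("cleaned matrix: ", nrow(m), " rows x ", ncol(m), " columns")
    write_tsv(data.frame(probe_id = rownames(m),
                         gene_symbol = unname(gene_symbols(m)), m,
                         check.names = FALSE),
              file.path(out_dir, "cleaned_matrix.tsv"))
    manifest$n_rows_clean <- nrow(m)
    conds <- split_by_condition(m, sheet)
    if (!all(c(from, to) %in% names(conds)))
      stop("contrast condition absent from data: ", from, " vs ", to)

    say("stage: differential expression (", to, " vs ", from, ")")
    degs <- call_degs(conds[[from]], conds[[to]],
                      lfc_cut = cfg$lfc_cut %||% 3.00,
                      p_cut = cfg$p_cut %||% 0.05,
                      test = cfg$test %||% "lrt")
    write_tsv(degs, file.path(out_dir, "deg_table.tsv"))
    manifest$n_degs <- sum(degs$is_deg)
    res$degs <- degs

    sets <- NULL
    if (!is.null(cfg$gene_sets))
      sets <- if (is.character(cfg$gene_sets)) load_gene_sets(cfg$gene_sets)
              else cfg$gene_sets
    say("stage: correlation matrices")
    use <- conds[c(from, to)]
    mats <- if (is.null(sets)) list(all = use) else
      lapply(sets, function(g) lapply(use, subset_matrix, genes = g))
    res$correlations <- list(); res$deltas <- list(); all_pairs <- NULL
    for (nm in names(mats)) {
      cc_from <- correlation_matrix(mats[[nm]][[from]], from)
      cc_to <- correlation_matrix(mats[[nm]][[to]], to)
      dd <- delta_matrix(cc_from, cc_to)
      res$correlations[[nm]] <- stats::setNames(list(cc_from, cc_to), c(from, to))
      res$deltas[[nm]] <- dd
      write_tsv(as.data.frame(cbind(id = rownames(dd), round(dd, 6))),
                file.path(out_dir, paste0("delta_cc_", gsub("\\W+", "_", nm), ".tsv")))
      rec <- with_pathway(changed_pairs(cc_from, cc_to, delta_cut), nm)
      all_pairs <- rbind(all_pairs, rec)
    }
    res$pairs <- all_pairs %||%
      data.frame(pathway = character(0), gene_a = character(0),
                 gene_b = character(0))
  }

  say("stage: pair screen and panel assembly")
  write_tsv(res$pairs, file.path(out_dir, "pair_report.tsv"))
  manifest$n_pairs <- nrow(res$pairs)
  res$selected <- select_panel(res$pairs)
  write_tsv(res$selected, file.path(out_dir, "selected_pairs.tsv"))
  manifest$n_selected <- nrow(res$selected)
  res$panel <- panel_genes(res$selected)
  writeLines(res$panel, file.path(out_dir, "panel_genes.tsv"))
  manifest$n_panel_genes <- length(res$panel)
  say("panel: ", length(res$panel), " genes from ", nrow(res$selected),
      " selected pairs")

  if (!is.null(cfg$seed)) manifest$seed <- cfg$seed
  mdf <- data.frame(key = names(manifest),
                    value = vapply(manifest, as.character, character(1)))
  write_tsv(mdf, file.path(out_dir, "manifest.tsv"))
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_pathway <- function(rec, nm) {
  rec$pathway <- rep(nm, nrow(rec))
  rec[, c("pathway", setdiff(names(rec), "pathway")), drop = FALSE]
}
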