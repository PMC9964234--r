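#' Read a sample sheet
#'
#' A sample sheet assigns every expression column to a subject, a condition
#' and a replicate. Conditions follow the three-phase study design: `Pre`
#' (before exposure), `In` (during) and `Post` (after).
#'
#' @param path Path to a tab-delimited file with columns `sample_id`,
#'   `subject_id`, `condition`, `replicate`.
#' @return A data.frame with those four columns; `condition` is a factor with
#'   levels `Pre`, `In`, `Post` and `replicate` an integer.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "subject_id", "condition", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  as_sample_sheet(df)
}

#' Build a sample sheet from vectors
#'
#' @param sample_id,subject_id Character identifiers, one per sample column.
#' @param condition Condition labels, each one of `Pre`, `In`, `Post`.
#' @param replicate Positive integer replicate index within subject/condition.
#' @return A validated sample-sheet data.frame.
#' @export
sample_sheet <- function(sample_id, subject_id, condition, replicate) {
  as_sample_sheet(data.frame(
    sample_id = as.character(sample_id),
    subject_id = as.character(subject_id),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  ))
}

as_sample_sheet <- function(df) {
  df$condition <- as.character(df$condition)
  bad <- setdiff(unique(df$condition), c("Pre", "In", "Post"))
  if (length(bad) > 0)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected Pre, In, Post)")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  triple <- paste(df$subject_id, df$condition, df$replicate, sep = "\r")
  if (anyDuplicated(triple))
    stop("duplicate (subject_id, condition, replicate) triples in sample sheet")
  if (any(!is.finite(df$replicate)) || any(df$replicate < 1))
    stop("replicate must be a positive integer")
  df$condition <- factor(df$condition, levels = c("Pre", "In", "Post"))
  rownames(df) <- NULL
  df
}

#' Assemble an expression matrix from per-profile TSV files
#'
#' Each file holds one or more sample columns of intensities keyed by probe id
#' (header row; first column is the probe id). Files are combined by outer
#' union over probe ids: probes absent from a file get `NA` placeholders,
#' which [drop_null_rows()] removes later. Columns are returned exactly in
#' sample-sheet order, which makes all downstream matrices deterministic.
#'
#' @param paths Character vector of TSV file paths.
#' @param sheet Sample sheet; every `sample_id` must appear as a column in
#'   exactly one file.
#' @param scale Either `"log2"` (default; values used as-is) or `"linear"`,
#'   in which case a `log2(x + 1)` transform is applied.
#' @return A numeric matrix, rows = probes (union over files), columns =
#'   `sheet$sample_id` in sheet order, with a `gene_symbol` attribute
#'   initialised to the probe ids.
#' @export
read_expression_profiles <- function(paths, sheet, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (length(paths) == 0) stop("no input profiles")
  tabs <- lapply(paths, function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#",
                            check.names = FALSE, na.strings = c("NA", "NaN", "null", ""))
    if (ncol(df) < 2) stop("expression file needs a probe column plus >=1 sample column: ", p)
    df
  })
  seen <- unlist(lapply(tabs, function(df) names(df)[-1]))
  if (anyDuplicated(seen))
    stop("duplicate sample id across files: ",
         paste(unique(seen[duplicated(seen)]), collapse = ", "))
  absent <- setdiff(sheet$sample_id, seen)
  if (length(absent) > 0)
    stop("sample(s) in sheet with no data column: ", paste(absent, collapse = ", "))

  probes <- unique(unlist(lapply(tabs, function(df) as.character(df[[1]]))))
  m <- matrix(NA_real_, nrow = length(probes), ncol = nrow(sheet),
              dimnames = list(probes, sheet$sample_id))
  for (df in tabs) {
    ids <- as.character(df[[1]])
    for (cn in intersect(names(df)[-1], sheet$sample_id)) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      m[ids, cn] <- v
    }
  }
  if (scale == "linear") m <- log2(m + 1)
  attr(m, "gene_symbol") <- stats::setNames(rownames(m), rownames(m))
  m
}

#' Drop rows containing null or non-finite values
#'
#' Any empty field, `NA`, `NaN` or non-numeric token in the source files
#' parses to a non-finite value; a row with one or more such entries is
#' removed wholesale. Row order is preserved and the operation is idempotent.
#'
#' @param m Expression matrix.
#' @return The matrix restricted to fully finite rows.
#' @export
drop_null_rows <- function(m) {
  keep <- rowSums(!is.finite(m)) == 0
  if (!any(keep)) stop("empty matrix after null filtering")
  subset_rows(m, which(keep))
}

#' Annotate probe rows with gene symbols
#'
#' Rows stay at probe level: the gene symbol is an annotation carried in the
#' `gene_symbol` attribute (and does not collapse probes of the same gene),
#' so transcript-level resolution is preserved. An optional collapse to one
#' row per gene (mean over probes) is available via `collapse`.
#'
#' @param m Expression matrix with probe-id rownames.
#' @param pm Probe map data.frame with columns `probe_id`, `gene_symbol`;
#'   `probe_id` must be unique.
#' @param unmapped_policy `"keep"` (default): unmapped probes retain the probe
#'   id as their symbol; `"drop"`: unmapped probes are removed.
#' @param collapse If `TRUE`, average probes sharing a symbol into one row
#'   per gene (rownames become symbols). Default `FALSE`.
#' @return The annotated (or collapsed) matrix.
#' @export
map_probe_ids <- function(m, pm, unmapped_policy = c("keep", "drop"),
                          collapse = FALSE) {
  unmapped_policy <- match.arg(unmapped_policy)
  if (anyDuplicated(pm$probe_id))
    stop("probe map has duplicate probe_id: ",
         paste(unique(pm$probe_id[duplicated(pm$probe_id)]), collapse = ", "))
  sym <- stats::setNames(as.character(pm$gene_symbol), as.character(pm$probe_id))
  if (unmapped_policy == "drop") {
    hit <- rownames(m) %in% names(sym)
    if (!any(hit)) stop("no probes mapped; nothing left after drop")
    m <- subset_rows(m, which(hit))
  }
  gs <- unname(sym[rownames(m)])
  gs[is.na(gs)] <- rownames(m)[is.na(gs)]
  attr(m, "gene_symbol") <- stats::setNames(unname(gs), rownames(m))
  if (collapse) {
    g <- factor(gs, levels = unique(gs))
    mm <- rowsum(m, g) / as.vector(table(g))
    attr(mm, "gene_symbol") <- stats::setNames(rownames(mm), rownames(mm))
    m <- mm
  }
  m
}

#' Gene symbols of an expression or correlation object
#'
#' @param m Matrix carrying a `gene_symbol` attribute.
#' @return Named character vector (names = row ids); falls back to rownames.
#' @export
gene_symbols <- function(m) {
  gs <- attr(m, "gene_symbol")
  if (is.null(gs)) gs <- stats::setNames(rownames(m), rownames(m))
  gs
}

#' Split an expression matrix into per-condition matrices
#'
#' @param m Expression matrix whose columns all appear in `sheet`.
#' @param sheet Sample sheet.
#' @return Named list of matrices (`Pre`, `In`, `Post` as present), columns in
#'   sheet order, identical row sets.
#' @export
split_by_condition <- function(m, sheet) {
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing) > 0)
    stop("column(s) of matrix absent from sample sheet: ",
         paste(missing, collapse = ", "))
  conds <- levels(droplevels(sheet$condition))
  out <- lapply(conds, function(cc) {
    ids <- sheet$sample_id[sheet$condition == cc]
    ids <- ids[ids %in% colnames(m)]
    if (length(ids) == 0) stop("condition with zero samples: ", cc)
    sub <- m[, ids, drop = FALSE]
    attr(sub, "gene_symbol") <- gene_symbols(m)
    sub
  })
  stats::setNames(out, conds)
}

# row subset that preserves the gene_symbol annotation
subset_rows <- function(m, idx) {
  gs <- gene_symbols(m)
  out <- m[idx, , drop = FALSE]
  attr(out, "gene_symbol") <- gs[idx]
  out
}
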