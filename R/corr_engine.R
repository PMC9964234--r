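#' Pearson correlation of two sample vectors
#'
#' Thin wrapper around [stats::cor()] enforcing the contracts the pipeline
#' relies on: equal lengths of at least 2, and an `NA` marker (rather than an
#' error) when either vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Pearson r in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Per-condition pairwise correlation matrix
#'
#' All-pairs Pearson correlation over the rows (genes/probes) of one
#' condition's expression matrix. Zero-variance rows yield `NA` entries;
#' their count is recorded in the `n_undefined_rows` attribute and such
#' entries are excluded from summaries and pair selection downstream.
#'
#' @param m Expression matrix with >= 2 columns.
#' @param condition_label Optional label stored on the result.
#' @return Symmetric correlation matrix with unit diagonal (for non-constant
#'   rows), `gene_symbol` and `condition` attributes.
#' @export
correlation_matrix <- function(m, condition_label = NULL) {
  if (ncol(m) < 2) stop("need at least 2 samples (columns) to correlate")
  cc <- suppressWarnings(stats::cor(t(m)))
  const <- apply(m, 1, stats::sd) == 0
  if (any(const)) {
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  attr(cc, "n_undefined_rows") <- sum(const)
  attr(cc, "gene_symbol") <- gene_symbols(m)
  attr(cc, "condition") <- condition_label
  cc
}

#' Correlation differential (delta-CC) between two conditions
#'
#' Elementwise subtraction `cc_to - cc_from` of two matched correlation
#' matrices; the field's measure of pair rewiring between conditions.
#'
#' @param cc_from,cc_to Correlation matrices over the same ids in the same
#'   order (e.g. Pre-flight and In-flight).
#' @return Symmetric matrix of differentials in `[-2, 2]` with zero diagonal
#'   and `from`/`to` attributes.
#' @export
delta_matrix <- function(cc_from, cc_to) {
  if (!identical(rownames(cc_from), rownames(cc_to)))
    stop("correlation matrices have mismatched ids")
  d <- cc_to - cc_from
  attr(d, "gene_symbol") <- gene_symbols(cc_from)
  attr(d, "from") <- attr(cc_from, "condition")
  attr(d, "to") <- attr(cc_to, "condition")
  d
}

#' Summarise the global correlation structure of one condition
#'
#' Quantifies overall genome coordination as the mean absolute correlation
#' and the fractions of pairs in each strength class (weak / moderate /
#' strong), over defined upper-triangle off-diagonal entries. A condition
#' whose regulation is "scrambled" shows a lower `mean_abs_cc` and a smaller
#' strong fraction than a coordinated one.
#'
#' @param cc Correlation matrix.
#' @param class_bounds Numeric length-2: lower |CC| bounds of the moderate
#'   and strong classes (default `c(0.36, 0.68)`).
#' @return List: `mean_abs_cc`, `frac_weak`, `frac_moderate`, `frac_strong`,
#'   `n_pairs`.
#' @export
correlation_summary <- function(cc, class_bounds = c(0.36, 0.68)) {
  v <- cc[upper.tri(cc)]
  v <- v[is.finite(v)]
  if (length(v) < 2) stop("no defined off-diagonal pairs to summarise")
  a <- abs(v)
  list(mean_abs_cc = mean(a),
       frac_weak = mean(a < class_bounds[1]),
       frac_moderate = mean(a >= class_bounds[1] & a < class_bounds[2]),
       frac_strong = mean(a >= class_bounds[2]),
       n_pairs = length(v))
}

#' Streaming correlation summary for large matrices
#'
#' Computes the same summary as [correlation_summary()] without ever
#' materialising the full all-pairs matrix: rows are processed in blocks of
#' `block_size` and only block-by-block correlation tiles are held in
#' memory. Intended for genome-scale matrices (tens of thousands of rows)
#' where the full matrix would be a memory hazard.
#'
#' @param m Expression matrix (>= 2 columns).
#' @param block_size Rows per block (default 1000).
#' @param class_bounds As in [correlation_summary()].
#' @return Same structure as [correlation_summary()].
#' @export
correlation_summary_stream <- function(m, block_size = 1000,
                                       class_bounds = c(0.36, 0.68)) {
  if (ncol(m) < 2) stop("need at least 2 samples (columns) to correlate")
  n <- nrow(m)
  starts <- seq(1, n, by = block_size)
  sum_abs <- 0; n_pairs <- 0
  n_weak <- 0; n_mod <- 0; n_strong <- 0
  tm <- t(m)
  for (bi in seq_along(starts)) {
    ri <- starts[bi]:min(starts[bi] + block_size - 1, n)
    for (bj in bi:length(starts)) {
      rj <- starts[bj]:min(starts[bj] + block_size - 1, n)
      tile <- suppressWarnings(stats::cor(tm[, ri, drop = FALSE],
                                          tm[, rj, drop = FALSE]))
      v <- if (bi == bj) tile[upper.tri(tile)] else as.vector(tile)
      v <- v[is.finite(v)]
      a <- abs(v)
      sum_abs <- sum_abs + sum(a)
      n_pairs <- n_pairs + length(a)
      n_weak <- n_weak + sum(a < class_bounds[1])
      n_mod <- n_mod + sum(a >= class_bounds[1] & a < class_bounds[2])
      n_strong <- n_strong + sum(a >= class_bounds[2])
    }
  }
  if (n_pairs < 2) stop("no defined off-diagonal pairs to summarise")
  list(mean_abs_cc = sum_abs / n_pairs,
       frac_weak = n_weak / n_pairs,
       frac_moderate = n_mod / n_pairs,
       frac_strong = n_strong / n_pairs,
       n_pairs = n_pairs)
}
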