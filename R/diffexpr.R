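#' Log2 fold change between two groups of one row
#'
#' On log2-scale data this is simply the difference of group means. On linear
#' data it is `log2((mean_b + eps) / (mean_a + eps))` with a pseudo-value
#' `eps` guarding zero means.
#'
#' @param values_a,values_b Numeric per-sample expression of the same row in
#'   the two conditions; fold change is condition b over condition a.
#' @param scale `"log2"` (default) or `"linear"`.
#' @param eps Pseudo-value added to both linear means (default `1e-6`).
#' @return Signed log2 fold change.
#' @export
log2_fold_change <- function(values_a, values_b, scale = c("log2", "linear"),
                             eps = 1e-6) {
  scale <- match.arg(scale)
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups must be non-empty")
  if (scale == "log2") return(mean(values_b) - mean(values_a))
  ma <- mean(values_a) + eps
  mb <- mean(values_b) + eps
  if (ma <= 0 || mb <= 0)
    stop("linear scale requires positive means (or a positive eps)")
  log2(mb / ma)
}

#' Poisson likelihood-ratio test of equal per-sample rate
#'
#' Tests whether two total counts are consistent with a common per-sample
#' rate. With totals \eqn{C_a, C_b}, sample counts \eqn{n_a, n_b}, expected
#' split \eqn{\pi = n_a / (n_a + n_b)} and \eqn{T = C_a + C_b}, the deviance
#' is \deqn{D = 2[C_a \log(C_a / (\pi T)) + C_b \log(C_b / ((1-\pi) T))]}
#' (a zero count contributes 0), referred to a chi-square distribution with
#' one degree of freedom.
#'
#' @param sum_a,sum_b Nonnegative totals (counts or pseudo-counts).
#' @param n_a,n_b Positive sample counts behind each total.
#' @return List with `statistic`, `p_value`, and `degenerate` (`TRUE` when
#'   both totals are zero, in which case D = 0 and p = 1).
#' @export
lrt_test <- function(sum_a, sum_b, n_a, n_b) {
  if (sum_a < 0 || sum_b < 0) stop("totals must be nonnegative")
  if (n_a <= 0 || n_b <= 0) stop("sample counts must be positive")
  total <- sum_a + sum_b
  if (total == 0)
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  prop <- n_a / (n_a + n_b)
  term <- function(cnt, expd) if (cnt == 0) 0 else cnt * log(cnt / expd)
  d <- 2 * (term(sum_a, prop * total) + term(sum_b, (1 - prop) * total))
  d <- max(d, 0)  # guard tiny negative round-off
  list(statistic = d,
       p_value = stats::pchisq(d, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Call differentially expressed genes between two conditions
#'
#' For each row, the log2 fold change is the mean difference on log2 scale,
#' and the p-value comes from the Poisson likelihood-ratio test applied to
#' per-condition totals of intensities rescaled to linear pseudo-counts
#' (`2^x`), mirroring a count-model LRT on microarray intensities. A Welch
#' two-sample t-test on the log2 values is available as an alternative.
#' A gene is a DEG when `|log2fc| >= lfc_cut` and `p < p_cut`; no
#' multiple-testing correction is applied by default (an optional
#' Benjamini-Hochberg adjustment can be switched on).
#'
#' @param cond_a,cond_b Expression matrices (log2 scale) with identical row
#'   sets; fold change is b over a.
#' @param lfc_cut Absolute log2-fold-change threshold (default 3.00).
#' @param p_cut P-value threshold (default 0.05).
#' @param test `"lrt"` (default) or `"welch"`.
#' @param adjust If `TRUE`, apply Benjamini-Hochberg and threshold the
#'   adjusted p-values instead. Default `FALSE`.
#' @return data.frame with one row per gene, ordered by `|log2fc|` descending
#'   (ties: p ascending, then row id): columns `row_id`, `gene_symbol`,
#'   `log2fc`, `p_value`, `is_deg`.
#' @export
call_degs <- function(cond_a, cond_b, lfc_cut = 3.00, p_cut = 0.05,
                      test = c("lrt", "welch"), adjust = FALSE) {
  test <- match.arg(test)
  if (!setequal(rownames(cond_a), rownames(cond_b)) ||
      nrow(cond_a) != nrow(cond_b)) {
    off <- c(setdiff(rownames(cond_a), rownames(cond_b)),
             setdiff(rownames(cond_b), rownames(cond_a)))
    stop("row sets differ between conditions: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  cond_b <- cond_b[rownames(cond_a), , drop = FALSE]
  lfc <- rowMeans(cond_b) - rowMeans(cond_a)
  n_a <- ncol(cond_a); n_b <- ncol(cond_b)
  if (test == "lrt") {
    sa <- rowSums(2^cond_a); sb <- rowSums(2^cond_b)
    pv <- vapply(seq_along(sa),
                 function(i) lrt_test(sa[i], sb[i], n_a, n_b)$p_value,
                 numeric(1))
  } else {
    pv <- vapply(seq_len(nrow(cond_a)), function(i) {
      a <- cond_a[i, ]; b <- cond_b[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (mean(a) == mean(b)) 1 else 0)
      stats::t.test(b, a)$p.value
    }, numeric(1))
  }
  p_use <- if (adjust) stats::p.adjust(pv, method = "BH") else pv
  res <- data.frame(
    row_id = rownames(cond_a),
    gene_symbol = unname(gene_symbols(cond_a)),
    log2fc = unname(lfc),
    p_value = unname(pv),
    is_deg = abs(lfc) >= lfc_cut & p_use < p_cut,
    stringsAsFactors = FALSE
  )
  res <- res[order(-abs(res$log2fc), res$p_value, res$row_id), ]
  rownames(res) <- NULL
  res
}
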