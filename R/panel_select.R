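#' Correlation strength class
#'
#' Trichotomy of the absolute correlation: weak (`|CC| < 0.36`), moderate
#' (`0.36 <= |CC| < 0.68`), strong (`|CC| >= 0.68`). The intervals are
#' half-open so every value is classified exactly once while agreeing with
#' the conventional two-decimal bounds (0.35 weak, 0.36 moderate, 0.67
#' moderate, 0.68 strong).
#'
#' @param cc Correlation value(s) in `[-1, 1]` (vectorised).
#' @param bounds Lower |CC| bounds of moderate and strong (default
#'   `c(0.36, 0.68)`).
#' @return Character vector in `{"weak", "moderate", "strong"}` (`NA` in,
#'   `NA` out).
#' @export
strength_class <- function(cc, bounds = c(0.36, 0.68)) {
  if (any(abs(cc) > 1 + 1e-12, na.rm = TRUE))
    stop("|cc| > 1: not a correlation")
  a <- abs(cc)
  out <- ifelse(a < bounds[1], "weak",
                ifelse(a < bounds[2], "moderate", "strong"))
  out[is.na(cc)] <- NA_character_
  out
}

#' Sign-transition category of a pair
#'
#' Classifies the move of a pair's correlation between two conditions by
#' sign: 1 = positive to positive, 2 = positive to negative, 3 = negative to
#' positive, 4 = negative to negative. Exact zero counts as nonnegative.
#'
#' @param cc_a,cc_b Correlations in the earlier and later condition
#'   (vectorised).
#' @return Integer category 1-4.
#' @export
transition_category <- function(cc_a, cc_b) {
  if (any(abs(c(cc_a, cc_b)) > 1 + 1e-12, na.rm = TRUE))
    stop("|cc| > 1: not a correlation")
  ifelse(cc_a >= 0,
         ifelse(cc_b >= 0, 1L, 2L),
         ifelse(cc_b >= 0, 3L, 4L))
}

#' Panel-transition rule for one pair
#'
#' A pair is panel-eligible when its correlation strength class changes
#' strong to weak, weak to strong, or strong to opposite-sign strong (a
#' strict sign flip between two strong values). Combined with the
#' differential cut in [changed_pairs()] this is the assay-design screen.
#'
#' @param class_a,class_b Strength classes in the two conditions
#'   (vectorised).
#' @param cc_a,cc_b The correlations themselves (needed for the sign-flip
#'   arm of the rule).
#' @return Logical.
#' @export
is_panel_transition <- function(class_a, cc_a, class_b, cc_b) {
  (class_a == "strong" & class_b == "weak") |
    (class_a == "weak" & class_b == "strong") |
    (class_a == "strong" & class_b == "strong" & sign(cc_a) != sign(cc_b))
}

#' Annotate pair correlations for two conditions
#'
#' Builds fully annotated pair records (differential, sign category,
#' strength classes, panel flag) from explicit per-pair correlation values,
#' e.g. values published for a study. Pairs are unordered and stored with
#' `gene_a < gene_b` lexicographically.
#'
#' @param gene_a,gene_b Gene identifiers per pair.
#' @param cc_a,cc_b Correlations in the earlier / later condition.
#' @param delta_cut Keep pairs with `|cc_b - cc_a| >= delta_cut`; `0` keeps
#'   all. Default 0.70.
#' @return data.frame with columns `gene_a`, `gene_b`, `cc_a`, `cc_b`,
#'   `dcc`, `category`, `class_a`, `class_b`, `selected`, ordered by `|dcc|`
#'   descending then pair id. `selected` marks panel transitions.
#' @export
classify_pairs <- function(gene_a, gene_b, cc_a, cc_b, delta_cut = 0.70) {
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]; gene_a[swap] <- gene_b[swap]; gene_b[swap] <- tmp
  df <- data.frame(gene_a = gene_a, gene_b = gene_b,
                   cc_a = cc_a, cc_b = cc_b, dcc = cc_b - cc_a,
                   stringsAsFactors = FALSE)
  df <- df[abs(df$dcc) >= delta_cut - 1e-12, , drop = FALSE]
  df$category <- if (nrow(df)) transition_category(df$cc_a, df$cc_b) else integer(0)
  df$class_a <- strength_class(df$cc_a)
  df$class_b <- strength_class(df$cc_b)
  df$selected <- if (nrow(df))
    is_panel_transition(df$class_a, df$cc_a, df$class_b, df$cc_b) else logical(0)
  df <- df[order(-abs(df$dcc), df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pairs whose correlation changed between two conditions
#'
#' Scans the upper triangle of two matched correlation matrices and returns
#' every unordered pair with `|delta-CC| >= delta_cut`, fully annotated.
#' Pairs with an undefined correlation in either condition are skipped.
#'
#' @param cc_from,cc_to Correlation matrices over identical ids (e.g.
#'   Pre-flight and In-flight).
#' @param delta_cut Differential threshold (default 0.70, applied as >=).
#' @return Pair records as in [classify_pairs()], genes labelled by symbol.
#' @export
changed_pairs <- function(cc_from, cc_to, delta_cut = 0.70) {
  if (!identical(rownames(cc_from), rownames(cc_to)))
    stop("correlation matrices have mismatched ids")
  labels <- unname(gene_symbols(cc_from)[rownames(cc_from)])
  labels[is.na(labels)] <- rownames(cc_from)[is.na(labels)]
  ut <- which(upper.tri(cc_from), arr.ind = TRUE)
  a <- cc_from[ut]; b <- cc_to[ut]
  ok <- is.finite(a) & is.finite(b)
  classify_pairs(labels[ut[ok, 1]], labels[ut[ok, 2]], a[ok], b[ok],
                 delta_cut = delta_cut)
}

#' Apply the panel-transition screen
#'
#' Restricts pair records (which already passed the delta-CC cut) to those
#' satisfying the strength-class transition rule. Idempotent.
#'
#' @param pairs Pair records from [changed_pairs()] or [classify_pairs()].
#' @return The selected subset, `selected` set to `TRUE`.
#' @export
select_panel <- function(pairs) {
  out <- pairs[pairs$selected %in% TRUE, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct genes of a pair list
#'
#' @param pairs Pair records; only rows with `selected == TRUE` are used
#'   unless none are flagged, in which case all rows are used.
#' @return Lexicographically sorted distinct gene symbols — the monitoring
#'   panel.
#' @export
panel_genes <- function(pairs) {
  if (nrow(pairs) == 0) return(character(0))
  use <- if (any(pairs$selected)) pairs[pairs$selected, , drop = FALSE] else pairs
  sort(unique(c(use$gene_a, use$gene_b)))
}

#' Count pairs per sign-transition category
#'
#' @param pairs Pair records.
#' @return Named integer vector over categories `"1"`..`"4"`; sums to
#'   `nrow(pairs)`.
#' @export
category_counts <- function(pairs) {
  tab <- table(factor(pairs$category, levels = 1:4))
  stats::setNames(as.integer(tab), names(tab))
}
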