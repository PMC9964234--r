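#' Configuration for a synthetic three-condition study
#'
#' Describes a simulated expression study with the same shape as a
#' before/during/after exposure design: `n_subjects` subjects, each
#' contributing `n_replicates` profiles per condition, Gaussian log2
#' intensities around `baseline_mean`, planted pairwise correlations per
#' condition and planted mean shifts (log2 fold changes) between Pre and In.
#' Defaults mirror the astronaut study's shape: 10 subjects, 2 replicates,
#' three conditions of 20 columns each.
#'
#' @param n_genes Number of genes (rows).
#' @param n_subjects,n_replicates Study shape; columns per condition =
#'   `n_subjects * n_replicates`.
#' @param baseline_mean Baseline log2 intensity (default 8).
#' @param noise_sd Per-gene standard deviation on log2 scale (default 0.5).
#' @param planted_pairs data.frame with columns `gene_i`, `gene_j` (1-based
#'   row indices) and `cc_pre`, `cc_in`, `cc_post` target correlations
#'   (`|cc| < 1`), or `NULL` for none.
#' @param planted_degs data.frame with columns `gene` (index) and `log2fc`
#'   (In minus Pre mean shift), or `NULL`. Post means equal In means, so the
#'   Post vs In contrast carries no planted effects.
#' @param background_cc Correlation of all non-planted pairs (default 0).
#' @param seed Integer seed driving all sampling.
#' @return A validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes, n_subjects = 10, n_replicates = 2,
                             baseline_mean = 8, noise_sd = 0.5,
                             planted_pairs = NULL, planted_degs = NULL,
                             background_cc = 0, seed = 1) {
  stopifnot(n_genes >= 2, n_subjects >= 1, n_replicates >= 1, noise_sd > 0,
            abs(background_cc) < 1)
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("gene_i", "gene_j", "cc_pre", "cc_in", "cc_post") %in%
                    names(planted_pairs)))
    idx <- c(planted_pairs$gene_i, planted_pairs$gene_j)
    if (any(idx < 1 | idx > n_genes)) stop("planted pair index out of range")
    if (any(planted_pairs$gene_i == planted_pairs$gene_j))
      stop("planted pair indices must be distinct")
    cc <- unlist(planted_pairs[, c("cc_pre", "cc_in", "cc_post")])
    if (any(abs(cc) >= 1)) stop("planted |target_cc| must be < 1")
    key <- pmin(planted_pairs$gene_i, planted_pairs$gene_j) * (n_genes + 1) +
      pmax(planted_pairs$gene_i, planted_pairs$gene_j)
    if (anyDuplicated(key)) stop("duplicate planted pair")
  }
  if (!is.null(planted_degs)) {
    stopifnot(all(c("gene", "log2fc") %in% names(planted_degs)))
    if (any(planted_degs$gene < 1 | planted_degs$gene > n_genes))
      stop("planted DEG index out of range")
  }
  structure(list(n_genes = n_genes, n_subjects = n_subjects,
                 n_replicates = n_replicates, baseline_mean = baseline_mean,
                 noise_sd = noise_sd, planted_pairs = planted_pairs,
                 planted_degs = planted_degs, background_cc = background_cc,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Repair a symmetric matrix to a positive semidefinite correlation matrix
#'
#' Eigenvalues below `eigen_floor` are clipped to the floor, the matrix is
#' reassembled and rescaled to unit diagonal. Deterministic; already-PSD
#' input passes through (numerically) unchanged.
#'
#' @param m Symmetric matrix.
#' @param eigen_floor Small positive eigenvalue floor (default `1e-8`).
#' @return PSD matrix with unit diagonal.
#' @export
nearest_psd <- function(m, eigen_floor = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("matrix must be symmetric")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eigen_floor) return(m)
  vals <- pmax(e$values, eigen_floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' Build a target correlation matrix with planted entries
#'
#' Starts from `background_cc` everywhere off-diagonal, sets the planted
#' entries, and repairs to positive semidefinite with [nearest_psd()]. The
#' repair must not move any planted entry by more than `tol` (default 0.02);
#' mutually inconsistent targets that drift further are an error.
#'
#' @param n_genes Matrix dimension.
#' @param planted data.frame with `gene_i`, `gene_j`, `cc` columns (targets
#'   for one condition), or `NULL`.
#' @param background_cc Off-diagonal background correlation.
#' @param tol Maximum tolerated planted-entry drift after repair.
#' @return PSD correlation matrix.
#' @export
build_target_correlation <- function(n_genes, planted = NULL,
                                     background_cc = 0, tol = 0.02) {
  m <- matrix(background_cc, n_genes, n_genes)
  diag(m) <- 1
  if (!is.null(planted) && nrow(planted) > 0) {
    for (k in seq_len(nrow(planted))) {
      i <- planted$gene_i[k]; j <- planted$gene_j[k]
      m[i, j] <- m[j, i] <- planted$cc[k]
    }
  }
  out <- nearest_psd(m)
  if (!is.null(planted) && nrow(planted) > 0) {
    drift <- abs(out[cbind(planted$gene_i, planted$gene_j)] - planted$cc)
    if (any(drift > tol))
      stop("planted correlations mutually inconsistent: max drift after PSD ",
           "repair ", format(max(drift), digits = 3), " exceeds ", tol)
  }
  out
}

#' Sample one condition from a target correlation structure
#'
#' Draws `n_samples` multivariate-normal profiles with the given per-gene
#' means, common standard deviation `noise_sd` and correlation
#' `target_corr`. Sampling is deterministic for a fixed seed.
#'
#' @param target_corr PSD correlation matrix (genes x genes).
#' @param means Per-gene mean log2 intensities.
#' @param noise_sd Common standard deviation.
#' @param n_samples Number of columns to draw.
#' @param seed Integer seed.
#' @return Expression matrix (genes x samples).
#' @export
sample_condition <- function(target_corr, means, noise_sd, n_samples, seed) {
  n_genes <- nrow(target_corr)
  stopifnot(length(means) == n_genes, n_samples >= 1)
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("target correlation matrix is not PSD")
  sigma <- target_corr * noise_sd^2
  set.seed(seed)
  x <- MASS::mvrnorm(n = n_samples, mu = means, Sigma = sigma)
  m <- t(x)
  rownames(m) <- rownames(target_corr)
  m
}

#' Generate a full synthetic three-condition study
#'
#' Produces Pre / In / Post expression matrices with
#' `n_subjects * n_replicates` columns each, a sample sheet, and a truth
#' ledger for recovery scoring. Columns are exchangeable within a condition
#' (no subject effect). Truth labels are derived by running the package's
#' own classification on the repaired noise-free target correlations, so
#' truth and selection agree by construction on noiseless input.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `matrices` (named list Pre/In/Post), `sheet`, and
#'   `truth`. `truth` holds `targets` (per-condition target correlation
#'   matrices), `pairs` (planted pair records with `should_be_selected`),
#'   `log2fc` (planted per-gene effects), and the `seed`.
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  g <- cfg$n_genes
  ids <- sprintf("g%04d", seq_len(g))
  pp <- cfg$planted_pairs
  tgt <- function(col) {
    planted <- if (is.null(pp)) NULL else
      data.frame(gene_i = pp$gene_i, gene_j = pp$gene_j, cc = pp[[col]])
    m <- build_target_correlation(g, planted, cfg$background_cc)
    dimnames(m) <- list(ids, ids)
    m
  }
  targets <- list(Pre = tgt("cc_pre"), In = tgt("cc_in"), Post = tgt("cc_post"))

  means <- list(Pre = rep(cfg$baseline_mean, g))
  shift <- rep(0, g)
  if (!is.null(cfg$planted_degs))
    shift[cfg$planted_degs$gene] <- cfg$planted_degs$log2fc
  means$In <- means$Pre + shift
  means$Post <- means$In  # no planted Post-vs-In effects

  n_cols <- cfg$n_subjects * cfg$n_replicates
  mats <- list()
  for (k in seq_along(targets)) {
    cond <- names(targets)[k]
    m <- sample_condition(targets[[cond]], means[[cond]], cfg$noise_sd,
                          n_cols, seed = cfg$seed + k)
    colnames(m) <- sprintf("%s_s%02d_r%d", cond,
                           rep(seq_len(cfg$n_subjects), each = cfg$n_replicates),
                           rep(seq_len(cfg$n_replicates), cfg$n_subjects))
    attr(m, "gene_symbol") <- stats::setNames(ids, ids)
    mats[[cond]] <- m
  }
  sheet <- sample_sheet(
    sample_id = unlist(lapply(mats, colnames), use.names = FALSE),
    subject_id = sprintf("s%02d", rep(rep(seq_len(cfg$n_subjects),
                                          each = cfg$n_replicates), 3)),
    condition = rep(names(mats), each = n_cols),
    replicate = rep(rep(seq_len(cfg$n_replicates), cfg$n_subjects), 3)
  )

  truth_pairs <- NULL
  if (!is.null(pp) && nrow(pp) > 0) {
    a <- targets$Pre[cbind(pp$gene_i, pp$gene_j)]
    b <- targets$In[cbind(pp$gene_i, pp$gene_j)]
    rec <- classify_pairs(ids[pp$gene_i], ids[pp$gene_j], a, b, delta_cut = 0)
    rec$should_be_selected <- abs(rec$dcc) >= 0.70 - 1e-12 & rec$selected
    truth_pairs <- rec
  }
  list(matrices = mats, sheet = sheet,
       truth = list(targets = targets, pairs = truth_pairs,
                    log2fc = stats::setNames(shift, ids), seed = cfg$seed))
}

#' Score recovery of planted correlation transitions
#'
#' Compares the pairs a caller selected against the truth ledger of a
#' synthetic study. Sensitivity is the fraction of planted panel-eligible
#' pairs that were selected; the false-positive rate is the fraction of
#' all non-planted pairs that were (wrongly) selected.
#'
#' @param selected Pair records (e.g. [select_panel()] output).
#' @param truth Truth component of [generate_study()] output.
#' @param n_genes Total genes in the study (for the non-planted pair count).
#' @return List: `sensitivity` (`NA` if nothing plantable), `fpr`,
#'   `n_selectable`, `n_recovered`, `n_false`.
#' @export
evaluate_recovery <- function(selected, truth, n_genes) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  sel_keys <- if (nrow(selected)) key(selected$gene_a, selected$gene_b) else character(0)
  tp <- truth$pairs
  planted_keys <- if (is.null(tp)) character(0) else key(tp$gene_a, tp$gene_b)
  selectable <- if (is.null(tp)) character(0) else
    key(tp$gene_a, tp$gene_b)[tp$should_be_selected]
  n_recovered <- length(intersect(sel_keys, selectable))
  false_keys <- setdiff(sel_keys, planted_keys)
  n_nonplanted <- choose(n_genes, 2) - length(planted_keys)
  list(sensitivity = if (length(selectable)) n_recovered / length(selectable)
                     else NA_real_,
       fpr = if (n_nonplanted > 0) length(false_keys) / n_nonplanted else 0,
       n_selectable = length(selectable),
       n_recovered = n_recovered,
       n_false = length(false_keys))
}
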