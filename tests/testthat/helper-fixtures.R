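# Shared in-code fixtures for the suite.

# Write per-profile expression TSVs into a temp dir; returns the file paths.
write_profiles <- function(tables, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  vapply(seq_along(tables), function(i) {
    p <- file.path(dir, paste0("profile", i, ".tsv"))
    utils::write.table(tables[[i]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
}

# Minimal 6-sample sheet: 2 columns per condition, one subject.
tiny_sheet <- function() {
  sample_sheet(
    sample_id = c("pre1", "pre2", "in1", "in2", "post1", "post2"),
    subject_id = rep("s01", 6),
    condition = rep(c("Pre", "In", "Post"), each = 2),
    replicate = rep(1:2, 3)
  )
}

# Expression matrix with gene_symbol annotation, rownames r1..rn.
toy_matrix <- function(values, symbols = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sprintf("r%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("c%d", seq_len(ncol(m)))
  attr(m, "gene_symbol") <- stats::setNames(
    symbols %||% rownames(m), rownames(m))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Planted-pair design used by the recovery tests: 20 disjoint 2-gene blocks
# over 40 genes covering all four sign categories and all three strength
# classes; 12 pairs are panel-selectable by construction, 8 are not.
recovery_pairs <- function() {
  data.frame(
    gene_i = seq(1, 39, by = 2),
    gene_j = seq(2, 40, by = 2),
    cc_pre = c(0.90, 0.00,  0.80, -0.90,  0.20, -0.85,  0.95, -0.30,
               0.85, -0.95,  0.30, -0.80,  0.50, -0.85,  0.10,  0.90,
               0.45, -0.50,  0.60, -0.20),
    cc_in  = c(0.00, 0.90, -0.80,  0.10, -0.85,  0.85, -0.30,  0.95,
              -0.85,  0.30, -0.95,  0.80, -0.50,  0.50, -0.10,  0.85,
              -0.45,  0.85,  0.10,  0.60),
    cc_post = c(0.00, 0.90, -0.80,  0.10, -0.85,  0.85, -0.30,  0.95,
               -0.85,  0.30, -0.95,  0.80, -0.50,  0.50, -0.10,  0.85,
               -0.45,  0.85,  0.10,  0.60)
  )
}
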