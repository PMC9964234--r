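test_that("PSD repair clips eigenvalues and keeps unit diagonal", {
  ident <- diag(4)
  expect_equal(nearest_psd(ident), ident, tolerance = 1e-10)
  set.seed(31)
  z <- matrix(rnorm(36), 6); psd <- stats::cov2cor(crossprod(z) + diag(6))
  expect_equal(nearest_psd(psd), psd, tolerance = 1e-10)
  # deliberately indefinite: three mutually incompatible strong correlations
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)  # oracle
  rep_m <- nearest_psd(bad)
  expect_gte(min(eigen(rep_m, symmetric = TRUE)$values), 0)
  expect_equal(unname(diag(rep_m)), rep(1, 3))
  expect_error(nearest_psd(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("target construction plants entries and detects irreparable targets", {
  expect_equal(build_target_correlation(4), diag(4))
  t2 <- build_target_correlation(
    2, data.frame(gene_i = 1, gene_j = 2, cc = 0.9))
  expect_equal(t2[1, 2], 0.9)  # 2-block is already PSD
  t3 <- build_target_correlation(
    10, data.frame(gene_i = c(1, 3, 5), gene_j = c(2, 4, 6),
                   cc = c(0.9, -0.8, 0.0)), background_cc = 0.1)
  expect_gte(min(eigen(t3, symmetric = TRUE)$values), -1e-10)
  expect_lt(max(abs(t3[cbind(c(1, 3, 5), c(2, 4, 6))] - c(0.9, -0.8, 0))), 0.02)
  expect_error(build_target_correlation(
    3, data.frame(gene_i = c(1, 1, 2), gene_j = c(2, 3, 3),
                  cc = c(0.95, -0.95, 0.95))), "inconsistent")
})

test_that("condition sampling is deterministic and hits planted moments", {
  tgt <- build_target_correlation(
    2, data.frame(gene_i = 1, gene_j = 2, cc = 0.9))
  dimnames(tgt) <- list(c("g1", "g2"), c("g1", "g2"))
  a <- sample_condition(tgt, c(0, 0), 1, 5000, seed = 37)
  b <- sample_condition(tgt, c(0, 0), 1, 5000, seed = 37)
  expect_identical(a, b)
  expect_equal(pearson(a[1, ], a[2, ]), 0.9, tolerance = 0.02)
  # planted mean shift recovered within 3 standard errors of the group mean
  lo <- sample_condition(tgt, c(0, 0), 0.5, 400, seed = 38)
  hi <- sample_condition(tgt, c(4, 0), 0.5, 400, seed = 39)
  expect_lt(abs(mean(hi[1, ]) - mean(lo[1, ]) - 4),
            3 * sqrt(2) * 0.5 / sqrt(400))
  expect_error(sample_condition(matrix(c(1, 2, 2, 1), 2), c(0, 0), 1, 5, 1),
               "not PSD")
})

test_that("generated studies have the study shape and a consistent truth ledger", {
  cfg <- synthetic_config(n_genes = 40, n_subjects = 10, n_replicates = 2,
                          planted_pairs = recovery_pairs(),
                          planted_degs = data.frame(gene = c(1, 5),
                                                    log2fc = c(4, -4)),
                          seed = 41)
  st <- generate_study(cfg)
  expect_named(st$matrices, c("Pre", "In", "Post"))
  expect_true(all(vapply(st$matrices, ncol, 1L) == 20))
  expect_true(all(vapply(st$matrices, nrow, 1L) == 40))
  expect_equal(nrow(st$sheet), 60)
  # truth selection flags equal the package rule applied to the targets
  tp <- st$truth$pairs
  redo <- classify_pairs(tp$gene_a, tp$gene_b, tp$cc_a, tp$cc_b, delta_cut = 0)
  redo_sel <- abs(redo$dcc) >= 0.70 - 1e-12 & redo$selected
  key <- function(d) paste(d$gene_a, d$gene_b)
  expect_setequal(key(tp)[tp$should_be_selected], key(redo)[redo_sel])
  expect_equal(sum(tp$should_be_selected), 12)  # by design of the fixture
  # planted effects recorded per gene
  expect_equal(unname(st$truth$log2fc[c(1, 5)]), c(4, -4))
  # no planted pairs -> nothing selectable
  st0 <- generate_study(synthetic_config(n_genes = 5, seed = 1))
  expect_null(st0$truth$pairs)
  ev0 <- evaluate_recovery(
    data.frame(gene_a = character(0), gene_b = character(0),
               selected = logical(0)), st0$truth, 5)
  expect_true(is.na(ev0$sensitivity))
})

test_that("recovery scoring counts hits and false selections", {
  cfg <- synthetic_config(n_genes = 40, planted_pairs = recovery_pairs(),
                          seed = 43)
  st <- generate_study(cfg)
  truth <- st$truth
  selectable <- truth$pairs[truth$pairs$should_be_selected, ]
  # perfect recovery
  ev <- evaluate_recovery(selectable, truth, 40)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fpr, 0)
  # empty selection
  ev2 <- evaluate_recovery(selectable[0, ], truth, 40)
  expect_equal(ev2$sensitivity, 0)
  expect_equal(ev2$fpr, 0)
  # one fabricated non-planted selection
  fake <- rbind(selectable,
                data.frame(gene_a = "g0001", gene_b = "g0003",
                           cc_a = 0.9, cc_b = 0, dcc = -0.9, category = 2L,
                           class_a = "strong", class_b = "weak",
                           selected = TRUE, should_be_selected = TRUE))
  ev3 <- evaluate_recovery(fake, truth, 40)
  expect_equal(ev3$sensitivity, 1)
  expect_equal(ev3$n_false, 1)
  expect_equal(ev3$fpr, 1 / (choose(40, 2) - 20))
})

test_that("synthetic config rejects invalid plantings", {
  expect_error(synthetic_config(2, planted_pairs = data.frame(
    gene_i = 1, gene_j = 3, cc_pre = 0, cc_in = 0, cc_post = 0)), "out of range")
  expect_error(synthetic_config(4, planted_pairs = data.frame(
    gene_i = 1, gene_j = 2, cc_pre = 1.0, cc_in = 0, cc_post = 0)), "< 1")
  expect_error(synthetic_config(4, planted_pairs = data.frame(
    gene_i = c(1, 2), gene_j = c(2, 1), cc_pre = c(0, 0), cc_in = c(0, 0),
    cc_post = c(0, 0))), "duplicate")
  expect_error(synthetic_config(4, planted_degs = data.frame(
    gene = 9, log2fc = 3)), "out of range")
})
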