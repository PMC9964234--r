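test_that("profiles are assembled by outer union in sample-sheet order", {
  sheet <- tiny_sheet()
  tabs <- list(
    data.frame(probe_id = c("A", "B"), pre1 = c(1, 2), pre2 = c(3, 4),
               in1 = c(5, 6), in2 = c(7, 8)),
    data.frame(probe_id = c("B", "C"), post1 = c(9, 10), post2 = c(11, 12))
  )
  m <- read_expression_profiles(write_profiles(tabs), sheet)
  # union oracle: rows are the set union of per-file probe universes
  expect_setequal(rownames(m), union(tabs[[1]]$probe_id, tabs[[2]]$probe_id))
  expect_identical(colnames(m), sheet$sample_id)
  expect_true(all(is.na(m["A", c("post1", "post2")])))
  expect_true(all(is.na(m["C", c("pre1", "in2")])))
  expect_equal(m["B", "in1"], 6)
  expect_equal(m["C", "post2"], 12)
})

test_that("assembly errors name the offending sample", {
  sheet <- tiny_sheet()
  expect_error(read_expression_profiles(character(0), sheet), "no input profiles")
  tabs <- list(
    data.frame(probe_id = "A", pre1 = 1, pre2 = 2, in1 = 3, in2 = 4, post1 = 5),
    data.frame(probe_id = "A", post1 = 6, post2 = 7)
  )
  expect_error(read_expression_profiles(write_profiles(tabs), sheet), "post1")
  tabs2 <- list(data.frame(probe_id = "A", pre1 = 1, pre2 = 2,
                           in1 = 3, in2 = 4, post1 = 5))
  expect_error(read_expression_profiles(write_profiles(tabs2), sheet), "post2")
})

test_that("linear-scale input is log2(x+1) transformed on read", {
  sheet <- tiny_sheet()
  tab <- data.frame(probe_id = "A", pre1 = 0, pre2 = 1, in1 = 3, in2 = 7,
                    post1 = 15, post2 = 31)
  m <- read_expression_profiles(write_profiles(list(tab)), sheet, scale = "linear")
  expect_equal(unname(m["A", ]), 0:5)
})

test_that("null rows are dropped exactly, preserving order, idempotently", {
  m <- toy_matrix(matrix(rnorm(20), 5, 4))
  m[2, 3] <- NA; m[4, 1] <- NaN
  # oracle: enumerate rows containing any non-finite entry
  bad <- which(apply(m, 1, function(r) any(!is.finite(r))))
  expect_equal(bad, c(2L, 4L), ignore_attr = TRUE)
  f <- drop_null_rows(m)
  expect_identical(rownames(f), rownames(m)[-bad])
  expect_identical(drop_null_rows(f), f)
  expect_identical(drop_null_rows(toy_matrix(diag(3))), toy_matrix(diag(3)))
  all_bad <- toy_matrix(matrix(NA_real_, 2, 2))
  expect_error(drop_null_rows(all_bad), "empty matrix")
})

test_that("probe mapping annotates without collapsing transcript rows", {
  m <- toy_matrix(matrix(1:8, 4, 2))
  pm <- data.frame(probe_id = c("r1", "r2", "r3"),
                   gene_symbol = c("G", "G", "H"))
  out <- map_probe_ids(m, pm)
  expect_equal(nrow(out), 4)  # two probes of gene G both retained
  expect_equal(unname(gene_symbols(out)), c("G", "G", "H", "r4"))
  dropped <- map_probe_ids(m, pm, unmapped_policy = "drop")
  expect_identical(rownames(dropped), c("r1", "r2", "r3"))
  # identity map is the identity operation
  idm <- data.frame(probe_id = rownames(m), gene_symbol = rownames(m))
  expect_equal(map_probe_ids(m, idm), m)
  expect_error(map_probe_ids(m, rbind(pm, pm[1, ])), "duplicate probe_id")
})

test_that("collapse option averages probes of a gene", {
  m <- toy_matrix(rbind(c(1, 3), c(3, 5), c(10, 10)))
  pm <- data.frame(probe_id = c("r1", "r2", "r3"),
                   gene_symbol = c("G", "G", "H"))
  out <- map_probe_ids(m, pm, collapse = TRUE)
  expect_equal(dim(out), c(2L, 2L))
  expect_equal(unname(out["G", ]), c(2, 4))
  expect_equal(unname(out["H", ]), c(10, 10))
})

test_that("condition split partitions columns and conserves them", {
  sheet <- tiny_sheet()
  m <- toy_matrix(matrix(rnorm(18), 3, 6), samples = sheet$sample_id)
  parts <- split_by_condition(m, sheet)
  expect_named(parts, c("Pre", "In", "Post"))
  expect_true(all(vapply(parts, ncol, 1L) == 2))
  expect_true(all(vapply(parts, function(p)
    identical(rownames(p), rownames(m)), TRUE)))
  # column-conservative: multiset in = union out
  expect_setequal(unlist(lapply(parts, colnames)), colnames(m))
  # missing sheet entry errors
  expect_error(split_by_condition(m, sheet[-1, ]), "pre1")
})

test_that("larger synthetic split keeps equal row sets per condition", {
  sheet <- sample_sheet(
    sample_id = sprintf("smp%02d", 1:60),
    subject_id = sprintf("s%02d", rep(1:10, each = 6)),
    condition = rep(rep(c("Pre", "In", "Post"), each = 2), 10),
    replicate = rep(1:2, 30)
  )
  m <- toy_matrix(matrix(rnorm(5 * 60), 5, 60), samples = sheet$sample_id)
  parts <- split_by_condition(m, sheet)
  expect_true(all(vapply(parts, ncol, 1L) == 20))
  # sheet order within condition
  expect_identical(colnames(parts$In),
                   sheet$sample_id[sheet$condition == "In"])
})

test_that("sample sheets reject malformed metadata", {
  expect_error(sample_sheet("a", "s1", "During", 1), "unknown condition")
  expect_error(sample_sheet(c("a", "a"), c("s1", "s1"), c("Pre", "In"), c(1, 1)),
               "duplicate sample_id")
  expect_error(sample_sheet(c("a", "b"), c("s1", "s1"), c("Pre", "Pre"), c(1, 1)),
               "triples")
})
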