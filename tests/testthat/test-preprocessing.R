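test_that("expression TSV round-trips and malformed input is rejected", {
  cfg <- sim_config(n_genes = 10, n_modules = 0, seed = 5)
  ds <- generate_dataset(cfg)$dataset
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ds, path)
  back <- read_expression(path)
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-12)
  expect_equal(back$samples, ds$samples)

  # negative entry
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tTh_cellulose_1\tTh_cellulose_2\tTh_cellulose_3",
               "g1\t1\t-2\t3"), bad)
  expect_error(read_expression(bad), "negative")

  # duplicate gene ID
  writeLines(c("gene_id\tTh_cellulose_1\tTh_cellulose_2\tTh_cellulose_3",
               "g1\t1\t2\t3", "g1\t4\t5\t6"), bad)
  expect_error(read_expression(bad), "duplicate")

  # malformed sample header
  writeLines(c("gene_id\tsample1\tsample2\tsample3",
               "g1\t1\t2\t3"), bad)
  expect_error(read_expression(bad), "malformed")
})

test_that("null-gene filter uses a strict zero-fraction threshold", {
  mat <- rbind(
    g_half = c(0, 0, 0, 5, 6, 7),   # zero fraction exactly 0.5: kept
    g_most = c(0, 0, 0, 0, 1, 0),   # 5/6: removed
    g_none = c(1, 2, 3, 4, 5, 6),
    g_all0 = c(0, 0, 0, 0, 0, 0))
  ds <- tiny_dataset(mat)
  res <- filter_null_genes(ds, max_zero_fraction = 0.5)
  expect_setequal(res$report$kept, c("g_half", "g_none"))
  expect_setequal(res$report$removed, c("g_most", "g_all0"))
  expect_setequal(c(res$report$kept, res$report$removed), genes(ds))

  # all-zero gene removed for any threshold below 1
  res99 <- filter_null_genes(ds, max_zero_fraction = 0.99)
  expect_true("g_all0" %in% res99$report$removed)
})

test_that("null-gene filter is idempotent", {
  cfg <- sim_config(n_genes = 200, dropout_prob = 0.4, seed = 11)
  ds <- generate_dataset(cfg)$dataset
  once <- filter_null_genes(ds)
  twice <- filter_null_genes(once$dataset)
  expect_identical(twice$dataset$matrix, once$dataset$matrix)
  expect_length(twice$report$removed, 0L)
})

test_that("per-condition filtering only drops genes dead in every condition", {
  mat <- rbind(
    g_cel_only = c(3, 4, 5, 0, 0, 0),  # alive in cellulose only
    g_dead = c(0, 0, 0, 0, 0, 0))
  ds <- tiny_dataset(mat)
  across <- filter_null_genes(ds, 0.5)
  per_cond <- filter_null_genes(ds, 0.5, per_condition = TRUE)
  expect_setequal(across$report$kept, c("g_cel_only"))
  expect_setequal(per_cond$report$kept, c("g_cel_only"))
  expect_true("g_dead" %in% per_cond$report$removed)
})

test_that("log2 transform matches hand-computed values", {
  ds <- tiny_dataset(matrix(c(0, 1, 3), 3, 1,
                            dimnames = list(c("a", "b", "c"), NULL)),
                     conditions = "cellulose")
  out <- log2_normalize(ds, pseudocount = 1, normalize = FALSE)
  expect_equal(unname(out$matrix[, 1]), c(0, 1, 2))
  expect_true(out$log_scale)
})

test_that("median-total scaling equalises column totals before the log", {
  mat <- matrix(c(10, 30, 60,   40, 60, 100), 3, 2,
                dimnames = list(c("a", "b", "c"), NULL))  # totals 100, 200
  ds <- tiny_dataset(mat, conditions = c("cellulose", "glucose"))
  # recover the linear scale to inspect totals
  out <- log2_normalize(ds, pseudocount = 1, normalize = TRUE)
  lin <- 2^out$matrix - 1
  expect_equal(unname(colSums(lin)), c(150, 150), tolerance = 1e-9)
})

test_that("all-zero matrix maps to all zeros and zero pseudocount errors", {
  mat <- matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL))
  ds <- tiny_dataset(mat, conditions = c("cellulose", "glucose"))
  expect_true(all(log2_normalize(ds)$matrix == 0))
  expect_error(log2_normalize(ds, pseudocount = 0), "pseudocount")
})

test_that("log2_normalize is monotone within each column", {
  cfg <- sim_config(n_genes = 50, seed = 3)
  ds <- generate_dataset(cfg)$dataset
  out <- log2_normalize(ds)
  for (j in seq_len(ncol(ds$matrix))) {
    expect_identical(order(ds$matrix[, j]), order(out$matrix[, j]))
  }
})

test_that("presence requires any non-zero replicate in the cell", {
  mat <- rbind(g_absent = c(0, 0, 0, 1, 1, 1),
               g_faint = c(0, 0, 0.1, 0, 0, 0),
               g_full = c(1, 1, 1, 1, 1, 1))
  ds <- tiny_dataset(mat)
  ps <- presence_sets(ds)
  expect_setequal(ps$Th_cellulose, c("g_faint", "g_full"))
  expect_setequal(ps$Th_glucose, c("g_absent", "g_full"))
})

test_that("presence sets shrink (or stay) after null filtering", {
  cfg <- sim_config(n_genes = 300, dropout_prob = 0.3, seed = 9)
  ds <- generate_dataset(cfg)$dataset
  before <- presence_sets(ds)
  after <- presence_sets(filter_null_genes(ds)$dataset)
  for (cell in names(before)) {
    expect_true(all(after[[cell]] %in% before[[cell]]))
  }
})
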