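log_dataset <- function(mat) tiny_dataset(mat, log_scale = TRUE)

test_that("fold change, degenerate p-values and calls match hand cases", {
  mat <- rbind(
    g_up = c(3, 3, 3, 2, 2, 2),      # constant groups, means differ
    g_same = c(1, 2, 3, 1, 2, 3),    # identical groups
    g_small = c(1.2, 1.2, 1.2, 1, 1, 1))  # |log2fc| = 0.2 < log2(1.5)
  de <- de_test(log_dataset(mat), contrast = c("cellulose", "glucose"))
  expect_equal(de$log2fc, c(1, 0, 0.2), tolerance = 1e-12)
  expect_equal(de$p_value[1], 0)   # both variances 0, means differ
  expect_equal(de$p_value[2], 1)   # identical groups
  expect_equal(de$call, c("up_in_cellulose", "none", "none"))
})

test_that("a strong p-value cannot rescue a sub-threshold fold change", {
  # tight groups, log2fc = 0.4 < log2(1.5) ~ 0.585, p very small
  mat <- rbind(g = c(1.4, 1.41, 1.39, 1.0, 1.01, 0.99))
  de <- de_test(log_dataset(mat), contrast = c("cellulose", "glucose"))
  expect_lt(de$p_value, 0.001)
  expect_equal(de$call, "none")
})

test_that("thresholds are inclusive at fold change 1.5 and p = 0.05", {
  expect_equal(
    hrrnet:::de_call(log2(1.5), 0.05, 1.5, 0.05, c("A", "B")), "up_in_A")
  expect_equal(
    hrrnet:::de_call(-log2(1.5), 0.05, 1.5, 0.05, c("A", "B")), "up_in_B")
  expect_equal(
    hrrnet:::de_call(log2(1.5) - 1e-6, 0.05, 1.5, 0.05, c("A", "B")), "none")
  expect_equal(
    hrrnet:::de_call(log2(1.5), 0.050001, 1.5, 0.05, c("A", "B")), "none")
  # end-to-end: constant groups exactly 1.5-fold apart on the linear scale
  mat <- rbind(g = log2(c(3, 3, 3, 2, 2, 2)))
  de <- de_test(log_dataset(mat), contrast = c("cellulose", "glucose"))
  expect_equal(2^de$log2fc, 1.5, tolerance = 1e-12)
  expect_equal(de$call, "up_in_cellulose")
})

test_that("p-values agree with stats::t.test on non-degenerate data", {
  set.seed(1)
  mat <- matrix(rnorm(50 * 6), 50, 6,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
  ds <- log_dataset(mat)
  de_s <- de_test(ds, c("cellulose", "glucose"), test = "student")
  de_w <- de_test(ds, c("cellulose", "glucose"), test = "welch")
  for (i in c(1, 17, 50)) {
    expect_equal(de_s$p_value[i],
                 stats::t.test(mat[i, 1:3], mat[i, 4:6],
                               var.equal = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(de_w$p_value[i],
                 stats::t.test(mat[i, 1:3], mat[i, 4:6])$p.value,
                 tolerance = 1e-12)
  }
})

test_that("replicate and condition preconditions are enforced", {
  mat <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), NULL))
  ds <- tiny_dataset(mat, conditions = c("cellulose", "glucose"))
  ds$log_scale <- TRUE
  expect_error(de_test(ds, c("cellulose", "xylose")), "xylose")
  ds2 <- log_dataset(matrix(1:6, 1, 6, dimnames = list("a", NULL)))
  ds2$samples$condition <- c("cellulose", rep("glucose", 5))
  expect_error(de_test(ds2, c("cellulose", "glucose")), "replicates")
  lin <- tiny_dataset(matrix(1:6, 1, 6, dimnames = list("a", NULL)))
  expect_error(de_test(lin, c("cellulose", "glucose")), "log2")
})

test_that("BH adjustment changes calls, not reported raw p-values", {
  set.seed(2)
  mat <- matrix(rnorm(200 * 6), 200, 6,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
  mat[1:5, 1:3] <- mat[1:5, 1:3] + 5
  ds <- log_dataset(mat)
  raw <- de_test(ds, c("cellulose", "glucose"))
  bh <- de_test(ds, c("cellulose", "glucose"), adjust = "BH")
  expect_identical(raw$p_value, bh$p_value)
  expect_lte(sum(bh$call != "none"), sum(raw$call != "none"))
})

test_that("de_summary counts every gene exactly once", {
  mat <- rbind(a = c(5, 5, 5, 1, 1, 1), b = c(1, 1, 1, 5, 5, 5),
               c = c(1, 2, 3, 1, 2, 3))
  de <- de_test(log_dataset(mat), contrast = c("cellulose", "glucose"))
  s <- de_summary(de)
  expect_equal(unname(s), c(1L, 1L, 1L))
  expect_equal(sum(s), nrow(de))
  expect_equal(names(s), c("up_in_cellulose", "up_in_glucose", "none"))
})

test_that("venn regions match brute-force membership enumeration", {
  sets <- list(X = c("1", "2", "3"), Y = c("2", "3", "4"), Z = "3")
  v <- venn(sets)
  expect_setequal(v[["X&Y&Z"]], "3")
  expect_setequal(v[["X"]], "1")
  expect_setequal(v[["Y"]], "4")
  expect_setequal(v[["X&Y"]], "2")
  expect_length(v[["Z"]], 0L)
  bf <- brute_force_venn(sets)
  for (sig in names(bf)) expect_setequal(v[[sig]], bf[[sig]])

  # random sets: regions partition the union
  set.seed(4)
  for (k in 2:4) {
    rs <- lapply(seq_len(k), function(i) sample(letters, sample(5:15, 1)))
    names(rs) <- LETTERS[seq_len(k)]
    v <- venn(rs)
    all_elements <- unlist(v, use.names = FALSE)
    expect_false(anyDuplicated(all_elements) > 0)
    expect_setequal(all_elements, unique(unlist(rs)))
    bf <- brute_force_venn(rs)
    for (sig in names(bf)) expect_setequal(v[[sig]], bf[[sig]])
  }
})

test_that("degenerate venn inputs behave and arity is bounded", {
  same <- list(A = c("x", "y"), B = c("x", "y"))
  expect_setequal(venn(same)[["A&B"]], c("x", "y"))
  disj <- venn(list(A = "x", B = "y"))
  expect_setequal(disj[["A"]], "x")
  expect_setequal(disj[["B"]], "y")
  expect_length(disj[["A&B"]], 0L)
  five <- stats::setNames(as.list(letters[1:5]), LETTERS[1:5])
  expect_error(venn(five), "2 to 4")
})
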