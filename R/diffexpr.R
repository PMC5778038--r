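#' Call differentially expressed genes between two conditions
#'
#' For every gene, computes the log2 fold change as the difference of mean
#' log2 expression (condition A minus condition B) and a two-sided
#' two-sample t-test p-value on the replicate log2 values. A gene is called
#' differential when both thresholds are met inclusively: `|log2fc| >=
#' log2(fc_threshold)` and `p <= alpha`. When both group variances are zero
#' the t-statistic is undefined and the degenerate rule applies: p = 1 if
#' the means are equal, p = 0 otherwise.
#'
#' The default test pools the two group variances (Student's t). With
#' balanced groups the pooled and Welch t statistics coincide, but at
#' triplicate scale the Welch-Satterthwaite degrees of freedom are noisy
#' and make the test conservative, so the pooled form — exact under equal
#' group variances — is the default; `test = "welch"` selects the unpooled
#' form for heteroscedastic data.
#'
#' @param ds An [expression_dataset()] on the log2 scale, containing a
#'   single species.
#' @param contrast Character vector of two condition labels `(A, B)`;
#'   positive log2fc means higher in A.
#' @param fc_threshold Linear fold-change threshold (>= 1); default 1.5.
#' @param alpha P-value cutoff; default 0.05.
#' @param adjust Multiple-testing adjustment applied before calling:
#'   `"none"` (default, thresholds on raw p-values) or `"BH"`
#'   (Benjamini-Hochberg).
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @return A `de_table`: data.frame with columns `gene_id`, `log2fc`,
#'   `p_value`, `call` where `call` is `up_in_<A>`, `up_in_<B>` or `none`.
#' @export
de_test <- function(ds, contrast, fc_threshold = 1.5, alpha = 0.05,
                    adjust = c("none", "BH"), test = c("student", "welch")) {
  stopifnot(inherits(ds, "expression_dataset"))
  adjust <- match.arg(adjust)
  test <- match.arg(test)
  if (!ds$log_scale) stop("de_test expects log2-scale data; see log2_normalize")
  if (length(contrast) != 2L) stop("contrast must name two conditions")
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (length(unique(ds$samples$species)) > 1L) {
    stop("de_test expects a single species; use subset_samples() first")
  }
  a_cols <- ds$samples$condition == contrast[1L]
  b_cols <- ds$samples$condition == contrast[2L]
  if (!any(a_cols) || !any(b_cols)) {
    missing <- contrast[c(!any(a_cols), !any(b_cols))]
    stop("condition not present in dataset: ", paste(missing, collapse = ", "))
  }
  na <- sum(a_cols); nb <- sum(b_cols)
  if (na < 2L || nb < 2L) stop("each condition needs >= 2 replicates")

  A <- ds$matrix[, a_cols, drop = FALSE]
  B <- ds$matrix[, b_cols, drop = FALSE]
  p <- if (test == "welch") welch_p(A, B) else student_p(A, B)
  log2fc <- rowMeans(A) - rowMeans(B)

  p_used <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  call <- de_call(log2fc, p_used, fc_threshold, alpha, contrast)

  structure(
    data.frame(gene_id = genes(ds), log2fc = log2fc, p_value = p,
               call = call, row.names = NULL, stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"),
    contrast = contrast, fc_threshold = fc_threshold, alpha = alpha,
    adjust = adjust, test = test
  )
}

# Vectorised two-sided pooled-variance (Student) t-test over matrix rows.
student_p <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums((A - ma)^2)
  ssb <- rowSums((B - mb)^2)
  df <- na + nb - 2
  s2 <- (ssa + ssb) / df
  se2 <- s2 * (1 / na + 1 / nb)
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  unname(p)
}

# Vectorised two-sided Welch t-test over matrix rows.
welch_p <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # both variances zero: t undefined; equal means are a perfect null fit,
  # unequal means a perfect separation
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  unname(p)
}

# Inclusive threshold rule; tiny tolerance keeps boundary cases (fold change
# exactly at fc_threshold, p exactly at alpha) inclusive under floating point.
de_call <- function(log2fc, p, fc_threshold, alpha, contrast) {
  eps <- 1e-10
  hit <- abs(log2fc) >= log2(fc_threshold) - eps & p <= alpha + eps
  out <- rep("none", length(log2fc))
  out[hit & log2fc > 0] <- paste0("up_in_", contrast[1L])
  out[hit & log2fc < 0] <- paste0("up_in_", contrast[2L])
  out
}

#' Summarise differential-expression calls
#'
#' @param table A `de_table` from [de_test()].
#' @return Named integer vector: counts of genes up in each condition and
#'   with no call; the counts sum to the number of genes.
#' @export
de_summary <- function(table) {
  stopifnot(inherits(table, "de_table"))
  contrast <- attr(table, "contrast")
  lv <- c(paste0("up_in_", contrast), "none")
  counts <- table(factor(table$call, levels = lv))
  out <- as.integer(counts)
  names(out) <- lv
  out
}

#' @export
print.de_table <- function(x, ...) {
  s <- de_summary(x)
  cat(sprintf("de_table: %d genes, contrast %s vs %s (fc >= %g, p <= %g)\n",
              nrow(x), attr(x, "contrast")[1L], attr(x, "contrast")[2L],
              attr(x, "fc_threshold"), attr(x, "alpha")))
  print(s)
  invisible(x)
}

#' Venn regions of 2 to 4 named sets
#'
#' Partitions the union of the input sets into the 2^k - 1 membership
#' regions. Every element of any input set appears in exactly one region.
#'
#' @param sets Named list of 2-4 character vectors.
#' @return Named list over all non-empty membership signatures (set names
#'   joined by `&`), each a character vector of elements belonging to
#'   exactly those sets. Regions with no elements are present and empty.
#' @export
venn <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a named list")
  }
  k <- length(sets)
  if (k < 2L || k > 4L) stop("venn supports 2 to 4 sets, got ", k)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  sig <- apply(membership, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  out <- list()
  for (m in seq_len(k)) {
    for (combo in utils::combn(names(sets), m, simplify = FALSE)) {
      out[[paste(combo, collapse = "&")]] <- character(0)
    }
  }
  found <- split(universe, sig)
  out[names(found)] <- found
  out
}
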