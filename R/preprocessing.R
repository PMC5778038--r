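#' Read an expression table from TSV
#'
#' Expects a tab-separated file with a header row; the first column holds
#' gene IDs and every other column is a sample labelled
#' `species_condition_rep` (e.g. `Th_cellulose_1`). Row and column order are
#' preserved.
#'
#' @param path Path to the TSV file.
#' @return An [expression_dataset()] on the linear scale.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("input error: expected gene_id plus sample columns")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop("input error: duplicate gene ID '", ids[duplicated(ids)][1L],
         "' in ", path)
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("input error: non-numeric expression values")
  rownames(mat) <- ids
  if (any(!is.finite(mat))) stop("input error: non-finite expression values")
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("input error: negative value at row %s, column %s",
                 ids[neg[1L, 1L]], colnames(mat)[neg[1L, 2L]]))
  }
  samples <- parse_sample_labels(colnames(mat))
  expression_dataset(mat, samples)
}

parse_sample_labels <- function(labels) {
  parts <- strsplit(labels, "_", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("input error: malformed sample header '", labels[bad][1L],
         "' (expected species_condition_rep)")
  }
  data.frame(
    species = vapply(parts, function(p) paste(p[seq_len(length(p) - 2L)],
                                              collapse = "_"), ""),
    condition = vapply(parts, function(p) p[length(p) - 1L], ""),
    replicate = as.integer(vapply(parts, function(p) p[length(p)], "")),
    stringsAsFactors = FALSE
  )
}

#' Write an expression dataset to TSV
#'
#' @param ds An [expression_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path) {
  tab <- data.frame(gene_id = genes(ds), ds$matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exclude genes that are zero in most samples
#'
#' Removes noise genes before network construction: a gene is dropped when
#' its fraction of zero values is strictly greater than
#' `max_zero_fraction`. By default the fraction is taken across all samples;
#' with `per_condition = TRUE` a gene is dropped only when it exceeds the
#' threshold within every condition (i.e. it is uninformative everywhere).
#'
#' @param ds An [expression_dataset()] on the linear scale.
#' @param max_zero_fraction Zero-fraction threshold in `[0, 1]`; a gene with
#'   exactly this fraction of zeros is kept.
#' @param per_condition Logical; see above.
#' @return A list with `dataset` (the filtered [expression_dataset()]) and
#'   `report` (a `filter_report`: `kept`, `removed`, `rule`).
#' @export
filter_null_genes <- function(ds, max_zero_fraction = 0.5,
                              per_condition = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (max_zero_fraction < 0 || max_zero_fraction > 1) {
    stop("max_zero_fraction must be in [0, 1]")
  }
  zero <- ds$matrix == 0
  if (per_condition) {
    conds <- unique(ds$samples$condition)
    frac_by_cond <- vapply(conds, function(cc) {
      cols <- ds$samples$condition == cc
      rowMeans(zero[, cols, drop = FALSE])
    }, numeric(nrow(zero)))
    remove <- apply(frac_by_cond > max_zero_fraction, 1L, all)
    rule <- sprintf(
      "removed genes with zero fraction > %g within every condition",
      max_zero_fraction)
  } else {
    remove <- rowMeans(zero) > max_zero_fraction
    rule <- sprintf("removed genes with zero fraction > %g across all samples",
                    max_zero_fraction)
  }
  kept <- genes(ds)[!remove]
  removed <- genes(ds)[remove]
  out <- expression_dataset(ds$matrix[!remove, , drop = FALSE], ds$samples,
                            log_scale = ds$log_scale)
  list(dataset = out,
       report = structure(list(kept = kept, removed = removed, rule = rule),
                          class = "filter_report"))
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: kept %d, removed %d (%s)\n",
              length(x$kept), length(x$removed), x$rule))
  invisible(x)
}

#' Normalize sample totals and log2-transform
#'
#' First each sample column is rescaled so that its total equals the median
#' of all column totals (columns whose total is zero are left untouched);
#' then every value is mapped to `log2(x + pseudocount)`. With
#' `normalize = FALSE` only the log transform is applied.
#'
#' @param ds An [expression_dataset()] on the linear scale.
#' @param pseudocount Value added before taking logs; must be positive when
#'   zeros are present. The default 1 maps zeros to zero.
#' @param normalize Logical; apply the median-total column scaling first.
#' @return An [expression_dataset()] with `log_scale = TRUE`.
#' @export
log2_normalize <- function(ds, pseudocount = 1, normalize = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$log_scale) stop("dataset is already on the log2 scale")
  mat <- ds$matrix
  if (normalize && ncol(mat) > 0L) {
    totals <- colSums(mat)
    target <- stats::median(totals)
    scale_ok <- totals > 0
    mat[, scale_ok] <- sweep(mat[, scale_ok, drop = FALSE], 2L,
                             target / totals[scale_ok], `*`)
  }
  if (pseudocount <= 0 && any(mat == 0)) {
    stop("pseudocount must be > 0 when zeros are present (log of 0)")
  }
  expression_dataset(log2(mat + pseudocount), ds$samples, log_scale = TRUE)
}

#' Presence sets per species-by-condition cell
#'
#' A gene is present in a (species, condition) cell when its mean linear
#' expression over that cell's replicates is greater than zero —
#' equivalently, when any replicate is non-zero. These are the sets compared
#' in cross-species Venn diagrams.
#'
#' @param ds An [expression_dataset()] on the linear (pre-log) scale.
#' @return A named list of gene-ID character vectors, one per
#'   `species_condition` cell.
#' @export
presence_sets <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$log_scale) stop("presence sets are defined on the linear scale")
  cells <- unique(ds$samples[, c("species", "condition")])
  out <- vector("list", nrow(cells))
  names(out) <- paste(cells$species, cells$condition, sep = "_")
  for (i in seq_len(nrow(cells))) {
    cols <- ds$samples$species == cells$species[i] &
      ds$samples$condition == cells$condition[i]
    present <- rowMeans(ds$matrix[, cols, drop = FALSE]) > 0
    out[[i]] <- genes(ds)[present]
  }
  out
}
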