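#' Expression dataset container
#'
#' Bundles a non-negative gene-by-sample expression matrix with its sample
#' metadata (species, carbon-source condition, replicate index). Column names
#' of the matrix follow the `species_condition_rep` convention used by the
#' on-disk TSV format.
#'
#' @param mat Numeric matrix, genes in rows (rownames = gene IDs), samples in
#'   columns. All values must be finite and `>= 0`.
#' @param samples Data frame with one row per column of `mat` and columns
#'   `species`, `condition`, `replicate`.
#' @param log_scale Logical; `TRUE` if values are log2-transformed (the
#'   non-negativity check is skipped on the log scale).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `samples` and attribute-like field `log_scale`.
#' @export
expression_dataset <- function(mat, samples, log_scale = FALSE) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`mat` must be a numeric matrix")
  }
  if (is.null(rownames(mat))) stop("`mat` must have gene IDs as rownames")
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1L]
    stop("duplicate gene ID: ", dup)
  }
  if (!is.data.frame(samples) ||
      !all(c("species", "condition", "replicate") %in% names(samples))) {
    stop("`samples` must be a data.frame with species, condition, replicate")
  }
  if (nrow(samples) != ncol(mat)) {
    stop("`samples` must have one row per matrix column")
  }
  lab <- sample_labels(samples)
  if (anyDuplicated(lab)) {
    stop("duplicate sample descriptor: ", lab[duplicated(lab)][1L])
  }
  colnames(mat) <- lab
  if (any(!is.finite(mat))) stop("expression values must be finite")
  if (!log_scale && any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at gene %s, sample %s",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
  }
  structure(
    list(matrix = mat, samples = samples, log_scale = isTRUE(log_scale)),
    class = "expression_dataset"
  )
}

sample_labels <- function(samples) {
  paste(samples$species, samples$condition, samples$replicate, sep = "_")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%s scale)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$log_scale) "log2" else "linear"))
  tab <- table(x$samples$species, x$samples$condition)
  cat("samples per species x condition:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Gene identifiers of a dataset
#' @param ds An `expression_dataset`.
#' @return Character vector of gene IDs in row order.
#' @export
genes <- function(ds) rownames(ds$matrix)

#' Subset an expression dataset by sample metadata
#'
#' @param ds An `expression_dataset`.
#' @param species,condition Optional labels to keep (all kept when `NULL`).
#' @return An `expression_dataset` restricted to the matching columns.
#' @export
subset_samples <- function(ds, species = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(ds$samples))
  if (!is.null(species)) keep <- keep & ds$samples$species %in% species
  if (!is.null(condition)) keep <- keep & ds$samples$condition %in% condition
  if (!any(keep)) stop("no samples match the requested subset")
  expression_dataset(ds$matrix[, keep, drop = FALSE],
                     droplevels(ds$samples[keep, , drop = FALSE]),
                     log_scale = ds$log_scale)
}
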