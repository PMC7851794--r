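#' Expression matrix container
#'
#' Bundles a genes-by-samples numeric matrix with per-sample metadata and a
#' scale flag. All pipeline stages consume and return this container; genes
#' are always rows.
#'
#' @param values Numeric matrix, genes as rows. Row names are gene ids,
#'   column names sample ids.
#' @param sample_meta Data frame with one row per sample; must contain a
#'   `sample` column matching `colnames(values)` and a `population` column.
#'   Optional columns: `tissue`, `condition`, `replicate`.
#' @param scale Either `"count"` (non-negative integers) or
#'   `"log-intensity"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `sample_meta` and `scale`.
#' @export
expression_matrix <- function(values, sample_meta,
                              scale = c("count", "log-intensity")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "))
  if (!is.data.frame(sample_meta) || !all(c("sample", "population") %in% names(sample_meta)))
    stop("`sample_meta` must be a data.frame with `sample` and `population` columns")
  sample_meta <- as.data.frame(sample_meta)
  if (!setequal(sample_meta$sample, colnames(values)) ||
      nrow(sample_meta) != ncol(values))
    stop("`sample_meta$sample` must match colnames(values) one-to-one")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- NULL
  if (anyNA(sample_meta$population))
    stop("every sample needs a population label")
  if (scale == "count") {
    if (any(values < 0) || any(values != round(values)))
      stop("count-scale values must be non-negative integers")
  }
  structure(list(values = values, sample_meta = sample_meta, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  pops <- table(x$sample_meta$population)
  cat("populations:",
      paste(sprintf("%s(%d)", names(pops), as.integer(pops)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Columns of an expression matrix restricted to one or more populations
#' @param mat An `expr_matrix`.
#' @param populations Character vector of population labels.
#' @return Numeric sub-matrix of `mat$values`.
#' @export
population_values <- function(mat, populations) {
  keep <- mat$sample_meta$population %in% populations
  if (!any(keep))
    stop("no samples in population(s): ", paste(populations, collapse = ", "))
  mat$values[, keep, drop = FALSE]
}

#' Subset an expression matrix to selected populations
#' @inheritParams population_values
#' @return An `expr_matrix` containing only the selected samples.
#' @export
subset_populations <- function(mat, populations) {
  keep <- mat$sample_meta$population %in% populations
  if (!any(keep))
    stop("no samples in population(s): ", paste(populations, collapse = ", "))
  expression_matrix(mat$values[, keep, drop = FALSE],
                    mat$sample_meta[keep, , drop = FALSE],
                    scale = mat$scale)
}

#' Library-size normalization and log transform
#'
#' Scales each sample by a median-of-ratios size factor (the DESeq-style
#' estimator) and applies `log2(x + pseudocount)`. When the median-of-ratios
#' estimator is undefined -- no gene has strictly positive counts in every
#' sample -- size factors fall back to library totals rescaled so the
#' smallest equals one.
#'
#' @param mat An `expr_matrix` on the count scale.
#' @param pseudocount Added before the log; default 1.
#' @param method `"median-of-ratios"` (default; falls back automatically when
#'   undefined) or `"total-count"` to force the library-total estimator.
#' @return An `expr_matrix` on the log-intensity scale. The size factors
#'   used are attached as attribute `"size_factors"`.
#' @export
normalize_counts <- function(mat, pseudocount = 1,
                             method = c("median-of-ratios", "total-count")) {
  stopifnot(inherits(mat, "expr_matrix"))
  method <- match.arg(method)
  if (mat$scale != "count")
    stop("normalize_counts() expects a count-scale matrix")
  x <- mat$values
  zero <- colSums(x) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(x)[zero], collapse = ", "))
  sf <- size_factors(x, force_total = method == "total-count")
  norm <- sweep(x, 2, sf, "/")
  out <- expression_matrix(log2(norm + pseudocount), mat$sample_meta,
                           scale = "log-intensity")
  attr(out, "size_factors") <- sf
  out
}

# Median-of-ratios size factors with total-count fallback.
size_factors <- function(x, force_total = FALSE) {
  all_pos <- rowSums(x > 0) == ncol(x)
  if (any(all_pos) && !force_total) {
    sf <- DESeq2::estimateSizeFactorsForMatrix(x)
  } else {
    tot <- colSums(x)
    sf <- tot / min(tot)
  }
  stats::setNames(as.numeric(sf), colnames(x))
}
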