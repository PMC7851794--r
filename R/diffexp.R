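new_deg_table <- function(df, engine, test_group, reference_group) {
  structure(df, class = c("deg_table", "data.frame"),
            engine = engine, test_group = test_group,
            reference_group = reference_group)
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("deg_table (%s): %s vs %s, %d genes\n",
              attr(x, "engine"),
              paste(attr(x, "test_group"), collapse = "+"),
              paste(attr(x, "reference_group"), collapse = "+"),
              nrow(x)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

group_matrices <- function(mat, test_group, reference_group, min_per_group = 2) {
  if (length(intersect(test_group, reference_group)))
    stop("test and reference groups must be disjoint")
  xt <- population_values(mat, test_group)
  xr <- population_values(mat, reference_group)
  if (ncol(xt) < min_per_group || ncol(xr) < min_per_group)
    stop("each group needs at least ", min_per_group, " samples")
  list(test = xt, ref = xr)
}

row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' Per-gene Welch test between two populations
#'
#' Generic two-group differential expression on the log scale: the log2 fold
#' change is the difference of group means and significance comes from
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom. Benjamini-Hochberg q-values are computed within the contrast.
#'
#' Degenerate genes follow fixed conventions: zero variance in both groups
#' with equal means gives p = 1; unequal means with zero variance gives the
#' smallest positive double and a `flagged` mark.
#'
#' @param mat Log-intensity `expr_matrix`.
#' @param test_group,reference_group Population labels (disjoint, each with
#'   at least two samples).
#' @return A `deg_table` data.frame: `gene`, `log2fc` (test minus
#'   reference), `t`, `df`, `p`, `q`, `flagged`.
#' @export
two_sample_test <- function(mat, test_group, reference_group) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$scale != "log-intensity")
    stop("two_sample_test() expects a log-intensity matrix; run normalize_counts() first")
  g <- group_matrices(mat, test_group, reference_group)
  n1 <- ncol(g$test); n2 <- ncol(g$ref)
  m1 <- rowMeans(g$test); m2 <- rowMeans(g$ref)
  v1 <- row_vars(g$test); v2 <- row_vars(g$ref)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  flagged <- rep(FALSE, length(p))
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & lfc == 0
    ne <- degen & lfc != 0
    p[eq] <- 1; tstat[eq] <- 0; df[eq] <- NA
    p[ne] <- .Machine$double.xmin; tstat[ne] <- sign(lfc[ne]) * Inf; df[ne] <- NA
    flagged[ne] <- TRUE
  }
  new_deg_table(
    data.frame(gene = rownames(mat$values), log2fc = lfc, t = tstat,
               df = df, p = p, q = stats::p.adjust(p, "BH"),
               flagged = flagged, row.names = NULL),
    "two-sample", test_group, reference_group)
}

#' Characteristic Direction differential expression
#'
#' Treats differential expression geometrically: the direction vector `b` is
#' the normal of a shrunken linear-discriminant hyperplane separating the
#' two groups, `b` proportional to `(gamma*I + (1-gamma)*Sigma)^-1 (mu_test -
#' mu_ref)` with `Sigma` the pooled within-group covariance, normalized to
#' unit length. A gene's characteristic score is its squared component
#' `b_i^2` (the scores sum to one); its sign is the component's sign after
#' orienting `b` so that its inner product with the mean-difference vector
#' is positive, making positive scores "induced in the test group".
#'
#' When genes outnumber samples the pooled covariance is singular; the
#' solve is then carried out exactly in the span of the within-group
#' residuals via the Woodbury identity, which is where the shrinkage term
#' `gamma > 0` is required.
#'
#' @inheritParams two_sample_test
#' @param shrinkage Shrinkage weight `gamma` in (0, 1]; default 0.5.
#' @return A `deg_table` with `gene`, `log2fc`, `cd_score`, `cd_sign`.
#' @export
characteristic_direction <- function(mat, test_group, reference_group,
                                     shrinkage = 0.5) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$scale != "log-intensity")
    stop("characteristic_direction() expects a log-intensity matrix")
  if (shrinkage <= 0 || shrinkage > 1)
    stop("shrinkage must lie in (0, 1]; gamma = 0 leaves the pooled covariance singular")
  g <- group_matrices(mat, test_group, reference_group)
  n <- nrow(g$test)
  m <- ncol(g$test) + ncol(g$ref)
  delta <- rowMeans(g$test) - rowMeans(g$ref)
  # within-group residuals, pooled: Sigma = R R^T / (m - 2)
  R <- cbind(g$test - rowMeans(g$test), g$ref - rowMeans(g$ref))
  gam <- shrinkage
  if (gam == 1) {
    b <- delta
  } else if (n <= m) {
    Sigma <- R %*% t(R) / (m - 2)
    b <- solve(gam * diag(n) + (1 - gam) * Sigma, delta)
  } else {
    # Woodbury: (gam I + c R R^T)^-1 d = (d - R (gam/c I + R^T R)^-1 R^T d)/gam
    cc <- (1 - gam) / (m - 2)
    inner <- solve(gam / cc * diag(m) + crossprod(R), crossprod(R, delta))
    b <- (delta - R %*% inner) / gam
  }
  b <- as.numeric(b)
  if (sum(b * delta) < 0) b <- -b
  b <- b / sqrt(sum(b^2))
  new_deg_table(
    data.frame(gene = rownames(mat$values), log2fc = delta,
               cd_score = b^2, cd_sign = sign(b), row.names = NULL),
    "characteristic-direction", test_group, reference_group)
}

#' Two-part zero-inflated test for single-cell counts
#'
#' Per gene: part 1 tests the zero pattern (two-sided Fisher's exact test on
#' the 2x2 table of zero / non-zero cells per group); part 2 compares the
#' non-zero values after total-count normalization (two-sided Wilcoxon
#' rank-sum). The parts are combined by Fisher's method (chi-square on 4
#' degrees of freedom). When one part is undefined -- a group with no
#' non-zero cells leaves the rank-sum empty -- the defined part's p-value is
#' used alone. The log2 fold change uses normalized group means with a
#' pseudocount.
#'
#' @param mat Count-scale single-cell `expr_matrix`.
#' @param test_group,reference_group Population labels; each group needs at
#'   least one cell.
#' @param pseudocount For the fold-change computation; default 1.
#' @return A `deg_table` with `gene`, `log2fc`, `p_zero`, `p_nonzero`, `p`,
#'   `q`.
#' @export
two_part_zero_inflated_test <- function(mat, test_group, reference_group,
                                        pseudocount = 1) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$scale != "count")
    stop("two_part_zero_inflated_test() expects raw counts")
  if (length(intersect(test_group, reference_group)))
    stop("test and reference groups must be disjoint")
  xt <- population_values(mat, test_group)
  xr <- population_values(mat, reference_group)
  if (ncol(xt) == 0 || ncol(xr) == 0) stop("a group has zero cells")
  # total-count normalization to the median library size
  libs <- c(colSums(xt), colSums(xr))
  med <- stats::median(libs[libs > 0])
  nt <- sweep(xt, 2, pmax(colSums(xt), 1), "/") * med
  nr <- sweep(xr, 2, pmax(colSums(xr), 1), "/") * med

  n_genes <- nrow(xt)
  p_zero <- p_nonzero <- p <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    zt <- sum(xt[i, ] == 0); zr <- sum(xr[i, ] == 0)
    tab <- matrix(c(zt, ncol(xt) - zt, zr, ncol(xr) - zr), 2)
    p1 <- stats::fisher.test(tab)$p.value
    vt <- nt[i, xt[i, ] > 0]; vr <- nr[i, xr[i, ] > 0]
    p2 <- if (length(vt) && length(vr))
      suppressWarnings(stats::wilcox.test(vt, vr, exact = FALSE)$p.value)
    else NA_real_
    p_zero[i] <- p1; p_nonzero[i] <- p2
    p[i] <- if (is.na(p2)) p1
      else stats::pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
  }
  lfc <- log2(rowMeans(nt) + pseudocount) - log2(rowMeans(nr) + pseudocount)
  new_deg_table(
    data.frame(gene = rownames(xt), log2fc = lfc, p_zero = p_zero,
               p_nonzero = p_nonzero, p = p, q = stats::p.adjust(p, "BH"),
               row.names = NULL),
    "two-part", test_group, reference_group)
}

#' Select differentially expressed genes from a contrast
#'
#' Applies the screen's selection rules. For p-value engines (two-sample,
#' two-part) a gene passes when its fold change exceeds `fc_threshold` on
#' the requested side and `p < p_threshold`. For Characteristic Direction a
#' gene passes when its characteristic score exceeds the uniform model `1/n`
#' (`n` = genes tested), restricted to the requested sign: with
#' `direction = "up"` only positive-score (induced) genes are kept.
#'
#' @param records A `deg_table`.
#' @param fc_threshold Fold-change threshold in linear fold units
#'   (default 2, i.e. |log2FC| > 1). Ignored by the CD rule.
#' @param p_threshold P-value threshold (default 0.01).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param name Optional name for the resulting set.
#' @return A `gene_set` whose provenance records the contrast and rules.
#' @export
select_degs <- function(records, fc_threshold = 2, p_threshold = 0.01,
                        direction = c("up", "down", "both"), name = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(records, "deg_table"))
  engine <- attr(records, "engine")
  contrast <- paste0(paste(attr(records, "test_group"), collapse = "+"),
                     " vs ",
                     paste(attr(records, "reference_group"), collapse = "+"))
  if (nrow(records) == 0) {
    warning("empty DEG record list")
    return(gene_set(character(0), name = name %||% contrast,
                    provenance = paste0(engine, ": ", contrast, " (empty input)")))
  }
  if (engine == "characteristic-direction") {
    cutoff <- 1 / nrow(records)
    keep <- records$cd_score > cutoff
    keep <- keep & switch(direction,
                          up = records$cd_sign > 0,
                          down = records$cd_sign < 0,
                          both = TRUE)
    rule <- sprintf("cd_score > 1/n (n=%d), direction=%s", nrow(records), direction)
  } else {
    lfc <- log2(fc_threshold)
    keep <- switch(direction,
                   up = records$log2fc > lfc,
                   down = records$log2fc < -lfc,
                   both = abs(records$log2fc) > lfc)
    keep <- keep & records$p < p_threshold
    rule <- sprintf("FC > %g, p < %g, direction=%s", fc_threshold,
                    p_threshold, direction)
  }
  gene_set(records$gene[keep], name = name %||% contrast,
           provenance = paste0(engine, ": ", contrast, "; ", rule))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
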