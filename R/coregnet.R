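#' Remove genes expressed no higher than negative-marker genes
#'
#' Technical-noise filter for network construction: genes expected not to
#' express in T cells (B-cell and macrophage markers such as CD19, CD79A/B,
#' CD163, CD14, CSF1R) define an expression floor. The threshold is the
#' maximum (default) or mean over negative markers of each marker's maximum
#' across samples; genes whose own maximum does not exceed it are removed,
#' as are the negative markers themselves.
#'
#' @param mat An `expr_matrix`.
#' @param negative_markers A `gene_set` of genes expected silent; members
#'   missing from the matrix are reported via a message, and none present
#'   is an error.
#' @param rule `"max"` (strictest) or `"mean"` of the per-marker maxima.
#' @return Filtered `expr_matrix` with attribute `"threshold"`.
#' @export
filter_expressed <- function(mat, negative_markers, rule = c("max", "mean")) {
  stopifnot(inherits(mat, "expr_matrix"), inherits(negative_markers, "gene_set"))
  rule <- match.arg(rule)
  found <- intersect(negative_markers$ids, rownames(mat$values))
  missing <- setdiff(negative_markers$ids, found)
  if (length(missing))
    message("negative marker(s) not in matrix: ", paste(missing, collapse = ", "))
  if (!length(found))
    stop("no negative marker found in the matrix")
  marker_maxima <- apply(mat$values[found, , drop = FALSE], 1, max)
  threshold <- if (rule == "max") max(marker_maxima) else mean(marker_maxima)
  gene_max <- apply(mat$values, 1, max)
  keep <- gene_max > threshold & !(rownames(mat$values) %in% found)
  if (!any(keep))
    warning("all genes fall at or below the negative-marker threshold")
  out <- mat
  out$values <- mat$values[keep, , drop = FALSE]
  attr(out, "threshold") <- threshold
  out
}

#' Root-mean-square normalization of gene rows
#'
#' Divides each gene's expression vector by its root mean square across
#' samples so every gene has RMS 1; Pearson correlations are unchanged but
#' values become scale-free. All-zero rows are dropped with a warning.
#'
#' @param mat An `expr_matrix`.
#' @return RMS-normalized `expr_matrix`.
#' @export
rms_normalize <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  rms <- sqrt(rowMeans(mat$values^2))
  drop <- rms == 0
  if (any(drop)) {
    warning(sum(drop), " all-zero gene row(s) dropped")
    mat$values <- mat$values[!drop, , drop = FALSE]
    rms <- rms[!drop]
  }
  mat$values <- mat$values / rms
  mat
}

#' Coexpression network from significant Pearson correlations
#'
#' Computes the Pearson correlation of every unordered gene pair across
#' samples and keeps a link when its correlation is significant: the
#' two-sided p-value of `t = r * sqrt((m-2) / (1-r^2))` on `m - 2` degrees
#' of freedom falls below `p_threshold`. Constant genes (undefined
#' correlation) are flagged and contribute no edges. Perfect correlations
#' are handled by capping `|r|` just below one so the statistic stays
#' finite.
#'
#' @param mat An `expr_matrix` with at least three samples.
#' @param p_threshold Edge significance threshold; default 0.01.
#' @return A `coreg_network`: list with `nodes`, `edges` (data.frame
#'   `gene_a`, `gene_b`, `r`, `p`; pairs stored once, lexicographic order),
#'   `m_samples`, `p_threshold` and `flagged` (constant genes).
#' @export
pcc_edges <- function(mat, p_threshold = 0.01) {
  stopifnot(inherits(mat, "expr_matrix"))
  m <- ncol(mat$values)
  if (m < 3) stop("need at least 3 samples (df = m - 2 >= 1)")
  sds <- apply(mat$values, 1, stats::sd)
  flagged <- rownames(mat$values)[sds == 0]
  r <- suppressWarnings(stats::cor(t(mat$values)))
  n <- nrow(r)
  ut <- which(upper.tri(r))
  rv <- r[ut]
  rc <- pmin(pmax(rv, -1 + 1e-15), 1 - 1e-15)
  tt <- rc * sqrt((m - 2) / (1 - rc^2))
  p <- 2 * stats::pt(-abs(tt), df = m - 2)
  keep <- !is.na(p) & p < p_threshold
  idx <- ut[keep]
  genes <- rownames(mat$values)
  a <- genes[(idx - 1) %% n + 1]
  b <- genes[(idx - 1) %/% n + 1]
  swap <- a > b
  edges <- data.frame(gene_a = ifelse(swap, b, a),
                      gene_b = ifelse(swap, a, b),
                      r = rv[keep], p = p[keep])
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = genes, edges = edges, m_samples = m,
                 p_threshold = p_threshold, flagged = flagged),
            class = "coreg_network")
}

#' @export
print.coreg_network <- function(x, ...) {
  cat(sprintf("coreg_network: %d links among %d genes (m = %d samples, edge p < %g)\n",
              nrow(x$edges), length(x$nodes), x$m_samples, x$p_threshold))
  invisible(x)
}

#' Number of network links inside a gene group
#'
#' @param net A `coreg_network`.
#' @param group A `gene_set`; ids absent from the network are reported via
#'   a message and ignored. Fewer than two in-network genes is an error.
#' @return Integer count of edges with both endpoints in the group.
#' @export
within_group_connectivity <- function(net, group) {
  stopifnot(inherits(net, "coreg_network"), inherits(group, "gene_set"))
  in_net <- intersect(group$ids, net$nodes)
  out <- setdiff(group$ids, net$nodes)
  if (length(out))
    message(length(out), " group gene(s) not in network")
  if (length(in_net) < 2)
    stop("fewer than 2 group genes present in the network")
  sum(net$edges$gene_a %in% in_net & net$edges$gene_b %in% in_net)
}

#' Permutation significance of within-group connectivity
#'
#' Compares the observed within-group link count with a null of random
#' gene groups: node sets of the same in-network size drawn uniformly
#' without replacement, each recounted for internal links. The empirical
#' p-value uses an add-one correction, `(1 + #{draws >= observed}) /
#' (1 + n_draws)`, so it is never zero (at 100,000 draws the strongest
#' possible report is p < 0.00001). When the number of possible groups
#' `choose(n, k)` is small (`<= exhaustive_limit`) every subset is
#' enumerated instead and the p-value is exact.
#'
#' @param net A `coreg_network`.
#' @param group A `gene_set`.
#' @param n_draws Number of random groups; at least 1,000 recommended,
#'   100,000 for headline runs.
#' @param seed Optional seed for the draws.
#' @param exhaustive_limit Enumerate exhaustively when `choose(n, k)` is at
#'   most this; default 1e5. Set to 0 to force sampling.
#' @return A `connectivity_result`: list with `group`, `observed`,
#'   `n_draws`, `p_value`, `method` (`"sampled"` or `"exhaustive"`).
#' @export
connectivity_null_test <- function(net, group, n_draws = 10000, seed = NULL,
                                   exhaustive_limit = 1e5) {
  stopifnot(inherits(net, "coreg_network"))
  in_net <- intersect(group$ids, net$nodes)
  k <- length(in_net)
  n <- length(net$nodes)
  if (length(unique(group$ids)) > n) stop("group size exceeds node count")
  observed <- within_group_connectivity(net, group)
  node_index <- stats::setNames(seq_len(n), net$nodes)
  ea <- node_index[net$edges$gene_a]
  eb <- node_index[net$edges$gene_b]
  count_internal <- function(members) {        # members: logical over nodes
    sum(members[ea] & members[eb])
  }
  if (choose(n, k) <= exhaustive_limit) {
    subsets <- utils::combn(n, k)
    conn <- apply(subsets, 2, function(s) {
      memb <- logical(n); memb[s] <- TRUE; count_internal(memb)
    })
    p <- mean(conn >= observed)
    method <- "exhaustive"
    n_draws <- ncol(subsets)
  } else {
    draw_one <- function(...) {
      memb <- logical(n); memb[sample.int(n, k)] <- TRUE
      count_internal(memb)
    }
    conn <- if (is.null(seed)) vapply(seq_len(n_draws), draw_one, numeric(1))
      else with_seed(seed, vapply(seq_len(n_draws), draw_one, numeric(1)))
    p <- (1 + sum(conn >= observed)) / (1 + n_draws)
    method <- "sampled"
  }
  structure(list(group = group$name, observed = observed, n_draws = n_draws,
                 p_value = p, method = method),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("within-group connectivity of '%s': %d links, empirical p = %.4g (%s, %d draws)\n",
              x$group, x$observed, x$p_value, x$method, x$n_draws))
  invisible(x)
}
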