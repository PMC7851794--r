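neighbor_list <- function(net) {
  e <- net$edges
  nb <- c(split(e$gene_b, e$gene_a), split(e$gene_a, e$gene_b))
  nb <- tapply(unlist(nb, use.names = FALSE),
               rep(names(nb), lengths(nb)), unique, simplify = FALSE)
  out <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  out[names(nb)] <- nb
  out
}

cac_record <- function(gene, neighbors, nodes, sig_ids) {
  universe <- length(nodes) - 1L                 # all nodes minus the focal gene
  sig_u <- setdiff(sig_ids, gene)
  K <- length(sig_u)
  deg <- length(neighbors)
  k <- length(intersect(neighbors, sig_u))
  p <- if (deg == 0 || K == 0) 1
    else stats::phyper(k - 1, K, universe - K, deg, lower.tail = FALSE)
  data.frame(gene = gene, degree = deg, n_signature = K, overlap = k,
             universe = universe, p = p, flagged = deg == 0)
}

#' Enrichment of a gene's network neighbors in a signature
#'
#' The per-gene statistic behind context-associated centrality: a one-sided
#' hypergeometric (Fisher enrichment) upper-tail p-value for the overlap
#' between the gene's network neighborhood and the context signature,
#' against a universe of all network nodes excluding the focal gene. A
#' degree-zero gene gets p = 1 and is flagged.
#'
#' @param net A `coreg_network`.
#' @param signature A `gene_set`; intersected with the universe before
#'   testing.
#' @param gene A gene id present in the network.
#' @return One-row data.frame: `gene`, `degree`, `n_signature`, `overlap`,
#'   `universe`, `p`, `flagged`.
#' @export
neighbor_enrichment <- function(net, signature, gene) {
  stopifnot(inherits(net, "coreg_network"), inherits(signature, "gene_set"))
  if (!gene %in% net$nodes) stop("gene not in network: ", gene)
  sig_ids <- intersect(signature$ids, net$nodes)
  nb <- neighbor_list(net)[[gene]]
  cac_record(gene, nb, net$nodes, sig_ids)
}

#' Context-associated centrality table
#'
#' Scores every network gene by the enrichment of its neighbors among
#' context signature genes: one-sided hypergeometric p per gene,
#' Benjamini-Hochberg adjustment across all genes, and
#' `cac_score = -log10(q)`. Genes are ranked by ascending p with ties
#' broken by descending overlap then gene id, so top-decile membership is
#' reproducible.
#'
#' @param net A `coreg_network`.
#' @param signature A `gene_set` of context signature genes.
#' @param top_fraction Fraction flagged as top-ranked; default 0.1 (the top
#'   decile).
#' @return A data.frame of class `cac_table` with one row per network gene:
#'   `gene`, `degree`, `n_signature`, `overlap`, `universe`, `p`, `q`,
#'   `cac_score`, `rank`, `top_decile`, `flagged`.
#' @export
cac_table <- function(net, signature, top_fraction = 0.1) {
  stopifnot(inherits(net, "coreg_network"), inherits(signature, "gene_set"))
  sig_ids <- intersect(signature$ids, net$nodes)
  n <- length(net$nodes)
  ia <- match(net$edges$gene_a, net$nodes)
  ib <- match(net$edges$gene_b, net$nodes)
  in_sig <- net$nodes %in% sig_ids
  degree <- tabulate(c(ia, ib), nbins = n)
  overlap <- tabulate(c(ia[in_sig[ib]], ib[in_sig[ia]]), nbins = n)
  # per focal gene: universe excludes the gene, so the signature loses one
  # member when the gene itself is in it
  K <- length(sig_ids) - as.integer(in_sig)
  universe <- n - 1L
  p <- stats::phyper(overlap - 1, K, universe - K, degree, lower.tail = FALSE)
  p[degree == 0 | K == 0] <- 1
  recs <- data.frame(gene = net$nodes, degree = degree, n_signature = K,
                     overlap = overlap, universe = universe, p = p,
                     flagged = degree == 0)
  recs$q <- stats::p.adjust(recs$p, "BH")
  recs$cac_score <- -log10(pmax(recs$q, .Machine$double.xmin))
  ord <- order(recs$p, -recs$overlap, recs$gene)
  recs <- recs[ord, , drop = FALSE]
  recs$rank <- seq_len(nrow(recs))
  recs$top_decile <- recs$rank <= ceiling(top_fraction * nrow(recs))
  rownames(recs) <- NULL
  structure(recs, class = c("cac_table", "data.frame"),
            signature = signature$name, top_fraction = top_fraction)
}

#' @export
print.cac_table <- function(x, ...) {
  cat(sprintf("cac_table: %d genes vs signature '%s'\n",
              nrow(x), attr(x, "signature")))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Membership of genes in the top-ranked fraction of a CAC table
#'
#' @param table A `cac_table`.
#' @param genes A `gene_set` (or character vector) of genes to look up.
#' @param fraction Fraction of the ranking considered "top"; in (0, 1].
#' @return Named logical vector: `TRUE` when the gene's rank is at most
#'   `ceiling(fraction * N)`. Genes missing from the table are `NA` and
#'   reported via a message.
#' @export
top_fraction_membership <- function(table, genes, fraction = 0.1) {
  stopifnot(inherits(table, "cac_table"), fraction > 0, fraction <= 1)
  ids <- if (inherits(genes, "gene_set")) genes$ids else as.character(genes)
  cutoff <- ceiling(fraction * nrow(table))
  idx <- match(ids, table$gene)
  out <- stats::setNames(table$rank[idx] <= cutoff, ids)
  if (anyNA(idx))
    message(sum(is.na(idx)), " gene(s) absent from the CAC table")
  out
}
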