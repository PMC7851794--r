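#' Gene set container
#'
#' @param ids Character vector of gene identifiers (de-duplicated).
#' @param name Set name.
#' @param provenance Character vector describing how the set was derived;
#'   set operations append to it so the full derivation is reconstructable.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(ids, name = "set", provenance = character(0)) {
  ids <- unique(as.character(ids))
  ids <- ids[!is.na(ids)]
  structure(list(name = name, ids = ids, provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$ids)))
  if (length(x$provenance))
    cat("provenance:\n", paste(" -", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

#' Intersection of gene sets
#'
#' The marker screen's core operation: genes present in every input set
#' (e.g. the 10 DEG sets of the TI-Treg screen, plus the surface catalog).
#'
#' @param sets A list of at least two `gene_set` objects.
#' @param name Name for the result.
#' @return A `gene_set`; provenance lists every input.
#' @export
intersect_sets <- function(sets, name = "intersection") {
  stopifnot(is.list(sets), length(sets) >= 2,
            all(vapply(sets, inherits, logical(1), "gene_set")))
  ids <- Reduce(intersect, lapply(sets, `[[`, "ids"))
  gene_set(ids, name = name,
           provenance = c(
             sprintf("intersection of %d sets: %s", length(sets),
                     paste(vapply(sets, `[[`, character(1), "name"),
                           collapse = ", ")),
             unlist(lapply(sets, `[[`, "provenance"))))
}

#' Set difference of gene sets
#'
#' Used to make the chronic-infection signature chronic-specific by
#' removing genes also responding to acute infection.
#'
#' @param minuend,subtrahend `gene_set` objects.
#' @param name Name for the result.
#' @return A `gene_set` containing `minuend` genes absent from
#'   `subtrahend`.
#' @export
subtract_sets <- function(minuend, subtrahend, name = NULL) {
  stopifnot(inherits(minuend, "gene_set"), inherits(subtrahend, "gene_set"))
  gene_set(setdiff(minuend$ids, subtrahend$ids),
           name = name %||% paste0(minuend$name, " minus ", subtrahend$name),
           provenance = c(sprintf("'%s' minus '%s'", minuend$name,
                                  subtrahend$name),
                          minuend$provenance, subtrahend$provenance))
}

#' Reciprocal-best-hit ortholog map from a similarity table
#'
#' A mouse/human pair is called orthologous when each is the other's unique
#' best-scoring partner. Ties at a best score are dropped (and reported via
#' a message) rather than resolved arbitrarily, keeping the map
#' deterministic and one-to-one.
#'
#' @param scores Data frame with columns `mouse_id`, `human_id`, `score`.
#' @return An `ortholog_map`: a data.frame of `mouse_id`, `human_id` pairs
#'   with attribute `method = "rbh"`.
#' @export
rbh_orthologs <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("mouse_id", "human_id", "score") %in% names(scores)))
  best_unique <- function(ids, partners, score) {
    out <- list()
    for (id in unique(ids)) {
      rows <- ids == id
      s <- score[rows]
      top <- max(s)
      hits <- partners[rows][s == top]
      if (length(hits) == 1) out[[id]] <- hits
    }
    out
  }
  m_best <- best_unique(scores$mouse_id, scores$human_id, scores$score)
  h_best <- best_unique(scores$human_id, scores$mouse_id, scores$score)
  pairs <- list()
  for (m in names(m_best)) {
    h <- m_best[[m]]
    if (!is.null(h_best[[h]]) && h_best[[h]] == m)
      pairs[[m]] <- h
  }
  n_tied <- length(unique(scores$mouse_id)) - length(m_best)
  if (n_tied > 0)
    message(n_tied, " mouse gene(s) dropped for tied best scores")
  ortholog_map(data.frame(mouse_id = names(pairs),
                          human_id = unlist(unname(pairs)),
                          stringsAsFactors = FALSE),
               method = "rbh")
}

#' One-to-one ortholog map
#'
#' @param pairs Data frame with columns `mouse_id` and `human_id`.
#' @param method `"provided"` or `"rbh"`.
#' @return An `ortholog_map`.
#' @export
ortholog_map <- function(pairs, method = "provided") {
  stopifnot(is.data.frame(pairs),
            all(c("mouse_id", "human_id") %in% names(pairs)))
  if (anyDuplicated(pairs$mouse_id) || anyDuplicated(pairs$human_id))
    stop("ortholog map must be one-to-one")
  rownames(pairs) <- NULL
  structure(pairs[c("mouse_id", "human_id")],
            class = c("ortholog_map", "data.frame"), method = method)
}

#' Map a gene set through an ortholog map
#'
#' @param set A `gene_set` (mouse ids by default).
#' @param map An `ortholog_map`.
#' @param reverse Map human to mouse instead.
#' @return The image `gene_set`; unmapped ids are dropped and reported via
#'   a message.
#' @export
map_set <- function(set, map, reverse = FALSE) {
  stopifnot(inherits(set, "gene_set"), inherits(map, "ortholog_map"))
  from <- if (reverse) map$human_id else map$mouse_id
  to <- if (reverse) map$mouse_id else map$human_id
  idx <- match(set$ids, from)
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    message(dropped, " id(s) without an ortholog dropped")
  gene_set(to[idx[!is.na(idx)]],
           name = paste0(set$name, if (reverse) " (mouse)" else " (human)"),
           provenance = c(sprintf("mapped via %s orthologs (%d of %d ids)",
                                  attr(map, "method"),
                                  length(set$ids) - dropped, length(set$ids)),
                          set$provenance))
}

#' Human-conserved marker candidates
#'
#' Keeps the mouse candidate markers whose human orthologs are
#' differentially expressed in the tumor-Treg population against every
#' comparison population (the three TTR contrasts).
#'
#' @param mouse_candidates `gene_set` of mouse candidate markers.
#' @param human_deg_sets List of `gene_set`s of human DEGs, one per
#'   contrast.
#' @param map An `ortholog_map`.
#' @return A human-id `gene_set` of conserved markers.
#' @export
conserved_markers <- function(mouse_candidates, human_deg_sets, map) {
  stopifnot(is.list(human_deg_sets), length(human_deg_sets) >= 1)
  human <- map_set(mouse_candidates, map)
  intersect_sets(c(list(human), human_deg_sets), name = "conserved markers")
}

#' Significance of the overlap between two gene sets
#'
#' One-sided hypergeometric upper-tail probability of observing at least
#' the realized overlap when `|A|` genes are drawn from a universe of size
#' `N` containing `|B|` marked genes (equivalently Fisher's exact test for
#' enrichment).
#'
#' @param setA,setB `gene_set`s, both subsets of `universe`.
#' @param universe A `gene_set` defining the background.
#' @return List with `overlap` (count) and `p_value`.
#' @export
overlap_significance <- function(setA, setB, universe) {
  stopifnot(inherits(setA, "gene_set"), inherits(setB, "gene_set"),
            inherits(universe, "gene_set"))
  N <- length(universe$ids)
  if (N == 0) stop("empty universe")
  if (length(setdiff(setA$ids, universe$ids)) ||
      length(setdiff(setB$ids, universe$ids)))
    stop("both sets must be subsets of the universe")
  k <- length(intersect(setA$ids, setB$ids))
  nA <- length(setA$ids); nB <- length(setB$ids)
  p <- stats::phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  list(overlap = k, p_value = p)
}
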