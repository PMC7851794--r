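#' Read an expression matrix from TSV or MatrixMarket triplet
#'
#' TSV: genes as rows, first column gene ids, header row of sample ids.
#' MTX: triplet file plus sidecar row-name (genes) and column-name
#' (barcodes) files, one id per line.
#'
#' @param path Matrix file.
#' @param format `"tsv"` or `"mtx"`.
#' @param meta Optional path to a sample-metadata TSV (columns `sample`,
#'   `population`, ...); when absent, every sample gets population
#'   `"unknown"`.
#' @param genes_file,barcodes_file Sidecar name files (MTX only); default
#'   `<path>.genes.tsv` / `<path>.barcodes.tsv`.
#' @param scale `"count"` or `"log-intensity"`.
#' @return An `expr_matrix`.
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"), meta = NULL,
                        genes_file = NULL, barcodes_file = NULL,
                        scale = "count") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    genes <- as.character(dt[[1]])
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
      stop("duplicated gene row(s): ", paste(utils::head(dup, 5), collapse = ", "))
    values <- as.matrix(dt[, -1, drop = FALSE])
    rownames(values) <- genes
  } else {
    genes_file <- genes_file %||% paste0(path, ".genes.tsv")
    barcodes_file <- barcodes_file %||% paste0(path, ".barcodes.tsv")
    mm <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_file)
    barcodes <- readLines(barcodes_file)
    if (nrow(mm) != length(genes) || ncol(mm) != length(barcodes))
      stop(sprintf("MTX dimensions %dx%d do not match %d gene / %d barcode names",
                   nrow(mm), ncol(mm), length(genes), length(barcodes)))
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
      stop("duplicated gene row(s): ", paste(utils::head(dup, 5), collapse = ", "))
    values <- mm
    dimnames(values) <- list(genes, barcodes)
  }
  sample_meta <- if (!is.null(meta))
    data.table::fread(meta, sep = "\t", header = TRUE, data.table = FALSE)
  else data.frame(sample = colnames(values), population = "unknown")
  expression_matrix(values, sample_meta, scale = scale)
}

#' Write an expression matrix (and optionally its metadata) as TSV
#'
#' @param mat An `expr_matrix`.
#' @param path Output TSV; genes as rows, first column `gene`.
#' @param meta Optional path for the sample-metadata TSV.
#' @param digits Significant digits for numeric values; default 6.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, meta = NULL, digits = 6) {
  stopifnot(inherits(mat, "expr_matrix"))
  vals <- mat$values
  if (mat$scale != "count") vals <- signif(vals, digits)
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  if (!is.null(meta))
    data.table::fwrite(mat$sample_meta, meta, sep = "\t")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then tab-separated gene ids. Duplicate
#' ids within a set are deduplicated with a warning; duplicate set names
#' and lines with fewer than three fields are errors naming the line.
#'
#' @param path GMT file.
#' @return Named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": needs name, description and >= 1 id")
    name <- fields[1]
    if (name %in% names(sets))
      stop("duplicate set name '", name, "' at line ", i)
    ids <- fields[-(1:2)]
    if (anyDuplicated(ids)) {
      warning("duplicate ids in set '", name, "' deduplicated")
      ids <- unique(ids)
    }
    sets[[name]] <- gene_set(ids, name = name, provenance = fields[2])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    desc <- if (length(s$provenance)) s$provenance[1] else "na"
    paste(c(s$name, desc, s$ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a survival cohort TSV
#'
#' Columns: `subject`, `time`, `event`, and any of `response`, `stage`,
#' `marker_expr`, `normalizer_expr`.
#'
#' @param path TSV file.
#' @return A `survival_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("subject", "time", "event")
  if (!all(need %in% names(df)))
    stop("cohort file needs columns: ", paste(need, collapse = ", "))
  if (any(df$time < 0)) stop("negative follow-up times")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  class(df) <- c("survival_cohort", "data.frame")
  df
}

#' @rdname read_cohort
#' @param cohort A `survival_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(as.data.frame(cohort), path, sep = "\t")
  invisible(path)
}

#' Read / write a coregulatory network edge list
#'
#' Edge TSV columns: `gene_a`, `gene_b`, `r`, `p`; a sidecar node file
#' holds one gene id per line (so isolated nodes survive the round trip).
#'
#' @param path Edge-list TSV.
#' @param nodes_file Node list; default `<path>.nodes.tsv`.
#' @param m_samples Sample count behind the correlations (stored in the
#'   node file header comment on write, required on read).
#' @return A `coreg_network`.
#' @export
read_network <- function(path, nodes_file = NULL, m_samples = NULL) {
  nodes_file <- nodes_file %||% paste0(path, ".nodes.tsv")
  edges <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  lines <- readLines(nodes_file)
  if (is.null(m_samples)) {
    header <- grep("^#m_samples=", lines, value = TRUE)
    if (length(header))
      m_samples <- as.integer(sub("^#m_samples=", "", header[1]))
    else stop("m_samples not recorded in node file and not supplied")
  }
  nodes <- lines[!startsWith(lines, "#")]
  structure(list(nodes = nodes, edges = edges, m_samples = m_samples,
                 p_threshold = NA_real_, flagged = character(0)),
            class = "coreg_network")
}

#' @rdname read_network
#' @param net A `coreg_network`.
#' @export
write_network <- function(net, path, nodes_file = NULL) {
  nodes_file <- nodes_file %||% paste0(path, ".nodes.tsv")
  edges <- net$edges
  edges$r <- signif(edges$r, 6)
  edges$p <- signif(edges$p, 6)
  data.table::fwrite(edges, path, sep = "\t")
  writeLines(c(sprintf("#m_samples=%d", net$m_samples), net$nodes), nodes_file)
  invisible(path)
}
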