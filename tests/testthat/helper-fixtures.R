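# Small, fast configurations and hand-built matrices shared across tests.

small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_genes = 400,
    surface_fraction = 0.2,
    n_planted_markers = 10,
    module_spec = data.frame(size = c(12, 12), r = 0.9),
    sc_populations = data.frame(label = c("TTR", "NTR", "PTR", "TTH"),
                                n_cells = 60),
    n_chronic_specific = 30,
    n_shared = 15,
    cohort_n = 100,
    seed = seed)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(sim_config, defaults)
}

# expr_matrix from a plain matrix; populations given per column
toy_matrix <- function(values, populations,
                       scale = "log-intensity",
                       gene_ids = sprintf("g%d", seq_len(nrow(values)))) {
  rownames(values) <- gene_ids
  colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values,
                    data.frame(sample = colnames(values),
                               population = populations),
                    scale = scale)
}

# deg_table from a plain data.frame (for selection-rule tests)
new_deg_table_for_test <- function(df, engine) {
  structure(df, class = c("deg_table", "data.frame"), engine = engine,
            test_group = "T", reference_group = "R")
}

# network from an explicit edge list (r/p filled with placeholders)
toy_network <- function(nodes, edge_pairs, m_samples = 10) {
  edges <- if (length(edge_pairs)) {
    a <- vapply(edge_pairs, `[`, character(1), 1)
    b <- vapply(edge_pairs, `[`, character(1), 2)
    swap <- a > b
    data.frame(gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b),
               r = 0.99, p = 1e-6)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               r = numeric(0), p = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges, m_samples = m_samples,
                 p_threshold = 0.01, flagged = character(0)),
            class = "coreg_network")
}

# small end-to-end pipeline configuration
pipeline_test_config <- function(outdir, seed = 1L) {
  pipeline_config(
    outdir = outdir, seed = seed,
    sim = list(n_genes = 300, surface_fraction = 0.2,
               n_planted_markers = 10,
               module_spec = data.frame(size = c(12, 12), r = 0.9),
               sc_populations = data.frame(
                 label = c("TTR", "NTR", "PTR", "TTH"), n_cells = 50),
               n_chronic_specific = 25, n_shared = 10, cohort_n = 80),
    n_draws = 2000)
}
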