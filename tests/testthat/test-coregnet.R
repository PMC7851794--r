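test_that("expression filter thresholds on negative-marker maxima", {
  x <- rbind(g1 = c(6, 1), g2 = c(8, 2), neg1 = c(5, 1), neg2 = c(7, 2))
  mat <- toy_matrix(x, c("A", "A"), gene_ids = rownames(x))
  neg <- gene_set(c("neg1", "neg2"), "neg")
  out <- filter_expressed(mat, neg)
  expect_equal(attr(out, "threshold"), 7)  # max of marker maxima {5, 7}
  expect_setequal(rownames(out$values), "g2")  # max 6 removed, max 8 kept
  # mean rule: threshold 6 keeps nothing extra here but is exposed
  expect_equal(attr(filter_expressed(mat, neg, rule = "mean"), "threshold"), 6)
  # missing markers are reported; none present is an error
  expect_message(filter_expressed(mat, gene_set(c("neg1", "nope"), "neg")),
                 "nope")
  expect_error(filter_expressed(mat, gene_set("nope", "neg")), "no negative")
  # everything at or below the floor: empty matrix with warning
  low <- toy_matrix(rbind(g1 = c(1, 1), neg1 = c(5, 5)), c("A", "A"),
                    gene_ids = c("g1", "neg1"))
  expect_warning(filter_expressed(low, gene_set("neg1", "neg")), "all genes")
})

test_that("expression filter agrees with a direct scan on simulated data", {
  cfg <- small_config(seed = 3)
  b <- simulate_bulk(cfg)
  norm <- normalize_counts(b$matrix)
  neg <- gene_set(b$truth$negative_marker_ids, "neg")
  out <- filter_expressed(norm, neg)
  thr <- max(apply(norm$values[neg$ids, ], 1, max))
  keep <- setdiff(rownames(norm$values)[apply(norm$values, 1, max) > thr],
                  neg$ids)
  expect_setequal(rownames(out$values), keep)
})

test_that("RMS normalization scales rows to unit root mean square", {
  mat <- toy_matrix(rbind(c(1, 1, 1), c(3, 4, 0)), rep("A", 3))
  out <- rms_normalize(mat)
  expect_equal(out$values[1, ], c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(sqrt(rowMeans(out$values^2)), c(g1 = 1, g2 = 1), tolerance = 1e-9)
  # the spec's 2-sample row: [3,4] / sqrt(12.5)
  two <- rms_normalize(toy_matrix(matrix(c(3, 4), 1, 2), rep("A", 2)))
  expect_equal(unname(two$values[1, ]), c(0.848528, 1.131371), tolerance = 1e-6)
  # PCC between rows is unchanged
  set.seed(12)
  x <- matrix(rnorm(5 * 10, 10), 5, 10)
  raw <- toy_matrix(x, rep("A", 10))
  expect_equal(cor(t(rms_normalize(raw)$values)), cor(t(x)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_warning(rms_normalize(toy_matrix(rbind(c(0, 0), c(1, 2)), rep("A", 2))),
                 "all-zero")
})

test_that("edge significance follows the t transform of the correlation", {
  # build 3 samples' worth ... m = 5 samples, one pair with r = 0.9 exactly
  base <- c(-1.2816, -0.5244, 0, 0.5244, 1.2816)
  y <- 0.9 * base + sqrt(1 - 0.81) * c(0.3246, -1.2001, 0.8059, -0.4871, 0.5567)
  # orthogonalize then mix to force sample r = 0.9
  e <- residuals(lm(y ~ base)); e <- e / sqrt(sum(e^2)); b2 <- base / sqrt(sum(base^2))
  y <- 0.9 * b2 + sqrt(1 - 0.81) * e
  x <- rbind(b2, y, rnorm(5))
  mat <- toy_matrix(x, rep("A", 5))
  expect_equal(cor(x[1, ], x[2, ]), 0.9, tolerance = 1e-9)  # fixture self-check
  net05 <- pcc_edges(mat, p_threshold = 0.05)
  net01 <- pcc_edges(mat, p_threshold = 0.01)
  has_edge <- function(net, a, b)
    any(net$edges$gene_a == a & net$edges$gene_b == b)
  # r = 0.9 at m = 5: t = 3.576, p ~ 0.0374
  expect_true(has_edge(net05, "g1", "g2"))
  expect_false(has_edge(net01, "g1", "g2"))
  e <- net05$edges[net05$edges$gene_a == "g1" & net05$edges$gene_b == "g2", ]
  expect_equal(e$p, 0.03738607, tolerance = 1e-6)
})

test_that("perfect and undefined correlations are handled", {
  x <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(5, 5, 5, 5), c(0.3, -2, 1, 0.5))
  net <- pcc_edges(toy_matrix(x, rep("A", 4)), p_threshold = 0.01)
  # |r| = 1 pair survives without division error
  expect_true(any(net$edges$gene_a == "g1" & net$edges$gene_b == "g2"))
  # constant gene is flagged and contributes no edges
  expect_identical(net$flagged, "g3")
  expect_false(any(net$edges$gene_a == "g3" | net$edges$gene_b == "g3"))
  expect_error(pcc_edges(toy_matrix(x[, 1:2], rep("A", 2))), "3 samples")
})

test_that("network edges match a dense per-pair recomputation", {
  cfg <- small_config(seed = 14, n_genes = 150, surface_fraction = 0.1,
                      module_spec = data.frame(size = 10, r = 0.9))
  norm <- normalize_counts(simulate_bulk(cfg)$matrix)
  treg <- subset_populations(norm, c("TBM-TI-Treg", "TBM-SP-Treg", "NM-SP-Treg"))
  net <- pcc_edges(rms_normalize(treg), p_threshold = 0.01)
  # oracle: per-pair cor.test over all pairs
  x <- rms_normalize(treg)$values
  n_expected <- 0
  for (i in 1:(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
    p <- cor.test(x[i, ], x[j, ])$p.value
    if (p < 0.01) n_expected <- n_expected + 1
  }
  expect_equal(nrow(net$edges), n_expected)
  # symmetric and simple: stored once, lexicographic, no self-edges
  expect_true(all(net$edges$gene_a < net$edges$gene_b))
  expect_false(anyDuplicated(paste(net$edges$gene_a, net$edges$gene_b)) > 0)
})

test_that("planted modules are denser than background in the network", {
  cfg <- small_config(seed = 26)
  b <- simulate_bulk(cfg)
  norm <- normalize_counts(b$matrix)
  treg <- subset_populations(norm, c("TBM-TI-Treg", "TBM-SP-Treg", "NM-SP-Treg"))
  net <- pcc_edges(rms_normalize(treg), p_threshold = 0.01)
  module_genes <- intersect(names(b$truth$module_membership), net$nodes)
  obs <- within_group_connectivity(net, gene_set(module_genes, "modules"))
  dens_mod <- obs / choose(length(module_genes), 2)
  dens_all <- nrow(net$edges) / choose(length(net$nodes), 2)
  expect_gt(dens_mod, dens_all)
})

test_that("within-group connectivity counts internal links exactly", {
  net <- toy_network(c("a", "b", "c", "d", "e"),
                     list(c("a", "b"), c("b", "c"), c("a", "c"), c("d", "a")))
  expect_equal(within_group_connectivity(net, gene_set(c("a", "b", "c"))), 3)
  expect_equal(within_group_connectivity(net, gene_set(c("d", "e"))), 0)
  expect_error(within_group_connectivity(net, gene_set("a")), "fewer than 2")
  expect_message(within_group_connectivity(net, gene_set(c("a", "b", "zz"))),
                 "not in network")
  # random graph vs an edge-list scan oracle
  set.seed(31)
  nodes <- sprintf("n%d", 1:30)
  pairs <- t(combn(nodes, 2))
  sel <- pairs[runif(nrow(pairs)) < 0.2, ]
  net2 <- toy_network(nodes, split(sel, row(sel)))
  grp <- sample(nodes, 8)
  oracle <- sum(apply(sel, 1, function(e) all(e %in% grp)))
  expect_equal(within_group_connectivity(net2, gene_set(grp)), oracle)
})

test_that("connectivity null test matches exhaustive enumeration", {
  # triangle {a,b,c} plus isolated {d,e}: only 1 of the C(5,3)=10 groups
  # reaches connectivity 3
  net <- toy_network(c("a", "b", "c", "d", "e"),
                     list(c("a", "b"), c("b", "c"), c("a", "c")))
  res <- connectivity_null_test(net, gene_set(c("a", "b", "c")))
  expect_identical(res$method, "exhaustive")
  expect_equal(res$p_value, 1 / 10)
  # sampled estimate converges to the same value (add-one corrected)
  samp <- connectivity_null_test(net, gene_set(c("a", "b", "c")),
                                 n_draws = 20000, seed = 2,
                                 exhaustive_limit = 0)
  expect_identical(samp$method, "sampled")
  mc_se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(samp$p_value - 0.1), 3 * mc_se + 1 / 20001)
  # seeded determinism
  samp2 <- connectivity_null_test(net, gene_set(c("a", "b", "c")),
                                  n_draws = 20000, seed = 2,
                                  exhaustive_limit = 0)
  expect_identical(samp$p_value, samp2$p_value)
  expect_error(connectivity_null_test(net, gene_set(letters[1:9])), "exceeds")
})
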