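#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-data generators.
#' The defaults define the study conditions used throughout the test suite:
#' six bulk CD4+ T-cell populations with three replicates each, 2,000 genes
#' of which 15% are cell-surface, 30 planted TI-Treg markers at a 4-fold
#' induction, five coregulated modules of 20 genes at within-module
#' correlation 0.9, and a 300-subject survival cohort whose hazard scales
#' with the FOXP3-normalized marker score.
#'
#' @param n_genes Number of genes.
#' @param populations Data frame with columns `label` and `n_reps` (bulk) or
#'   `n_cells` (single-cell). The first row is the target (TI-Treg / TTR)
#'   population. Defaults to the six bulk populations.
#' @param target_population Label of the population in which markers are
#'   planted; default the first `populations$label`.
#' @param surface_fraction Proportion of genes flagged as cell-surface.
#' @param n_planted_markers Number of surface genes induced in the target
#'   population only.
#' @param marker_log2fc Planted induction, log2 units (2 = 4-fold).
#' @param nb_dispersion Common negative-binomial dispersion. The default
#'   0.01 reflects sorted, near-homogeneous cell populations from inbred
#'   mice, where replicate-to-replicate biological variability is low.
#' @param planted_floor_log2 Floor on the base log2 mean of planted marker
#'   and module genes (default 7, about 128 counts): surface markers are
#'   screened among detectably expressed genes and coexpression modules are
#'   measured on genes that survive the expression filter, so planting them
#'   at the noise floor would emulate data the method never sees.
#' @param module_spec Data frame with columns `size` (genes per module,
#'   including its hub) and `r` (target within-module Pearson correlation).
#' @param module_sd Latent-factor standard deviation on the log2 scale
#'   shared by module genes; large relative to count noise so the observed
#'   correlation tracks the latent target.
#' @param signature_overlap Proportion of each module's non-hub genes placed
#'   in the context signature.
#' @param libsize_cv Coefficient of variation of log-normal library sizes.
#' @param base_log2_mean,base_log2_sd Log-normal law of gene base means
#'   (log2 scale).
#' @param n_negative_markers Genes planted at the noise floor to serve as
#'   negative (non-T-cell) markers for expression filtering.
#' @param dropout_logit Length-2 numeric `c(intercept, slope)` of the
#'   detection model: a single-cell measurement is detected with probability
#'   `plogis(intercept + slope * log2(mu + 1))` and dropped out otherwise,
#'   so lowering the intercept raises the observed zero fraction.
#' @param sc_populations Population labels for the single-cell generator.
#' @param conserved_fraction Proportion of planted markers whose human
#'   orthologs are also planted in the single-cell TTR population.
#' @param ortholog_fraction Proportion of genes with a one-to-one human
#'   ortholog in the emitted map.
#' @param n_chronic_specific,n_shared Microarray genes induced in chronic
#'   infection only / in both chronic and acute.
#' @param ma_reps Microarray replicates per condition.
#' @param ma_log2fc Planted microarray effect, log2 units.
#' @param cohort_n Survival-cohort size (>= 20).
#' @param hazard_ratio Hazard multiplier per unit of marker score (> 0).
#' @param censor_rate Expected proportion censored, in [0, 1).
#' @param stage_effect Shift of the marker score per tumor stage above 1.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       populations = default_bulk_populations(),
                       target_population = NULL,
                       surface_fraction = 0.15,
                       n_planted_markers = 30,
                       marker_log2fc = 2,
                       nb_dispersion = 0.01,
                       planted_floor_log2 = 7,
                       module_spec = data.frame(size = rep(20, 5), r = 0.9),
                       module_sd = 2,
                       signature_overlap = 0.6,
                       libsize_cv = 0.2,
                       base_log2_mean = 6,
                       base_log2_sd = 1.5,
                       n_negative_markers = 6,
                       dropout_logit = c(intercept = -1, slope = 0.6),
                       sc_populations = data.frame(
                         label = c("TTR", "NTR", "PTR", "TTH"),
                         n_cells = 200),
                       conserved_fraction = 0.8,
                       ortholog_fraction = 0.9,
                       n_chronic_specific = 60,
                       n_shared = 40,
                       ma_reps = 5,
                       ma_log2fc = 2,
                       cohort_n = 300,
                       hazard_ratio = 2.5,
                       censor_rate = 0.3,
                       stage_effect = 0.3,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  if (is.null(cfg$target_population))
    cfg$target_population <- populations$label[1]
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_bulk_populations <- function() {
  data.frame(
    label = c("TBM-TI-Treg", "TBM-TI-Tconv", "TBM-SP-Treg",
              "NM-SP-Treg", "TBM-SP-Tconv", "NM-SP-Tconv"),
    tissue = c("tumor", "tumor", "spleen", "spleen", "spleen", "spleen"),
    n_reps = 3L)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$cohort_n >= 1, cfg$ma_reps >= 2)
  props <- c(cfg$surface_fraction, cfg$signature_overlap,
             cfg$conserved_fraction, cfg$ortholog_fraction)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  if (cfg$hazard_ratio <= 0)
    stop("hazard_ratio must be positive")
  if (cfg$nb_dispersion <= 0)
    stop("nb_dispersion must be positive")
  low <- cfg$populations$n_reps < 2
  if (any(low))
    stop("population(s) with fewer than 2 replicates: ",
         paste(cfg$populations$label[low], collapse = ", "))
  n_special <- ceiling(cfg$surface_fraction * cfg$n_genes) +
    sum(cfg$module_spec$size) + cfg$n_negative_markers
  if (n_special > cfg$n_genes)
    stop("surface, module and negative-marker genes exceed n_genes")
  if (cfg$n_planted_markers > ceiling(cfg$surface_fraction * cfg$n_genes))
    stop("planted markers must fit inside the surface catalog")
  invisible(cfg)
}

# Deterministic gene layout shared by the generators: surface catalog first
# (markers at its head), then module blocks, then negative markers, then
# background. Module memberships are disjoint and disjoint from the surface
# catalog so latent-factor covariance cannot leak into the marker screen.
gene_layout <- function(cfg) {
  ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  n_surface <- ceiling(cfg$surface_fraction * cfg$n_genes)
  surface <- ids[seq_len(n_surface)]
  markers <- surface[seq_len(cfg$n_planted_markers)]
  pos <- n_surface
  modules <- vector("list", nrow(cfg$module_spec))
  for (k in seq_len(nrow(cfg$module_spec))) {
    size <- cfg$module_spec$size[k]
    modules[[k]] <- ids[pos + seq_len(size)]
    pos <- pos + size
  }
  negative <- ids[pos + seq_len(cfg$n_negative_markers)]
  list(ids = ids, surface = surface, markers = markers,
       modules = modules, negative = negative)
}

new_sim_truth <- function(...) structure(list(...), class = "sim_truth")

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:",
      length(x$planted_marker_ids), "planted markers,",
      length(x$hub_ids), "hubs,",
      length(x$signature_ids), "signature genes\n")
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate the six-population bulk RNA-seq experiment
#'
#' Negative-binomial counts with log-normally distributed gene base means, a
#' common dispersion, and log-normal library sizes. Planted markers are
#' induced by `marker_log2fc` in the target population only. Each module's
#' genes share a latent Gaussian factor on the log2-mean scale: the hub
#' carries the factor itself and every member loads on it with
#' `sqrt(r)` so the latent member-member correlation equals the configured
#' `r` (hub-member correlation `sqrt(r)`). Negative-marker genes sit at the
#' noise floor.
#'
#' @param config A `sim_config`.
#' @return A list with elements `matrix` (count-scale `expr_matrix`) and
#'   `truth` (a `sim_truth` with `planted_marker_ids`, `surface_ids`,
#'   `hub_ids`, `module_membership`, `signature_ids`, `negative_marker_ids`).
#' @export
simulate_bulk <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  lay <- gene_layout(config)
  pops <- config$populations
  with_seed(config$seed, {
    samples <- data.frame(
      sample = unlist(lapply(seq_len(nrow(pops)), function(i)
        sprintf("%s_r%d", pops$label[i], seq_len(pops$n_reps[i])))),
      population = rep(pops$label, pops$n_reps),
      tissue = if ("tissue" %in% names(pops))
        rep(pops$tissue, pops$n_reps) else NA,
      replicate = unlist(lapply(pops$n_reps, seq_len)))
    m <- nrow(samples)
    n <- config$n_genes

    base <- stats::rnorm(n, config$base_log2_mean, config$base_log2_sd)
    names(base) <- lay$ids
    planted <- c(lay$markers, unlist(lay$modules))
    base[planted] <- pmax(base[planted], config$planted_floor_log2)
    base[lay$negative] <- 1  # noise floor: ~2 counts

    log2mu <- matrix(base, n, m, dimnames = list(lay$ids, samples$sample))
    target_cols <- samples$population == config$target_population
    log2mu[lay$markers, target_cols] <-
      log2mu[lay$markers, target_cols] + config$marker_log2fc

    hubs <- character(0)
    membership <- character(0)
    signature <- character(0)
    for (k in seq_along(lay$modules)) {
      genes <- lay$modules[[k]]
      r <- config$module_spec$r[k]
      tau <- config$module_sd
      f <- stats::rnorm(m)                       # shared latent factor
      hub <- genes[1]
      members <- genes[-1]
      log2mu[hub, ] <- log2mu[hub, ] + tau * f + stats::rnorm(m, 0, 0.05)
      load <- sqrt(r) * tau
      noise <- sqrt(1 - r) * tau
      for (g in members)
        log2mu[g, ] <- log2mu[g, ] + load * f + stats::rnorm(m, 0, noise)
      hubs <- c(hubs, hub)
      membership <- c(membership,
                      stats::setNames(rep(hub, length(genes)), genes))
      n_sig <- ceiling(config$signature_overlap * length(members))
      signature <- c(signature, members[seq_len(n_sig)])
    }

    libsize <- stats::rlnorm(m, 0, config$libsize_cv)
    libsize <- libsize / mean(libsize)
    mu <- sweep(2^log2mu, 2, libsize, "*")
    counts <- matrix(stats::rnbinom(n * m, mu = mu, size = 1 / config$nb_dispersion),
                     n, m, dimnames = dimnames(mu))

    truth <- new_sim_truth(
      planted_marker_ids = lay$markers,
      surface_ids = lay$surface,
      hub_ids = hubs,
      module_membership = membership,
      signature_ids = unique(c(signature, lay$markers)),
      module_signature_ids = unique(signature),
      negative_marker_ids = lay$negative)
    list(matrix = expression_matrix(counts, samples, scale = "count"),
         truth = truth)
  })
}

#' Simulate the four-population single-cell experiment
#'
#' Zero-inflated negative-binomial counts over presorted populations
#' (tumor Treg TTR, adjacent-normal Treg NTR, blood Treg PTR, tumor
#' conventional helper TTH by default). Dropout probability per entry is
#' `1 - plogis(intercept + slope * log2(mu + 1))`, so lowering the
#' intercept raises the observed zero fraction. Human orthologs of a
#' `conserved_fraction` of the planted bulk markers are induced in TTR only.
#'
#' @param config A `sim_config`.
#' @return List with `matrix` (count `expr_matrix`, human gene ids) and
#'   `truth` (`planted_marker_ids` on the human side, `conserved_mouse_ids`,
#'   and `ortholog_pairs`, a data.frame of mouse/human id pairs).
#' @export
simulate_singlecell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  lay <- gene_layout(config)
  pops <- config$sc_populations
  if (nrow(pops) < 2) stop("need at least two single-cell populations")
  with_seed(config$seed + 1L, {
    human_ids <- sub("^g", "h", lay$ids)
    n_orth <- floor(config$ortholog_fraction * config$n_genes)
    # markers first so conserved markers are always mapped
    orth_mouse <- unique(c(lay$markers, lay$ids))[seq_len(n_orth)]
    ortholog_pairs <- data.frame(mouse_id = orth_mouse,
                                 human_id = sub("^g", "h", orth_mouse))

    n_cons <- floor(config$conserved_fraction * length(lay$markers))
    conserved_mouse <- lay$markers[seq_len(n_cons)]
    planted_human <- sub("^g", "h", conserved_mouse)

    samples <- data.frame(
      sample = unlist(lapply(seq_len(nrow(pops)), function(i)
        sprintf("%s_c%03d", pops$label[i], seq_len(pops$n_cells[i])))),
      population = rep(pops$label, pops$n_cells),
      replicate = unlist(lapply(pops$n_cells, seq_len)))
    m <- nrow(samples)
    n <- config$n_genes

    base <- stats::rnorm(n, 3, 1.2)  # lower means than bulk
    log2mu <- matrix(base, n, m, dimnames = list(human_ids, samples$sample))
    target_cols <- samples$population == pops$label[1]
    log2mu[planted_human, target_cols] <-
      log2mu[planted_human, target_cols] + config$marker_log2fc

    mu <- 2^log2mu
    pi_drop <- 1 - stats::plogis(config$dropout_logit[[1]] +
                                 config$dropout_logit[[2]] * log2(mu + 1))
    if (any(!is.finite(pi_drop) | pi_drop < 0 | pi_drop >= 1))
      stop("dropout probability outside [0, 1) after logistic transform")
    counts <- matrix(stats::rnbinom(n * m, mu = mu, size = 1 / config$nb_dispersion),
                     n, m, dimnames = dimnames(mu))
    keep <- matrix(stats::rbinom(n * m, 1, 1 - pi_drop), n, m)
    counts <- counts * keep

    truth <- new_sim_truth(
      planted_marker_ids = planted_human,
      conserved_mouse_ids = conserved_mouse,
      ortholog_pairs = ortholog_pairs)
    list(matrix = expression_matrix(counts, samples, scale = "count"),
         truth = truth)
  })
}

#' Simulate the three-condition Treg microarray experiment
#'
#' Log-normal intensities (Gaussian on the log2 scale) for naive,
#' acute-infection and chronic-infection Tregs. A chronic-specific gene set
#' is induced in the chronic condition only; a shared set is induced in both
#' chronic and acute, exercising the acute-from-chronic subtraction rule.
#' The chronic-specific set contains the planted bulk markers, so the core
#' signature (bulk DEGs intersected with chronic-specific DEGs) recovers
#' them.
#'
#' @param config A `sim_config`.
#' @return List with `matrix` (log-intensity `expr_matrix`) and `truth`
#'   (`chronic_specific_ids`, `shared_ids`).
#' @export
simulate_microarray <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  lay <- gene_layout(config)
  with_seed(config$seed + 2L, {
    conditions <- c("chronic", "acute", "naive")
    samples <- data.frame(
      sample = sprintf("%s_r%d", rep(conditions, each = config$ma_reps),
                       rep(seq_len(config$ma_reps), 3)),
      population = rep(conditions, each = config$ma_reps),
      condition = rep(conditions, each = config$ma_reps),
      replicate = rep(seq_len(config$ma_reps), 3))
    m <- nrow(samples)
    n <- config$n_genes

    # chronic-specific genes: the planted markers plus extra non-surface genes
    extra_pool <- setdiff(lay$ids, c(lay$surface, unlist(lay$modules), lay$negative))
    n_extra <- max(0, config$n_chronic_specific - length(lay$markers))
    if (n_extra + config$n_shared > length(extra_pool))
      stop("n_chronic_specific + n_shared exceed the available background genes")
    chronic_specific <- c(lay$markers, extra_pool[seq_len(n_extra)])
    shared <- extra_pool[n_extra + seq_len(config$n_shared)]

    base <- stats::rnorm(n, 8, 1)
    x <- matrix(stats::rnorm(n * m, base, 0.5), n, m,
                dimnames = list(lay$ids, samples$sample))
    chronic_cols <- samples$condition == "chronic"
    acute_cols <- samples$condition == "acute"
    x[chronic_specific, chronic_cols] <-
      x[chronic_specific, chronic_cols] + config$ma_log2fc
    x[shared, chronic_cols] <- x[shared, chronic_cols] + config$ma_log2fc
    x[shared, acute_cols] <- x[shared, acute_cols] + config$ma_log2fc

    truth <- new_sim_truth(chronic_specific_ids = chronic_specific,
                           shared_ids = shared)
    list(matrix = expression_matrix(x, samples, scale = "log-intensity"),
         truth = truth)
  })
}

#' Simulate a survival / response cohort
#'
#' Each subject carries a latent marker score (standard normal plus a tumor
#' stage effect); normalizer (FOXP3-like) expression is log-normal and
#' marker expression equals normalizer times `2^score`, so the log2
#' FOXP3-normalized ratio recovers the score. Event times are exponential
#' with hazard `0.1 * hazard_ratio^score`; censoring times are independent
#' Uniform(0, C) with C calibrated so the expected censored proportion
#' equals `censor_rate`. Binary response is drawn with log-odds `-score`.
#'
#' @param config A `sim_config` with `cohort_n >= 20`.
#' @return A data.frame of class `survival_cohort` with columns `subject`,
#'   `time`, `event`, `response`, `stage`, `marker_expr`, `normalizer_expr`.
#'   The true per-subject score is attached as attribute `"true_score"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (config$cohort_n < 20) stop("cohort_n must be at least 20")
  with_seed(config$seed + 3L, {
    n <- config$cohort_n
    stage <- sample(1:4, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    score <- stats::rnorm(n) + config$stage_effect * (stage - 1)
    normalizer <- stats::rlnorm(n, 2, 0.5)
    marker <- normalizer * 2^score
    rate <- 0.1 * config$hazard_ratio^score
    t_event <- stats::rexp(n, rate)
    if (config$censor_rate > 0) {
      cens_frac <- function(C) mean(pmin(t_event / C, 1)) - config$censor_rate
      C <- stats::uniroot(cens_frac, c(1e-6, 1e9), tol = 1e-8)$root
      t_cens <- stats::runif(n, 0, C)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    response <- stats::rbinom(n, 1, stats::plogis(-score))
    cohort <- data.frame(
      subject = sprintf("s%04d", seq_len(n)),
      time = time, event = event, response = response, stage = stage,
      marker_expr = marker, normalizer_expr = normalizer)
    class(cohort) <- c("survival_cohort", "data.frame")
    attr(cohort, "true_score") <- score
    cohort
  })
}
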