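#' Pipeline configuration
#'
#' Collects the thresholds, stage toggles and seed of an end-to-end run on
#' synthetic data. Stage outputs land under `outdir`; a stage whose outputs
#' already exist for the same configuration is skipped unless an upstream
#' stage was recomputed, so deleting one stage's directory recomputes only
#' that stage and its dependents.
#'
#' @param outdir Output directory.
#' @param seed Integer master seed; all stage randomness derives from it.
#' @param sim Named list of overrides passed to [sim_config()].
#' @param fc_threshold,p_threshold DEG selection rules (fold units /
#'   probability).
#' @param edge_p Edge significance threshold of the network stage.
#' @param n_draws Draws of the connectivity null test.
#' @param upper,lower Stratification quantiles of the outcome stage.
#' @param stages Stages to run, in dependency order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = list(),
                            fc_threshold = 2, p_threshold = 0.01,
                            edge_p = 0.01, n_draws = 10000,
                            upper = 0.3, lower = 0.3,
                            stages = c("simulate", "de", "signature",
                                       "network", "cac", "outcome")) {
  stopifnot(fc_threshold > 1, p_threshold > 0, p_threshold < 1,
            edge_p > 0, edge_p < 1, upper + lower <= 1)
  known <- c("simulate", "de", "signature", "network", "cac", "outcome")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 edge_p = edge_p, n_draws = n_draws,
                 upper = upper, lower = lower,
                 stages = intersect(known, stages)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`
#' block holds [sim_config()] overrides.
#'
#' @param path YAML file.
#' @param outdir Overrides the file's `outdir` when given.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  y$outdir <- outdir %||% y$outdir
  if (is.null(y$outdir)) stop("config must set outdir")
  for (field in c("module_spec", "populations", "sc_populations"))
    if (!is.null(y$sim[[field]]))
      y$sim[[field]] <- as.data.frame(y$sim[[field]])
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "outdir")]), tmp)
  unname(tools::md5sum(tmp))
}

stage_done <- function(outdir, stage, hash) {
  f <- file.path(outdir, paste0(".done_", stage))
  file.exists(f) && identical(readLines(f)[1], hash)
}

mark_done <- function(outdir, stage, hash) {
  writeLines(hash, file.path(outdir, paste0(".done_", stage)))
}

#' Run the full marker-discovery pipeline on synthetic data
#'
#' Executes, in dependency order: `simulate` (bulk, single-cell,
#' microarray and cohort generators with planted truth), `de` (Welch and
#' Characteristic Direction contrasts of the target population against
#' every other bulk population; two-part tests of TTR against the other
#' single-cell populations; chronic/acute microarray contrasts),
#' `signature` (the 10-set surface-restricted marker screen, the
#' chronic-specific subtraction, the core signature, conserved human
#' markers via the ortholog map), `network` (expression filter, RMS
#' normalization and PCC edges over the Treg populations, plus the
#' connectivity null test on the planted module group), `cac`
#' (context-associated centrality against the core signature) and
#' `outcome` (FOXP3-normalized score, stratified Kaplan-Meier and log-rank,
#' waterfall deltas, stage comparison).
#'
#' @param config A `pipeline_config`.
#' @param force Recompute every stage even if outputs exist.
#' @return The run manifest (list, also written as `manifest.json`):
#'   per-stage summaries -- set sizes, network size, top CAC genes, outcome
#'   p-values -- plus the configuration hash.
#' @export
run_all <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  manifest <- list(config_hash = hash, seed = config$seed, stages = list())
  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  simcfg <- do.call(sim_config, sim_args)
  ran_upstream <- force

  paths <- list(
    bulk = file.path(out, "bulk_counts.tsv"),
    bulk_meta = file.path(out, "bulk_meta.tsv"),
    sc = file.path(out, "sc_counts.tsv"),
    sc_meta = file.path(out, "sc_meta.tsv"),
    ma = file.path(out, "microarray.tsv"),
    ma_meta = file.path(out, "microarray_meta.tsv"),
    cohort = file.path(out, "cohort.tsv"),
    catalogs = file.path(out, "catalogs.gmt"),
    orthologs = file.path(out, "orthologs.tsv"),
    degs = file.path(out, "degs"),
    sets = file.path(out, "sets.gmt"),
    network = file.path(out, "network_edges.tsv"),
    cac = file.path(out, "cac.tsv"),
    outcome = file.path(out, "outcome"))

  # -- simulate ---------------------------------------------------------
  if ("simulate" %in% config$stages) {
    if (ran_upstream || !stage_done(out, "simulate", hash)) {
      bulk <- simulate_bulk(simcfg)
      sc <- simulate_singlecell(simcfg)
      ma <- simulate_microarray(simcfg)
      cohort <- simulate_cohort(simcfg)
      write_matrix(bulk$matrix, paths$bulk, meta = paths$bulk_meta)
      write_matrix(sc$matrix, paths$sc, meta = paths$sc_meta)
      write_matrix(ma$matrix, paths$ma, meta = paths$ma_meta)
      write_cohort(cohort, paths$cohort)
      tr <- bulk$truth
      write_gmt(list(
        gene_set(tr$surface_ids, "surface_catalog", "simulated surface genes"),
        gene_set(tr$negative_marker_ids, "negative_markers", "simulated non-T-cell markers"),
        gene_set(tr$planted_marker_ids, "planted_markers", "ground truth"),
        gene_set(tr$hub_ids, "planted_hubs", "ground truth"),
        gene_set(tr$module_signature_ids, "module_signature", "ground truth"),
        gene_set(names(tr$module_membership), "module_genes", "ground truth"),
        gene_set(sc$truth$planted_marker_ids, "planted_human_markers", "ground truth"),
        gene_set(ma$truth$chronic_specific_ids, "chronic_specific_truth", "ground truth")),
        paths$catalogs)
      data.table::fwrite(sc$truth$ortholog_pairs, paths$orthologs, sep = "\t")
      mark_done(out, "simulate", hash)
      ran_upstream <- TRUE
    }
    catalogs <- read_gmt(paths$catalogs)
    manifest$stages$simulate <- list(
      n_genes = simcfg$n_genes,
      n_bulk_samples = sum(simcfg$populations$n_reps),
      n_cells = sum(simcfg$sc_populations$n_cells),
      n_planted_markers = length(catalogs$planted_markers$ids),
      cohort_n = simcfg$cohort_n)
  }

  # -- de ---------------------------------------------------------------
  if ("de" %in% config$stages) {
    dir.create(paths$degs, showWarnings = FALSE)
    if (ran_upstream || !stage_done(out, "de", hash)) {
      bulk <- read_matrix(paths$bulk, meta = paths$bulk_meta, scale = "count")
      norm <- normalize_counts(bulk)
      target <- simcfg$target_population
      others <- setdiff(unique(bulk$sample_meta$population), target)
      index <- list()
      save_degs <- function(tab, name) {
        f <- file.path(paths$degs, paste0(name, ".tsv"))
        data.table::fwrite(as.data.frame(tab), f, sep = "\t")
        index[[length(index) + 1]] <<- data.frame(
          name = name, engine = attr(tab, "engine"),
          test = paste(attr(tab, "test_group"), collapse = "|"),
          reference = paste(attr(tab, "reference_group"), collapse = "|"))
      }
      for (pop in others) {
        save_degs(two_sample_test(norm, target, pop),
                  paste0("bulk_", gsub("[^A-Za-z0-9]", "", pop), "_welch"))
        save_degs(characteristic_direction(norm, target, pop),
                  paste0("bulk_", gsub("[^A-Za-z0-9]", "", pop), "_cd"))
      }
      save_degs(two_sample_test(norm, target, others), "bulk_pooled_welch")
      sc <- read_matrix(paths$sc, meta = paths$sc_meta, scale = "count")
      ttr <- simcfg$sc_populations$label[1]
      for (pop in setdiff(unique(sc$sample_meta$population), ttr))
        save_degs(two_part_zero_inflated_test(sc, ttr, pop),
                  paste0("sc_", pop, "_twopart"))
      ma <- read_matrix(paths$ma, meta = paths$ma_meta,
                        scale = "log-intensity")
      save_degs(two_sample_test(ma, "chronic", "naive"), "ma_chronic_welch")
      save_degs(two_sample_test(ma, "acute", "naive"), "ma_acute_welch")
      data.table::fwrite(do.call(rbind, index),
                         file.path(paths$degs, "index.tsv"), sep = "\t")
      mark_done(out, "de", hash)
      ran_upstream <- TRUE
    }
    idx <- data.table::fread(file.path(paths$degs, "index.tsv"),
                             data.table = FALSE)
    manifest$stages$de <- list(n_contrasts = nrow(idx),
                               engines = sort(unique(idx$engine)))
  }

  load_degs <- function(name) {
    idx <- data.table::fread(file.path(paths$degs, "index.tsv"),
                             data.table = FALSE)
    row <- idx[idx$name == name, ]
    tab <- data.table::fread(file.path(paths$degs, paste0(name, ".tsv")),
                             data.table = FALSE)
    new_deg_table(tab, row$engine, strsplit(row$test, "|", fixed = TRUE)[[1]],
                  strsplit(row$reference, "|", fixed = TRUE)[[1]])
  }

  # -- signature --------------------------------------------------------
  if ("signature" %in% config$stages) {
    if (ran_upstream || !stage_done(out, "signature", hash)) {
      catalogs <- read_gmt(paths$catalogs)
      idx <- data.table::fread(file.path(paths$degs, "index.tsv"),
                               data.table = FALSE)
      bulk_names <- idx$name[grepl("^bulk_", idx$name) &
                               idx$name != "bulk_pooled_welch"]
      deg_sets <- lapply(bulk_names, function(nm)
        select_degs(load_degs(nm), config$fc_threshold, config$p_threshold,
                    direction = "up", name = nm))
      candidates <- intersect_sets(c(deg_sets, list(catalogs$surface_catalog)),
                                   name = "candidate_markers")
      sc_names <- idx$name[grepl("^sc_", idx$name)]
      sc_sets <- lapply(sc_names, function(nm)
        select_degs(load_degs(nm), config$fc_threshold, config$p_threshold,
                    direction = "up", name = nm))
      orth <- ortholog_map(data.table::fread(paths$orthologs,
                                             data.table = FALSE))
      conserved <- conserved_markers(candidates, sc_sets, orth)
      chronic <- select_degs(load_degs("ma_chronic_welch"),
                             config$fc_threshold, config$p_threshold,
                             direction = "both", name = "chronic_degs")
      acute <- select_degs(load_degs("ma_acute_welch"),
                           config$fc_threshold, config$p_threshold,
                           direction = "both", name = "acute_degs")
      chronic_specific <- subtract_sets(chronic, acute, name = "chronic_specific")
      bulk_degs <- select_degs(load_degs("bulk_pooled_welch"),
                               config$fc_threshold, config$p_threshold,
                               direction = "both", name = "bulk_ti_treg_degs")
      core <- intersect_sets(list(bulk_degs, chronic_specific),
                             name = "core_signature")
      write_gmt(list(candidates, conserved, chronic_specific, bulk_degs, core),
                paths$sets)
      mark_done(out, "signature", hash)
      ran_upstream <- TRUE
    }
    sets <- read_gmt(paths$sets)
    manifest$stages$signature <- list(
      n_candidates = length(sets$candidate_markers$ids),
      n_conserved = length(sets$`conserved markers`$ids),
      n_chronic_specific = length(sets$chronic_specific$ids),
      n_core_signature = length(sets$core_signature$ids))
  }

  # -- network ----------------------------------------------------------
  if ("network" %in% config$stages) {
    if (ran_upstream || !stage_done(out, "network", hash)) {
      catalogs <- read_gmt(paths$catalogs)
      bulk <- read_matrix(paths$bulk, meta = paths$bulk_meta, scale = "count")
      norm <- normalize_counts(bulk)
      treg_pops <- grep("Treg$", unique(norm$sample_meta$population),
                        value = TRUE)
      treg <- subset_populations(norm, treg_pops)
      filtered <- filter_expressed(treg, catalogs$negative_markers)
      net <- pcc_edges(rms_normalize(filtered), p_threshold = config$edge_p)
      write_network(net, paths$network)
      conn <- connectivity_null_test(net, catalogs$module_genes,
                                     n_draws = config$n_draws,
                                     seed = config$seed + 11L,
                                     exhaustive_limit = 0)
      writeLines(jsonlite::toJSON(conn[c("group", "observed", "n_draws",
                                         "p_value", "method")],
                                  auto_unbox = TRUE, digits = 10),
                 file.path(out, "connectivity.json"))
      mark_done(out, "network", hash)
      ran_upstream <- TRUE
    }
    net <- read_network(paths$network)
    conn <- jsonlite::read_json(file.path(out, "connectivity.json"))
    manifest$stages$network <- list(
      n_nodes = length(net$nodes), n_edges = nrow(net$edges),
      module_connectivity = conn$observed,
      module_connectivity_p = conn$p_value)
  }

  # -- cac --------------------------------------------------------------
  if ("cac" %in% config$stages) {
    if (ran_upstream || !stage_done(out, "cac", hash)) {
      net <- read_network(paths$network)
      sets <- read_gmt(paths$sets)
      cac <- cac_table(net, sets$core_signature)
      data.table::fwrite(as.data.frame(cac), paths$cac, sep = "\t")
      mark_done(out, "cac", hash)
      ran_upstream <- TRUE
    }
    cac <- data.table::fread(paths$cac, data.table = FALSE)
    manifest$stages$cac <- list(
      n_ranked = nrow(cac),
      top_genes = utils::head(cac$gene, 10),
      top_decile_size = sum(cac$top_decile))
  }

  # -- outcome ----------------------------------------------------------
  if ("outcome" %in% config$stages) {
    dir.create(paths$outcome, showWarnings = FALSE)
    if (ran_upstream || !stage_done(out, "outcome", hash)) {
      cohort <- read_cohort(paths$cohort)
      scores <- marker_score(cohort)
      strata <- stratify(scores, upper = config$upper, lower = config$lower)
      hi <- cohort[strata$stratum == "High", ]
      lo <- cohort[strata$stratum == "Low", ]
      lr <- logrank_test(hi, lo)
      data.table::fwrite(strata, file.path(paths$outcome, "strata.tsv"),
                         sep = "\t")
      data.table::fwrite(km_curve(hi), file.path(paths$outcome, "km_high.tsv"),
                         sep = "\t")
      data.table::fwrite(km_curve(lo), file.path(paths$outcome, "km_low.tsv"),
                         sep = "\t")
      data.table::fwrite(waterfall_deltas(cohort, scores),
                         file.path(paths$outcome, "waterfall.tsv"), sep = "\t")
      stage_p <- if (all(c(1, 4) %in% cohort$stage))
        stage_comparison(scores[cohort$stage == 4],
                         scores[cohort$stage == 1])$p_value
      else NA_real_
      writeLines(jsonlite::toJSON(list(logrank_chisq = lr$chisq,
                                       logrank_p = lr$p_value,
                                       stage_p = stage_p,
                                       n_high = nrow(hi), n_low = nrow(lo)),
                                  auto_unbox = TRUE, digits = 10),
                 file.path(paths$outcome, "tests.json"))
      mark_done(out, "outcome", hash)
    }
    manifest$stages$outcome <- jsonlite::read_json(
      file.path(paths$outcome, "tests.json"))
  }

  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = 10,
                                    pretty = TRUE)
  writeLines(manifest_json, file.path(out, "manifest.json"))
  invisible(manifest)
}
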