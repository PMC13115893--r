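# End-to-end orchestration: simulate (or load) -> harmonize -> screen ->
# select -> train/compare -> panel sweep -> map/classify -> ORA ->
# network scoring, with per-stage seeds derived from one global seed and a
# machine-readable run report.

#' Pipeline configuration
#'
#' Desk-scale defaults: the synthetic cohort uses the default
#' [sim_config()] study shape (94 cases / 31 controls, 2000 CpGs, 100
#' planted differential sites), while screening-pool sizes, selection
#' grids and the fusion-model dimensions are scaled to sizes a single CPU
#' handles in minutes. Every stage parameter is overridable.
#'
#' @param sim A [sim_config()] for self-contained synthetic runs, or
#'   `NULL` when `paths` supplies real inputs.
#' @param paths Named list of input paths (`matrix`, `sheet`,
#'   `annotation`, `effectors`, `edge_list`, `gene_sets`) for runs on real
#'   data; unused entries may be omitted.
#' @param screen List: `k_t_pool`, `window_bp`, `p_thresh`,
#'   `delta_thresh`.
#' @param select List: `size_grid`, `elim_fraction`, `n_trees`,
#'   `n_folds`.
#' @param model List of [fusion_config()] overrides applied to every
#'   fusion-model training (e.g. `d_model`, `n_layers`, `max_epochs`).
#' @param sweep List: `size_grid`, `n_repeats` for the panel sweep.
#' @param network List: `min_score`, `w_degree`, `w_between`, `top_k`,
#'   `n_hubs` (synthetic network), `n_sets`, `enriched_fraction`
#'   (synthetic gene sets).
#' @param compare_repeats Stratified-split repeats for the feature-set
#'   comparison table.
#' @param out_dir Directory for stage artifacts; `NULL` skips writing.
#' @param seed Global seed; each stage derives its own seed from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            paths = NULL,
                            screen = list(),
                            select = list(),
                            model = list(),
                            sweep = list(),
                            network = list(),
                            compare_repeats = 2L,
                            out_dir = NULL,
                            seed = 1L) {
  merge_defaults <- function(user, defaults) {
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    sim = sim,
    paths = paths,
    screen = merge_defaults(screen, list(
      k_t_pool = 300L, window_bp = 2000L, p_thresh = 0.05,
      delta_thresh = 0.2)),
    select = merge_defaults(select, list(
      size_grid = c(50L, 100L, 150L), elim_fraction = 0.2,
      n_trees = 200L, n_folds = 5L)),
    model = merge_defaults(model, list(
      d_model = 16L, cnn_out = 16L, fusion_dim = 16L, n_heads = 2L,
      n_layers = 1L, ff_dim = 32L, kernel_sizes = c(5L, 3L),
      conv_channels = c(8L, 16L), dropout = 0.1, lr = 2e-3,
      batch_size = 16L, max_epochs = 40L, patience = 8L)),
    sweep = merge_defaults(sweep, list(
      size_grid = c(40L, 60L, 80L), n_repeats = 1L)),
    network = merge_defaults(network, list(
      min_score = 500L, w_degree = 0.5, w_between = 0.5, top_k = 20L,
      n_hubs = 3L, n_sets = 30L, enriched_fraction = 0.1)),
    compare_repeats = assert_count(compare_repeats, "compare_repeats"),
    out_dir = out_dir,
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (is.null(cfg$sim) && is.null(cfg$paths)) {
    stop_oam("either a simulation block or input paths must be provided")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

make_model_config <- function(n_features, overrides, seed) {
  args <- c(list(n_features = n_features, seed = seed), overrides)
  do.call(fusion_config, args)
}

#' Compare diagnostic performance across feature sets
#'
#' Trains the fusion classifier on each feature set under identical
#' stratified splits and seeds, over `n_repeats` repeats, and reports the
#' mean and standard deviation of validation ACC, F1 and AUC per set.
#' Empty feature sets are skipped with a warning.
#'
#' @param sets Named list of probe-id character vectors (e.g. `T-sites`,
#'   `G-sites`, `U-sites`, `panel`).
#' @param X,y Labeled data (samples x probes) covering all sets.
#' @param model_overrides List of [fusion_config()] overrides.
#' @param n_repeats Number of repeated stratified splits.
#' @param seed Global seed.
#' @return data.frame: one row per set with `acc_mean`, `acc_sd`,
#'   `f1_mean`, `f1_sd`, `auc_mean`, `auc_sd`, `n_features`.
#' @export
compare_feature_sets <- function(sets, X, y, model_overrides = list(),
                                 n_repeats = 2L, seed = 1L) {
  rows <- list()
  for (nm in names(sets)) {
    ids <- intersect(sets[[nm]], colnames(X))
    if (length(ids) < 2) {
      warning(sprintf("feature set '%s' is empty or too small; skipped", nm))
      next
    }
    mets <- matrix(NA_real_, n_repeats, 3)
    for (r in seq_len(n_repeats)) {
      cfg <- make_model_config(length(ids), model_overrides,
                               derive_seed(seed, r))
      hold <- stratified_holdout(y, cfg$val_fraction, cfg$seed)
      m <- train_fusion_model(X[-hold, ids, drop = FALSE], y[-hold], cfg,
                              X_val = X[hold, ids, drop = FALSE],
                              y_val = y[hold])
      met <- evaluate_model(m, X[hold, ids, drop = FALSE], y[hold])
      mets[r, ] <- c(met$acc, met$f1, met$auc)
    }
    rows[[nm]] <- data.frame(
      set = nm, n_features = length(ids),
      acc_mean = mean(mets[, 1]), acc_sd = stats::sd(mets[, 1]),
      f1_mean = mean(mets[, 2]), f1_sd = stats::sd(mets[, 2]),
      auc_mean = mean(mets[, 3]), auc_sd = stats::sd(mets[, 3]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> harmonize -> dual-strategy screening ->
#' consensus feature selection -> fusion-model comparison -> gradient
#' panel sweep -> gene mapping and effector classification ->
#' over-representation analysis -> network hub scoring, returning a
#' machine-readable run report. All randomness derives from
#' `config$seed`, so a fixed seed reproduces the report exactly
#' ([report_fingerprint()]).
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-stage progress lines.
#' @return A list of class `run_report`; see the `stages` element for
#'   per-stage outputs and sizes.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  report <- list(config_seed = config$seed, stages = list())
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  # -- stage 1: inputs ---------------------------------------------------
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- derive_seed(config$seed, 1L)
    cohort <- generate_cohort(sim_cfg)
    bm_raw <- cohort$beta
    annotation <- cohort$annotation
    truth <- cohort$truth
    effectors <- truth$effector_genes
    say("simulate: %d CpGs x %d samples", nrow(bm_raw$values),
        ncol(bm_raw$values))
  } else {
    p <- config$paths
    for (need in c("matrix", "sheet", "annotation", "effectors")) {
      if (is.null(p[[need]])) stop_oam("paths$%s is required", need)
    }
    bm_raw <- read_beta_matrix(p$matrix, p$sheet)
    annotation <- read_cpg_annotation(p$annotation)
    effectors <- readLines(p$effectors)
    truth <- NULL
  }
  report$stages$input <- list(n_cpg = nrow(bm_raw$values),
                              n_samples = ncol(bm_raw$values),
                              n_case = sum(bm_raw$labels == 1L),
                              n_control = sum(bm_raw$labels == 0L))

  # -- stage 2: harmonize ------------------------------------------------
  bm <- harmonize_datasets(bm_raw, annotation)
  say("harmonize: %d CpGs retained", nrow(bm$values))
  report$stages$harmonize <- list(n_cpg = nrow(bm$values))

  # -- stage 3: screening ------------------------------------------------
  sc <- config$screen
  dm <- differential_methylation(bm)
  t_pool <- select_t_pool(dm, k = min(sc$k_t_pool, nrow(dm)))
  sig <- significant_sites(dm, sc$p_thresh, sc$delta_thresh)
  g_pool <- select_g_pool(annotation, effectors, sc$window_bp)
  say("screen: T-pool %d, G-pool %d, significant %d",
      length(t_pool$cpg_ids), length(g_pool$cpg_ids), length(sig))
  report$stages$screen <- list(
    t_pool_size = length(t_pool$cpg_ids),
    g_pool_size = length(g_pool$cpg_ids),
    n_significant = length(sig),
    n_hyper = sum(dm$direction == "hyper" & dm$cpg_id %in% t_pool$cpg_ids),
    n_hypo = sum(dm$direction == "hypo" & dm$cpg_id %in% t_pool$cpg_ids))

  # -- stage 4: consensus selection ---------------------------------------
  X_all <- t(bm$values)
  y <- bm$labels
  sel <- config$select
  select_pool <- function(pool, tag, offset) {
    ids <- intersect(pool$cpg_ids, colnames(X_all))
    Xp <- X_all[, ids, drop = FALSE]
    grid <- sel$size_grid[sel$size_grid <= ncol(Xp)]
    if (length(grid) == 0) grid <- ncol(Xp)
    seed_s <- derive_seed(config$seed, offset)
    rk_svm <- svm_rfe_ranking(Xp, y, elim_fraction = sel$elim_fraction,
                              seed = seed_s)
    rk_rf <- rf_importance_ranking(Xp, y, n_trees = sel$n_trees,
                                   seed = seed_s)
    cv_svm <- cv_subset_selection(rk_svm, Xp, y, grid, sel$n_folds, seed_s,
                                  n_trees = sel$n_trees)
    cv_rf <- cv_subset_selection(rk_rf, Xp, y, grid, sel$n_folds, seed_s,
                                 n_trees = sel$n_trees)
    top_svm <- rk_svm$ranked_cpg_ids[seq_len(cv_svm$optimal_size)]
    top_rf <- rk_rf$ranked_cpg_ids[seq_len(cv_rf$optimal_size)]
    list(sites = consensus_sites(top_svm, top_rf, set_tag = tag),
         svm_size = cv_svm$optimal_size, rf_size = cv_rf$optimal_size)
  }
  t_sel <- select_pool(t_pool, "T-sites", 41L)
  g_sel <- select_pool(g_pool, "G-sites", 42L)
  u_sites <- union_sites(t_sel$sites, g_sel$sites)
  say("select: T-sites %d, G-sites %d, U-sites %d",
      length(t_sel$sites$cpg_ids), length(g_sel$sites$cpg_ids),
      length(u_sites$cpg_ids))
  report$stages$select <- list(
    svm_optimal_t = t_sel$svm_size, rf_optimal_t = t_sel$rf_size,
    svm_optimal_g = g_sel$svm_size, rf_optimal_g = g_sel$rf_size,
    t_sites = length(t_sel$sites$cpg_ids),
    g_sites = length(g_sel$sites$cpg_ids),
    t_g_overlap = u_sites$source_sizes[3],
    u_sites = length(u_sites$cpg_ids))

  # -- stage 5: model comparison -----------------------------------------
  comp <- compare_feature_sets(
    list(`T-sites` = t_sel$sites$cpg_ids, `G-sites` = g_sel$sites$cpg_ids,
         `U-sites` = u_sites$cpg_ids),
    X_all, y, model_overrides = config$model,
    n_repeats = config$compare_repeats, seed = derive_seed(config$seed, 51L))
  say("compare: U-sites mean val ACC %.4f",
      comp$acc_mean[comp$set == "U-sites"])
  report$stages$compare <- comp

  # -- stage 6: panel sweep ----------------------------------------------
  u_ids <- u_sites$cpg_ids
  ucfg <- make_model_config(length(u_ids), config$model,
                            derive_seed(config$seed, 61L))
  u_model <- train_fusion_model(X_all[, u_ids, drop = FALSE], y, ucfg)
  imp <- gradient_importance(u_model, X_all[, u_ids, drop = FALSE])
  sw_grid <- config$sweep$size_grid[config$sweep$size_grid <= length(u_ids)]
  if (length(sw_grid) == 0) sw_grid <- length(u_ids)
  sweep <- panel_sweep(imp, X_all[, u_ids, drop = FALSE], y,
                       size_grid = sw_grid, config = ucfg,
                       n_repeats = config$sweep$n_repeats)
  panel <- sweep$panel_cpg_ids
  prov <- panel_provenance(panel, t_sel$sites, g_sel$sites)
  gates <- gate_contribution(u_model, X_all[, u_ids, drop = FALSE])
  say("sweep: panel size %d (T %d / G %d)", length(panel),
      prov$n_from_t, prov$n_from_g)
  report$stages$panel <- list(
    best_size = sweep$best_size,
    acc_curve = sweep$per_size,
    n_from_t = prov$n_from_t, n_from_g = prov$n_from_g,
    pct_from_t = prov$pct_from_t, pct_from_g = prov$pct_from_g,
    mean_transformer_weight = round(gates$mean_transformer_weight, 4),
    mean_cnn_weight = round(gates$mean_cnn_weight, 4))

  # -- stage 7: gene mapping + effector classification -------------------
  mapped <- map_cpg_to_genes(panel, annotation)
  eff_cls <- classify_effector_status(mapped$genes, effectors, character(0))
  say("map: %d genes (%d validated effectors, %d novel)",
      length(mapped$genes), eff_cls$n_validated, eff_cls$n_novel)
  report$stages$genes <- list(
    n_genes = length(mapped$genes), n_unmapped_probes = length(mapped$unmapped),
    n_validated = eff_cls$n_validated, n_database = eff_cls$n_database,
    n_novel = eff_cls$n_novel)

  # -- stage 8: over-representation --------------------------------------
  universe <- sort(unique(annotation$links$gene))
  nw <- config$network
  if (!is.null(config$paths$gene_sets)) {
    gs <- read_gmt(config$paths$gene_sets)
    gs_truth <- NULL
  } else {
    gsim <- generate_gene_sets(universe, n_sets = nw$n_sets,
                               enriched_fraction = nw$enriched_fraction,
                               seed = derive_seed(config$seed, 81L),
                               query_genes = mapped$genes)
    gs <- gsim$sets
    gs_truth <- gsim$truth
  }
  ora <- hypergeometric_ora(mapped$genes, gs, universe)
  say("ora: top set %s (adj_p %.3g)", ora$set_name[1], ora$adj_p[1])
  report$stages$enrichment <- list(
    n_sets = length(gs), top_set = ora$set_name[1],
    top_adj_p = ora$adj_p[1],
    n_significant = sum(ora$adj_p < 0.05))

  # -- stage 9: network scoring ------------------------------------------
  if (!is.null(config$paths$edge_list)) {
    net <- load_edge_list(config$paths$edge_list, nw$min_score)
    net_truth <- NULL
  } else {
    nsim <- generate_interaction_network(
      mapped$genes, n_hubs = min(nw$n_hubs, length(mapped$genes)),
      seed = derive_seed(config$seed, 91L))
    net <- nsim$network
    net$edges <- net$edges[net$edges$combined_score >= nw$min_score, ,
                           drop = FALSE]
    net <- interaction_network(net$edges, net$nodes)
    net_truth <- nsim$truth
  }
  hubs <- composite_node_score(net, nw$w_degree, nw$w_between, nw$top_k)
  say("network: %d nodes, top node %s", length(net$nodes), hubs$node[1])
  report$stages$network <- list(
    n_nodes = length(net$nodes), n_edges = nrow(net$edges),
    top_nodes = hubs$node, top_composite = hubs$composite)

  report$truth <- if (!is.null(truth)) {
    list(n_dm = length(truth$dm_cpg_ids),
         t_pool_recall = length(intersect(t_pool$cpg_ids, truth$dm_cpg_ids)) /
           max(1L, length(truth$dm_cpg_ids)),
         planted_hub_in_top = if (!is.null(net_truth)) {
           sum(net_truth$hub_nodes %in% hubs$node)
         } else NA,
         enriched_set_top = if (!is.null(gs_truth)) {
           ora$set_name[1] %in% gs_truth$enriched_sets
         } else NA)
  } else NULL

  report$panel <- panel
  report$elapsed_s <- proc.time()[["elapsed"]] - t0
  class(report) <- "run_report"

  if (!is.null(out_dir)) write_report_artifacts(report, bm, dm, out_dir)
  report
}

write_report_artifacts <- function(report, bm, dm, out_dir) {
  write_beta_matrix(bm, file.path(out_dir, "beta_harmonized.tsv"))
  write_dm_table(dm, file.path(out_dir, "dm_table.tsv"))
  writeLines(report$panel, file.path(out_dir, "panel.txt"))
  jsonlite::write_json(strip_timing(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

strip_timing <- function(report) {
  report$elapsed_s <- NULL
  unclass(report)
}

#' Fingerprint of a run report
#'
#' MD5 digest of the canonical JSON serialization of the report with
#' timing fields removed; two runs of [run_pipeline()] with the same
#' configuration and seed yield identical fingerprints.
#'
#' @param report A `run_report`.
#' @return Character MD5 string.
#' @export
report_fingerprint <- function(report) {
  stopifnot(inherits(report, "run_report"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(strip_timing(report), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$stages
  cat("run_report\n")
  cat(sprintf("  input:    %d CpGs x %d samples\n", s$input$n_cpg,
              s$input$n_samples))
  cat(sprintf("  screen:   T-pool %d / G-pool %d / significant %d\n",
              s$screen$t_pool_size, s$screen$g_pool_size,
              s$screen$n_significant))
  cat(sprintf("  select:   T %d / G %d / U %d\n", s$select$t_sites,
              s$select$g_sites, s$select$u_sites))
  cat(sprintf("  panel:    %d sites (T %.1f%% / G %.1f%%)\n",
              s$panel$best_size, s$panel$pct_from_t, s$panel$pct_from_g))
  cat(sprintf("  genes:    %d mapped, %d validated, %d novel\n",
              s$genes$n_genes, s$genes$n_validated, s$genes$n_novel))
  cat(sprintf("  network:  %d nodes, top %s\n", s$network$n_nodes,
              s$network$top_nodes[1]))
  cat(sprintf("  elapsed:  %.1f s\n", x$elapsed_s))
  invisible(x)
}
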