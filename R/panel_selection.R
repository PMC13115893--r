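# Gradient-saliency biomarker panel selection.
#
# U-site probes are ranked by mean absolute gradient of the positive-class
# logit with respect to the input beta value; nested prefix subsets over a
# size grid are retrained and the size with the best mean validation
# accuracy becomes the biomarker panel.

#' Gradient importance of input CpGs
#'
#' Computes, for each probe, the mean over samples of the absolute
#' gradient of the positive-class logit with respect to the input beta
#' value, and returns probes in descending importance (probe-id
#' tie-break).
#'
#' @param model A trained `fusion_model`.
#' @param X Input samples (matrix, samples x features).
#' @param signed Return the signed mean gradient instead of the mean
#'   absolute gradient (default FALSE).
#' @return List of class `importance_ranking`: `ranked_cpg_ids`,
#'   `scores` (importance in ranked order), `raw` (per-probe importance in
#'   input order).
#' @export
gradient_importance <- function(model, X, signed = FALSE) {
  check_model_input(model, X)
  Xs <- scale(X, model$center, model$scale)
  cfg <- model$config
  acc <- matrix(0, nrow(Xs), cfg$n_features)
  for (i in seq_len(nrow(Xs))) {
    cache <- fusion_forward(Xs[i, ], model$params, cfg)
    grads <- zero_like(model$params)
    bw <- fusion_backward(c(0, 1), cache, model$params, cfg, grads)
    # chain through the input standardization back to the beta scale
    acc[i, ] <- bw$dx / model$scale
  }
  imp <- if (signed) colMeans(acc) else colMeans(abs(acc))
  ids <- if (!is.null(model$feature_ids)) model$feature_ids else
    sprintf("f%05d", seq_len(cfg$n_features))
  names(imp) <- ids
  ord <- order(-imp, ids)
  structure(
    list(ranked_cpg_ids = ids[ord], scores = unname(imp[ord]), raw = imp),
    class = "importance_ranking"
  )
}

#' Panel subset-size sweep
#'
#' Trains and evaluates the fusion model on each nested prefix of the
#' importance ranking over a grid of subset sizes, under identical seeds
#' and train/validation splits, and selects the size with the highest mean
#' validation accuracy (ties broken toward the smaller panel).
#'
#' @param ranking An `importance_ranking` (or character vector of probe
#'   ids in descending importance).
#' @param X,y Labeled data covering all ranked probes.
#' @param size_grid Candidate panel sizes (default the 100-320 grid).
#' @param config A [fusion_config()] template; `n_features` is overridden
#'   per size.
#' @param n_repeats Independent stratified splits averaged per size.
#' @return List of class `panel_sweep`: `size_grid`, `mean_acc_per_size`,
#'   `best_size`, `panel_cpg_ids`, `per_size` (data.frame).
#' @export
panel_sweep <- function(ranking, X, y,
                        size_grid = c(100L, 120L, 150L, 180L, 200L, 220L,
                                      250L, 280L, 300L, 320L),
                        config, n_repeats = 3L) {
  ids <- if (inherits(ranking, "importance_ranking")) ranking$ranked_cpg_ids
         else as.character(ranking)
  size_grid <- sort(unique(as.integer(size_grid)))
  if (max(size_grid) > length(ids)) {
    stop_oam("size grid exceeds ranking length (%d)", length(ids))
  }
  if (!all(ids %in% colnames(X))) stop_oam("X lacks some ranked probes")
  accs <- matrix(NA_real_, length(size_grid), n_repeats)
  for (si in seq_along(size_grid)) {
    k <- size_grid[si]
    feats <- ids[seq_len(k)]
    for (r in seq_len(n_repeats)) {
      cfg <- config
      cfg$n_features <- k
      cfg$seed <- derive_seed(config$seed, r)
      hold <- stratified_holdout(y, cfg$val_fraction, cfg$seed)
      m <- train_fusion_model(X[-hold, feats, drop = FALSE], y[-hold], cfg,
                              X_val = X[hold, feats, drop = FALSE],
                              y_val = y[hold])
      accs[si, r] <- evaluate_model(m, X[hold, feats, drop = FALSE],
                                    y[hold])$acc
    }
  }
  mean_acc <- rowMeans(accs)
  best <- order(-mean_acc, size_grid)[1]
  structure(
    list(size_grid = size_grid, mean_acc_per_size = mean_acc,
         best_size = size_grid[best],
         panel_cpg_ids = ids[seq_len(size_grid[best])],
         per_size = data.frame(size = size_grid, mean_acc = mean_acc)),
    class = "panel_sweep"
  )
}

#' @export
print.panel_sweep <- function(x, ...) {
  cat(sprintf("panel_sweep: best size %d (mean val ACC %.4f) of grid %s\n",
              x$best_size, max(x$mean_acc_per_size),
              paste(x$size_grid, collapse = ",")))
  invisible(x)
}

#' Panel provenance accounting
#'
#' Attributes each panel probe to its source feature set. Probes present
#' in both T-sites and G-sites are assigned to G-sites under the default
#' `"assign-to-G"` policy. Percentages are rounded to one decimal and
#' reconciled to sum to 100.
#'
#' @param panel Character vector of panel probe ids.
#' @param t_sites,g_sites `feature_set`s or character vectors.
#' @param overlap_policy `"assign-to-G"` (default) or `"assign-to-T"`.
#' @return List of class `panel_provenance`: `n_from_t`, `n_from_g`,
#'   `pct_from_t`, `pct_from_g`, `overlap_policy`.
#' @export
panel_provenance <- function(panel, t_sites, g_sites,
                             overlap_policy = c("assign-to-G", "assign-to-T")) {
  overlap_policy <- match.arg(overlap_policy)
  panel <- unique(as.character(panel))
  tv <- as_id_set(t_sites); gv <- as_id_set(g_sites)
  outside <- setdiff(panel, union(tv, gv))
  if (length(outside) > 0) {
    stop_oam("panel probes outside both source sets: %s",
             paste(utils::head(outside, 5), collapse = ", "))
  }
  both <- intersect(panel, intersect(tv, gv))
  if (overlap_policy == "assign-to-G") {
    n_g <- length(intersect(panel, gv))
    n_t <- length(panel) - n_g
  } else {
    n_t <- length(intersect(panel, tv))
    n_g <- length(panel) - n_t
  }
  pct_t <- round(100 * n_t / length(panel), 1)
  pct_g <- round(100 * n_g / length(panel), 1)
  if (pct_t + pct_g != 100) pct_t <- round(100 - pct_g, 1)
  structure(
    list(n_from_t = n_t, n_from_g = n_g, pct_from_t = pct_t,
         pct_from_g = pct_g, n_overlap = length(both),
         overlap_policy = overlap_policy),
    class = "panel_provenance"
  )
}

#' @export
print.panel_provenance <- function(x, ...) {
  cat(sprintf("panel_provenance: T %d (%.1f%%) / G %d (%.1f%%), policy %s\n",
              x$n_from_t, x$pct_from_t, x$n_from_g, x$pct_from_g,
              x$overlap_policy))
  invisible(x)
}
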