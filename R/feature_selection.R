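# Consensus machine-learning feature selection.
#
# Two independent rankers — SVM-RFE (linear max-margin weights, recursive
# elimination) and random-forest mean-decrease-in-impurity — are each run on
# a feature pool; cross-validation over a size grid picks each ranker's
# optimal subset; the intersection of the two subsets gives the consensus
# sites, and the union of the T- and G-derived consensus sets gives the
# integrated U-sites.

#' SVM-RFE feature ranking
#'
#' Recursive feature elimination driven by a linear-kernel support vector
#' machine: at each round the model is fitted on the z-scored surviving
#' features, per-feature weights `w = t(coefs) %*% SV` are computed, and the
#' lowest-|w| fraction of survivors (at least one feature) is eliminated.
#' The last surviving feature has rank 1.
#'
#' @param X Numeric matrix, samples in rows, features (CpGs) in columns
#'   (colnames required).
#' @param y Binary labels (0/1), one per sample.
#' @param elim_fraction Fraction of surviving features removed per round.
#' @param seed Integer RNG seed.
#' @param cost SVM regularization constant.
#' @return A `feature_ranking` object: `method`, `ranked_cpg_ids`
#'   (descending importance), `scores` (|weight| at elimination time).
#' @export
svm_rfe_ranking <- function(X, y, elim_fraction = 0.1, seed = 1L, cost = 1) {
  check_xy(X, y)
  assert_number(elim_fraction, "elim_fraction", 0, 1, TRUE, TRUE)
  set.seed(assert_count(seed, "seed", min = 0L))
  surviving <- colnames(X)
  n_feat <- length(surviving)
  rank_order <- character(0)   # filled worst-first
  score_order <- numeric(0)
  yf <- factor(y, levels = c(0, 1))
  while (length(surviving) > 1) {
    Xs <- scale(X[, surviving, drop = FALSE])
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
    fit <- e1071::svm(Xs, yf, kernel = "linear", cost = cost, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    names(w) <- surviving
    n_drop <- max(1L, floor(elim_fraction * length(surviving)))
    ord <- order(abs(w), names(w))   # weakest first, id tie-break
    drop <- names(w)[ord[seq_len(n_drop)]]
    rank_order <- c(rank_order, drop)
    score_order <- c(score_order, abs(w)[ord[seq_len(n_drop)]])
    surviving <- setdiff(surviving, drop)
  }
  rank_order <- c(rank_order, surviving)
  score_order <- c(score_order, Inf)
  ranked <- rev(rank_order)
  structure(
    list(method = "svm_rfe", ranked_cpg_ids = ranked,
         scores = rev(score_order)),
    class = "feature_ranking"
  )
}

#' Random-forest impurity-importance feature ranking
#'
#' Ranks features by mean decrease in Gini impurity from a seeded random
#' forest; ties are broken by probe id. Deterministic for a fixed seed.
#'
#' @inheritParams svm_rfe_ranking
#' @param n_trees Number of trees.
#' @return A `feature_ranking` object (`method = "rf"`, `scores` =
#'   importance values).
#' @export
rf_importance_ranking <- function(X, y, n_trees = 500L, seed = 1L) {
  check_xy(X, y)
  set.seed(assert_count(seed, "seed", min = 0L))
  fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                    ntree = assert_count(n_trees, "n_trees"))
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, names(imp))
  structure(
    list(method = "rf", ranked_cpg_ids = names(imp)[ord],
         scores = unname(imp[ord])),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking [%s]: %d features\n", x$method,
              length(x$ranked_cpg_ids)))
  invisible(x)
}

#' Cross-validated optimal subset size along a ranking
#'
#' For every size `k` in the grid, the top-`k` nested prefix of the ranking
#' is evaluated by stratified k-fold cross-validation of the ranking's own
#' model family (linear SVM for `svm_rfe`, random forest for `rf`); mean
#' accuracy and AUC are recorded per size. The optimal size maximizes mean
#' ACC; ties go to the higher mean AUC, residual ties to the smaller size.
#'
#' Folds are assigned on samples sorted by id, so the result is invariant
#' to input sample order.
#'
#' @param ranking A `feature_ranking`.
#' @param X,y As in [svm_rfe_ranking()] (X must carry sample rownames for
#'   order invariance; row order itself does not matter).
#' @param size_grid Integer vector of candidate subset sizes.
#' @param n_folds Number of CV folds (default 5).
#' @param seed Integer RNG seed.
#' @param n_trees Trees for the rf family evaluator.
#' @return List with `optimal_size` and `per_size_metrics`
#'   (data.frame: size, acc, auc).
#' @export
cv_subset_selection <- function(ranking, X, y, size_grid, n_folds = 5L,
                                seed = 1L, n_trees = 200L) {
  stopifnot(inherits(ranking, "feature_ranking"))
  check_xy(X, y)
  size_grid <- sort(unique(as.integer(size_grid)))
  if (max(size_grid) > length(ranking$ranked_cpg_ids)) {
    stop_oam("size grid exceeds ranking length (%d)",
             length(ranking$ranked_cpg_ids))
  }
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%05d", seq_len(nrow(X)))
  ord <- order(rownames(X))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  folds <- stratified_folds(y, n_folds, seed)
  if (any(vapply(folds, function(f) length(unique(y[f])) < 2, logical(1)))) {
    stop_oam("a CV fold contains a single class; use fewer folds")
  }
  res <- lapply(size_grid, function(k) {
    feats <- ranking$ranked_cpg_ids[seq_len(k)]
    accs <- auc_v <- numeric(length(folds))
    for (i in seq_along(folds)) {
      te <- folds[[i]]
      tr <- setdiff(seq_along(y), te)
      sc <- fit_predict_family(ranking$method,
                               X[tr, feats, drop = FALSE], y[tr],
                               X[te, feats, drop = FALSE],
                               seed = derive_seed(seed, i), n_trees = n_trees)
      accs[i] <- mean((sc > 0.5) == (y[te] == 1))
      auc_v[i] <- auc_rank(sc, y[te])
    }
    c(acc = mean(accs), auc = mean(auc_v))
  })
  tab <- data.frame(size = size_grid,
                    acc = vapply(res, `[[`, numeric(1), "acc"),
                    auc = vapply(res, `[[`, numeric(1), "auc"))
  list(optimal_size = select_best_size(tab), per_size_metrics = tab)
}

# Subset-size decision rule: highest mean ACC; ties -> higher mean AUC;
# residual ties -> smaller size.
select_best_size <- function(tab) {
  tab$size[order(-tab$acc, -tab$auc, tab$size)[1]]
}

# Stratified fold assignment, deterministic given (y, n_folds, seed).
stratified_folds <- function(y, n_folds, seed) {
  set.seed(derive_seed(seed, 777L))
  idx <- seq_along(y)
  folds <- vector("list", n_folds)
  for (cls in unique(y)) {
    members <- sample(idx[y == cls])
    fid <- rep_len(seq_len(n_folds), length(members))
    for (f in seq_len(n_folds)) {
      folds[[f]] <- c(folds[[f]], members[fid == f])
    }
  }
  lapply(folds, sort)
}

# Fit the ranking's own model family and return positive-class scores on
# the test rows.
fit_predict_family <- function(method, X_tr, y_tr, X_te, seed, n_trees = 200L) {
  yf <- factor(y_tr, levels = c(0, 1))
  if (method == "svm_rfe") {
    mu <- colMeans(X_tr)
    sd_ <- apply(X_tr, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    fit <- e1071::svm(scale(X_tr, mu, sd_), yf, kernel = "linear", cost = 1,
                      scale = FALSE)
    dv <- attr(stats::predict(fit, scale(X_te, mu, sd_),
                              decision.values = TRUE), "decision.values")
    sc <- as.numeric(dv)
    # orient decision values so larger = class 1
    if (colnames(dv)[1] == "0/1") sc <- -sc
    stats::plogis(sc)
  } else {
    set.seed(seed)
    fit <- randomForest::randomForest(X_tr, yf, ntree = n_trees)
    stats::predict(fit, X_te, type = "prob")[, "1"]
  }
}

#' Consensus feature set (intersection of two selections)
#'
#' @param a,b Character vectors of probe ids (or `feature_set`s), typically
#'   the optimal top-k subsets of the SVM-RFE and RF rankings.
#' @param set_tag Label for the derived set (e.g. "T-sites").
#' @return A `feature_set` with `cpg_ids` = exact intersection and
#'   `source_sizes = c(|A|, |B|, |A intersect B|)`.
#' @export
consensus_sites <- function(a, b, set_tag = "T-sites") {
  a <- as_id_set(a); b <- as_id_set(b)
  inter <- sort(intersect(a, b))
  if (length(inter) == 0) warning("consensus set is empty")
  structure(
    list(set_tag = set_tag, cpg_ids = inter,
         source_sizes = c(length(a), length(b), length(inter))),
    class = "feature_set"
  )
}

#' Union feature set (integrated U-sites)
#'
#' Exact set union with the cardinality identity
#' `|A u B| = |A| + |B| - |A n B|` verified on construction.
#'
#' @param a,b `feature_set`s or character vectors of probe ids.
#' @param set_tag Label for the derived set (default "U-sites").
#' @return A `feature_set`.
#' @export
union_sites <- function(a, b, set_tag = "U-sites") {
  av <- as_id_set(a); bv <- as_id_set(b)
  u <- sort(union(av, bv))
  stopifnot(length(u) == length(av) + length(bv) - length(intersect(av, bv)))
  structure(
    list(set_tag = set_tag, cpg_ids = u,
         source_sizes = c(length(av), length(bv), length(intersect(av, bv)))),
    class = "feature_set"
  )
}

as_id_set <- function(x) {
  if (inherits(x, "feature_set")) return(unique(x$cpg_ids))
  if (inherits(x, "feature_pool")) return(unique(x$cpg_ids))
  unique(as.character(x))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set [%s]: %d CpGs (sources %s)\n", x$set_tag,
              length(x$cpg_ids), paste(x$source_sizes, collapse = "/")))
  invisible(x)
}

check_xy <- function(X, y) {
  if (!is.matrix(X) || !is.numeric(X)) stop_oam("'X' must be a numeric matrix")
  if (is.null(colnames(X))) stop_oam("'X' must carry feature colnames")
  if (ncol(X) < 2) stop_oam("need >= 2 features")
  if (length(y) != nrow(X)) stop_oam("length(y) != nrow(X)")
  if (length(unique(y)) < 2) stop_oam("'y' must contain both classes")
  invisible(TRUE)
}
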