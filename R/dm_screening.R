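# Dual-strategy preliminary CpG screening.
#
# Strategy 1 (T-pool): per-CpG Welch t statistics case-vs-control, BH FDR
# adjustment, and the group mean beta difference (delta beta); the top-k
# probes by (adj.p, |delta beta|) form the statistical feature pool.
# Strategy 2 (G-pool): probes lying within a fixed window of the TSS of a
# known effector gene form the annotation-driven pool.

#' Per-CpG differential methylation statistics
#'
#' Computes, for every probe, the two-sided Welch (unequal-variance) t
#' statistic comparing cases (label 1) to controls (label 0), the raw
#' p-value, the Benjamini-Hochberg adjusted p-value over all tested probes,
#' the group mean difference `delta_beta = mean(case) - mean(control)`, and
#' the direction (`hyper` if `delta_beta > 0`, else `hypo`).
#'
#' Degenerate probes with zero variance in both groups and zero mean
#' difference receive `t = 0, p = 1`.
#'
#' @param matrix A [beta_matrix()] with at least two samples per class.
#' @return A `data.frame` of class `dm_table` with columns `cpg_id`,
#'   `t_stat`, `p_value`, `adj_p`, `delta_beta`, `direction`.
#' @export
differential_methylation <- function(matrix) {
  stopifnot(inherits(matrix, "beta_matrix"))
  case <- matrix$labels == 1L
  ctrl <- matrix$labels == 0L
  n1 <- sum(case); n0 <- sum(ctrl)
  if (n1 < 2 || n0 < 2) {
    stop_oam("each class needs >= 2 samples (got %d case, %d control)", n1, n0)
  }
  x1 <- matrix$values[, case, drop = FALSE]
  x0 <- matrix$values[, ctrl, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  delta <- m1 - m0
  t_stat <- ifelse(se2 > 0, delta / sqrt(se2), ifelse(delta == 0, 0, Inf * sign(delta)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
               1)
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df), 0)
  p[t_stat == 0 & se2 == 0] <- 1
  out <- data.frame(
    cpg_id = matrix$cpg_ids,
    t_stat = t_stat,
    p_value = p,
    adj_p = benjamini_hochberg(p),
    delta_beta = delta,
    direction = ifelse(delta > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("dm_table", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' output order matches input order. Thin validated interface over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of raw p-values in \[0,1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_oam("p-values must lie in [0,1] with no missing values")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select the statistical feature pool (T-pool)
#'
#' Probes are ranked by adjusted p-value ascending, ties broken by
#' |delta beta| descending, then probe id; the first `k` form the pool.
#'
#' @param dm A [differential_methylation()] table.
#' @param k Pool size (default 5000).
#' @return A `feature_pool` object (`pool_tag = "T"`), with per-probe
#'   provenance (rank, adj_p, delta_beta).
#' @export
select_t_pool <- function(dm, k = 5000L) {
  stopifnot(inherits(dm, "dm_table"))
  k <- assert_count(k, "k")
  if (k > nrow(dm)) {
    stop_oam("k = %d exceeds number of tested probes (%d)", k, nrow(dm))
  }
  ord <- order(dm$adj_p, -abs(dm$delta_beta), dm$cpg_id)
  sel <- ord[seq_len(k)]
  structure(
    list(pool_tag = "T",
         cpg_ids = dm$cpg_id[sel],
         provenance = data.frame(cpg_id = dm$cpg_id[sel],
                                 rank = seq_len(k),
                                 adj_p = dm$adj_p[sel],
                                 delta_beta = dm$delta_beta[sel],
                                 stringsAsFactors = FALSE)),
    class = "feature_pool"
  )
}

#' Probes meeting both significance criteria
#'
#' Returns probes with `adj_p < p_thresh` and `|delta_beta| > delta_thresh`
#' (both strict inequalities).
#'
#' @param dm A [differential_methylation()] table.
#' @param p_thresh Adjusted p-value threshold (default 0.05).
#' @param delta_thresh Absolute delta-beta threshold (default 0.2).
#' @return Character vector of probe ids.
#' @export
significant_sites <- function(dm, p_thresh = 0.05, delta_thresh = 0.2) {
  stopifnot(inherits(dm, "dm_table"))
  assert_number(p_thresh, "p_thresh", 0, Inf, strict_lower = TRUE)
  assert_number(delta_thresh, "delta_thresh", 0, Inf, strict_lower = TRUE)
  dm$cpg_id[dm$adj_p < p_thresh & abs(dm$delta_beta) > delta_thresh]
}

#' Select the annotation-driven feature pool (G-pool)
#'
#' A probe enters the pool if it lies within `window_bp` base pairs
#' (closed interval, unsigned distance) of the TSS of at least one listed
#' effector gene. Provenance records, per probe, the nearest qualifying
#' gene and the signed distance `pos - tss`; probes qualifying via several
#' genes appear once.
#'
#' @param annotation A [cpg_annotation()].
#' @param effector_genes Character vector of effector gene symbols.
#' @param window_bp TSS window half-width in bp (default 2000).
#' @return A `feature_pool` object (`pool_tag = "G"`).
#' @export
select_g_pool <- function(annotation, effector_genes, window_bp = 2000L) {
  stopifnot(inherits(annotation, "cpg_annotation"))
  window_bp <- assert_count(window_bp, "window_bp")
  if (nrow(annotation$probes) == 0) stop_oam("empty annotation")
  if (length(effector_genes) == 0) {
    warning("empty effector gene list: G-pool is empty")
    return(structure(list(pool_tag = "G", cpg_ids = character(0),
                          provenance = data.frame(cpg_id = character(0),
                                                  gene = character(0),
                                                  distance = integer(0))),
                     class = "feature_pool"))
  }
  ln <- annotation$links[annotation$links$gene %in% effector_genes, , drop = FALSE]
  pos <- annotation$probes$pos[match(ln$cpg_id, annotation$probes$cpg_id)]
  dist <- pos - ln$tss
  hit <- abs(dist) <= window_bp
  ln <- ln[hit, , drop = FALSE]
  dist <- dist[hit]
  # one row per probe: keep the nearest qualifying gene
  ord <- order(ln$cpg_id, abs(dist), ln$gene)
  ln <- ln[ord, , drop = FALSE]
  dist <- dist[ord]
  first <- !duplicated(ln$cpg_id)
  structure(
    list(pool_tag = "G",
         cpg_ids = ln$cpg_id[first],
         provenance = data.frame(cpg_id = ln$cpg_id[first],
                                 gene = ln$gene[first],
                                 distance = dist[first],
                                 stringsAsFactors = FALSE)),
    class = "feature_pool"
  )
}

#' @export
print.feature_pool <- function(x, ...) {
  cat(sprintf("feature_pool [%s]: %d CpGs\n", x$pool_tag, length(x$cpg_ids)))
  invisible(x)
}

#' Write a differential-methylation table to TSV
#'
#' @param dm A `dm_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dm_table <- function(dm, path) {
  stopifnot(inherits(dm, "dm_table"))
  utils::write.table(dm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
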