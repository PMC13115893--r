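# Programmatic fixtures shared across test files.

# Small labeled beta matrix with explicit values.
toy_beta <- function(n_cpg = 8, n_samp = 6, seed = 3) {
  set.seed(seed)
  v <- matrix(stats::runif(n_cpg * n_samp, 0.2, 0.8), n_cpg, n_samp,
              dimnames = list(sprintf("cg%05d", seq_len(n_cpg)),
                              sprintf("S%02d", seq_len(n_samp))))
  beta_matrix(v, labels = rep_len(c(1L, 0L), n_samp),
              batch = rep_len(c("A", "B"), n_samp))
}

toy_annotation <- function(cpg_ids, chrom = "chr1",
                           pos = seq_along(cpg_ids) * 1000L,
                           links = NULL) {
  if (is.null(links)) {
    links <- data.frame(cpg_id = character(0), gene = character(0),
                        tss = integer(0), strand = character(0))
  }
  cpg_annotation(
    probes = data.frame(cpg_id = cpg_ids, chrom = rep_len(chrom, length(cpg_ids)),
                        pos = pos, stringsAsFactors = FALSE),
    links = links
  )
}

# Linearly separable design: two informative probes with opposite-direction
# Beta-distributed class shifts, the rest Beta(2,2) noise.
make_separable <- function(n = 120, L = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rbeta(n * L, 2, 2), n, L,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("cg%05d", seq_len(L))))
  X[y == 1, 1] <- stats::rbeta(sum(y == 1), 8, 2)
  X[y == 0, 1] <- stats::rbeta(sum(y == 0), 2, 8)
  X[y == 1, 2] <- stats::rbeta(sum(y == 1), 2, 8)
  X[y == 0, 2] <- stats::rbeta(sum(y == 0), 8, 2)
  list(X = X, y = y)
}

# Mixed-signal design: cases carry a translation-jittered local motif
# (three adjacent probes elevated) plus a small global mean shift.
make_mixed_signal <- function(n = 120, L = 24, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rbeta(n * L, 2, 2), n, L,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("cg%05d", seq_len(L))))
  for (i in which(y == 1)) {
    s <- sample(2:(L - 3), 1)
    X[i, s:(s + 2)] <- pmin(1, X[i, s:(s + 2)] + 0.35)
    X[i, ] <- pmin(1, X[i, ] + 0.04)
  }
  list(X = X, y = y)
}

# Small fusion configuration used wherever the architecture itself (not
# its capacity) is under test.
tiny_fusion_config <- function(n_features = 10, seed = 7, ...) {
  args <- utils::modifyList(
    list(n_features = n_features, d_model = 16L, cnn_out = 16L,
         fusion_dim = 16L, n_heads = 2L, n_layers = 1L, ff_dim = 32L,
         kernel_sizes = c(3L, 3L), conv_channels = c(8L, 16L),
         max_epochs = 60L, patience = 15L, lr = 2e-3, seed = seed),
    list(...))
  do.call(fusion_config, args)
}

# Deterministic random graph for centrality oracle checks.
random_graph_edges <- function(n_nodes, p = 0.35, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  # ensure no isolated graph pathologies: add a spanning path
  path <- cbind(nodes[-n_nodes], nodes[-1])
  ed <- unique(rbind(t(pairs[, keep, drop = FALSE]), path))
  data.frame(node_a = ed[, 1], node_b = ed[, 2],
             combined_score = 800L, stringsAsFactors = FALSE)
}
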