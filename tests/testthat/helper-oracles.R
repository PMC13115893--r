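# Independent oracles, coded separately from the package implementations.

# Benjamini-Hochberg step-up, written directly from the procedure:
# adj p_(k) = min over j >= k of min(1, p_(j) * n / j), mapped back to the
# original order.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, ps * n / seq_len(n))
  for (k in (n - 1):1) {
    if (n == 1) break
    adj[k] <- min(adj[k], adj[k + 1])
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Welch two-sample t-test p-value, recomputed from the closed form.
welch_oracle <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  v1 <- stats::var(x1); v0 <- stats::var(x0)
  se2 <- v1 / n1 + v0 / n0
  t <- (mean(x1) - mean(x0)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  2 * stats::pt(-abs(t), df)
}

# Exhaustive betweenness centrality by BFS shortest-path enumeration
# (counts all shortest paths between every ordered pair through each
# vertex; normalized as 2 * B / ((n-1)(n-2)) for undirected graphs).
betweenness_oracle <- function(edges, nodes) {
  n <- length(nodes)
  adj <- lapply(nodes, function(v) {
    c(edges$node_b[edges$node_a == v], edges$node_a[edges$node_b == v])
  })
  names(adj) <- nodes
  all_shortest <- function(from, to) {
    # BFS collecting every shortest path
    if (from == to) return(list())
    paths <- list(from)
    found <- list()
    best <- Inf
    while (length(paths) > 0 && length(paths[[1]]) <= best) {
      nxt <- list()
      for (p in paths) {
        tip <- p[length(p)]
        for (nb in adj[[tip]]) {
          if (nb %in% p) next
          q <- c(p, nb)
          if (nb == to) {
            if (length(q) <= best) {
              best <- length(q)
              found[[length(found) + 1]] <- q
            }
          } else if (length(q) < best) {
            nxt[[length(nxt) + 1]] <- q
          }
        }
      }
      paths <- nxt
    }
    found[vapply(found, length, integer(1)) == best]
  }
  B <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- all_shortest(nodes[i], nodes[j])
      if (length(sp) == 0) next
      for (p in sp) {
        inner <- p[-c(1, length(p))]
        for (v in inner) B[v] <- B[v] + 1 / length(sp)
      }
    }
  }
  if (n > 2) 2 * B / ((n - 1) * (n - 2)) else B * 0
}

# Scalar-loop evaluation of the gated fusion equations, one coordinate at
# a time (no vectorization, no shared code with the package).
gated_fusion_oracle <- function(p_a, p_b, W1, b1, W2, b2) {
  f <- length(p_a)
  z <- c(p_a, p_b)
  h <- numeric(f)
  for (j in seq_len(f)) {
    s <- b1[j]
    for (i in seq_len(2 * f)) s <- s + z[i] * W1[i, j]
    h[j] <- max(s, 0)
  }
  g <- numeric(f)
  for (j in seq_len(f)) {
    s <- b2[j]
    for (i in seq_len(f)) s <- s + h[i] * W2[i, j]
    g[j] <- 1 / (1 + exp(-s))
  }
  fused <- numeric(f)
  for (j in seq_len(f)) fused[j] <- g[j] * p_a[j] + (1 - g[j]) * p_b[j]
  list(fused = fused, g = g)
}

# Pairwise-comparison AUC (explicit double loop).
auc_pairs_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
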