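test_that("degenerate and forced-sign probes behave as contracted", {
  v <- rbind(
    cg1 = rep(0.5, 8),                             # identical everywhere
    cg2 = c(rep(0.2, 4), rep(0.8, 4)) +
      c(1, -1, 1, -1, 1, -1, 1, -1) * 1e-3         # tiny jitter, huge gap
  )
  colnames(v) <- sprintf("S%d", 1:8)
  bm <- beta_matrix(v, labels = c(rep(1L, 4), rep(0L, 4)),
                    batch = rep("A", 8))
  dm <- differential_methylation(bm)
  expect_identical(dm$t_stat[dm$cpg_id == "cg1"], 0)
  expect_identical(dm$p_value[dm$cpg_id == "cg1"], 1)
  expect_identical(dm$delta_beta[dm$cpg_id == "cg1"], 0)
  d2 <- dm[dm$cpg_id == "cg2", ]
  expect_equal(d2$delta_beta, -0.6, tolerance = 0.01)
  expect_lt(d2$adj_p, 0.05)
  expect_identical(d2$direction, "hypo")
})

test_that("Welch p-values match an independent closed-form oracle", {
  set.seed(21)
  n1 <- 9; n0 <- 5
  v <- matrix(runif(50 * (n1 + n0), 0.1, 0.9), 50,
              dimnames = list(sprintf("cg%02d", 1:50),
                              sprintf("S%02d", 1:(n1 + n0))))
  bm <- beta_matrix(v, labels = c(rep(1L, n1), rep(0L, n0)),
                    batch = rep("A", n1 + n0))
  dm <- differential_methylation(bm)
  for (i in seq_len(50)) {
    expect_equal(dm$p_value[i], welch_oracle(v[i, 1:n1], v[i, n1 + 1:n0]),
                 tolerance = 1e-12)
  }
  # and against stats::t.test on a handful of probes
  for (i in c(1, 17, 42)) {
    tt <- t.test(v[i, 1:n1], v[i, n1 + 1:n0])
    expect_equal(dm$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(dm$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
  }
  expect_error(differential_methylation(
    beta_matrix(v[, 1:3], labels = c(1L, 1L, 0L), batch = rep("A", 3))),
    ">= 2 samples")
})

test_that("BH adjustment matches the independent step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_identical(benjamini_hochberg(1), 1)
  # grid of 4-element vectors
  grid <- c(0.001, 0.01, 0.05, 0.2, 0.5, 1.0)
  combs <- expand.grid(grid, grid, grid, grid)
  for (i in seq(1, nrow(combs), by = 7)) {
    p <- as.numeric(combs[i, ])
    expect_equal(benjamini_hochberg(p), bh_stepup_oracle(p),
                 tolerance = 1e-14)
  }
  # random vectors of varying length
  set.seed(5)
  for (r in 1:200) {
    p <- runif(sample(1:40, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-14)
    expect_true(all(adj >= p))        # dominance
    expect_true(all(adj <= 1))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("T-pool selection ranks by adj_p with |delta| tie-break", {
  dm <- data.frame(
    cpg_id = sprintf("cg%02d", 1:10),
    t_stat = 0, p_value = 0,
    adj_p = c(0.001, 0.001, 0.5, 0.2, 0.3, 0.01, 0.9, 0.05, 0.6, 0.7),
    delta_beta = c(0.1, 0.3, 0, 0, 0, 0, 0, 0, 0, 0),
    direction = "hyper", stringsAsFactors = FALSE)
  class(dm) <- c("dm_table", "data.frame")
  pool <- select_t_pool(dm, k = 3)
  # tie at 0.001 resolved toward the larger |delta_beta|
  expect_identical(pool$cpg_ids, c("cg02", "cg01", "cg06"))
  expect_error(select_t_pool(dm, k = 11), "exceeds")

  # row-order invariance
  shuf <- dm[sample(nrow(dm)), ]
  class(shuf) <- c("dm_table", "data.frame")
  expect_identical(select_t_pool(shuf, k = 5)$cpg_ids,
                   select_t_pool(dm, k = 5)$cpg_ids)
})

test_that("significance filter applies strict thresholds as printed", {
  dm <- data.frame(
    cpg_id = c("a", "b", "c", "d", "e", "f"),
    t_stat = 0, p_value = 0,
    adj_p = c(0.05, 0.01, 0.049, 0.2, 0.01, 0.04),
    delta_beta = c(0.3, 0.21, 0.2, 0.5, -0.25, 0.19),
    direction = "hyper", stringsAsFactors = FALSE)
  class(dm) <- c("dm_table", "data.frame")
  # a: adj_p not < 0.05; c: |delta| not > 0.2; d: adj_p; f: delta
  expect_setequal(significant_sites(dm), c("b", "e"))
})

test_that("G-pool honors the inclusive TSS window boundary", {
  ann <- toy_annotation(
    c("p1", "p2", "p3"), pos = c(10000L, 14001L, 11999L),
    links = data.frame(cpg_id = c("p1", "p2", "p3"),
                       gene = "EFF1", tss = 12000L, strand = c("+", "-", "+"),
                       stringsAsFactors = FALSE))
  pool <- select_g_pool(ann, "EFF1", window_bp = 2000)
  # distance -2000 inclusive; +2001 excluded; -1 included
  expect_setequal(pool$cpg_ids, c("p1", "p3"))
  expect_identical(pool$provenance$distance[pool$provenance$cpg_id == "p1"],
                   -2000L)
  expect_warning(empty <- select_g_pool(ann, character(0)), "empty")
  expect_length(empty$cpg_ids, 0)
})

test_that("G-pool equals the brute-force probe-by-gene scan", {
  co <- generate_cohort(sim_config(n_cpg = 400, n_dm = 30, n_genes = 60,
                                   n_effectors = 30, seed = 13))
  eff <- co$truth$effector_genes
  pool <- select_g_pool(co$annotation, eff, window_bp = 2000)
  # quadratic oracle over all probe x gene pairs, geometry only
  pr <- co$annotation$probes
  ln <- co$annotation$links
  hits <- character(0)
  for (i in seq_len(nrow(pr))) {
    li <- ln[ln$cpg_id == pr$cpg_id[i] & ln$gene %in% eff, ]
    if (nrow(li) > 0 && any(abs(pr$pos[i] - li$tss) <= 2000)) {
      hits <- c(hits, pr$cpg_id[i])
    }
  }
  expect_setequal(pool$cpg_ids, hits)
  expect_false(anyDuplicated(pool$cpg_ids) > 0)
})

test_that("null cohorts keep the significant fraction near the FDR level", {
  # spot check at test scale; the full 20-replicate check runs in the
  # acceptance suite
  fdp <- vapply(1:5, function(s) {
    co <- generate_cohort(sim_config(n_cases = 30, n_controls = 15,
                                     n_cpg = 500, n_dm = 0, seed = s))
    dm <- differential_methylation(co$beta)
    mean(dm$adj_p < 0.05)
  }, numeric(1))
  expect_lt(mean(fdp), 0.05 + 3 * sd(fdp) / sqrt(5) + 1e-9)
})
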