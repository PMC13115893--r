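test_that("configuration invariants are enforced", {
  expect_error(fusion_config(n_features = 10, d_model = 10, n_heads = 4),
               "divide")
  expect_error(fusion_config(n_features = 4, kernel_sizes = c(7, 3),
                             conv_channels = c(8, 16), cnn_out = 16),
               "wider")
  expect_error(fusion_config(n_features = 10, conv_channels = c(8, 8),
                             cnn_out = 16), "cnn_out")
  cfg <- fusion_config(n_features = 220)
  expect_identical(c(cfg$d_model, cfg$cnn_out, cfg$fusion_dim),
                   c(64L, 64L, 64L))
})

test_that("embedding produces one token per CpG with affine structure", {
  cfg <- tiny_fusion_config(n_features = 220)
  set.seed(1)
  P <- init_fusion_params(cfg)
  tok <- embed_tokens(runif(220), P, cfg)
  expect_identical(dim(tok), c(220L, 16L))
  # zero input -> bias + position embedding only
  expect_equal(embed_tokens(rep(0, 220), P, cfg), P$emb_B + P$emb_P,
               tolerance = 0)
  expect_error(embed_tokens(runif(10), P, cfg), "length")
})

test_that("attention branch pools equivariantly and normalizes weights", {
  cfg <- tiny_fusion_config(n_features = 12)
  set.seed(2)
  P <- init_fusion_params(cfg)
  x <- runif(12)
  tok <- embed_tokens(x, P, cfg)
  p_a <- attention_branch(tok, P, cfg)
  expect_length(p_a, cfg$fusion_dim)

  # per-head attention weights sum to 1 over keys
  fwd <- oamethyl:::attention_fwd(tok, P, cfg)
  for (A in fwd$layers[[1]]$A) {
    expect_equal(rowSums(A), rep(1, 12), tolerance = 1e-12)
  }

  # permuting features together with the embedding rows leaves the pooled
  # attention output unchanged (self-attention + mean pooling are
  # permutation-invariant)
  perm <- sample(12)
  P2 <- P
  P2$emb_A <- P$emb_A[perm, ]; P2$emb_B <- P$emb_B[perm, ]
  P2$emb_P <- P$emb_P[perm, ]
  tok2 <- embed_tokens(x[perm], P2, cfg)
  expect_equal(attention_branch(tok2, P, cfg), p_a, tolerance = 1e-10)
})

test_that("convolution branch preserves length and handles constants", {
  cfg <- fusion_config(n_features = 220, d_model = 16, cnn_out = 16,
                       fusion_dim = 16, n_heads = 2, n_layers = 1,
                       ff_dim = 32, kernel_sizes = c(7L, 3L),
                       conv_channels = c(8L, 16L), seed = 1)
  set.seed(3)
  P <- init_fusion_params(cfg)
  tok <- embed_tokens(runif(220), P, cfg)
  fwd <- oamethyl:::convolution_fwd(tok, P, cfg)
  expect_length(fwd$p_b, 16L)
  # same-padding: 220 positions preserved through the stack
  expect_identical(nrow(fwd$X_out), 220L)

  # constant token rows -> interior feature-map rows constant (edges see
  # zero padding)
  tok_const <- matrix(rep(tok[1, ], each = 220), 220)
  f2 <- oamethyl:::convolution_fwd(tok_const, P, cfg)
  interior <- 8:213
  first <- f2$X_out[interior[1], ]
  for (r in interior) {
    expect_equal(f2$X_out[r, ], first, tolerance = 1e-12)
  }
})

test_that("gated fusion matches the scalar-loop oracle on random instances", {
  set.seed(4)
  for (r in 1:100) {
    f <- 4
    p_a <- rnorm(f); p_b <- rnorm(f)
    gp <- list(W1 = matrix(rnorm(2 * f * f), 2 * f, f), b1 = rnorm(f),
               W2 = matrix(rnorm(f * f), f, f), b2 = rnorm(f))
    got <- gated_fusion(p_a, p_b, gp)
    want <- gated_fusion_oracle(p_a, p_b, gp$W1, gp$b1, gp$W2, gp$b2)
    expect_equal(got$fused, want$fused, tolerance = 1e-12)
    expect_equal(got$g, want$g, tolerance = 1e-12)
    # convexity: fused coordinates lie between the branch coordinates
    expect_true(all(got$fused >= pmin(p_a, p_b) - 1e-12 &
                      got$fused <= pmax(p_a, p_b) + 1e-12))
    expect_true(all(got$g > 0 & got$g < 1))
  }
  expect_error(gated_fusion(rnorm(4), rnorm(3), NULL), "widths differ")
})

test_that("gate boundary values reduce fusion to its endpoints", {
  f <- 6
  p_a <- rnorm(f); p_b <- rnorm(f)
  # drive the sigmoid to ~1 with a huge bias: fused -> p_a
  gp1 <- list(W1 = matrix(0, 2 * f, f), b1 = rep(0, f),
              W2 = matrix(0, f, f), b2 = rep(100, f))
  expect_equal(gated_fusion(p_a, p_b, gp1)$fused, p_a, tolerance = 1e-12)
  # zero pre-activation: g = 0.5 exactly -> midpoint
  gp2 <- list(W1 = matrix(0, 2 * f, f), b1 = rep(0, f),
              W2 = matrix(0, f, f), b2 = rep(0, f))
  expect_equal(gated_fusion(p_a, p_b, gp2)$fused, (p_a + p_b) / 2,
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences in every mode", {
  ns <- asNamespace("oamethyl")
  for (mode in c("gated", "concat", "transformer", "cnn")) {
    set.seed(42)
    cfg <- fusion_config(n_features = 7, d_model = 4, cnn_out = 4,
                         fusion_dim = 4, n_heads = 2, n_layers = 2,
                         ff_dim = 6, kernel_sizes = c(3, 3),
                         conv_channels = c(5, 4), dropout = 0,
                         fusion_mode = mode, seed = 1)
    P <- init_fusion_params(cfg)
    x <- runif(7)
    lossfn <- function(P) {
      -log(ns$softmax_vec(ns$fusion_forward(x, P, cfg)$logits)[2])
    }
    cache <- ns$fusion_forward(x, P, cfg)
    dlogits <- ns$softmax_vec(cache$logits) - c(0, 1)
    bw <- ns$fusion_backward(dlogits, cache, P, cfg, ns$zero_like(P))
    eps <- 1e-6
    for (nm in names(P)) {
      for (i in sample(length(P[[nm]]), min(3, length(P[[nm]])))) {
        P2 <- P; P2[[nm]][i] <- P2[[nm]][i] + eps
        P3 <- P; P3[[nm]][i] <- P3[[nm]][i] - eps
        num <- (lossfn(P2) - lossfn(P3)) / (2 * eps)
        expect_lt(abs(num - bw$grads[[nm]][i]), 1e-6)
      }
    }
    # gradient with respect to the input (saliency path)
    bw2 <- ns$fusion_backward(c(0, 1), cache, P, cfg, ns$zero_like(P))
    num_dx <- vapply(1:7, function(i) {
      x2 <- x; x2[i] <- x2[i] + eps
      x3 <- x; x3[i] <- x3[i] - eps
      (ns$fusion_forward(x2, P, cfg)$logits[2] -
         ns$fusion_forward(x3, P, cfg)$logits[2]) / (2 * eps)
    }, numeric(1))
    expect_equal(bw2$dx, num_dx, tolerance = 1e-6)
  }
})

test_that("training is deterministic and learns separable data", {
  d <- make_separable(seed = 1)
  cfg <- tiny_fusion_config(seed = 7, max_epochs = 30L, patience = 10L)
  m1 <- train_fusion_model(d$X, d$y, cfg)
  m2 <- train_fusion_model(d$X, d$y, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_gt(max(m1$history$val_acc), 0.9)
  expect_error(train_fusion_model(d$X[, 1:5], d$y, cfg), "n_features")
})

test_that("evaluation metrics follow their rank-statistic definitions", {
  # perfect predictor
  expect_equal(unclass(oamethyl:::metrics_from_scores(
    c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)))[c("acc", "f1", "auc")],
    list(acc = 1, f1 = 1, auc = 1))
  # one misranked pair of four: AUC 3/4
  m <- oamethyl:::metrics_from_scores(c(0.9, 0.3, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 0.75)
  # rank AUC equals the pairwise-count oracle on random small sets
  set.seed(6)
  for (r in 1:25) {
    n <- sample(4:30, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)   # ties likely
    expect_equal(auc_rank(s, y), auc_pairs_oracle(s, y), tolerance = 1e-12)
  }
  expect_warning(a <- auc_rank(c(0.2, 0.4), c(1, 1)), "one class")
  expect_true(is.na(a))
})

test_that("positive-only evaluation reports the documented accuracy", {
  r <- positive_only_accuracy(59, 62)
  expect_identical(r$accuracy, 0.9516)
  expect_false(r$specificity_assessable)
  expect_identical(positive_only_accuracy(5, 5)$accuracy, 1)
  expect_identical(positive_only_accuracy(0, 5)$accuracy, 0)
  expect_error(positive_only_accuracy(6, 5), "exceeds")
})

test_that("gate records are exactly complementary", {
  g <- matrix(c(0.513, 0.513, 0.513, 0.513), 2)
  rec <- gate_record(g)
  expect_identical(rec$mean_transformer_weight + rec$mean_cnn_weight, 1)
  expect_equal(rec$mean_cnn_weight, 0.487, tolerance = 1e-12)
  rec2 <- gate_record(matrix(0.5, 3, 4))
  expect_identical(rec2$mean_transformer_weight, 0.5)
  expect_error(gate_record(matrix(c(0.5, 1), 1)), "strictly")

  # complementarity holds for a real trained model
  d <- make_separable(n = 40, seed = 2)
  cfg <- tiny_fusion_config(seed = 3, max_epochs = 5L, patience = 5L)
  m <- train_fusion_model(d$X, d$y, cfg)
  rec3 <- gate_contribution(m, d$X)
  expect_identical(rec3$mean_transformer_weight + rec3$mean_cnn_weight, 1)
  expect_true(all(rec3$g > 0 & rec3$g < 1))
  expect_identical(dim(rec3$g), c(40L, 16L))
})

test_that("ablation table compares all variants under one split", {
  d <- make_separable(n = 60, seed = 5)
  cfg <- tiny_fusion_config(seed = 9, max_epochs = 8L, patience = 8L)
  tab <- ablation_compare(d$X, d$y, cfg)
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$variant, c("transformer", "cnn", "concat", "gated"))
  expect_true(all(tab$acc >= 0 & tab$acc <= 1))
})
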