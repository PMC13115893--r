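# Dual-branch gated-fusion diagnostic model (Trans-CNN).
#
# Per-sample beta values are embedded one token per CpG (learned per-feature
# affine map into d_model plus a learned position embedding indexed by
# genomic order), then processed in parallel by a Transformer encoder
# (global dependencies among CpGs) and a stack of 1-D convolutions (local
# methylation patterns). Both branches are globally average-pooled,
# projected to a common fusion width, and blended per dimension by a
# learned gating vector g in (0,1):
#
#   Z     = [p_a ; p_b]
#   g     = sigmoid(W2 . relu(W1 . Z + b1) + b2)
#   fused = g * p_a + (1 - g) * p_b
#
# A 2-logit softmax head classifies the fused representation. All forward
# and backward passes are written out explicitly in base R; correctness is
# guarded by a finite-difference gradient check and a scalar-loop oracle
# for the fusion equations in the test suite.

#' Configuration of the gated Trans-CNN fusion classifier
#'
#' @param n_features Number of input CpG features (token sequence length).
#' @param d_model Attention-branch token width (default 64).
#' @param cnn_out Convolution-branch output channels (default 64).
#' @param fusion_dim Fused feature width (default 64).
#' @param n_heads Attention heads; must divide `d_model`.
#' @param n_layers Transformer encoder layers.
#' @param ff_dim Encoder feed-forward width.
#' @param kernel_sizes Integer vector of 1-D convolution kernel widths, one
#'   per conv layer.
#' @param conv_channels Output channels per conv layer; last entry must
#'   equal `cnn_out`.
#' @param dropout Dropout rate applied to the pooled branch vectors during
#'   training.
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to
#'   weight matrices; biases, layer-norm gains and embeddings are exempt.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-ACC
#'   improvement).
#' @param class_weighting Weight the cross-entropy loss inversely to class
#'   frequency (for imbalanced cohorts).
#' @param fusion_mode One of `"gated"` (default), `"concat"`,
#'   `"transformer"` (attention branch only), `"cnn"` (convolution branch
#'   only); the non-gated modes exist for ablation experiments.
#' @param standardize Z-score inputs with training-set statistics.
#' @param val_fraction Fraction held out for validation when no explicit
#'   validation set is passed to [train_fusion_model()].
#' @param seed Integer RNG seed (initialization, shuffling, dropout).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(n_features,
                          d_model = 64L, cnn_out = 64L, fusion_dim = 64L,
                          n_heads = 4L, n_layers = 2L, ff_dim = 128L,
                          kernel_sizes = c(7L, 3L),
                          conv_channels = c(32L, cnn_out),
                          dropout = 0.1, lr = 1e-3, weight_decay = 1e-3,
                          batch_size = 16L,
                          max_epochs = 200L, patience = 20L,
                          class_weighting = TRUE,
                          fusion_mode = c("gated", "concat", "transformer", "cnn"),
                          standardize = TRUE, val_fraction = 0.2,
                          seed = 1L) {
  fusion_mode <- match.arg(fusion_mode)
  cfg <- list(
    n_features = assert_count(n_features, "n_features", 2L),
    d_model = assert_count(d_model, "d_model"),
    cnn_out = assert_count(cnn_out, "cnn_out"),
    fusion_dim = assert_count(fusion_dim, "fusion_dim"),
    n_heads = assert_count(n_heads, "n_heads"),
    n_layers = assert_count(n_layers, "n_layers"),
    ff_dim = assert_count(ff_dim, "ff_dim"),
    kernel_sizes = vapply(kernel_sizes, assert_count, integer(1), "kernel_sizes"),
    conv_channels = vapply(conv_channels, assert_count, integer(1), "conv_channels"),
    dropout = assert_number(dropout, "dropout", 0, 1, FALSE, TRUE),
    lr = assert_number(lr, "lr", 0, Inf, TRUE),
    weight_decay = assert_number(weight_decay, "weight_decay", 0, Inf),
    batch_size = assert_count(batch_size, "batch_size"),
    max_epochs = assert_count(max_epochs, "max_epochs"),
    patience = assert_count(patience, "patience"),
    class_weighting = isTRUE(class_weighting),
    fusion_mode = fusion_mode,
    standardize = isTRUE(standardize),
    val_fraction = assert_number(val_fraction, "val_fraction", 0, 0.9),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$d_model %% cfg$n_heads != 0) {
    stop_oam("n_heads (%d) must divide d_model (%d)", cfg$n_heads, cfg$d_model)
  }
  if (length(cfg$kernel_sizes) != length(cfg$conv_channels)) {
    stop_oam("kernel_sizes and conv_channels must have the same length")
  }
  if (cfg$conv_channels[length(cfg$conv_channels)] != cfg$cnn_out) {
    stop_oam("last conv channel count must equal cnn_out")
  }
  if (any(cfg$kernel_sizes > cfg$n_features)) {
    stop_oam("convolution kernel wider than the token sequence")
  }
  class(cfg) <- "fusion_config"
  cfg
}

# ---- parameter initialization ----------------------------------------

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Initialize fusion-model parameters
#'
#' Glorot-uniform weights, zero biases, unit layer-norm gains. Uses the
#' current RNG state; seed externally for reproducibility.
#'
#' @param config A [fusion_config()].
#' @return Named list of parameter matrices/vectors.
#' @export
init_fusion_params <- function(config) {
  L <- config$n_features; d <- config$d_model; f <- config$fusion_dim
  P <- list(
    emb_A = matrix(stats::rnorm(L * d, 0, 1 / sqrt(d)), L, d),
    emb_B = matrix(0, L, d),
    emb_P = matrix(stats::rnorm(L * d, 0, 0.02), L, d)
  )
  for (l in seq_len(config$n_layers)) {
    p <- function(nm) paste0("l", l, "_", nm)
    P[[p("Wq")]] <- glorot(d, d); P[[p("bq")]] <- numeric(d)
    P[[p("Wk")]] <- glorot(d, d); P[[p("bk")]] <- numeric(d)
    P[[p("Wv")]] <- glorot(d, d); P[[p("bv")]] <- numeric(d)
    P[[p("Wo")]] <- glorot(d, d); P[[p("bo")]] <- numeric(d)
    P[[p("ln1_g")]] <- rep(1, d); P[[p("ln1_b")]] <- numeric(d)
    P[[p("Wf1")]] <- glorot(d, config$ff_dim)
    P[[p("bf1")]] <- numeric(config$ff_dim)
    P[[p("Wf2")]] <- glorot(config$ff_dim, d)
    P[[p("bf2")]] <- numeric(d)
    P[[p("ln2_g")]] <- rep(1, d); P[[p("ln2_b")]] <- numeric(d)
  }
  P$Wpa <- glorot(d, f); P$bpa <- numeric(f)
  c_prev <- d
  for (j in seq_along(config$kernel_sizes)) {
    k <- config$kernel_sizes[j]; c_out <- config$conv_channels[j]
    P[[paste0("c", j, "_W")]] <- glorot(k * c_prev, c_out)
    P[[paste0("c", j, "_b")]] <- numeric(c_out)
    c_prev <- c_out
  }
  P$Wpb <- glorot(c_prev, f); P$bpb <- numeric(f)
  P$Wg1 <- glorot(2 * f, f); P$bg1 <- numeric(f)
  P$Wg2 <- glorot(f, f); P$bg2 <- numeric(f)
  cls_in <- if (config$fusion_mode == "concat") 2L * f else f
  P$Wc <- glorot(cls_in, 2L); P$bc <- numeric(2L)
  P
}

# ---- primitive layers ------------------------------------------------

addb <- function(M, b) M + rep(b, each = nrow(M))

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

LN_EPS <- 1e-5

layernorm_fwd <- function(X, g, b) {
  m <- rowMeans(X)
  xc <- X - m
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(out = addb(xhat * rep(g, each = nrow(X)), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(g, each = nrow(dY))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Embed a beta-value vector into a token sequence
#'
#' One token per CpG: `token_i = x_i * A_i + B_i + P_i`, where `A_i`
#' (per-feature scale vector), `B_i` (per-feature bias) and `P_i` (position
#' embedding, indexed by genomic order) are learned rows of width
#' `d_model`.
#'
#' @param x Numeric vector of length `config$n_features`.
#' @param params Parameter list from [init_fusion_params()].
#' @param config A [fusion_config()].
#' @return `n_features x d_model` token matrix.
#' @export
embed_tokens <- function(x, params, config) {
  if (length(x) != config$n_features) {
    stop_oam("input length %d != configured n_features %d",
             length(x), config$n_features)
  }
  params$emb_A * x + params$emb_B + params$emb_P
}

# Transformer encoder forward for one sample; returns pooled projection
# p_a and a cache for backprop.
attention_fwd <- function(tok, params, config) {
  L <- nrow(tok); d <- config$d_model
  nh <- config$n_heads; dh <- d %/% nh
  X <- tok
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    p <- function(nm) params[[paste0("l", l, "_", nm)]]
    Q <- addb(X %*% p("Wq"), p("bq"))
    K <- addb(X %*% p("Wk"), p("bk"))
    V <- addb(X %*% p("Wv"), p("bv"))
    A_list <- vector("list", nh)
    O <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
      A <- softmax_rows(S)
      A_list[[h]] <- A
      O[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    attn <- addb(O %*% p("Wo"), p("bo"))
    R1 <- X + attn
    ln1 <- layernorm_fwd(R1, p("ln1_g"), p("ln1_b"))
    X1 <- ln1$out
    Hpre <- addb(X1 %*% p("Wf1"), p("bf1"))
    H <- pmax(Hpre, 0)
    Fo <- addb(H %*% p("Wf2"), p("bf2"))
    ln2 <- layernorm_fwd(X1 + Fo, p("ln2_g"), p("ln2_b"))
    layers[[l]] <- list(X = X, Q = Q, K = K, V = V, A = A_list, O = O,
                        ln1 = ln1, X1 = X1, H = H, ln2 = ln2)
    X <- ln2$out
  }
  h_a <- colMeans(X)
  p_a <- as.numeric(h_a %*% params$Wpa) + params$bpa
  list(p_a = p_a, h_a = h_a, layers = layers, X_out = X)
}

attention_bwd <- function(dp_a, cache, params, config, grads) {
  L <- config$n_features; d <- config$d_model
  nh <- config$n_heads; dh <- d %/% nh
  grads$Wpa <- grads$Wpa + outer(cache$h_a, dp_a)
  grads$bpa <- grads$bpa + dp_a
  dh_a <- as.numeric(params$Wpa %*% dp_a)
  dX <- matrix(rep(dh_a / L, each = L), L, d)
  for (l in rev(seq_len(config$n_layers))) {
    p <- function(nm) params[[paste0("l", l, "_", nm)]]
    g <- function(nm) paste0("l", l, "_", nm)
    cl <- cache$layers[[l]]
    ln2b <- layernorm_bwd(dX, cl$ln2, p("ln2_g"))
    grads[[g("ln2_g")]] <- grads[[g("ln2_g")]] + ln2b$dgamma
    grads[[g("ln2_b")]] <- grads[[g("ln2_b")]] + ln2b$dbeta
    dR2 <- ln2b$dx
    dFo <- dR2
    dX1 <- dR2
    grads[[g("Wf2")]] <- grads[[g("Wf2")]] + crossprod(cl$H, dFo)
    grads[[g("bf2")]] <- grads[[g("bf2")]] + colSums(dFo)
    dH <- dFo %*% t(p("Wf2"))
    dHpre <- dH * (cl$H > 0)
    grads[[g("Wf1")]] <- grads[[g("Wf1")]] + crossprod(cl$X1, dHpre)
    grads[[g("bf1")]] <- grads[[g("bf1")]] + colSums(dHpre)
    dX1 <- dX1 + dHpre %*% t(p("Wf1"))
    ln1b <- layernorm_bwd(dX1, cl$ln1, p("ln1_g"))
    grads[[g("ln1_g")]] <- grads[[g("ln1_g")]] + ln1b$dgamma
    grads[[g("ln1_b")]] <- grads[[g("ln1_b")]] + ln1b$dbeta
    dR1 <- ln1b$dx
    dattn <- dR1
    dXres <- dR1
    grads[[g("Wo")]] <- grads[[g("Wo")]] + crossprod(cl$O, dattn)
    grads[[g("bo")]] <- grads[[g("bo")]] + colSums(dattn)
    dO <- dattn %*% t(p("Wo"))
    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      A <- cl$A[[h]]
      dOh <- dO[, idx, drop = FALSE]
      Vh <- cl$V[, idx, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[, idx] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(dh)
      dQ[, idx] <- dS %*% cl$K[, idx, drop = FALSE]
      dK[, idx] <- crossprod(dS, cl$Q[, idx, drop = FALSE])
    }
    X <- cl$X
    grads[[g("Wq")]] <- grads[[g("Wq")]] + crossprod(X, dQ)
    grads[[g("bq")]] <- grads[[g("bq")]] + colSums(dQ)
    grads[[g("Wk")]] <- grads[[g("Wk")]] + crossprod(X, dK)
    grads[[g("bk")]] <- grads[[g("bk")]] + colSums(dK)
    grads[[g("Wv")]] <- grads[[g("Wv")]] + crossprod(X, dV)
    grads[[g("bv")]] <- grads[[g("bv")]] + colSums(dV)
    dX <- dXres + dQ %*% t(p("Wq")) + dK %*% t(p("Wk")) + dV %*% t(p("Wv"))
  }
  list(grads = grads, dtok = dX)
}

# 1-D convolution stack forward; 'same' zero padding, relu, global average
# pooling, projection to fusion_dim.
conv_unfold <- function(Xpad, k, L) {
  do.call(cbind, lapply(seq_len(k), function(tp) {
    Xpad[tp:(tp + L - 1), , drop = FALSE]
  }))
}

convolution_fwd <- function(tok, params, config) {
  L <- nrow(tok)
  X <- tok
  convs <- vector("list", length(config$kernel_sizes))
  for (j in seq_along(config$kernel_sizes)) {
    k <- config$kernel_sizes[j]
    pad <- (k - 1L) %/% 2L
    cch <- ncol(X)
    Xpad <- rbind(matrix(0, pad, cch), X, matrix(0, k - 1L - pad, cch))
    U <- conv_unfold(Xpad, k, L)
    pre <- addb(U %*% params[[paste0("c", j, "_W")]], params[[paste0("c", j, "_b")]])
    out <- pmax(pre, 0)
    convs[[j]] <- list(U = U, pre = pre, pad = pad, k = k, c_in = cch)
    X <- out
  }
  h_b <- colMeans(X)
  p_b <- as.numeric(h_b %*% params$Wpb) + params$bpb
  list(p_b = p_b, h_b = h_b, convs = convs, X_out = X)
}

convolution_bwd <- function(dp_b, cache, params, config, grads) {
  L <- config$n_features
  grads$Wpb <- grads$Wpb + outer(cache$h_b, dp_b)
  grads$bpb <- grads$bpb + dp_b
  dh_b <- as.numeric(params$Wpb %*% dp_b)
  nC <- length(config$kernel_sizes)
  c_last <- config$conv_channels[nC]
  dX <- matrix(rep(dh_b / L, each = L), L, c_last)
  for (j in rev(seq_len(nC))) {
    cj <- cache$convs[[j]]
    dpre <- dX * (cj$pre > 0)
    W <- params[[paste0("c", j, "_W")]]
    grads[[paste0("c", j, "_W")]] <- grads[[paste0("c", j, "_W")]] +
      crossprod(cj$U, dpre)
    grads[[paste0("c", j, "_b")]] <- grads[[paste0("c", j, "_b")]] +
      colSums(dpre)
    dU <- dpre %*% t(W)
    dXpad <- matrix(0, L + cj$k - 1L, cj$c_in)
    for (tp in seq_len(cj$k)) {
      cols <- ((tp - 1) * cj$c_in + 1):(tp * cj$c_in)
      dXpad[tp:(tp + L - 1), ] <- dXpad[tp:(tp + L - 1), ] + dU[, cols, drop = FALSE]
    }
    dX <- dXpad[(cj$pad + 1):(cj$pad + L), , drop = FALSE]
  }
  list(grads = grads, dtok = dX)
}

#' Dynamic weight-gated feature fusion
#'
#' Concatenates the two projected branch vectors, passes them through a
#' two-layer gating network (`relu` then `sigmoid`) to obtain the gating
#' vector `g`, and blends the branches per dimension:
#' `fused = g * p_a + (1 - g) * p_b`.
#'
#' @param p_a,p_b Numeric vectors of equal width (attention- and
#'   convolution-branch projections).
#' @param gate_params List with `W1` (2f x f), `b1` (f), `W2` (f x f),
#'   `b2` (f).
#' @return List with `fused`, `g`, and `h` (gate hidden activations).
#' @export
gated_fusion <- function(p_a, p_b, gate_params) {
  if (length(p_a) != length(p_b)) {
    stop_oam("branch widths differ: %d vs %d", length(p_a), length(p_b))
  }
  z <- c(p_a, p_b)
  h <- pmax(as.numeric(z %*% gate_params$W1) + gate_params$b1, 0)
  g <- stats::plogis(as.numeric(h %*% gate_params$W2) + gate_params$b2)
  list(fused = g * p_a + (1 - g) * p_b, g = g, h = h)
}

# ---- full forward / backward for one sample --------------------------

fusion_forward <- function(x, params, config, drop_mask_a = NULL,
                           drop_mask_b = NULL) {
  tok <- embed_tokens(x, params, config)
  att <- attention_fwd(tok, params, config)
  cnv <- convolution_fwd(tok, params, config)
  p_a <- att$p_a
  p_b <- cnv$p_b
  if (!is.null(drop_mask_a)) p_a <- p_a * drop_mask_a
  if (!is.null(drop_mask_b)) p_b <- p_b * drop_mask_b
  mode <- config$fusion_mode
  gate <- NULL
  if (mode == "gated") {
    gate <- gated_fusion(p_a, p_b,
                         list(W1 = params$Wg1, b1 = params$bg1,
                              W2 = params$Wg2, b2 = params$bg2))
    fused <- gate$fused
  } else if (mode == "concat") {
    fused <- c(p_a, p_b)
  } else if (mode == "transformer") {
    fused <- p_a
  } else {
    fused <- p_b
  }
  logits <- as.numeric(fused %*% params$Wc) + params$bc
  list(x = x, tok = tok, att = att, cnv = cnv, p_a = p_a, p_b = p_b,
       gate = gate, fused = fused, logits = logits,
       drop_mask_a = drop_mask_a, drop_mask_b = drop_mask_b)
}

fusion_backward <- function(dlogits, cache, params, config, grads) {
  f <- config$fusion_dim
  grads$Wc <- grads$Wc + outer(cache$fused, dlogits)
  grads$bc <- grads$bc + dlogits
  dfused <- as.numeric(params$Wc %*% dlogits)
  mode <- config$fusion_mode
  if (mode == "gated") {
    gcache <- cache$gate
    g <- gcache$g; h <- gcache$h
    dg <- dfused * (cache$p_a - cache$p_b)
    dp_a <- dfused * g
    dp_b <- dfused * (1 - g)
    du <- dg * g * (1 - g)
    grads$Wg2 <- grads$Wg2 + outer(h, du)
    grads$bg2 <- grads$bg2 + du
    dh <- as.numeric(params$Wg2 %*% du)
    dpre <- dh * (h > 0)
    z <- c(cache$p_a, cache$p_b)
    grads$Wg1 <- grads$Wg1 + outer(z, dpre)
    grads$bg1 <- grads$bg1 + dpre
    dz <- as.numeric(params$Wg1 %*% dpre)
    dp_a <- dp_a + dz[seq_len(f)]
    dp_b <- dp_b + dz[f + seq_len(f)]
  } else if (mode == "concat") {
    dp_a <- dfused[seq_len(f)]
    dp_b <- dfused[f + seq_len(f)]
  } else if (mode == "transformer") {
    dp_a <- dfused
    dp_b <- numeric(f)
  } else {
    dp_a <- numeric(f)
    dp_b <- dfused
  }
  if (!is.null(cache$drop_mask_a)) dp_a <- dp_a * cache$drop_mask_a
  if (!is.null(cache$drop_mask_b)) dp_b <- dp_b * cache$drop_mask_b
  ab <- attention_bwd(dp_a, cache$att, params, config, grads)
  cb <- convolution_bwd(dp_b, cache$cnv, params, config, ab$grads)
  grads <- cb$grads
  dtok <- ab$dtok + cb$dtok
  grads$emb_A <- grads$emb_A + dtok * cache$x
  grads$emb_B <- grads$emb_B + dtok
  grads$emb_P <- grads$emb_P + dtok
  dx <- rowSums(dtok * params$emb_A)
  list(grads = grads, dx = dx)
}

zero_like <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))
}

#' Attention branch of the fusion model
#'
#' Runs the Transformer encoder on a token sequence and returns the pooled
#' projected vector `p_a` (width `fusion_dim`).
#'
#' @param tokens `n_features x d_model` token matrix (see
#'   [embed_tokens()]).
#' @param params,config Model parameters and configuration.
#' @return Numeric vector of width `fusion_dim`.
#' @export
attention_branch <- function(tokens, params, config) {
  attention_fwd(tokens, params, config)$p_a
}

#' Convolution branch of the fusion model
#'
#' Runs the 1-D convolution stack (same-padding, relu, global average
#' pooling) on a token sequence and returns the pooled projected vector
#' `p_b` (width `fusion_dim`).
#'
#' @inheritParams attention_branch
#' @return Numeric vector of width `fusion_dim`.
#' @export
convolution_branch <- function(tokens, params, config) {
  convolution_fwd(tokens, params, config)$p_b
}
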