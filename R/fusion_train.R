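# Training and evaluation of the gated Trans-CNN fusion classifier.

#' Train the gated Trans-CNN fusion classifier
#'
#' Minimizes (optionally class-weighted) softmax cross-entropy with Adam
#' and minibatches, early-stopping on validation accuracy. If no explicit
#' validation set is supplied, a stratified fraction of the training data
#' is held out. Fully seeded: the same seed yields identical final
#' weights.
#'
#' @param X Numeric matrix, samples x features (colnames = probe ids).
#' @param y Binary labels (0/1).
#' @param config A [fusion_config()]; `config$n_features` must equal
#'   `ncol(X)`.
#' @param X_val,y_val Optional explicit validation set.
#' @param verbose Print per-epoch progress.
#' @return An object of class `fusion_model`: `params` (best weights),
#'   `config`, `center`/`scale` (input standardization), `history`
#'   (per-epoch data.frame: epoch, train_loss, val_acc), `best_epoch`.
#' @export
train_fusion_model <- function(X, y, config, X_val = NULL, y_val = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(config, "fusion_config"))
  check_xy(X, y)
  if (ncol(X) != config$n_features) {
    stop_oam("ncol(X) = %d but config$n_features = %d", ncol(X),
             config$n_features)
  }
  if (any(!is.finite(X))) stop_oam("non-finite values in X")
  set.seed(config$seed)

  if (config$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- scale(X, ctr, scl)

  if (is.null(X_val)) {
    hold <- stratified_holdout(y, config$val_fraction, config$seed)
    Xv <- Xs[hold, , drop = FALSE]; yv <- y[hold]
    Xs <- Xs[-hold, , drop = FALSE]; ytr <- y[-hold]
  } else {
    Xv <- scale(X_val, ctr, scl); yv <- y_val; ytr <- y
  }
  if (length(unique(ytr)) < 2 || length(unique(yv)) < 2) {
    stop_oam("train or validation split contains a single class")
  }

  n <- nrow(Xs)
  w_cls <- if (config$class_weighting) {
    c(n / (2 * sum(ytr == 0)), n / (2 * sum(ytr == 1)))
  } else c(1, 1)

  params <- init_fusion_params(config)
  adam <- adam_state(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_acc = numeric(0))
  wait <- 0L
  f <- config$fusion_dim

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      grads <- zero_like(params)
      bl <- 0
      for (i in idx) {
        ma <- mb <- NULL
        if (config$dropout > 0) {
          ma <- (stats::runif(f) >= config$dropout) / (1 - config$dropout)
          mb <- (stats::runif(f) >= config$dropout) / (1 - config$dropout)
        }
        cache <- fusion_forward(Xs[i, ], params, config, ma, mb)
        sm <- softmax_vec(cache$logits)
        yi <- ytr[i]
        wi <- w_cls[yi + 1L]
        bl <- bl - wi * log(max(sm[yi + 1L], 1e-12))
        dlogits <- wi * (sm - c(1 - yi, yi))
        grads <- fusion_backward(dlogits, cache, params, config, grads)$grads
      }
      grads <- lapply(grads, function(g) g / length(idx))
      upd <- adam_step(params, grads, adam, config$lr, config$weight_decay)
      params <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + bl
    }
    ep_loss <- ep_loss / n
    if (!is.finite(ep_loss)) {
      stop_oam("training diverged (non-finite loss) at epoch %d", epoch)
    }
    val_scores <- predict_scores(params, config, Xv)
    val_acc <- mean((val_scores > 0.5) == (yv == 1))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_acc %.4f", epoch, ep_loss,
                      val_acc))
    }
    if (val_acc > best$acc + 1e-12) {
      best <- list(acc = val_acc, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  structure(
    list(params = best$params, config = config, center = ctr, scale = scl,
         feature_ids = colnames(X), history = hist,
         best_epoch = best$epoch, trained = TRUE),
    class = "fusion_model"
  )
}

stratified_holdout <- function(y, fraction, seed) {
  set.seed(derive_seed(seed, 4242L))
  idx <- seq_along(y)
  hold <- integer(0)
  for (cls in sort(unique(y))) {
    members <- idx[y == cls]
    k <- max(1L, round(fraction * length(members)))
    hold <- c(hold, sample(members, k))
  }
  sort(hold)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  decay_ok <- grepl("W", names(params), fixed = TRUE)
  for (k in seq_along(params)) {
    nm <- names(params)[k]
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    step <- mhat / (sqrt(vhat) + eps)
    # decoupled weight decay on weight matrices only (not biases/LN gains)
    if (weight_decay > 0 && decay_ok[k]) {
      step <- step + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, state = state)
}

predict_scores <- function(params, config, Xs) {
  vapply(seq_len(nrow(Xs)), function(i) {
    softmax_vec(fusion_forward(Xs[i, ], params, config)$logits)[2]
  }, numeric(1))
}

#' Predict positive-class probabilities from a fusion model
#'
#' @param object A trained `fusion_model`.
#' @param X Numeric matrix, samples x features, matching the training
#'   feature set.
#' @param ... Unused.
#' @return Numeric vector of positive-class (OA) probabilities.
#' @export
predict.fusion_model <- function(object, X, ...) {
  check_model_input(object, X)
  Xs <- scale(X, object$center, object$scale)
  predict_scores(object$params, object$config, Xs)
}

check_model_input <- function(model, X) {
  if (!isTRUE(model$trained)) stop_oam("model is not trained")
  if (ncol(X) != model$config$n_features) {
    stop_oam("X has %d features; model expects %d", ncol(X),
             model$config$n_features)
  }
  invisible(TRUE)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(
    "fusion_model [%s]: %d features, d_model=%d, %d layers, best epoch %d (val_acc %.4f)\n",
    x$config$fusion_mode, x$config$n_features, x$config$d_model,
    x$config$n_layers, x$best_epoch, max(x$history$val_acc)))
  invisible(x)
}

# ---- metrics ---------------------------------------------------------

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney pairwise
#' probability that a positive sample outscores a negative one (ties count
#' one half).
#'
#' @param scores Predicted positive-class scores.
#' @param y Binary labels (0/1).
#' @return AUC in \[0,1\], or `NA` (with a warning) if only one class is
#'   present.
#' @export
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics: accuracy, F1, AUC
#'
#' Accuracy and F1 use the 0.5 probability threshold; F1 is computed on
#' the positive (OA) class; AUC is the rank statistic of [auc_rank()].
#'
#' @param model A trained `fusion_model`.
#' @param X,y Labeled evaluation data.
#' @return List of class `fusion_metrics`: `acc`, `f1`, `auc`.
#' @export
evaluate_model <- function(model, X, y) {
  scores <- stats::predict(model, X)
  metrics_from_scores(scores, y)
}

metrics_from_scores <- function(scores, y) {
  pred <- as.integer(scores > 0.5)
  acc <- mean(pred == y)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(list(acc = acc, f1 = f1, auc = auc_rank(scores, y)),
            class = "fusion_metrics")
}

#' @export
print.fusion_metrics <- function(x, ...) {
  cat(sprintf("ACC %.4f  F1 %.4f  AUC %s\n", x$acc, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Accuracy on a positive-only external cohort
#'
#' For external datasets containing only disease samples, only sensitivity
#' is estimable; this reports the number and fraction of correctly
#' identified positives (rounded to 4 decimals) and flags that specificity
#' is unassessable.
#'
#' @param model A trained `fusion_model`.
#' @param X_positive Matrix of known-positive samples.
#' @return List: `n_correct`, `n_total`, `accuracy`,
#'   `specificity_assessable = FALSE`.
#' @export
evaluate_positive_only <- function(model, X_positive) {
  if (is.null(dim(X_positive)) || nrow(X_positive) == 0) {
    stop_oam("empty positive-only evaluation set")
  }
  scores <- stats::predict(model, X_positive)
  n_correct <- sum(scores > 0.5)
  positive_only_accuracy(n_correct, nrow(X_positive))
}

#' Positive-only accuracy from counts
#'
#' @param n_correct Correctly identified positives.
#' @param n_total Total positives evaluated.
#' @return List: `n_correct`, `n_total`, `accuracy` (4-decimal rounding),
#'   `specificity_assessable = FALSE`.
#' @export
positive_only_accuracy <- function(n_correct, n_total) {
  n_total <- assert_count(n_total, "n_total")
  n_correct <- assert_count(n_correct, "n_correct", min = 0L)
  if (n_correct > n_total) stop_oam("n_correct exceeds n_total")
  list(n_correct = n_correct, n_total = n_total,
       accuracy = round(n_correct / n_total, 4),
       specificity_assessable = FALSE)
}

# ---- gate contribution -----------------------------------------------

#' Gating-vector contribution statistics
#'
#' Collects the gating vector `g` for every sample and summarizes the mean
#' contribution weight of the Transformer branch (`mean(g)`) and of the CNN
#' branch (`1 - mean(g)`); the two sum to 1 exactly by construction.
#'
#' @param model A trained `fusion_model` with `fusion_mode = "gated"`.
#' @param X Input samples.
#' @return List of class `gate_record`: `g` (samples x fusion_dim matrix),
#'   `mean_transformer_weight`, `mean_cnn_weight`.
#' @export
gate_contribution <- function(model, X) {
  check_model_input(model, X)
  if (model$config$fusion_mode != "gated") {
    stop_oam("gate statistics require fusion_mode = 'gated'")
  }
  Xs <- scale(X, model$center, model$scale)
  G <- t(vapply(seq_len(nrow(Xs)), function(i) {
    fusion_forward(Xs[i, ], model$params, model$config)$gate$g
  }, numeric(model$config$fusion_dim)))
  gate_record(G)
}

#' Build a gate record from a gating matrix
#'
#' @param g Matrix of gate values in (0,1), one row per sample.
#' @return List of class `gate_record`.
#' @export
gate_record <- function(g) {
  g <- as.matrix(g)
  if (any(g <= 0 | g >= 1)) stop_oam("gate entries must lie strictly in (0,1)")
  mt <- mean(g)
  structure(list(g = g, mean_transformer_weight = mt,
                 mean_cnn_weight = 1 - mt),
            class = "gate_record")
}

#' @export
print.gate_record <- function(x, ...) {
  cat(sprintf("gate_record: transformer %.1f%% / cnn %.1f%% (n = %d)\n",
              100 * x$mean_transformer_weight, 100 * x$mean_cnn_weight,
              nrow(x$g)))
  invisible(x)
}

# ---- ablation --------------------------------------------------------

#' Ablation comparison of fusion variants
#'
#' Trains four architecture variants — attention branch only, convolution
#' branch only, simple concatenation fusion, and gated fusion — under
#' identical seeds and train/validation splits, and reports validation
#' metrics per variant.
#'
#' @param X,y Labeled data.
#' @param config Base [fusion_config()]; its `fusion_mode` is overridden
#'   per variant.
#' @return data.frame with one row per variant: `variant`, `acc`, `f1`,
#'   `auc`.
#' @export
ablation_compare <- function(X, y, config) {
  variants <- c("transformer", "cnn", "concat", "gated")
  hold <- stratified_holdout(y, config$val_fraction, config$seed)
  Xv <- X[hold, , drop = FALSE]; yv <- y[hold]
  Xt <- X[-hold, , drop = FALSE]; yt <- y[-hold]
  rows <- lapply(variants, function(v) {
    cfg <- config
    cfg$fusion_mode <- v
    m <- train_fusion_model(Xt, yt, cfg, X_val = Xv, y_val = yv)
    met <- evaluate_model(m, Xv, yv)
    data.frame(variant = v, acc = met$acc, f1 = met$f1, auc = met$auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
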