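#' Assemble the full attention-based DSC-ConvLSTM classifier
#'
#' Composition: DSC backbone -> the backbone output's time axis (`T'//81`
#' steps, feature width `D*F4`) becomes the recurrent sequence ->
#' bidirectional ConvLSTM -> attention pooling -> pointwise (1x1)
#' convolutional classification layer -> softmax. With
#' `use_recurrent_head = FALSE` (ablation) the recurrent/attention head is
#' dropped and the classifier acts on the time-averaged backbone features.
#'
#' @param backbone_cfg a [backbone_config()].
#' @param n_classes number of output classes.
#' @param candidate_kernel odd kernel length of the ConvLSTM candidate
#'   convolution.
#' @param attention_dim attention key-space dimension (the default completes
#'   the calibrated 17,972-parameter configuration).
#' @param use_recurrent_head keep the bidirectional ConvLSTM + attention
#'   head (`TRUE`) or classify pooled backbone features directly (`FALSE`).
#' @param seed RNG seed for weight initialization.
#' @return an object of class `dsc_convlstm`.
#' @export
#' @examples
#' model <- build_model(backbone_config(C = 4, F1 = 2, F2 = 2, F3 = 2, F4 = 2),
#'                      n_classes = 2, attention_dim = 3)
#' count_parameters(model)
build_model <- function(backbone_cfg = backbone_config(), n_classes = 4L,
                        candidate_kernel = 3L, attention_dim = 26L,
                        use_recurrent_head = TRUE, seed = 1L) {
  stopifnot(inherits(backbone_cfg, "backbone_config"))
  if (!is_count(n_classes)) stop_config("`n_classes` must be a positive integer")
  m <- backbone_out_maps(backbone_cfg)
  with_seed(seed, {
    params <- init_backbone_params(backbone_cfg)
    if (use_recurrent_head) {
      params$lstm_f <- init_convlstm_params(m, candidate_kernel)
      params$lstm_b <- init_convlstm_params(m, candidate_kernel)
      params$attn <- init_attention_params(2L * m, attention_dim)
      cls_in <- 2L * m
    } else {
      cls_in <- m
    }
    params$w_cls <- init_uniform(c(n_classes, cls_in), cls_in)
    params$b_cls <- rep(0, n_classes)
  })
  bn_state <- as.environment(init_backbone_bn_state(backbone_cfg))
  structure(
    list(backbone_cfg = backbone_cfg, n_classes = as.integer(n_classes),
         candidate_kernel = as.integer(candidate_kernel),
         attention_dim = as.integer(attention_dim),
         use_recurrent_head = isTRUE(use_recurrent_head),
         params = params, bn_state = bn_state, seed = as.integer(seed)),
    class = "dsc_convlstm"
  )
}

#' @export
print.dsc_convlstm <- function(x, ...) {
  cfg <- x$backbone_cfg
  cat(sprintf("<dsc_convlstm> C=%d filters %d/%d/%d/%d D=%d, %s, %d classes\n",
              cfg$C, cfg$F1, cfg$F2, cfg$F3, cfg$F4, cfg$D,
              if (x$use_recurrent_head)
                sprintf("BiConvLSTM(h=%d) + attention(key=%d)",
                        backbone_out_maps(cfg), x$attention_dim)
              else "pooled-feature head (ablation)",
              x$n_classes))
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution and dense weights, biases, and
#' batch-norm affine pairs. Accepts a fitted/initialized model or any nested
#' list of numeric arrays.
#'
#' @param model a `dsc_convlstm` model or a nested list of numeric arrays.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  x <- if (inherits(model, "dsc_convlstm")) model$params else model
  count_leaves <- function(v) {
    if (is.numeric(v)) return(length(v))
    if (is.list(v)) return(sum(vapply(v, count_leaves, numeric(1))))
    0L
  }
  as.integer(count_leaves(x))
}

# Forward over a window batch x (B, C, T'). Returns probabilities (B, K)
# and, when keep_cache, everything needed for the backward pass.
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  bb <- backbone_forward(model$params, model$backbone_cfg, x, model$bn_state,
                         training = training)
  feats <- bb$out                                       # (B, M, T_out)
  if (model$use_recurrent_head) {
    rf <- run_convlstm(feats, model$params$lstm_f, "forward")
    rb <- run_convlstm(feats, model$params$lstm_b, "backward")
    fused <- bidirectional_fuse(rf$H_seq, rb$H_seq)     # (B, 2M, T_out)
    at <- attention_pool(fused, model$params$attn)
    pooled <- at$y                                      # (B, 2M)
  } else {
    d <- dim(feats)
    pooled <- matrix(rowMeans(matrix(feats, nrow = d[1] * d[2])), d[1], d[2])
    rf <- rb <- at <- NULL
  }
  logits <- tcrossprod(pooled, model$params$w_cls)
  logits <- sweep(logits, 2, model$params$b_cls, `+`)
  lmax <- apply(logits, 1, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  cache <- NULL
  if (keep_cache)
    cache <- list(bb = bb$cache, rf = rf, rb = rb, at = at, pooled = pooled,
                  probs = probs, feat_dim = dim(feats))
  list(probs = probs, cache = cache)
}

# Backward from dlogits (B, K). Returns the full nested gradient list.
model_backward <- function(model, dlogits, cache) {
  grads <- list()
  grads$w_cls <- crossprod(dlogits, cache$pooled)
  grads$b_cls <- colSums(dlogits)
  dpooled <- dlogits %*% model$params$w_cls             # (B, cls_in)
  fd <- cache$feat_dim
  if (model$use_recurrent_head) {
    ab <- attention_bwd(dpooled, cache$at$cache)
    grads$attn <- list(w_w = ab$dw_w, b_w = ab$db_w, z_w = ab$dz_w)
    m <- fd[2]
    dh_f <- ab$dh[, seq_len(m), , drop = FALSE]
    dh_b <- ab$dh[, m + seq_len(m), , drop = FALSE]
    bf <- run_convlstm_bwd(dh_f, cache$rf$cache, model$params$lstm_f)
    bb_ <- run_convlstm_bwd(dh_b, cache$rb$cache, model$params$lstm_b)
    grads$lstm_f <- bf$grads
    grads$lstm_b <- bb_$grads
    dfeats <- bf$dx + bb_$dx
  } else {
    dfeats <- array(rep(dpooled / fd[3], times = fd[3]), dim = fd)
  }
  c(grads, backbone_backward(model$params, model$backbone_cfg, dfeats,
                             cache$bb))
}

# Cross-entropy loss and parameter gradients for one minibatch.
#   per_window:    every window is an independent example; the loss is the
#                  mean per-window cross-entropy.
#   averaged_prob: windows are grouped by source trial, trial probability =
#                  mean of window probabilities, loss = mean per-trial
#                  cross-entropy of the averaged probability.
# `labels` are 0-based; `trial_index` groups windows for averaged_prob.
model_loss_grads <- function(model, x, labels, loss_mode = "per_window",
                             trial_index = NULL, training = TRUE) {
  fw <- model_forward(model, x, training = training, keep_cache = TRUE)
  p <- fw$probs
  b <- nrow(p)
  k <- ncol(p)
  yi <- cbind(seq_len(b), labels + 1L)
  if (loss_mode == "per_window") {
    loss <- -mean(log(pmax(p[yi], 1e-12)))
    dlogits <- p
    dlogits[yi] <- dlogits[yi] - 1
    dlogits <- dlogits / b
  } else {
    if (is.null(trial_index))
      stop_config("`trial_index` is required for loss_mode = 'averaged_prob'")
    groups <- split(seq_len(b), trial_index)
    n_tr <- length(groups)
    loss <- 0
    dp <- matrix(0, b, k)
    for (g in groups) {
      y <- labels[g[1]] + 1L
      pbar <- colMeans(p[g, , drop = FALSE])
      loss <- loss - log(max(pbar[y], 1e-12))
      s <- numeric(k)
      s[y] <- -1 / max(pbar[y], 1e-12)
      dp[g, ] <- matrix(s / (length(g) * n_tr), length(g), k, byrow = TRUE)
    }
    loss <- loss / n_tr
    # chain through the softmax: dz = p * (dp - sum(p * dp))
    dlogits <- p * (dp - rowSums(p * dp))
  }
  grads <- model_backward(model, dlogits, fw$cache)
  list(loss = loss, grads = grads, probs = p)
}

#' Predict window probabilities
#'
#' Runs the model in evaluation mode (fixed batch-norm statistics, no
#' dropout) over a window array.
#'
#' @param object a `dsc_convlstm` model.
#' @param windows array `(B, C, T')` of input windows.
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return matrix `(B, n_classes)` of class probabilities (rows sum to 1).
#' @export
predict.dsc_convlstm <- function(object, windows, batch_size = 256L, ...) {
  b <- dim(windows)[1]
  out <- matrix(0, b, object$n_classes)
  for (s in seq(1L, b, by = batch_size)) {
    e <- min(s + batch_size - 1L, b)
    out[s:e, ] <- model_forward(object, windows[s:e, , , drop = FALSE],
                                training = FALSE)$probs
  }
  out
}

#' Per-layer model summary
#'
#' @param object a `dsc_convlstm` model.
#' @param t_in input window length in samples used to report time axes.
#' @param ... unused.
#' @return a tibble with layer name, output shape and parameter count.
#' @export
summary.dsc_convlstm <- function(object, t_in = 500L, ...) {
  cfg <- object$backbone_cfg
  m1 <- cfg$D * cfg$F1
  m <- backbone_out_maps(cfg)
  t1 <- t_in %/% cfg$pool; t2 <- t1 %/% cfg$pool
  t3 <- t2 %/% cfg$pool; t4 <- t3 %/% cfg$pool
  p <- object$params
  rows <- list(
    list("conv_time", sprintf("[%d, %d, %d]", cfg$F1, cfg$C, t_in),
         length(p$w_time) + length(p$bn1_gamma) + length(p$bn1_beta)),
    list("conv_spat (depthwise)", sprintf("[%d, 1, %d]", m1, t_in),
         length(p$w_spat) + length(p$bn2_gamma) + length(p$bn2_beta)),
    list("block1 pool/dropout", sprintf("[%d, 1, %d]", m1, t1), 0L),
    list("block2 separable", sprintf("[%d, 1, %d]", cfg$F2, t2),
         length(p$w_dw2) + length(p$w_pw2) + length(p$bn3_gamma) + length(p$bn3_beta)),
    list("block3 separable", sprintf("[%d, 1, %d]", cfg$F3, t3),
         length(p$w_dw3) + length(p$w_pw3) + length(p$bn4_gamma) + length(p$bn4_beta)),
    list("block4 separable (mean-pool)", sprintf("[%d, 1, %d]", cfg$F4, t4),
         length(p$w_dw4) + length(p$w_pw4) + length(p$bn5_gamma) + length(p$bn5_beta))
  )
  if (object$use_recurrent_head) {
    rows <- c(rows, list(
      list("BiConvLSTM", sprintf("[%d, %d]", 2 * m, t4),
           count_parameters(list(p$lstm_f, p$lstm_b))),
      list("attention pool", sprintf("[%d]", 2 * m),
           count_parameters(p$attn))
    ))
  }
  rows <- c(rows, list(
    list("classifier (1x1 conv)", sprintf("[%d]", object$n_classes),
         length(p$w_cls) + length(p$b_cls))
  ))
  tb <- tibble::tibble(
    layer = vapply(rows, `[[`, character(1), 1),
    output_shape = vapply(rows, `[[`, character(1), 2),
    parameters = vapply(rows, function(r) as.integer(r[[3]]), integer(1))
  )
  tb
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint embeds the full configuration, all weights and the
#' batch-norm running statistics, so a loaded model is immediately usable
#' for prediction and further training.
#'
#' @param model a `dsc_convlstm`.
#' @param path file path.
#' @return `load_model` returns the `dsc_convlstm`; `save_model` returns
#'   `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dsc_convlstm"))
  obj <- unclass(model)
  obj$bn_state <- as.list(model$bn_state)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such checkpoint: %s", path))
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$params) || is.null(obj$backbone_cfg))
    stop_io(sprintf("file is not a model checkpoint: %s", path))
  obj$bn_state <- as.environment(obj$bn_state)
  structure(obj, class = "dsc_convlstm")
}
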