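# Modified ConvLSTM cell with dense gates on globally pooled features and a
# convolutional candidate path, plus temporal attention pooling and the
# bidirectional wrapper. The cell state update is:
#
#   Xp_t    = global mean pool of the input feature maps
#   Hp_t-1  = global mean pool of the previous hidden state
#   f_t     = sigmoid(W_xf Xp_t + W_hf Hp_t-1 + b_f)
#   i_t     = sigmoid(W_xi Xp_t + W_hi Hp_t-1 + b_i)
#   Ct_t    = f_t . C_t-1 + i_t . tanh(w_xc * Xp_t + w_hc * Hp_t-1 + b_c)
#   o_t     = sigmoid(W_xo Xp_t + W_ho Hp_t-1 + b_o)
#   H_t     = o_t . tanh(Ct_t)
#
# where * is a 1-D convolution along the feature axis (the only
# convolutional transformation; the gates stay dense) and Ct_t, which
# already blends the previous memory through f_t, is carried forward as the
# next cell memory. Pooling collapses any residual spatial extent, so the
# hidden width equals the feature-map count.

#' Initialize ConvLSTM cell parameters
#'
#' Dense gate weights use fan-in-scaled uniform draws; recurrent (hidden-to-
#' hidden) weights are orthogonal; the candidate path holds one shared
#' odd-length kernel per stream; biases start at zero.
#'
#' @param m feature-map count = hidden width (the candidate convolution
#'   requires the pooled input and the hidden state to share this length).
#' @param candidate_kernel odd kernel length of the candidate convolution.
#' @return a named list of cell parameters.
#' @export
init_convlstm_params <- function(m, candidate_kernel = 3L) {
  if (!is_count(m)) stop_config("`m` must be a positive integer")
  if (!is_count(candidate_kernel) || candidate_kernel %% 2 == 0)
    stop_config("`candidate_kernel` must be a positive odd integer")
  gate <- function() init_uniform(c(m, m), m)
  list(
    w_xf = gate(), w_hf = init_orthogonal(m), b_f = rep(0, m),
    w_xi = gate(), w_hi = init_orthogonal(m), b_i = rep(0, m),
    w_xc = as.numeric(init_uniform(candidate_kernel, candidate_kernel)),
    w_hc = as.numeric(init_uniform(candidate_kernel, candidate_kernel)),
    b_c = rep(0, m),
    w_xo = gate(), w_ho = init_orthogonal(m), b_o = rep(0, m)
  )
}

# Collapse trailing spatial dims of (B, M) or (B, M, S...) to (B, M) by
# global mean pooling.
global_mean_pool <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) return(as.matrix(x))
  m <- matrix(x, nrow = d[1] * d[2])
  matrix(rowMeans(m), d[1], d[2])
}

#' One ConvLSTM step
#'
#' Advances the cell by a single time step. Inputs with residual spatial
#' extent are global-mean-pooled to `(batch, features)` first.
#'
#' @param x_t input features: `(B, M)` matrix or `(B, M, S)` array.
#' @param state list with `H` and `C`, each `(B, M)` (zeros for the initial
#'   state).
#' @param params from [init_convlstm_params()].
#' @return list with the new `H`, `C`, the gate activations `f`, `i`, `o`,
#'   the candidate input `g`, and a `cache` for backpropagation.
#' @export
convlstm_step <- function(x_t, state, params) {
  xp <- global_mean_pool(x_t)
  m <- ncol(xp)
  if (ncol(params$w_xf) != m)
    mid_stop(sprintf("w_xf expects %d input features, got %d",
                     ncol(params$w_xf), m), "midecoder_parameter_error")
  hp <- state$H  # hidden state has no spatial extent; pooling is identity
  if (ncol(hp) != ncol(params$w_hf))
    mid_stop("hidden state width does not match w_hf", "midecoder_parameter_error")
  af <- tcrossprod(xp, params$w_xf) + tcrossprod(hp, params$w_hf) +
    rep(params$b_f, each = nrow(xp))
  f <- sigmoid(af)
  ai <- tcrossprod(xp, params$w_xi) + tcrossprod(hp, params$w_hi) +
    rep(params$b_i, each = nrow(xp))
  i <- sigmoid(ai)
  cx <- featconv_fwd(xp, params$w_xc)
  ch <- featconv_fwd(hp, params$w_hc)
  u <- cx$out + ch$out + rep(params$b_c, each = nrow(xp))
  g <- tanh(u)
  ct <- f * state$C + i * g
  ao <- tcrossprod(xp, params$w_xo) + tcrossprod(hp, params$w_ho) +
    rep(params$b_o, each = nrow(xp))
  o <- sigmoid(ao)
  tc <- tanh(ct)
  h <- o * tc
  list(H = h, C = ct, f = f, i = i, o = o, g = g,
       cache = list(xp = xp, hp = hp, c_prev = state$C, f = f, i = i, o = o,
                    g = g, tc = tc, cx = cx$cache, ch = ch$cache))
}

# Backward through one step. Returns gradients for the step inputs (dX, and
# dH_prev/dC_prev to chain through time) and accumulates into `acc`, a list
# of parameter gradients.
convlstm_step_bwd <- function(dh, dc_next, cache, params, acc) {
  o <- cache$o; f <- cache$f; i <- cache$i; g <- cache$g; tc <- cache$tc
  dao <- dh * tc * o * (1 - o)
  dct <- dh * o * (1 - tc * tc) + dc_next
  daf <- dct * cache$c_prev * f * (1 - f)
  dai <- dct * g * i * (1 - i)
  du <- dct * i * (1 - g * g)
  dc_prev <- dct * f
  bx <- featconv_bwd(du, cache$cx)
  bh <- featconv_bwd(du, cache$ch)
  dx <- daf %*% params$w_xf + dai %*% params$w_xi + dao %*% params$w_xo + bx$dx
  dh_prev <- daf %*% params$w_hf + dai %*% params$w_hi + dao %*% params$w_ho +
    bh$dx
  acc$w_xf <- acc$w_xf + crossprod(daf, cache$xp)
  acc$w_hf <- acc$w_hf + crossprod(daf, cache$hp)
  acc$b_f <- acc$b_f + colSums(daf)
  acc$w_xi <- acc$w_xi + crossprod(dai, cache$xp)
  acc$w_hi <- acc$w_hi + crossprod(dai, cache$hp)
  acc$b_i <- acc$b_i + colSums(dai)
  acc$w_xc <- acc$w_xc + bx$dw
  acc$w_hc <- acc$w_hc + bh$dw
  acc$b_c <- acc$b_c + colSums(du)
  acc$w_xo <- acc$w_xo + crossprod(dao, cache$xp)
  acc$w_ho <- acc$w_ho + crossprod(dao, cache$hp)
  acc$b_o <- acc$b_o + colSums(dao)
  list(dx = dx, dh_prev = dh_prev, dc_prev = dc_prev, acc = acc)
}

#' Run a ConvLSTM over a feature sequence
#'
#' Iterates [convlstm_step()] from a zero initial state. The backward
#' direction processes the time-reversed sequence and reports hidden states
#' re-aligned to the original time order.
#'
#' @param x sequence array `(B, M, T)` (or `(M, T)` for a single sequence).
#' @param params from [init_convlstm_params()].
#' @param direction `"forward"` or `"backward"`.
#' @return list with `H_seq` (`(B, M, T)` hidden states in original time
#'   order) and a `cache` for backpropagation.
#' @export
run_convlstm <- function(x, params, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (length(dim(x)) == 2) x <- array(x, dim = c(1, dim(x)))
  d <- dim(x)
  if (d[3] < 1) mid_stop("empty input sequence", "midecoder_sequence_error")
  steps <- if (direction == "forward") seq_len(d[3]) else rev(seq_len(d[3]))
  state <- list(H = matrix(0, d[1], d[2]), C = matrix(0, d[1], d[2]))
  h_seq <- array(0, dim = d)
  caches <- vector("list", d[3])
  for (idx in seq_along(steps)) {
    t <- steps[idx]
    st <- convlstm_step(matrix(x[, , t], d[1], d[2]), state, params)
    state <- list(H = st$H, C = st$C)
    h_seq[, , t] <- st$H
    caches[[idx]] <- st$cache
  }
  list(H_seq = h_seq, cache = list(caches = caches, steps = steps, dim = d))
}

# BPTT through run_convlstm. `dh_seq` matches H_seq layout (original time
# order). Returns dX (B, M, T) and parameter gradients.
run_convlstm_bwd <- function(dh_seq, run_cache, params) {
  d <- run_cache$dim
  steps <- run_cache$steps
  acc <- setNames(lapply(names(params), function(nm) {
    p <- params[[nm]]
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  }), names(params))
  dx <- array(0, dim = d)
  dh_carry <- matrix(0, d[1], d[2])
  dc_carry <- matrix(0, d[1], d[2])
  for (idx in rev(seq_along(steps))) {
    t <- steps[idx]
    dh <- dh_carry + matrix(dh_seq[, , t], d[1], d[2])
    res <- convlstm_step_bwd(dh, dc_carry, run_cache$caches[[idx]], params, acc)
    acc <- res$acc
    dx[, , t] <- res$dx
    dh_carry <- res$dh_prev
    dc_carry <- res$dc_prev
  }
  list(dx = dx, grads = acc)
}

#' Fuse forward and backward hidden sequences
#'
#' Per-time-step concatenation along the feature axis.
#'
#' @param h_fwd,h_bwd arrays `(B, M, T)` (or matrices `(M, T)`).
#' @return array `(B, 2M, T)`.
#' @export
bidirectional_fuse <- function(h_fwd, h_bwd) {
  if (length(dim(h_fwd)) == 2) h_fwd <- array(h_fwd, dim = c(1, dim(h_fwd)))
  if (length(dim(h_bwd)) == 2) h_bwd <- array(h_bwd, dim = c(1, dim(h_bwd)))
  df <- dim(h_fwd); db <- dim(h_bwd)
  if (!identical(df, db))
    mid_stop(sprintf("cannot fuse hidden sequences of shape [%s] and [%s]",
                     paste(df, collapse = ","), paste(db, collapse = ",")),
             "midecoder_fusion_error")
  fused <- array(0, dim = c(df[1], 2 * df[2], df[3]))
  fused[, seq_len(df[2]), ] <- h_fwd
  fused[, df[2] + seq_len(df[2]), ] <- h_bwd
  fused
}

#' Initialize attention-pooling parameters
#'
#' @param width hidden-sequence feature width (2x hidden for bidirectional).
#' @param key_dim attention key-space dimension.
#' @return list with `w_w` (`key_dim x width`), `b_w`, `z_w`.
#' @export
init_attention_params <- function(width, key_dim) {
  if (!is_count(key_dim)) stop_config("`key_dim` must be a positive integer")
  list(w_w = init_uniform(c(key_dim, width), width),
       b_w = rep(0, key_dim),
       z_w = as.numeric(init_uniform(key_dim, key_dim)))
}

#' Attention pooling over a hidden-state sequence
#'
#' Keys `Z_t = tanh(W_w H_t + b_w)`, scores `Z_t . z_w` softmax-normalized
#' over time into weights `a_t > 0` with `sum(a_t) = 1`, output
#' `y = sum_t a_t H_t` (a convex combination of the hidden states).
#'
#' @param h hidden sequence: `(T, W)` matrix or `(B, W, T)` array.
#' @param params from [init_attention_params()].
#' @return for matrix input, list with `y` (length-`W` vector), `weights`
#'   (length `T`), and `cache`; for array input `y` is `(B, W)` and
#'   `weights` is `(B, T)`.
#' @export
attention_pool <- function(h, params) {
  single <- is.matrix(h)
  if (single) h <- aperm(array(h, dim = c(dim(h), 1)), c(3, 2, 1))  # (1, W, T)
  d <- dim(h)  # B, W, T
  b <- d[1]; w_n <- d[2]; t_n <- d[3]
  hm <- matrix(aperm(h, c(1, 3, 2)), ncol = w_n)     # (B*T) x W
  zpre <- tcrossprod(hm, params$w_w)                 # (B*T) x A
  zpre <- sweep(zpre, 2, params$b_w, `+`)
  z <- tanh(zpre)
  s <- matrix(z %*% params$z_w, b, t_n)              # scores
  smax <- apply(s, 1, max)
  es <- exp(s - smax)
  a <- es / rowSums(es)
  # y[b, w] = sum_t a[b, t] * h[b, w, t]
  y <- matrix(0, b, w_n)
  for (t in seq_len(t_n)) y <- y + matrix(h[, , t], b, w_n) * a[, t]
  cache <- list(h = h, hm = hm, z = z, a = a, d = d, params = params)
  if (single)
    list(y = as.numeric(y), weights = as.numeric(a), cache = cache)
  else
    list(y = y, weights = a, cache = cache)
}

attention_bwd <- function(dy, cache) {
  d <- cache$d; b <- d[1]; w_n <- d[2]; t_n <- d[3]
  h <- cache$h; a <- cache$a; z <- cache$z
  params <- cache$params
  if (is.null(dim(dy))) dy <- matrix(dy, b, w_n)
  dh <- array(0, dim = d)
  ds <- matrix(0, b, t_n)
  for (t in seq_len(t_n)) {
    ht <- matrix(h[, , t], b, w_n)
    dh[, , t] <- dy * a[, t]
    ds[, t] <- rowSums(dy * ht)
  }
  dsraw <- a * (ds - rowSums(a * ds))                 # softmax backward
  # scores s = z %*% z_w with z = tanh(W_w h + b_w)
  dsv <- as.numeric(dsraw)                            # (B*T), b fastest
  dz <- outer(dsv, params$z_w)
  dzw <- colSums(z * dsv)
  dzpre <- dz * (1 - z * z)
  dww <- crossprod(dzpre, cache$hm)                   # A x W
  dbw <- colSums(dzpre)
  dhm <- dzpre %*% params$w_w                         # (B*T) x W
  dh <- dh + aperm(array(dhm, dim = c(b, t_n, w_n)), c(1, 3, 2))
  list(dh = dh, dw_w = dww, db_w = dbw, dz_w = dzw)
}
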