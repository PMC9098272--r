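# Differentiable layer primitives. Each *_fwd returns list(out, cache); each
# *_bwd consumes the upstream gradient plus the cache and returns gradients
# for its inputs and parameters. Array convention: batch first, time last;
# batch-norm works on a features-last matrix view.

sigmoid <- function(x) 1 / (1 + exp(-x))

elu_fwd <- function(x) {
  neg <- x < 0
  out <- x
  out[neg] <- exp(x[neg]) - 1
  list(out = out, cache = list(out = out, neg = neg))
}

elu_bwd <- function(g, cache) {
  d <- g
  d[cache$neg] <- g[cache$neg] * (cache$out[cache$neg] + 1)
  d
}

# Batch norm over a (n x F) matrix view: per-column statistics. In training
# mode batch statistics are used and running statistics updated in place
# (torch convention: running <- (1 - momentum) * running + momentum * batch);
# in eval mode the stored running statistics are used, making the forward
# pass deterministic.
bn_fwd <- function(xm, gamma, beta, state, training, momentum, eps) {
  r <- bn_fwd_cpp(xm, gamma, beta, state$mean, state$var, training, momentum,
                  eps)
  if (training) state <- list(mean = as.numeric(r$new_mean),
                              var = as.numeric(r$new_var))
  list(out = r$out, state = state,
       cache = list(x = xm, mu = as.numeric(r$mu),
                    invstd = as.numeric(r$invstd), gamma = gamma,
                    training = training))
}

bn_bwd <- function(g, cache) {
  r <- bn_bwd_cpp(g, cache$x, cache$mu, cache$invstd, cache$gamma,
                  cache$training)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# Pool along the last (time) axis of a (B, M, T) array, kernel = stride = k;
# trailing samples beyond k * floor(T/k) are dropped.
maxpool_fwd <- function(x, k = 3L) {
  d <- dim(x)
  tp <- d[3] %/% k
  x4 <- array(x[, , seq_len(k * tp), drop = FALSE], dim = c(d[1], d[2], k, tp))
  out <- x4[, , 1, , drop = FALSE]
  arg <- array(1L, dim = c(d[1], d[2], 1, tp))
  for (r in 2:k) {
    xr <- x4[, , r, , drop = FALSE]
    upd <- xr > out
    out[upd] <- xr[upd]
    arg[upd] <- r
  }
  list(out = array(out, dim = c(d[1], d[2], tp)),
       cache = list(arg = array(arg, dim = c(d[1], d[2], tp)),
                    in_dim = d, k = k))
}

maxpool_bwd <- function(g, cache) {
  d <- cache$in_dim; k <- cache$k
  tp <- d[3] %/% k
  dx4 <- array(0, dim = c(d[1], d[2], k, tp))
  for (r in seq_len(k)) {
    mask <- cache$arg == r
    gr <- array(0, dim = dim(g))
    gr[mask] <- g[mask]
    dx4[, , r, ] <- gr
  }
  dx <- array(0, dim = d)
  dx[, , seq_len(k * tp)] <- dx4
  dx
}

meanpool_fwd <- function(x, k = 3L) {
  d <- dim(x)
  tp <- d[3] %/% k
  x4 <- array(x[, , seq_len(k * tp), drop = FALSE], dim = c(d[1], d[2], k, tp))
  out <- array(0, dim = c(d[1], d[2], tp))
  for (r in seq_len(k)) {
    xr <- x4[, , r, , drop = FALSE]
    dim(xr) <- c(d[1], d[2], tp)
    out <- out + xr
  }
  list(out = out / k, cache = list(in_dim = d, k = k))
}

meanpool_bwd <- function(g, cache) {
  d <- cache$in_dim; k <- cache$k
  tp <- d[3] %/% k
  dx <- array(0, dim = d)
  for (r in seq_len(k)) dx[, , seq(r, k * tp, by = k)] <- g / k
  dx
}

# Inverted dropout: active only in training mode; draws from the session RNG
# so a fixed seed reproduces the mask sequence.
dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(g, cache) {
  if (is.null(cache)) g else g * cache
}

# Depthwise temporal convolution on (B, M, T): one length-K kernel per map,
# same-length zero padding (left K/2, right K/2 - 1 for even K).
dwconv_fwd <- function(x, w) {
  list(out = dwconv_fwd_cpp(x, w), cache = list(x = x, w = w))
}

dwconv_bwd <- function(g, cache) {
  dwconv_bwd_cpp(g, cache$x, cache$w)
}

# Pointwise (1x1) cross-map convolution on (B, M, T): out[b,g,t] =
# sum_m x[b,m,t] P[m,g].
pwconv_fwd <- function(x, p) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(2, 1, 3)), nrow = d[2])      # M x (B*T)
  ym <- crossprod(p, xm)                                # G x (B*T)
  out <- aperm(array(ym, dim = c(ncol(p), d[1], d[3])), c(2, 1, 3))
  list(out = out, cache = list(xm = xm, p = p, d = d))
}

pwconv_bwd <- function(g, cache) {
  d <- cache$d
  gm <- matrix(aperm(g, c(2, 1, 3)), nrow = ncol(cache$p))  # G x (B*T)
  dp <- tcrossprod(cache$xm, gm)                            # M x G
  dxm <- cache$p %*% gm                                     # M x (B*T)
  dx <- aperm(array(dxm, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  list(dx = dx, dp = dp)
}

# 1-D convolution along the feature axis of a (B, M) matrix with a shared
# odd-length kernel and symmetric zero padding (the ConvLSTM candidate
# path).
featconv_fwd <- function(x, w) {
  k <- length(w); c0 <- (k + 1L) %/% 2L
  m <- ncol(x)
  xp <- cbind(matrix(0, nrow(x), c0 - 1L), x, matrix(0, nrow(x), k - c0))
  out <- matrix(0, nrow(x), m)
  for (j in seq_len(k)) out <- out + w[j] * xp[, j:(j + m - 1), drop = FALSE]
  list(out = out, cache = list(xp = xp, w = w, m = m))
}

featconv_bwd <- function(g, cache) {
  k <- length(cache$w); m <- cache$m
  c0 <- (k + 1L) %/% 2L
  dxp <- matrix(0, nrow(g), ncol(cache$xp))
  dw <- numeric(k)
  for (j in seq_len(k)) {
    dxp[, j:(j + m - 1)] <- dxp[, j:(j + m - 1)] + cache$w[j] * g
    dw[j] <- sum(cache$xp[, j:(j + m - 1), drop = FALSE] * g)
  }
  list(dx = dxp[, (c0):(c0 + m - 1), drop = FALSE], dw = dw)
}

# Parameter initializers ------------------------------------------------

init_uniform <- function(dims, fan_in) {
  lim <- sqrt(1 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# Gabor filter-bank initializer for the block-1 temporal kernels: windowed
# cosines with center frequencies evenly laddered across 2..7 cycles per
# kernel (7.8-27 Hz for a 64-sample kernel at 250 Hz, spanning the mu and
# beta rhythms) and random phases, each normalized to the expected norm of a
# fan-in-scaled uniform draw. Starting from band-pass structure instead of
# white noise removes the long plateau the filters otherwise spend
# discovering oscillatory features.
init_gabor_bank <- function(k, f_n) {
  w <- matrix(0, k, f_n)
  env <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))
  cycles <- seq(2, 7, length.out = f_n)
  u <- (seq_len(k) - (k + 1) / 2) / k
  for (f in seq_len(f_n)) {
    g <- cos(2 * pi * cycles[f] * u + runif(1, 0, 2 * pi)) * env
    w[, f] <- g / sqrt(sum(g * g)) * sqrt(1 / 3)
  }
  w
}

init_orthogonal <- function(n) {
  a <- matrix(rnorm(n * n), n, n)
  qr_ <- qr(a)
  q <- qr.Q(qr_)
  # fix the sign convention so the draw is rotation-invariant
  q * rep(sign(diag(qr.R(qr_))), each = n)
}
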