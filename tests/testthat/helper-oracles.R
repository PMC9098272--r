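# Shared fixtures and independent reference implementations used as oracles.

tiny_backbone_cfg <- function(C = 3L, dropout_p = 0) {
  backbone_config(C = C, F1 = 2L, F2 = 2L, F3 = 3L, F4 = 3L,
                  dropout_p = dropout_p)
}

tiny_model <- function(C = 3L, n_classes = 3L, seed = 5L, dropout_p = 0,
                       ...) {
  build_model(tiny_backbone_cfg(C = C, dropout_p = dropout_p),
              n_classes = n_classes, candidate_kernel = 3L,
              attention_dim = 2L, seed = seed, ...)
}

# Small, fast trial dataset for training-path tests: low rate, short trials.
tiny_train_dataset <- function(n_trials = 16L, n_channels = 4L, fs = 100,
                               erd_depth = 0.8, seed = 21L, noise_sd = 0.5) {
  generate_dataset(synthetic_spec(
    n_trials = n_trials, n_classes = 4L, n_channels = n_channels, fs = fs,
    trial_duration_s = 4.5, erd_depth = erd_depth, noise_sd = noise_sd,
    seed = seed))
}

tiny_crop_spec <- function(fs = 100) {
  crop_spec(window_len_s = 2, start_min_s = -0.5, start_max_s = 2,
            stride_samples = 125L, fs = fs)  # 3 windows per trial
}

# Scalar-loop reference for one ConvLSTM step: evaluates the cell equations
# element by element, independently of the vectorized implementation.
convlstm_step_ref <- function(x, h_prev, c_prev, p) {
  b_n <- nrow(x); m <- ncol(x)
  k <- length(p$w_xc); c0 <- (k + 1) %/% 2
  H <- matrix(0, b_n, m); Cn <- matrix(0, b_n, m)
  gates <- list(f = matrix(0, b_n, m), i = matrix(0, b_n, m),
                o = matrix(0, b_n, m))
  sig <- function(v) 1 / (1 + exp(-v))
  conv1 <- function(vec, w) {
    out <- numeric(m)
    for (u in seq_len(m)) {
      acc <- 0
      for (j in seq_len(k)) {
        src <- u + j - c0
        if (src >= 1 && src <= m) acc <- acc + vec[src] * w[j]
      }
      out[u] <- acc
    }
    out
  }
  for (bb in seq_len(b_n)) {
    xv <- x[bb, ]; hv <- h_prev[bb, ]; cv <- c_prev[bb, ]
    cxv <- conv1(xv, p$w_xc); chv <- conv1(hv, p$w_hc)
    for (u in seq_len(m)) {
      af <- sum(p$w_xf[u, ] * xv) + sum(p$w_hf[u, ] * hv) + p$b_f[u]
      ai <- sum(p$w_xi[u, ] * xv) + sum(p$w_hi[u, ] * hv) + p$b_i[u]
      ao <- sum(p$w_xo[u, ] * xv) + sum(p$w_ho[u, ] * hv) + p$b_o[u]
      f <- sig(af); i <- sig(ai); o <- sig(ao)
      g <- tanh(cxv[u] + chv[u] + p$b_c[u])
      ct <- f * cv[u] + i * g
      Cn[bb, u] <- ct
      H[bb, u] <- o * tanh(ct)
      gates$f[bb, u] <- f; gates$i[bb, u] <- i; gates$o[bb, u] <- o
    }
  }
  list(H = H, C = Cn, gates = gates)
}

# Brute-force attention pooling on a (T, W) hidden sequence.
attention_ref <- function(h, p) {
  t_n <- nrow(h)
  s <- numeric(t_n)
  for (t in seq_len(t_n)) {
    z <- tanh(as.numeric(p$w_w %*% h[t, ]) + p$b_w)
    s[t] <- sum(z * p$z_w)
  }
  a <- exp(s - max(s)); a <- a / sum(a)
  y <- numeric(ncol(h))
  for (t in seq_len(t_n)) y <- y + a[t] * h[t, ]
  list(y = y, a = a)
}

# Parameter-path helpers for gradient checks.
flat_param_paths <- function(p, prefix = character()) {
  if (is.numeric(p)) return(list(prefix))
  unlist(lapply(names(p), function(nm)
    flat_param_paths(p[[nm]], c(prefix, nm))), recursive = FALSE)
}

param_get <- function(p, path) { for (nm in path) p <- p[[nm]]; p }

param_set <- function(p, path, v) {
  if (length(path) == 1) { p[[path[1]]] <- v; return(p) }
  p[[path[1]]] <- param_set(p[[path[1]]], path[-1], v)
  p
}
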