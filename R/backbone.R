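#' Backbone configuration for the depthwise-separable feature extractor
#'
#' Four blocks. Block 1 splits the convolution into a temporal filter bank
#' (F1 kernels of length `temporal_kernel` shared across electrodes) and a
#' depthwise spatial filter over the full electrode axis (kernel `(C, 1)`,
#' `D` filters per temporal map), each followed by batch norm, with ELU,
#' max-pool (1, 3) and dropout closing the block. Blocks 2--4 are separable
#' convolutions: a depthwise temporal kernel of length `separable_kernel`
#' per map, a pointwise (1, 1) cross-map combination, batch norm, ELU,
#' pooling by 3 (max for blocks 2--3, mean for block 4) and dropout.
#' Convolutions carry no bias (redundant under the affine batch norms).
#' Temporal kernels use same-length zero padding, so the time axis shrinks
#' only at the pools: `T' -> T'//3 -> T'//9 -> T'//27 -> T'//81`.
#'
#' @param C input electrode channels.
#' @param F1,F2,F3,F4 filter counts per block (defaults from the parameter
#'   calibration, see [calibrate_architecture()]).
#' @param D depth multiplier of the spatial filter.
#' @param temporal_kernel block-1 temporal kernel length in samples.
#' @param separable_kernel blocks 2--4 depthwise kernel length in samples.
#' @param pool pooling size and stride.
#' @param dropout_p dropout probability (0.25 within subjects; 0.5 is the
#'   cross-subject setting).
#' @param bn_eps,bn_momentum batch-norm numerical floor and running-stat
#'   momentum.
#' @return an object of class `backbone_config`.
#' @export
backbone_config <- function(C = 22L, F1 = 8L, F2 = 16L, F3 = 32L, F4 = 32L,
                            D = 1L, temporal_kernel = 64L,
                            separable_kernel = 16L, pool = 3L,
                            dropout_p = 0.25, bn_eps = 1e-3,
                            bn_momentum = 0.01) {
  for (nm in c("C", "F1", "F2", "F3", "F4", "D", "temporal_kernel",
               "separable_kernel", "pool")) {
    if (!is_count(get(nm))) stop_config(sprintf("`%s` must be a positive integer", nm))
  }
  if (!is_number(dropout_p) || dropout_p < 0 || dropout_p >= 1)
    stop_config("`dropout_p` must lie in [0, 1)")
  structure(
    list(C = as.integer(C), F1 = as.integer(F1), F2 = as.integer(F2),
         F3 = as.integer(F3), F4 = as.integer(F4), D = as.integer(D),
         temporal_kernel = as.integer(temporal_kernel),
         separable_kernel = as.integer(separable_kernel),
         pool = as.integer(pool), dropout_p = dropout_p,
         bn_eps = bn_eps, bn_momentum = bn_momentum),
    class = "backbone_config"
  )
}

# Output time length after the four pool stages.
backbone_out_len <- function(cfg, t_in) {
  t <- t_in
  for (i in 1:4) t <- t %/% cfg$pool
  t
}

# Final map count: the depth multiplier acts inside block 1 (D spatial
# filters per temporal map); the separable blocks' pointwise stages fix the
# map counts at F2/F3/F4. With the published D = 1 these coincide with the
# D*F notation.
backbone_out_maps <- function(cfg) cfg$F4

# Map index -> parent temporal-map index for the depthwise spatial filter
# (D filters per temporal map).
spat_parent <- function(cfg) rep(seq_len(cfg$F1), each = cfg$D)

init_backbone_params <- function(cfg) {
  m1 <- cfg$D * cfg$F1
  list(
    w_time = init_gabor_bank(cfg$temporal_kernel, cfg$F1),
    bn1_gamma = rep(1, cfg$F1), bn1_beta = rep(0, cfg$F1),
    w_spat = init_uniform(c(cfg$C, m1), cfg$C),
    bn2_gamma = rep(1, m1), bn2_beta = rep(0, m1),
    w_dw2 = init_uniform(c(cfg$separable_kernel, m1), cfg$separable_kernel),
    w_pw2 = init_uniform(c(m1, cfg$F2), m1),
    bn3_gamma = rep(1, cfg$F2), bn3_beta = rep(0, cfg$F2),
    w_dw3 = init_uniform(c(cfg$separable_kernel, cfg$F2), cfg$separable_kernel),
    w_pw3 = init_uniform(c(cfg$F2, cfg$F3), cfg$F2),
    bn4_gamma = rep(1, cfg$F3), bn4_beta = rep(0, cfg$F3),
    w_dw4 = init_uniform(c(cfg$separable_kernel, cfg$F3), cfg$separable_kernel),
    w_pw4 = init_uniform(c(cfg$F3, cfg$F4), cfg$F3),
    bn5_gamma = rep(1, cfg$F4), bn5_beta = rep(0, cfg$F4)
  )
}

init_backbone_bn_state <- function(cfg) {
  mk <- function(n) list(mean = rep(0, n), var = rep(1, n))
  m1 <- cfg$D * cfg$F1
  list(bn1 = mk(cfg$F1), bn2 = mk(m1), bn3 = mk(cfg$F2), bn4 = mk(cfg$F3),
       bn5 = mk(cfg$F4))
}

check_backbone_geometry <- function(cfg, t_in) {
  if (t_in < cfg$temporal_kernel)
    stop_geometry(sprintf(
      "block 1 temporal convolution: window of %d samples is shorter than the %d-sample kernel",
      t_in, cfg$temporal_kernel))
  t <- t_in
  for (blk in 1:4) {
    if (t < cfg$pool)
      stop_geometry(sprintf(
        "block %d pooling: time axis of %d samples cannot be pooled by %d",
        blk, t, cfg$pool))
    t <- t %/% cfg$pool
  }
  invisible(t)
}

# Forward pass over a window batch X (B, C, T'). Returns (B, D*F4, T'//81)
# features plus the cache for the backward pass. `bn_state` is an
# environment carrying the running batch-norm statistics; it is updated in
# training mode.
backbone_forward <- function(params, cfg, x, bn_state, training = FALSE) {
  d <- dim(x)
  b <- d[1]
  if (d[2] != cfg$C)
    stop_geometry(sprintf("input has %d channels but the backbone expects %d",
                          d[2], cfg$C))
  t_in <- d[3]
  check_backbone_geometry(cfg, t_in)
  cache <- list(b = b, t_in = t_in)

  cache$training <- training

  # Block 1: temporal filter bank over every (trial, electrode) row,
  # time-major layout (T, B*C) so the convolution streams contiguously
  xt <- matrix(aperm(x, c(3, 1, 2)), t_in, b * cfg$C)
  pl_time <- cfg$temporal_kernel %/% 2L
  z1 <- conv_time_fwd(xt, params$w_time, pl_time)        # (T, B*C, F1)
  cache$xt <- xt

  # fused batch norm + depthwise spatial filter (electrode axis collapses)
  m1 <- cfg$D * cfg$F1
  parent <- spat_parent(cfg)
  bs <- bnspat_fwd(z1, params$bn1_gamma, params$bn1_beta,
                   bn_state$bn1$mean, bn_state$bn1$var, training,
                   cfg$bn_momentum, cfg$bn_eps, params$w_spat,
                   as.integer(parent), b)
  if (training) bn_state$bn1 <- list(mean = as.numeric(bs$new_mean),
                                     var = as.numeric(bs$new_var))
  cache$z1 <- z1
  cache$bs_mu <- as.numeric(bs$mu)
  cache$bs_invstd <- as.numeric(bs$invstd)
  y <- bs$out                                            # (T, B, M1)

  dim(y) <- c(t_in * b, m1)
  bn2 <- bn_fwd(y, params$bn2_gamma, params$bn2_beta,
                bn_state$bn2, training, cfg$bn_momentum, cfg$bn_eps)
  if (training) bn_state$bn2 <- bn2$state
  cache$bn2 <- bn2$cache
  e1 <- elu_fwd(bn2$out)
  cache$e1 <- e1$cache
  h <- aperm(array(e1$out, dim = c(t_in, b, m1)), c(2, 3, 1))  # (B, M1, T)
  p1 <- maxpool_fwd(h, cfg$pool)
  cache$p1 <- p1$cache
  dr1 <- dropout_fwd(p1$out, cfg$dropout_p, training)
  cache$dr1 <- dr1$cache
  h <- dr1$out

  # Blocks 2-4: separable convolutions
  for (blk in 2:4) {
    dw <- params[[paste0("w_dw", blk)]]
    pw <- params[[paste0("w_pw", blk)]]
    bn_nm <- paste0("bn", blk + 1)
    cdw <- dwconv_fwd(h, dw)
    cache[[paste0("dw", blk)]] <- cdw$cache
    cpw <- pwconv_fwd(cdw$out, pw)
    cache[[paste0("pw", blk)]] <- cpw$cache
    hm <- aperm(cpw$out, c(1, 3, 2))                    # (B, T, G) for BN
    g_n <- dim(hm)[3]
    bnr <- bn_fwd(matrix(hm, ncol = g_n), params[[paste0(bn_nm, "_gamma")]],
                  params[[paste0(bn_nm, "_beta")]], bn_state[[bn_nm]],
                  training, cfg$bn_momentum, cfg$bn_eps)
    if (training) bn_state[[bn_nm]] <- bnr$state
    cache[[bn_nm]] <- bnr$cache
    el <- elu_fwd(bnr$out)
    cache[[paste0("elu", blk)]] <- el$cache
    hh <- aperm(array(el$out, dim = dim(hm)), c(1, 3, 2))  # (B, G, T)
    if (blk < 4) {
      pp <- maxpool_fwd(hh, cfg$pool)
    } else {
      pp <- meanpool_fwd(hh, cfg$pool)
    }
    cache[[paste0("pool", blk)]] <- pp$cache
    drr <- dropout_fwd(pp$out, cfg$dropout_p, training)
    cache[[paste0("drop", blk)]] <- drr$cache
    h <- drr$out
    cache[[paste0("tdim", blk)]] <- dim(hm)
  }
  list(out = h, cache = cache)
}

backbone_backward <- function(params, cfg, grad, cache) {
  b <- cache$b
  dp <- list()
  h_grad <- grad
  for (blk in 4:2) {
    bn_nm <- paste0("bn", blk + 1)
    h_grad <- dropout_bwd(h_grad, cache[[paste0("drop", blk)]])
    if (blk < 4) {
      h_grad <- maxpool_bwd(h_grad, cache[[paste0("pool", blk)]])
    } else {
      h_grad <- meanpool_bwd(h_grad, cache[[paste0("pool", blk)]])
    }
    hm_dim <- cache[[paste0("tdim", blk)]]
    gel <- matrix(aperm(h_grad, c(1, 3, 2)), ncol = hm_dim[3])
    gbn <- elu_bwd(gel, cache[[paste0("elu", blk)]])
    bnb <- bn_bwd(gbn, cache[[bn_nm]])
    dp[[paste0(bn_nm, "_gamma")]] <- bnb$dgamma
    dp[[paste0(bn_nm, "_beta")]] <- bnb$dbeta
    gpw <- aperm(array(bnb$dx, dim = hm_dim), c(1, 3, 2))  # (B, G, T)
    pwb <- pwconv_bwd(gpw, cache[[paste0("pw", blk)]])
    dp[[paste0("w_pw", blk)]] <- pwb$dp
    dwb <- dwconv_bwd(pwb$dx, cache[[paste0("dw", blk)]])
    dp[[paste0("w_dw", blk)]] <- dwb$dw
    h_grad <- dwb$dx
  }

  # Block 1
  h_grad <- dropout_bwd(h_grad, cache$dr1)
  h_grad <- maxpool_bwd(h_grad, cache$p1)                 # (B, M1, T)
  t_in <- cache$t_in
  m1 <- cfg$D * cfg$F1
  ge <- matrix(aperm(h_grad, c(3, 1, 2)), ncol = m1)      # (T*B) x M1
  gbn2 <- elu_bwd(ge, cache$e1)
  bn2b <- bn_bwd(gbn2, cache$bn2)
  dp$bn2_gamma <- bn2b$dgamma
  dp$bn2_beta <- bn2b$dbeta
  gy <- bn2b$dx
  dim(gy) <- c(t_in, b, m1)

  parent <- spat_parent(cfg)
  sb <- bnspat_bwd(cache$z1, gy, cache$bs_mu, cache$bs_invstd,
                   params$bn1_gamma, params$bn1_beta, params$w_spat,
                   as.integer(parent), b, cache$training)
  dp$w_spat <- sb$dw
  dp$bn1_gamma <- as.numeric(sb$dgamma)
  dp$bn1_beta <- as.numeric(sb$dbeta)
  pl_time <- cfg$temporal_kernel %/% 2L
  cb <- conv_time_bwd(cache$xt, sb$dz, params$w_time, pl_time, FALSE)
  dp$w_time <- cb$dW
  dp
}
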