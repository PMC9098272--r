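# Depthwise-separable backbone: geometry, determinism, parameter economy.

test_that("output shape follows the four floor-by-3 pool stages", {
  cfg <- backbone_config(C = 22)
  t <- 500
  for (p in 1:4) t <- t %/% 3
  expect_equal(t, 6L)
  expect_equal(backbone_out_len(cfg, 500), 6)
  model <- build_model(cfg, n_classes = 4, seed = 1)
  x <- array(rnorm(8 * 22 * 500), dim = c(8, 22, 500))
  bb <- backbone_forward(model$params, cfg, x, model$bn_state, training = FALSE)
  # electrode axis is collapsed by the spatial filter; maps x time remain
  expect_equal(dim(bb$out), c(8, 32, 6))
})

test_that("shape chain matches repeated floor division for random sizes", {
  set.seed(3)
  for (i in 1:20) {
    C <- sample(2:8, 1)
    t_in <- sample(81:400, 1)
    cfg <- backbone_config(C = C, F1 = 2, F2 = 2, F3 = 2, F4 = 2,
                           dropout_p = 0)
    m <- build_model(cfg, n_classes = 2, attention_dim = 2, seed = i)
    x <- array(rnorm(2 * C * t_in), dim = c(2, C, t_in))
    out <- backbone_forward(m$params, cfg, x, m$bn_state, FALSE)$out
    expect_equal(dim(out), c(2, 2, ((t_in %/% 3) %/% 3 %/% 3) %/% 3))
  }
})

test_that("evaluation-mode forward is deterministic", {
  m <- tiny_model(dropout_p = 0.25)  # dropout configured but eval-only here
  x <- array(rnorm(4 * 3 * 162), dim = c(4, 3, 162))
  p1 <- model_forward(m, x, training = FALSE)$probs
  p2 <- model_forward(m, x, training = FALSE)$probs
  expect_identical(p1, p2)
})

test_that("windows too short for the layer chain raise geometry errors", {
  cfg <- tiny_backbone_cfg()
  m <- tiny_model()
  x <- array(rnorm(2 * 3 * 40), dim = c(2, 3, 40))  # < temporal kernel
  expect_error(backbone_forward(m$params, cfg, x, m$bn_state, FALSE),
               class = "midecoder_geometry_error")
  x2 <- array(rnorm(2 * 3 * 70), dim = c(2, 3, 70))  # dies at a pool stage
  expect_error(backbone_forward(m$params, cfg, x2, m$bn_state, FALSE),
               class = "midecoder_geometry_error")
})

test_that("count_parameters enumerates trainable scalars", {
  dense <- list(w = matrix(0, 2, 3), b = numeric(2))
  expect_equal(count_parameters(dense), 8L)
  conv <- list(w = array(0, c(64, 8)))
  expect_equal(count_parameters(conv), 512L)
})

test_that("separable convolution is cheaper than its dense equivalent", {
  cfg <- backbone_config()
  # block 3: dense (1,16) convolution F2 -> F3 vs depthwise + pointwise
  dense <- cfg$separable_kernel * cfg$F2 * cfg$F3
  separable <- cfg$separable_kernel * cfg$F2 + cfg$F2 * cfg$F3
  expect_lt(separable, dense)
})
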