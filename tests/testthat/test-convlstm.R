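# Modified ConvLSTM cell, bidirectional wrapper and attention pooling.

test_that("zero parameters give the closed-form gate values", {
  m <- 4
  p <- init_convlstm_params(m, 3)
  for (nm in names(p)) p[[nm]][] <- 0
  x <- matrix(rnorm(2 * m), 2, m)
  cprev <- matrix(0.6, 2, m)
  st <- convlstm_step(x, list(H = matrix(0, 2, m), C = cprev), p)
  expect_equal(st$f, matrix(0.5, 2, m))
  expect_equal(st$i, matrix(0.5, 2, m))
  expect_equal(st$o, matrix(0.5, 2, m))
  expect_equal(st$C, 0.5 * cprev)                    # f * C + i * tanh(0)
  expect_equal(st$H, 0.5 * tanh(0.5 * cprev))
  # zero memory and zero candidate path: exact zero output
  st0 <- convlstm_step(x, list(H = matrix(0, 2, m), C = matrix(0, 2, m)), p)
  expect_true(all(st0$H == 0))
})

test_that("vectorized cell matches the scalar-loop reference", {
  set.seed(17)
  worst <- 0
  for (i in 1:100) {
    m <- sample(3:7, 1)
    p <- with_seed(i, init_convlstm_params(m, 3))
    x <- matrix(rnorm(2 * m, sd = 2), 2, m)
    h <- matrix(rnorm(2 * m), 2, m)
    cc <- matrix(rnorm(2 * m), 2, m)
    st <- convlstm_step(x, list(H = h, C = cc), p)
    ref <- convlstm_step_ref(x, h, cc, p)
    worst <- max(worst, max(abs(st$H - ref$H)), max(abs(st$C - ref$C)))
  }
  expect_lt(worst, 1e-6)
})

test_that("gates stay in (0,1) and hidden activations in (-1,1)", {
  set.seed(23)
  for (i in 1:1000) {
    m <- sample(2:6, 1)
    p <- init_convlstm_params(m, 3)
    x <- matrix(rnorm(m, sd = 3), 1, m)
    st <- convlstm_step(x, list(H = matrix(rnorm(m), 1, m),
                                C = matrix(rnorm(m), 1, m)), p)
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$H) < 1))
  }
})

test_that("sequence runs respect direction and causality", {
  set.seed(5)
  m <- 4
  p <- init_convlstm_params(m, 3)
  x <- array(rnorm(2 * m * 6), dim = c(2, m, 6))
  fwd <- run_convlstm(x, p, "forward")
  # single step: both directions identical
  x1 <- array(x[, , 1], dim = c(2, m, 1))
  expect_equal(run_convlstm(x1, p, "forward")$H_seq,
               run_convlstm(x1, p, "backward")$H_seq)
  # backward pass == forward pass on the reversed sequence, reversed
  bwd <- run_convlstm(x, p, "backward")
  xr <- x[, , 6:1, drop = FALSE]
  fwd_on_rev <- run_convlstm(xr, p, "forward")
  expect_equal(bwd$H_seq, fwd_on_rev$H_seq[, , 6:1, drop = FALSE])
  # causality: perturbing step 4 leaves steps 1-3 untouched
  x2 <- x
  x2[, , 4] <- x2[, , 4] + rnorm(2 * m)
  fwd2 <- run_convlstm(x2, p, "forward")
  expect_equal(fwd2$H_seq[, , 1:3], fwd$H_seq[, , 1:3])
  expect_false(isTRUE(all.equal(fwd2$H_seq[, , 4], fwd$H_seq[, , 4])))
  expect_error(run_convlstm(array(0, c(2, m, 0)), p),
               class = "midecoder_sequence_error")
})

test_that("bidirectional fusion concatenates hidden streams", {
  h <- array(rnorm(2 * 4 * 5), dim = c(2, 4, 5))
  fused <- bidirectional_fuse(h, h)
  expect_equal(dim(fused), c(2, 8, 5))
  expect_equal(fused[, 1:4, ], h)
  zero <- array(0, dim = dim(h))
  expect_true(all(bidirectional_fuse(h, zero)[, 5:8, ] == 0))
  expect_error(bidirectional_fuse(h, h[, , 1:3]),
               class = "midecoder_fusion_error")
})

test_that("palindromic input with shared weights mirrors the streams", {
  set.seed(9)
  m <- 3
  p <- init_convlstm_params(m, 3)
  half <- array(rnorm(1 * m * 3), dim = c(1, m, 3))
  x <- array(0, dim = c(1, m, 6))
  x[, , 1:3] <- half
  x[, , 4:6] <- half[, , 3:1]
  fwd <- run_convlstm(x, p, "forward")
  bwd <- run_convlstm(x, p, "backward")
  expect_equal(bwd$H_seq, fwd$H_seq[, , 6:1, drop = FALSE])
})

test_that("attention weights are a positive partition of unity", {
  set.seed(13)
  p <- init_attention_params(width = 4, key_dim = 3)
  # identical hidden states: uniform weights, output equals the state
  h <- matrix(rep(c(0.3, -1, 2, 0.5), each = 5), 5, 4)
  at <- attention_pool(h, p)
  expect_equal(at$weights, rep(0.2, 5))
  expect_equal(at$y, c(0.3, -1, 2, 0.5))
  # single step: weight 1, identity
  h1 <- matrix(rnorm(4), 1, 4)
  at1 <- attention_pool(h1, p)
  expect_equal(at1$weights, 1)
  expect_equal(at1$y, as.numeric(h1))
  # conservation and convex-hull property on random sequences
  for (i in 1:25) {
    hs <- matrix(rnorm(6 * 4, sd = 2), 6, 4)
    a <- attention_pool(hs, p)
    expect_equal(sum(a$weights), 1, tolerance = 1e-6)
    expect_true(all(a$weights > 0))
    expect_true(all(a$y >= apply(hs, 2, min) - 1e-12))
    expect_true(all(a$y <= apply(hs, 2, max) + 1e-12))
  }
})

test_that("attention matches brute-force evaluation with a dominant step", {
  # construct parameters that give step 2 a dominant score
  p <- list(w_w = matrix(c(1, 0, 0, 0), 1, 4), b_w = 0, z_w = 5)
  h <- rbind(c(-1, 1, 0, 0), c(1, 2, 0, 0), c(-1, 0, 1, 0))
  at <- attention_pool(h, p)
  ref <- attention_ref(h, p)
  expect_equal(at$weights, ref$a, tolerance = 1e-12)
  expect_equal(at$y, ref$y, tolerance = 1e-12)
  expect_gt(at$weights[2], 0.5)
  # and on random parameter draws
  set.seed(29)
  for (i in 1:20) {
    pp <- init_attention_params(4, 3)
    hh <- matrix(rnorm(5 * 4), 5, 4)
    aa <- attention_pool(hh, pp)
    rr <- attention_ref(hh, pp)
    expect_equal(aa$weights, rr$a, tolerance = 1e-10)
    expect_equal(aa$y, rr$y, tolerance = 1e-10)
  }
})
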