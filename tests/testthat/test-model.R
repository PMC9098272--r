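# Full model assembly: probability outputs, parameter accounting, and
# finite-difference validation of the hand-written backward pass.

test_that("assembled model emits one probability vector per window", {
  model <- build_model(backbone_config(C = 22), n_classes = 4, seed = 2)
  x <- array(rnorm(8 * 22 * 500), dim = c(8, 22, 500))
  p <- model_forward(model, x)$probs
  expect_equal(dim(p), c(8, 4))
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
  expect_true(all(p > 0))
})

test_that("the calibrated default configuration totals 17,972 parameters", {
  model <- build_model()
  expect_identical(count_parameters(model), 17972L)
  expect_identical(
    parameter_count_formula(C = 22, F1 = 8, F2 = 16, F3 = 32, F4 = 32,
                            candidate_kernel = 3, attention_dim = 26),
    17972L)
})

test_that("the closed-form count matches enumeration across configurations", {
  combos <- list(
    list(C = 5L, F = c(2L, 4L, 4L, 8L), k = 3L, a = 3L, K = 2L),
    list(C = 22L, F = c(8L, 16L, 32L, 32L), k = 3L, a = 26L, K = 4L),
    list(C = 10L, F = c(4L, 4L, 8L, 16L), k = 5L, a = 7L, K = 5L))
  for (cb in combos) {
    cfg <- backbone_config(C = cb$C, F1 = cb$F[1], F2 = cb$F[2],
                           F3 = cb$F[3], F4 = cb$F[4])
    m <- build_model(cfg, n_classes = cb$K, candidate_kernel = cb$k,
                     attention_dim = cb$a, seed = 3)
    expect_identical(count_parameters(m),
                     parameter_count_formula(
                       C = cb$C, F1 = cb$F[1], F2 = cb$F[2], F3 = cb$F[3],
                       F4 = cb$F[4], candidate_kernel = cb$k,
                       attention_dim = cb$a, n_classes = cb$K))
  }
  # ablation head
  m0 <- build_model(tiny_backbone_cfg(), n_classes = 3,
                    use_recurrent_head = FALSE, seed = 4)
  expect_identical(count_parameters(m0),
                   parameter_count_formula(
                     C = 3, F1 = 2, F2 = 2, F3 = 3, F4 = 3, n_classes = 3,
                     use_recurrent_head = FALSE))
})

test_that("disabling the recurrent head still yields valid probabilities", {
  m0 <- tiny_model(use_recurrent_head = FALSE)
  x <- array(rnorm(5 * 3 * 162), dim = c(5, 3, 162))
  p <- model_forward(m0, x)$probs
  expect_equal(dim(p), c(5, 3))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("analytic gradients match finite differences everywhere", {
  set.seed(99)
  model <- tiny_model()
  b <- 3
  x <- array(rnorm(b * 3 * 162), dim = c(b, 3, 162))
  y <- c(0L, 1L, 2L)
  res <- model_loss_grads(model, x, y, training = TRUE)
  eps <- 1e-5
  worst <- 0
  for (pp in flat_param_paths(model$params)) {
    pv <- param_get(model$params, pp)
    gv <- param_get(res$grads, pp)
    for (ix in sample(length(pv), min(3, length(pv)))) {
      m2 <- model
      pv2 <- pv
      pv2[ix] <- pv[ix] + eps
      m2$params <- param_set(model$params, pp, pv2)
      lp <- model_loss_grads(m2, x, y, training = TRUE)$loss
      pv2[ix] <- pv[ix] - eps
      m2$params <- param_set(model$params, pp, pv2)
      lm <- model_loss_grads(m2, x, y, training = TRUE)$loss
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - gv[ix]) /
                     max(1e-6, abs(num) + abs(gv[ix])))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("averaged-probability loss gradients also verify", {
  set.seed(77)
  model <- tiny_model()
  x <- array(rnorm(4 * 3 * 162), dim = c(4, 3, 162))
  y <- c(0L, 0L, 2L, 2L)
  tr <- c(1L, 1L, 2L, 2L)
  res <- model_loss_grads(model, x, y, loss_mode = "averaged_prob",
                          trial_index = tr, training = TRUE)
  eps <- 1e-5
  worst <- 0
  for (pp in list(c("w_cls"), c("attn", "z_w"), c("lstm_f", "w_xc"),
                  c("w_time"), c("bn3_gamma"))) {
    pv <- param_get(model$params, pp)
    gv <- param_get(res$grads, pp)
    for (ix in sample(length(pv), min(3, length(pv)))) {
      m2 <- model
      pv2 <- pv
      pv2[ix] <- pv[ix] + eps
      m2$params <- param_set(model$params, pp, pv2)
      lp <- model_loss_grads(m2, x, y, loss_mode = "averaged_prob",
                             trial_index = tr, training = TRUE)$loss
      pv2[ix] <- pv[ix] - eps
      m2$params <- param_set(model$params, pp, pv2)
      lm <- model_loss_grads(m2, x, y, loss_mode = "averaged_prob",
                             trial_index = tr, training = TRUE)$loss
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - gv[ix]) /
                     max(1e-6, abs(num) + abs(gv[ix])))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("model summary accounts for every parameter", {
  model <- build_model()
  tb <- summary(model, t_in = 500)
  expect_s3_class(tb, "tbl_df")
  expect_equal(sum(tb$parameters), 17972L)
})

test_that("model checkpoints round-trip with configuration embedded", {
  m <- tiny_model(seed = 12)
  x <- array(rnorm(3 * 3 * 162), dim = c(3, 3, 162))
  p1 <- predict(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, x), p1)
  expect_identical(count_parameters(m2), count_parameters(m))
  expect_error(load_model("nope.rds"), class = "midecoder_io_error")
})
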