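# Sliding-window cropping and trial-level prediction aggregation.

test_that("count_windows matches the closed form and the printed default", {
  expect_equal(count_windows(crop_spec()), 625L)
  expect_equal(count_windows(crop_spec(start_min_s = 1, start_max_s = 1)), 1L)
  # half-open half-second start range at 100 Hz: starts 0..49
  expect_equal(count_windows(crop_spec(window_len_s = 1, start_min_s = 0,
                                       start_max_s = 0.5, fs = 100)), 50L)
  # stride 50 over the default 625-sample range: starts 0, 50, ..., 600
  expect_equal(count_windows(crop_spec(stride_samples = 50L)), 13L)
})

test_that("count_windows agrees with brute-force start enumeration", {
  set.seed(42)
  for (i in 1:50) {
    fs <- sample(c(100, 128, 250, 500), 1)
    smin <- round(runif(1, -0.5, 0.5), 2)
    rng <- round(runif(1, 0, 2.5), 2)
    stride <- sample(1:40, 1)
    spec <- crop_spec(window_len_s = 1, start_min_s = smin,
                      start_max_s = smin + rng, stride_samples = stride,
                      fs = fs)
    # enumerate start-sample offsets in the half-open range directly
    span <- (smin + rng - smin) * fs
    k <- 0; n_ref <- 0
    while (k < span) { n_ref <- n_ref + 1; k <- k + stride }
    n_ref <- max(1, n_ref)
    expect_equal(count_windows(spec), as.integer(n_ref))
  }
})

test_that("crop_windows reproduces direct trial slices", {
  ds <- generate_dataset(synthetic_spec(n_trials = 2, n_channels = 4,
                                        seed = 9))
  wb <- crop_windows(ds, crop_spec())
  expect_s3_class(wb, "window_batch")
  expect_equal(dim(wb$windows), c(1250, 4, 500))  # 2 x 625 windows of 2 s
  expect_equal(wb$windows_per_trial, 625L)
  expect_equal(wb$labels, rep(ds$labels, each = 625))
  set.seed(7)
  for (i in sample(1250, 12)) {
    tr <- wb$trial_index[i]
    j <- wb$window_index[i]
    s0 <- (j - 1)  # base start is sample 0 for the default geometry
    expect_identical(wb$windows[i, , ],
                     ds$trials[tr, , (s0 + 1):(s0 + 500)])
  }
})

test_that("stride equal to the start range yields the single -0.5 s crop", {
  ds <- generate_dataset(synthetic_spec(n_trials = 2, n_channels = 4,
                                        seed = 9))
  wb <- crop_windows(ds, crop_spec(stride_samples = 625L))
  expect_equal(dim(wb$windows)[1], 2L)
  expect_identical(wb$windows[1, , ], ds$trials[1, , 1:500])
})

test_that("constant trials produce constant windows", {
  arr <- array(7, dim = c(1, 2, 1125))
  ds <- trial_dataset(arr, 0L, fs = 250, n_classes = 1)
  wb <- crop_windows(ds, crop_spec(stride_samples = 125L))
  expect_true(all(wb$windows == 7))
})

test_that("windows exceeding the trial signal a geometry error", {
  arr <- array(0, dim = c(1, 2, 800))  # too short for start_max 2 s
  ds <- trial_dataset(arr, 0L, fs = 250, n_classes = 1)
  expect_error(crop_windows(ds, crop_spec()),
               class = "midecoder_geometry_error")
  expect_error(crop_windows(ds, crop_spec(fs = 100)),
               "fs", class = "midecoder_config_error")
})

test_that("trial probabilities are the window mean and order-invariant", {
  p <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(aggregate_window_predictions(p), c(0.5, 0.5, 0, 0))
  same <- matrix(rep(c(0.1, 0.2, 0.3, 0.4), each = 5), 5)
  expect_equal(aggregate_window_predictions(same), c(0.1, 0.2, 0.3, 0.4))
  set.seed(11)
  for (i in 1:20) {
    w <- matrix(rexp(6 * 4), 6)
    w <- w / rowSums(w)
    agg <- aggregate_window_predictions(w)
    expect_equal(sum(agg), 1, tolerance = 1e-12)
    expect_true(all(agg >= 0))
    perm <- w[sample(nrow(w)), ]
    expect_equal(aggregate_window_predictions(perm), agg)
  }
  expect_error(aggregate_window_predictions(matrix(numeric(0), 0, 4)),
               class = "midecoder_aggregation_error")
  expect_error(aggregate_window_predictions(rbind(c(0.5, 0.4, 0, 0))),
               class = "midecoder_validation_error")
})
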