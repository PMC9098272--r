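# Synthetic ERD/ERS generator: balance, determinism, spectral structure.

test_that("generated datasets are balanced, labeled 0..K-1 and reproducible", {
  spec <- synthetic_spec(n_trials = 8, n_classes = 4, n_channels = 6,
                         seed = 7)
  ds <- generate_dataset(spec)
  expect_s3_class(ds, "trial_dataset")
  expect_equal(dim(ds$trials), c(8, 6, 1125))
  expect_equal(as.integer(table(ds$labels)), rep(2L, 4))
  expect_setequal(unique(ds$labels), 0:3)
  # bit-identical regeneration from the same spec
  expect_identical(generate_dataset(spec)$trials, ds$trials)
  # a different seed changes the samples
  spec2 <- synthetic_spec(n_trials = 8, n_classes = 4, n_channels = 6,
                          seed = 8)
  expect_false(identical(generate_dataset(spec2)$trials, ds$trials))
})

test_that("invalid generator specs name the offending field", {
  expect_error(synthetic_spec(n_trials = 10, erd_depth = 1.4),
               "erd_depth", class = "midecoder_config_error")
  expect_error(synthetic_spec(n_trials = 10, fs = 250,
                              trial_duration_s = 4.501),
               "integer sample count", class = "midecoder_config_error")
  expect_error(
    synthetic_spec(n_trials = 10, n_channels = 4,
                   class_topographies = list(1:2, integer(0), 3, 4)),
    "class_topographies", class = "midecoder_config_error")
  expect_error(
    synthetic_spec(n_trials = 10, n_channels = 4,
                   class_topographies = rep(list(1:2), 4)),
    "identical", class = "midecoder_config_error")
})

test_that("erd_depth = 0 leaves post/pre band power flat everywhere", {
  spec <- synthetic_spec(n_trials = 80, erd_depth = 0, n_channels = 8,
                         noise_sd = 0.5, seed = 13)
  ds <- generate_dataset(spec)
  # the 0.5-s baseline gives the pooled estimator ~10% relative error at
  # 20 trials x 2 channels per class; bound at roughly 2.5 sigma
  for (k in 0:3) {
    att <- erd_attenuation(subset_trials(ds, which(ds$labels == k)),
                           spec$class_topographies[[k + 1]],
                           spec$bands[[k + 1]])
    expect_gt(att, 0.75)
    expect_lt(att, 1.3)
  }
})

test_that("Welch band power recovers the configured ERD attenuation", {
  # erd_depth 0.8 with weak noise: post/pre band power on each class's own
  # channels and band should be 1 - 0.8 = 0.2 within +/- 0.05
  spec <- synthetic_spec(n_trials = 200, erd_depth = 0.8, noise_sd = 0.5,
                         seed = 3)
  ds <- generate_dataset(spec)
  for (k in 0:3) {
    att <- erd_attenuation(subset_trials(ds, which(ds$labels == k)),
                           spec$class_topographies[[k + 1]],
                           spec$bands[[k + 1]])
    expect_gt(att, 0.15)
    expect_lt(att, 0.25)
  }
  # no attenuation on another class's topography/band
  att_off <- erd_attenuation(subset_trials(ds, which(ds$labels == 0)),
                             spec$class_topographies[[4]], spec$bands[[4]])
  expect_gt(att_off, 0.85)
  expect_lt(att_off, 1.15)
})

test_that("class separability is monotone in erd_depth and chance at zero", {
  accs <- vapply(c(0, 0.45, 0.9), function(d) {
    spec <- synthetic_spec(n_trials = 200, erd_depth = d, noise_sd = 0.5,
                           n_channels = 8, seed = 31)
    ds <- generate_dataset(spec)
    pred <- bandpower_rule_classify(ds, spec$class_topographies, spec$bands)
    mean(pred == ds$labels)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  # erd_depth 0: within binomial noise of chance 1/4 (3.5 sigma, n = 200)
  expect_lt(abs(accs[1] - 0.25), 3.5 * sqrt(0.25 * 0.75 / 200))
  expect_gt(accs[3], 0.8)
})

test_that("default topographies are disjoint lateralized blocks", {
  topo <- default_topographies(22, 4)
  expect_length(topo, 4)
  expect_equal(sort(unlist(topo)), 1:22)
  # left hand maps to a later (right-hemisphere) block than right hand
  expect_gt(min(topo[[1]]), max(topo[[2]]))
})
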