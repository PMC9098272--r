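# Cross-validation splitting, training loop, and trial-level evaluation.

test_that("stratified 4-fold rotations partition trials 2/1/1", {
  arr <- array(rnorm(288 * 2 * 120), dim = c(288, 2, 120))
  ds <- trial_dataset(arr, rep(0:3, each = 72), fs = 100)
  sp <- kfold_split(ds, seed = 4)
  expect_length(sp$groups, 4)
  for (g in sp$groups) {
    expect_length(g, 72)
    expect_equal(as.integer(table(ds$labels[g])), rep(18L, 4))
  }
  tests <- lapply(sp$rotations, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:288)     # coverage, exactly once
  for (rot in sp$rotations) {
    expect_length(intersect(rot$train, rot$test), 0)
    expect_length(intersect(rot$train, rot$val), 0)
    expect_length(intersect(rot$val, rot$test), 0)
    expect_length(c(rot$train, rot$val, rot$test), 288)
  }
  expect_identical(kfold_split(ds, seed = 4), sp)
  expect_false(identical(kfold_split(ds, seed = 5)$groups, sp$groups))
})

test_that("too few trials per class is a split error", {
  arr <- array(0, dim = c(8, 2, 120))
  ds <- trial_dataset(arr, c(rep(0L, 5), 1L, 2L, 3L), fs = 100)
  expect_error(kfold_split(ds), class = "midecoder_split_error")
})

test_that("an uninformative model scores at chance on balanced trials", {
  ds <- tiny_train_dataset(n_trials = 60, erd_depth = 0)
  model <- tiny_model(C = 4, n_classes = 4)
  ev <- evaluate(model, ds, tiny_crop_spec())
  expect_equal(sum(ev$confusion), 60)
  expect_equal(as.integer(rowSums(ev$confusion)), as.integer(table(ds$labels)))
  expect_lt(abs(ev$accuracy - 0.25), 3.5 * sqrt(0.25 * 0.75 / 60))
})

test_that("a biased constant model shows a single confusion diagonal", {
  model <- tiny_model(C = 4, n_classes = 4)
  model$params$w_cls[] <- 0
  model$params$b_cls <- c(0, 5, 0, 0)  # always predicts class 1
  arr <- array(rnorm(1 * 4 * 450), dim = c(1, 4, 450))
  ds <- trial_dataset(arr, 1L, fs = 100, n_classes = 4)
  ev <- evaluate(model, ds, tiny_crop_spec())
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$confusion["1", "1"], 1L)
  expect_equal(sum(ev$confusion), 1L)
})

test_that("60/40 window probability splits decode to the majority class", {
  probs <- rbind(matrix(rep(c(1, 0, 0, 0), 6), 6, byrow = TRUE),
                 matrix(rep(c(0, 1, 0, 0), 4), 4, byrow = TRUE))
  agg <- aggregate_window_predictions(probs)
  expect_equal(agg, c(0.6, 0.4, 0, 0))
  expect_equal(which.max(agg), 1L)
})

test_that("training improves a separable problem and is reproducible", {
  ds <- tiny_train_dataset(n_trials = 24)
  sp <- kfold_split(ds, seed = 1)
  rot <- sp$rotations[[1]]
  spec <- tiny_crop_spec()
  cfg <- train_config(learning_rate = 3e-3, batch_size = 16,
                      max_epochs = 3, early_stop_patience = 3, seed = 2)
  fit <- train(tiny_model(C = 4, n_classes = 4),
               subset_trials(ds, rot$train), subset_trials(ds, rot$val),
               spec, cfg)
  expect_s3_class(fit$history, "tbl_df")
  expect_equal(nrow(fit$history), 3)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_lt(fit$history$train_loss[3], fit$history$train_loss[1])
  # early stopping restored the best-validation weights
  ev <- evaluate(fit$model, subset_trials(ds, rot$val), spec)
  expect_equal(ev$accuracy, max(fit$history$val_accuracy))
  # identical seed: identical epoch-by-epoch loss series
  fit2 <- train(tiny_model(C = 4, n_classes = 4),
                subset_trials(ds, rot$train), subset_trials(ds, rot$val),
                spec, cfg)
  expect_identical(fit2$history$train_loss, fit$history$train_loss)
  expect_identical(fit2$history$val_accuracy, fit$history$val_accuracy)
})

test_that("label permutation collapses accuracy to chance", {
  ds <- tiny_train_dataset(n_trials = 40)
  model <- tiny_model(C = 4, n_classes = 4)
  perm <- ds
  perm$labels <- with_seed(6, sample(ds$labels))
  ev <- evaluate(model, perm, tiny_crop_spec())
  expect_lt(abs(ev$accuracy - 0.25), 3.5 * sqrt(0.25 * 0.75 / 40))
})

test_that("run_experiment aggregates folds and writes a reproducible report", {
  ds <- tiny_train_dataset(n_trials = 16)
  spec <- tiny_crop_spec()
  cfg <- train_config(learning_rate = 3e-3, batch_size = 16, max_epochs = 2,
                      early_stop_patience = 2, seed = 3)
  out <- withr::local_tempdir()
  res <- run_experiment(
    ds, spec, cfg,
    model_args = list(backbone_cfg = tiny_backbone_cfg(C = 4,
                                                       dropout_p = 0.25)),
    out_dir = out)
  expect_s3_class(res, "mi_experiment")
  expect_equal(nrow(res$per_fold), 4)
  expect_equal(res$mean_accuracy, mean(res$per_fold$accuracy))
  expect_equal(sum(res$confusion), 16)  # every trial tested exactly once
  expect_true(file.exists(file.path(out, "report.csv")))
  expect_true(file.exists(file.path(out, "history.csv")))
  expect_true(file.exists(file.path(out, "report.txt")))
  # rerun with the same config: identical report
  res2 <- run_experiment(
    ds, spec, cfg,
    model_args = list(backbone_cfg = tiny_backbone_cfg(C = 4,
                                                       dropout_p = 0.25)))
  expect_identical(res2$per_fold$accuracy, res$per_fold$accuracy)
  expect_identical(res2$confusion, res$confusion)
  # tidy accessors
  expect_identical(tidy(res), res$per_fold)
  expect_equal(glance(res)$mean_accuracy, res$mean_accuracy)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_confusion(res), "ggplot")
})

test_that("ablation and full configurations run under the same harness", {
  ds <- tiny_train_dataset(n_trials = 16)
  spec <- tiny_crop_spec()
  cfg <- train_config(learning_rate = 3e-3, batch_size = 16, max_epochs = 1,
                      early_stop_patience = 1, seed = 9)
  full <- run_experiment(ds, spec, cfg,
                         model_args = list(backbone_cfg = tiny_backbone_cfg(C = 4)))
  bare <- run_experiment(ds, spec, cfg,
                         model_args = list(backbone_cfg = tiny_backbone_cfg(C = 4),
                                           use_recurrent_head = FALSE))
  expect_equal(nrow(full$per_fold), 4)
  expect_equal(nrow(bare$per_fold), 4)
  expect_gt(count_parameters(full$models[[1]]),
            count_parameters(bare$models[[1]]))
})
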