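#' Training configuration
#'
#' Adam on window-level cross-entropy. The published protocol fixes the
#' optimizer (Adam), the loss (cross-entropy), and 4-fold cross-validation;
#' learning rate, batch size, epoch budget and early stopping are
#' unpublished tunables fixed here and exposed as configuration.
#'
#' @param learning_rate Adam step size.
#' @param batch_size windows per minibatch (source trials per minibatch for
#'   `loss_mode = "averaged_prob"`).
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation trial-accuracy
#'   improvement before stopping; the best-validation weights are restored.
#' @param seed RNG seed for shuffling, dropout and weight initialization.
#' @param loss_mode `"per_window"` (each crop an independent example) or
#'   `"averaged_prob"` (cross-entropy of the trial-averaged probability).
#' @param fold_count cross-validation folds; the protocol fixes 4.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 100L, early_stop_patience = 15L,
                         seed = 1L, loss_mode = c("per_window", "averaged_prob"),
                         fold_count = 4L) {
  if (!is_number(learning_rate) || learning_rate <= 0)
    stop_config("`learning_rate` must be positive")
  if (!is_count(batch_size)) stop_config("`batch_size` must be a positive integer")
  if (!is_count(max_epochs)) stop_config("`max_epochs` must be a positive integer")
  if (!is_count(early_stop_patience))
    stop_config("`early_stop_patience` must be a positive integer")
  if (fold_count != 4L) stop_config("`fold_count` is fixed at 4 by the protocol")
  loss_mode <- match.arg(loss_mode)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         seed = as.integer(seed), loss_mode = loss_mode, fold_count = 4L),
    class = "train_config"
  )
}

#' Class-stratified 4-fold split with train/validation/test rotations
#'
#' Trials are partitioned into 4 class-stratified disjoint groups; rotation
#' `i` uses groups `(i, i+1)` for training, `(i+2)` for validation and
#' `(i+3)` for testing (mod 4), so every trial is tested exactly once
#' across the four rotations.
#'
#' @param ds a [trial_dataset()].
#' @param seed RNG seed for the within-class shuffles.
#' @return list with `groups` (4 integer vectors) and `rotations` (4 lists
#'   with `train`, `val`, `test` index vectors).
#' @export
kfold_split <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "trial_dataset"))
  n <- dim(ds$trials)[1]
  if (n < 8) mid_stop("need at least 8 trials for a 2/1/1 4-fold split",
                      "midecoder_split_error")
  counts <- table(factor(ds$labels, levels = 0:(ds$n_classes - 1)))
  if (any(counts < 4))
    mid_stop(sprintf(
      "every class needs >= 4 trials for stratified 4-fold splitting (class %s has %d)",
      names(counts)[which.min(counts)], min(counts)),
      "midecoder_split_error")
  groups <- vector("list", 4L)
  with_seed(seed, {
    for (k in 0:(ds$n_classes - 1)) {
      idx <- sample(which(ds$labels == k))
      for (g in 1:4) {
        take <- idx[seq(g, length(idx), by = 4)]
        groups[[g]] <- c(groups[[g]], take)
      }
    }
  })
  groups <- lapply(groups, sort)
  rotations <- lapply(1:4, function(i) {
    g <- function(j) groups[[((i - 1 + j) %% 4) + 1]]
    list(train = sort(c(g(0), g(1))), val = g(2), test = g(3))
  })
  list(groups = groups, rotations = rotations)
}

# Elementwise Adam over the nested parameter list.
adam_init <- function(params) {
  zeros_like <- function(p) {
    if (is.list(p)) lapply(p, zeros_like)
    else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
    else if (is.array(p)) array(0, dim = dim(p))
    else numeric(length(p))
  }
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- purrr::pmap(list(p, g, m, v), step)
      return(list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  res <- step(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

#' Train the decoder on cropped windows
#'
#' Optimizes window-level cross-entropy with Adam under the configured loss
#' mode. After every epoch the validation trial accuracy (window
#' probabilities averaged per trial, argmax) is recorded; training stops
#' early when it has not improved for `early_stop_patience` epochs, and the
#' best-validation weights are restored. Fully reproducible under a fixed
#' config seed.
#'
#' @param model a `dsc_convlstm` from [build_model()].
#' @param train_ds,val_ds disjoint [trial_dataset()]s.
#' @param spec a [crop_spec()].
#' @param cfg a [train_config()].
#' @return list with `model` (best weights), `history` (tibble with epoch,
#'   train_loss, val_accuracy) and `best_epoch`.
#' @export
train <- function(model, train_ds, val_ds, spec, cfg) {
  stopifnot(inherits(model, "dsc_convlstm"), inherits(cfg, "train_config"))
  wb <- crop_windows(train_ds, spec)
  val_wb <- crop_windows(val_ds, spec)
  n_win <- dim(wb$windows)[1]
  opt <- adam_init(model$params)
  history <- vector("list", cfg$max_epochs)
  best <- list(acc = -Inf, params = model$params,
               bn = as.list(model$bn_state), epoch = 0L)
  stale <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      if (cfg$loss_mode == "per_window") {
        order_ <- sample.int(n_win)
        starts <- seq(1L, n_win, by = cfg$batch_size)
        batches <- lapply(starts, function(s)
          order_[s:min(s + cfg$batch_size - 1L, n_win)])
      } else {
        # keep each trial's windows together; batch_size counts trials
        tr_order <- sample.int(wb$n_trials)
        starts <- seq(1L, wb$n_trials, by = cfg$batch_size)
        batches <- lapply(starts, function(s) {
          trs <- tr_order[s:min(s + cfg$batch_size - 1L, wb$n_trials)]
          which(wb$trial_index %in% trs)
        })
      }
      ep_loss <- 0
      for (bi in batches) {
        res <- model_loss_grads(model, wb$windows[bi, , , drop = FALSE],
                                wb$labels[bi], loss_mode = cfg$loss_mode,
                                trial_index = wb$trial_index[bi],
                                training = TRUE)
        if (!is.finite(res$loss))
          mid_stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
                   "midecoder_divergence_error")
        upd <- adam_update(model$params, res$grads[names(model$params)],
                           opt, cfg$learning_rate)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + res$loss * length(bi)
      }
      ep_loss <- ep_loss / n_win
      val <- evaluate(model, val_ds, spec, windows = val_wb)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss, val_accuracy = val$accuracy)
      if (val$accuracy > best$acc) {
        best <- list(acc = val$accuracy, params = model$params,
                     bn = as.list(model$bn_state), epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (stale >= cfg$early_stop_patience) break
    }
  })
  model$params <- best$params
  for (nm in names(best$bn)) model$bn_state[[nm]] <- best$bn[[nm]]
  list(model = model, history = dplyr::bind_rows(history),
       best_epoch = best$epoch)
}

#' Evaluate the decoder on held-out trials
#'
#' Each trial is decoded as the argmax of the mean of its windows' softmax
#' probabilities ([aggregate_window_predictions()]).
#'
#' @param model a fitted `dsc_convlstm`.
#' @param ds a [trial_dataset()] of held-out trials.
#' @param spec a [crop_spec()].
#' @param windows optional precomputed [crop_windows()] batch for `ds`.
#' @return list with `accuracy`, `confusion` (K x K count matrix, true class
#'   in rows) and `predictions` (tibble: trial, label, predicted, plus one
#'   probability column per class).
#' @export
evaluate <- function(model, ds, spec, windows = NULL) {
  stopifnot(inherits(model, "dsc_convlstm"), inherits(ds, "trial_dataset"))
  if (ds$n_classes > model$n_classes)
    mid_stop(sprintf("dataset has %d classes but the model outputs %d",
                     ds$n_classes, model$n_classes), "midecoder_label_error")
  if (is.null(windows)) windows <- crop_windows(ds, spec)
  probs <- predict(model, windows$windows)
  trial_probs <- rowsum(probs, windows$trial_index) / windows$windows_per_trial
  pred <- max.col(trial_probs, ties.method = "first") - 1L
  labels <- ds$labels
  k <- model$n_classes
  confusion <- table(factor(labels, levels = 0:(k - 1)),
                     factor(pred, levels = 0:(k - 1)))
  confusion <- matrix(as.integer(confusion), k, k,
                      dimnames = list(true = 0:(k - 1), predicted = 0:(k - 1)))
  ptb <- tibble::as_tibble(as.data.frame(trial_probs))
  names(ptb) <- sprintf("p%d", 0:(k - 1))
  list(accuracy = mean(pred == labels), confusion = confusion,
       predictions = dplyr::bind_cols(
         tibble::tibble(trial = seq_along(labels), label = labels,
                        predicted = pred), ptb))
}

#' Run the full 4-fold cross-validation experiment
#'
#' Orchestrates the protocol end to end: stratified [kfold_split()], one
#' freshly initialized model trained per rotation, held-out evaluation with
#' trial-level prediction averaging, and aggregation into a report.
#'
#' @param ds a [trial_dataset()].
#' @param spec a [crop_spec()].
#' @param cfg a [train_config()].
#' @param model_args list of arguments passed to [build_model()]
#'   (`backbone_cfg` defaults to the calibrated architecture sized to the
#'   dataset's channel count).
#' @param out_dir optional directory; when given, the fold report and
#'   training history are written there as `report.csv`, `history.csv` and
#'   a plain-text summary `report.txt`.
#' @return an object of class `mi_experiment`: list with `per_fold`
#'   (tibble), `mean_accuracy`, `confusion` (summed over folds),
#'   `histories`, `split`, and the configs.
#' @export
run_experiment <- function(ds, spec = crop_spec(fs = ds$fs),
                           cfg = train_config(), model_args = list(),
                           out_dir = NULL) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (is.null(model_args$backbone_cfg)) {
    arch <- default_architecture(C = dim(ds$trials)[2])
    model_args$backbone_cfg <- arch$backbone_cfg
    if (is.null(model_args$candidate_kernel))
      model_args$candidate_kernel <- arch$candidate_kernel
    if (is.null(model_args$attention_dim))
      model_args$attention_dim <- arch$attention_dim
  }
  if (is.null(model_args$n_classes)) model_args$n_classes <- ds$n_classes
  split <- kfold_split(ds, seed = cfg$seed)
  k <- model_args$n_classes
  confusion <- matrix(0L, k, k, dimnames = list(true = 0:(k - 1),
                                                predicted = 0:(k - 1)))
  per_fold <- vector("list", 4L)
  histories <- vector("list", 4L)
  models <- vector("list", 4L)
  for (i in 1:4) {
    rot <- split$rotations[[i]]
    model <- do.call(build_model, c(model_args, list(seed = cfg$seed + i)))
    fit <- train(model, subset_trials(ds, rot$train),
                 subset_trials(ds, rot$val), spec, cfg)
    ev <- evaluate(fit$model, subset_trials(ds, rot$test), spec)
    per_fold[[i]] <- tibble::tibble(
      fold = i, n_train = length(rot$train), n_val = length(rot$val),
      n_test = length(rot$test), best_epoch = fit$best_epoch,
      accuracy = ev$accuracy)
    confusion <- confusion + ev$confusion
    histories[[i]] <- dplyr::mutate(fit$history, fold = i)
    models[[i]] <- fit$model
  }
  per_fold <- dplyr::bind_rows(per_fold)
  res <- structure(
    list(per_fold = per_fold, mean_accuracy = mean(per_fold$accuracy),
         confusion = confusion, histories = dplyr::bind_rows(histories),
         split = split, crop_spec = spec, train_config = cfg,
         model_args = model_args, models = models,
         n_trials = dim(ds$trials)[1]),
    class = "mi_experiment")
  if (!is.null(out_dir)) write_experiment_report(res, out_dir)
  res
}

#' @export
print.mi_experiment <- function(x, ...) {
  cat(sprintf("<mi_experiment> 4-fold CV over %d trials\n", x$n_trials))
  cat(sprintf("  per-fold accuracy: %s\n",
              paste(sprintf("%.3f", x$per_fold$accuracy), collapse = " ")))
  cat(sprintf("  mean accuracy: %.3f\n", x$mean_accuracy))
  invisible(x)
}

write_experiment_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$per_fold, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$histories, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines(sprintf("[%s] 4-fold cross-validation, %d trials",
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S"), res$n_trials), con)
  writeLines(sprintf("seed: %d, loss_mode: %s, lr: %g, batch: %d",
                     res$train_config$seed, res$train_config$loss_mode,
                     res$train_config$learning_rate,
                     res$train_config$batch_size), con)
  writeLines(sprintf("fold %d accuracy %.4f (best epoch %d)",
                     res$per_fold$fold, res$per_fold$accuracy,
                     res$per_fold$best_epoch), con)
  writeLines(sprintf("mean accuracy %.4f", res$mean_accuracy), con)
  writeLines("confusion (true rows):", con)
  utils::write.table(res$confusion, con, col.names = FALSE)
  invisible(out_dir)
}
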