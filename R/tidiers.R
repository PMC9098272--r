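#' Tidy a cross-validation experiment
#'
#' @param x an `mi_experiment` from [run_experiment()].
#' @param ... unused.
#' @return one row per fold: fold, n_train, n_val, n_test, best_epoch,
#'   accuracy.
#' @export
tidy.mi_experiment <- function(x, ...) x$per_fold

#' One-row experiment summary
#'
#' @param x an `mi_experiment`.
#' @param ... unused.
#' @return tibble with n_trials, folds, mean_accuracy, sd_accuracy,
#'   min_accuracy, max_accuracy.
#' @export
glance.mi_experiment <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials, folds = nrow(x$per_fold),
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = stats::sd(x$per_fold$accuracy),
    min_accuracy = min(x$per_fold$accuracy),
    max_accuracy = max(x$per_fold$accuracy))
}

#' Training-history curves
#'
#' Loss and validation trial-accuracy per epoch, one panel pair per fold.
#'
#' @param object an `mi_experiment`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mi_experiment <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(object$histories,
                                   c("train_loss", "val_accuracy"),
                                   names_to = "series")
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(colour = "fold", y = NULL,
                  title = "Cross-validation training curves")
}

#' Confusion-matrix heat map
#'
#' @param x an `mi_experiment` or a K x K confusion count matrix.
#' @return a ggplot object.
#' @export
plot_confusion <- function(x) {
  cm <- if (inherits(x, "mi_experiment")) x$confusion else x
  df <- tibble::as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Trial-level confusion (all test folds)")
}

#' @importFrom ggplot2 .data
NULL
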