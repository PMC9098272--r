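#' Labeled multichannel EEG trial container
#'
#' The package-wide data model: an `[N, C, T_full]` array of samples in
#' microvolts plus per-trial integer class labels and sampling metadata.
#' Sample index `s` (1-based) maps to cue-relative time
#' `t0_offset_s + (s - 1) / fs`; all window arithmetic is cue-relative and
#' half-open `[start, start + len)`.
#'
#' @param trials numeric array `[N, C, T_full]` (trials x channels x samples).
#' @param labels integer vector of length `N` with values in `0 .. K - 1`.
#' @param fs sampling rate in Hz.
#' @param t0_offset_s cue-relative time of sample 1 (default -0.5).
#' @param channel_names optional character vector of length `C`.
#' @param subject_id identifier string.
#' @param n_classes number of classes `K`; defaults to `max(labels) + 1`.
#' @return an object of class `trial_dataset`.
#' @export
trial_dataset <- function(trials, labels, fs, t0_offset_s = -0.5,
                          channel_names = NULL, subject_id = "S00",
                          n_classes = NULL) {
  if (!is.array(trials) || length(dim(trials)) != 3)
    stop_validation("`trials` must be a 3-D array [N, C, T_full]")
  d <- dim(trials)
  if (length(labels) != d[1])
    stop_validation(sprintf("length(labels) == %d but dataset has %d trials",
                            length(labels), d[1]))
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0))
    stop_validation("`labels` must be nonnegative integers (0-based classes)")
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (any(labels >= n_classes))
    stop_validation("all labels must lie in 0 .. n_classes - 1")
  if (!is_number(fs) || fs <= 0) stop_validation("`fs` must be a positive number")
  if (anyNA(trials) || any(!is.finite(trials)))
    stop_validation("`trials` contains NaN or infinite samples")
  if (is.null(channel_names))
    channel_names <- sprintf("EEG%02d", seq_len(d[2]))
  if (length(channel_names) != d[2])
    stop_validation("`channel_names` must have one entry per channel")
  structure(
    list(trials = trials, labels = labels, fs = fs,
         t0_offset_s = t0_offset_s,
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id),
         n_classes = n_classes),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<trial_dataset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  subject: %s, classes: %d, t0 offset: %g s\n",
              x$subject_id, x$n_classes, x$t0_offset_s))
  cat("  label counts:", paste(sprintf("%d:%d", as.integer(names(table(x$labels))),
                                       as.integer(table(x$labels))), collapse = " "), "\n")
  invisible(x)
}

#' Save / load a trial dataset
#'
#' Round-trip is bit-exact on samples and field-for-field on metadata. The
#' on-disk container is a single self-contained RDS file.
#'
#' @param ds a [trial_dataset()].
#' @param path file path.
#' @return `load_dataset` returns the validated [trial_dataset()];
#'   `save_dataset` returns `path` invisibly.
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "trial_dataset"))
  saveRDS(unclass(ds), path, version = 3)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such dataset file: %s", path))
  obj <- tryCatch(readRDS(path), error = function(e)
    stop_io(sprintf("corrupt or unreadable dataset container: %s", path)))
  if (!is.list(obj) || is.null(obj$trials) || is.null(obj$labels))
    stop_io(sprintf("file is not a trial_dataset container: %s", path))
  # revalidate: a tampered container must fail loudly
  trial_dataset(obj$trials, obj$labels, fs = obj$fs,
                t0_offset_s = obj$t0_offset_s,
                channel_names = obj$channel_names,
                subject_id = obj$subject_id,
                n_classes = obj$n_classes)
}

#' Subset a trial dataset by trial index
#' @param ds a [trial_dataset()].
#' @param idx integer trial indices (1-based).
#' @return a [trial_dataset()] with the selected trials.
#' @export
subset_trials <- function(ds, idx) {
  stopifnot(inherits(ds, "trial_dataset"))
  trial_dataset(ds$trials[idx, , , drop = FALSE], ds$labels[idx],
                fs = ds$fs, t0_offset_s = ds$t0_offset_s,
                channel_names = ds$channel_names,
                subject_id = ds$subject_id, n_classes = ds$n_classes)
}
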