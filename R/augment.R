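#' Sliding-window crop specification
#'
#' Defines the cropped-training geometry: fixed-length windows slid across
#' each trial from `start_min_s` to `start_max_s` (cue-relative start times)
#' in steps of `stride_samples`. With the defaults (2-s windows starting
#' between -0.5 s and 2 s at 250 Hz, stride 1 sample) each trial yields 625
#' crops.
#'
#' @param window_len_s window length in seconds.
#' @param start_min_s,start_max_s cue-relative start-time range in seconds.
#' @param stride_samples stride between consecutive window starts, samples.
#' @param fs sampling rate in Hz.
#' @return an object of class `crop_spec`.
#' @export
crop_spec <- function(window_len_s = 2.0, start_min_s = -0.5,
                      start_max_s = 2.0, stride_samples = 1L, fs = 250) {
  if (!is_number(window_len_s) || window_len_s <= 0)
    stop_config("`window_len_s` must be positive")
  if (!is_number(start_min_s) || !is_number(start_max_s) ||
      start_min_s > start_max_s)
    stop_config("`start_min_s` must not exceed `start_max_s`")
  if (!is_count(stride_samples)) stop_config("`stride_samples` must be a positive integer")
  if (!is_number(fs) || fs <= 0) stop_config("`fs` must be a positive number")
  structure(
    list(window_len_s = window_len_s, start_min_s = start_min_s,
         start_max_s = start_max_s, stride_samples = as.integer(stride_samples),
         fs = fs),
    class = "crop_spec"
  )
}

#' Number of sliding windows per trial
#'
#' One window per admissible start sample in the half-open cue-relative
#' range `[start_min_s, start_max_s)` (all window arithmetic in this package
#' is half-open): `max(1, ceiling((start_max_s - start_min_s) * fs /
#' stride_samples))`, with the degenerate equal-endpoint range yielding a
#' single window. The default geometry (2.5-s start range, 250 Hz, stride 1)
#' gives the published 625 crops per trial.
#'
#' @param spec a [crop_spec()].
#' @return integer window count.
#' @export
#' @examples
#' count_windows(crop_spec())  # 625
count_windows <- function(spec) {
  stopifnot(inherits(spec, "crop_spec"))
  n <- ceiling((spec$start_max_s - spec$start_min_s) * spec$fs /
                 spec$stride_samples)
  as.integer(max(1, n))
}

#' Crop a trial dataset into a window batch
#'
#' Window `j` (0-based) of trial `i` is the contiguous slice starting at
#' sample `round_haz((start_min_s - t0_offset_s) * fs) + j * stride_samples`
#' (0-based), of length `window_len_s * fs`. Labels are inherited from the
#' source trial and each window keeps a back-pointer to it.
#'
#' @param ds a [trial_dataset()].
#' @param spec a [crop_spec()]; its `fs` must match the dataset.
#' @return an object of class `window_batch`: list with `windows`
#'   (`[M, C, T']` array), `trial_index`, `window_index`, `labels`,
#'   `n_trials`, `windows_per_trial`.
#' @export
crop_windows <- function(ds, spec) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(spec, "crop_spec"))
  if (!isTRUE(all.equal(ds$fs, spec$fs)))
    stop_config(sprintf("crop_spec fs (%g) does not match dataset fs (%g)",
                        spec$fs, ds$fs))
  d <- dim(ds$trials)
  t_len <- as.integer(round(spec$window_len_s * spec$fs))
  nw <- count_windows(spec)
  base0 <- as.integer(round_haz((spec$start_min_s - ds$t0_offset_s) * spec$fs))
  starts0 <- base0 + (seq_len(nw) - 1L) * spec$stride_samples
  bad <- which(starts0 < 0 | starts0 + t_len > d[3])
  if (length(bad) > 0) {
    t_bad <- ds$t0_offset_s + starts0[bad[1]] / spec$fs
    stop_geometry(sprintf(
      "window starting at %g s (samples %d..%d) exceeds the %d-sample trial",
      t_bad, starts0[bad[1]] + 1, starts0[bad[1]] + t_len, d[3]))
  }
  m <- d[1] * nw
  windows <- array(0, dim = c(m, d[2], t_len))
  # window-major within trial: rows ordered (trial 1: w1..wnw, trial 2: ...)
  for (j in seq_len(nw)) {
    sl <- (starts0[j] + 1):(starts0[j] + t_len)
    rows <- (seq_len(d[1]) - 1L) * nw + j
    windows[rows, , ] <- ds$trials[, , sl]
  }
  structure(
    list(windows = windows,
         trial_index = rep(seq_len(d[1]), each = nw),
         window_index = rep(seq_len(nw), times = d[1]),
         labels = rep(ds$labels, each = nw),
         n_trials = d[1], windows_per_trial = nw),
    class = "window_batch"
  )
}

#' @export
print.window_batch <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_batch> %d windows (%d trials x %d) x %d channels x %d samples\n",
              d[1], x$n_trials, x$windows_per_trial, d[2], d[3]))
  invisible(x)
}

#' Aggregate per-window class probabilities into a trial prediction
#'
#' The trial-level probability vector is the arithmetic mean of the window
#' probability rows (order-invariant, sums to 1); the decoded class is its
#' argmax.
#'
#' @param window_probs numeric matrix `[W, K]`; each row a probability
#'   vector.
#' @param reduction aggregation rule; only `"mean"` is defined.
#' @return numeric probability vector of length `K`.
#' @export
aggregate_window_predictions <- function(window_probs, reduction = "mean") {
  if (is.null(dim(window_probs)))
    window_probs <- matrix(window_probs, nrow = 1)
  if (nrow(window_probs) == 0)
    mid_stop("cannot aggregate an empty set of window predictions",
             "midecoder_aggregation_error")
  reduction <- match.arg(reduction, "mean")
  if (any(window_probs < -1e-9))
    stop_validation("window probabilities must be nonnegative")
  rs <- rowSums(window_probs)
  if (any(abs(rs - 1) > 1e-6))
    stop_validation("each window probability row must sum to 1")
  colMeans(window_probs)
}
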