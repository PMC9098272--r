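#' Specification for the synthetic motor-imagery EEG generator
#'
#' The generator emulates the physiology that motor-imagery decoders exploit:
#' event-related desynchronization (ERD) of the mu (8--12 Hz) and beta
#' (18--26 Hz) sensorimotor rhythms. Every channel carries each rhythm as a
#' band-limited stochastic oscillation over 1/f background noise; for a trial
#' of class \code{k}, the class's rhythm is attenuated on the class's channel
#' subset during the post-cue period, so that post-cue band power equals
#' \code{(1 - erd_depth)} times the pre-cue baseline in expectation.
#'
#' @param n_trials number of trials to generate (labels are balanced).
#' @param n_classes number of imagery classes.
#' @param n_channels number of electrode channels.
#' @param fs sampling rate in Hz.
#' @param trial_duration_s trial length in seconds (cue-relative span
#'   \code{t0_offset_s} to \code{t0_offset_s + trial_duration_s}).
#' @param t0_offset_s cue-relative time of the first sample.
#' @param class_topographies list of integer channel-index vectors, one per
#'   class; defaults to a lateralized somatotopy-style block scheme
#'   (see [default_topographies()]).
#' @param bands list of length-2 numeric vectors (Hz), one per class;
#'   defaults alternate mu and beta.
#' @param erd_depth fractional band-power attenuation during imagery, in
#'   \code{[0, 1]}; 0 means no class information.
#' @param background_exponent spectral slope of the 1/f background noise.
#' @param noise_sd standard deviation of the background noise (microvolts).
#' @param rhythm_sd standard deviation of each band-limited rhythm
#'   (microvolts) at baseline.
#' @param artifacts if \code{TRUE}, inject occasional slow EOG-like
#'   transients on the first channels.
#' @param seed integer RNG seed; the same spec (including seed) reproduces a
#'   bit-identical dataset.
#' @return an object of class \code{synthetic_spec}.
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(n_trials,
                           n_classes = 4L,
                           n_channels = 22L,
                           fs = 250,
                           trial_duration_s = 4.5,
                           t0_offset_s = -0.5,
                           class_topographies = NULL,
                           bands = NULL,
                           erd_depth = 0.5,
                           background_exponent = 1,
                           noise_sd = 2,
                           rhythm_sd = 5,
                           artifacts = FALSE,
                           seed = 1L) {
  if (!is_count(n_trials)) stop_config("`n_trials` must be a positive integer")
  if (!is_count(n_classes)) stop_config("`n_classes` must be a positive integer")
  if (!is_count(n_channels)) stop_config("`n_channels` must be a positive integer")
  if (!is_number(fs) || fs <= 0) stop_config("`fs` must be a positive number")
  if (!is_number(trial_duration_s) || trial_duration_s <= 0)
    stop_config("`trial_duration_s` must be a positive number")
  n_samples <- fs * trial_duration_s
  if (abs(n_samples - round(n_samples)) > 1e-8)
    stop_config("`fs` * `trial_duration_s` must be an integer sample count")
  if (!is_number(erd_depth) || erd_depth < 0 || erd_depth > 1)
    stop_config("`erd_depth` must lie in [0, 1]")
  if (!is_number(background_exponent) || background_exponent < 0)
    stop_config("`background_exponent` must be nonnegative")
  if (!is_number(noise_sd) || noise_sd < 0)
    stop_config("`noise_sd` must be nonnegative")
  if (!is_number(rhythm_sd) || rhythm_sd < 0)
    stop_config("`rhythm_sd` must be nonnegative")
  if (is.null(class_topographies))
    class_topographies <- default_topographies(n_channels, n_classes)
  if (!is.list(class_topographies) || length(class_topographies) != n_classes)
    stop_config("`class_topographies` must be a list with one entry per class")
  for (k in seq_len(n_classes)) {
    topo <- class_topographies[[k]]
    if (length(topo) == 0 || !all(topo == floor(topo)) ||
        any(topo < 1) || any(topo > n_channels))
      stop_config(sprintf(
        "`class_topographies` entry %d must be a nonempty subset of channel indices", k))
  }
  if (n_classes > 1 &&
      all(vapply(class_topographies[-1], function(x)
        identical(sort(as.integer(x)), sort(as.integer(class_topographies[[1]]))),
        logical(1))))
    stop_config("`class_topographies` must not be identical for all classes")
  if (is.null(bands)) bands <- default_bands(n_classes)
  if (!is.list(bands) || length(bands) != n_classes)
    stop_config("`bands` must be a list with one entry per class")
  for (k in seq_len(n_classes)) {
    b <- bands[[k]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] <= 0 || b[2] <= b[1] ||
        b[2] >= fs / 2)
      stop_config(sprintf("`bands` entry %d must be an increasing Hz interval below Nyquist", k))
  }
  if (!is_number(seed) || seed != floor(seed)) stop_config("`seed` must be an integer")
  structure(
    list(
      n_trials = as.integer(n_trials), n_classes = as.integer(n_classes),
      n_channels = as.integer(n_channels), fs = fs,
      trial_duration_s = trial_duration_s, t0_offset_s = t0_offset_s,
      class_topographies = lapply(class_topographies, as.integer),
      bands = bands, erd_depth = erd_depth,
      background_exponent = background_exponent, noise_sd = noise_sd,
      rhythm_sd = rhythm_sd, artifacts = isTRUE(artifacts),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Lateralized default class topographies
#'
#' Splits the channel range into contiguous blocks and assigns them to
#' classes following motor-cortex somatotopy: class 1 (left hand) maps to a
#' right-hemisphere block, class 2 (right hand) to a left block, class 3
#' (feet) to a central block, further classes to the remaining blocks.
#'
#' @param n_channels number of channels.
#' @param n_classes number of classes (at most `n_channels`).
#' @return list of integer channel-index vectors, one per class.
#' @export
default_topographies <- function(n_channels, n_classes) {
  if (n_classes > n_channels)
    stop_config("cannot build topographies: more classes than channels")
  blocks <- split(seq_len(n_channels),
                  cut(seq_len(n_channels), n_classes, labels = FALSE))
  # left hand -> right-hemisphere (later) block, right hand -> left block,
  # feet -> central, remaining classes in order
  ord <- seq_len(n_classes)
  if (n_classes >= 3) {
    ord[1] <- 3L   # left hand: right-hemisphere block
    ord[2] <- 1L   # right hand: left-hemisphere block
    ord[3] <- 2L   # feet: central block
  }
  lapply(ord, function(i) as.integer(blocks[[i]]))
}

default_bands <- function(n_classes) {
  base <- list(c(8, 12), c(8, 12), c(18, 26), c(18, 26))
  lapply(seq_len(n_classes), function(k) base[[((k - 1) %% 4) + 1]])
}

# Gaussian noise with power spectral density proportional to 1/f^exponent,
# synthesized by spectral shaping; scaled to standard deviation `sd`.
one_over_f_noise <- function(n, exponent, sd) {
  if (sd == 0) return(numeric(n))
  x <- shaped_noise(n, function(f) f^(-exponent / 2))
  sd * x / stats::sd(x)
}

# Band-limited Gaussian noise in [lo, hi] Hz, scaled to standard deviation
# `sd`. Used as the ongoing sensorimotor rhythm with random phase.
band_noise <- function(n, fs, band, sd) {
  if (sd == 0) return(numeric(n))
  f <- (seq_len(n) - 1) * fs / n
  x <- shaped_noise(n, function(fr) as.numeric(fr >= band[1] & fr <= band[2]), fs = fs)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  sd * x / s
}

# Real noise with spectral amplitude shape `shape(f)` over positive
# frequencies (f in Hz when fs given, otherwise in cycles/series).
shaped_noise <- function(n, shape, fs = 1) {
  half <- floor(n / 2)
  f <- (1:half) * fs / n
  amp <- shape(f)
  coef <- complex(real = rnorm(half), imaginary = rnorm(half)) * amp
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2:(half + 1)] <- coef
  # conjugate symmetry for a real series; Nyquist bin (even n) forced real
  if (n %% 2 == 0) {
    spec[half + 1] <- complex(real = Re(spec[half + 1]), imaginary = 0)
    spec[n:(half + 2)] <- Conj(spec[2:half])
  } else {
    spec[n:(half + 2)] <- Conj(spec[2:(half + 1)])
  }
  Re(fft(spec, inverse = TRUE)) / n
}

#' Generate a labeled synthetic motor-imagery EEG dataset
#'
#' Synthesizes `n_trials` multichannel trials according to a
#' [synthetic_spec()]. ERD is multiplicative: for a trial of class `k`, the
#' band-limited rhythm in the class's band on the class's channels is scaled
#' by `sqrt(1 - erd_depth)` during the post-cue period, so that post-cue
#' band power is attenuated by the factor `(1 - erd_depth)` relative to the
#' pre-cue baseline. Labels are balanced over classes (cyclic assignment).
#' The same spec (including `seed`) reproduces a bit-identical dataset.
#'
#' @param spec a [synthetic_spec()].
#' @return a [trial_dataset()] with integer labels `0 .. n_classes - 1`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_trials = 8, seed = 7))
#' table(ds$labels)
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop_config("`spec` must be a synthetic_spec object")
  n <- round(spec$fs * spec$trial_duration_s)
  t_rel <- spec$t0_offset_s + (seq_len(n) - 1) / spec$fs
  post <- t_rel >= 0
  scale_env <- sqrt(1 - spec$erd_depth)
  labels <- rep_len(0:(spec$n_classes - 1L), spec$n_trials)
  trials <- array(0, dim = c(spec$n_trials, spec$n_channels, n))
  ubands <- unique(spec$bands)
  with_seed(spec$seed, {
    for (i in seq_len(spec$n_trials)) {
      k <- labels[i] + 1L
      topo <- spec$class_topographies[[k]]
      class_band <- spec$bands[[k]]
      for (ch in seq_len(spec$n_channels)) {
        x <- one_over_f_noise(n, spec$background_exponent, spec$noise_sd)
        for (b in ubands) {
          osc <- band_noise(n, spec$fs, b, spec$rhythm_sd)
          if (identical(b, class_band) && ch %in% topo)
            osc[post] <- osc[post] * scale_env
          x <- x + osc
        }
        trials[i, ch, ] <- x
      }
      if (spec$artifacts && runif(1) < 0.2) {
        # slow frontal EOG-like blink transient
        onset <- sample.int(n - round(0.3 * spec$fs), 1)
        span <- onset:(onset + round(0.3 * spec$fs) - 1)
        blip <- 50 * sin(pi * seq_along(span) / length(span))
        for (ch in seq_len(min(3L, spec$n_channels)))
          trials[i, ch, span] <- trials[i, ch, span] + blip
      }
    }
  })
  trial_dataset(trials, labels, fs = spec$fs,
                t0_offset_s = spec$t0_offset_s,
                subject_id = sprintf("synthetic-seed%d", spec$seed),
                n_classes = spec$n_classes)
}

#' Welch band power
#'
#' Integrated spectral power of a single-channel sample series within a
#' frequency band, estimated by Welch's method: Hann-windowed overlapping
#' segments, mean-removed per segment, periodograms averaged, power summed
#' over the band's frequency bins. Serves as the validation oracle for the
#' synthetic generator's ERD structure.
#'
#' @param x numeric sample series.
#' @param fs sampling rate in Hz.
#' @param band length-2 Hz interval within `(0, fs/2)`.
#' @param seg_s Welch segment length in seconds (default 1 s; segments
#'   overlap by half). `x` must span at least one full segment.
#' @return nonnegative scalar power (same units as `x` squared).
#' @export
#' @examples
#' t <- seq(0, 4, by = 1 / 250)[-1]
#' bandpower(sin(2 * pi * 10 * t), 250, c(8, 12))
bandpower <- function(x, fs, band, seg_s = 1) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop_config("`band` must be an increasing interval inside (0, fs/2)")
  nseg <- round(seg_s * fs)
  if (length(x) < nseg)
    stop_config(sprintf("signal too short: need at least %d samples (one %g-s segment)",
                        nseg, seg_s))
  psd <- welch_psd(x, fs, nseg)
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$power[sel]) * (fs / nseg)
}

# Welch PSD with Hann window and 50% overlap; one-sided density.
welch_psd <- function(x, fs, nseg) {
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(w^2)
  acc <- numeric(floor(nseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2
    acc <- acc + sp[seq_along(acc)]
  }
  pow <- acc / (length(starts) * fs * u)
  # one-sided: double everything but DC (and Nyquist for even nseg)
  dbl <- rep(2, length(acc)); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[length(acc)] <- 1
  list(freq = (seq_along(acc) - 1) * fs / nseg, power = pow * dbl)
}

#' Post/pre-cue band-power ratio per trial
#'
#' For every trial, band power is averaged over the given channels in the
#' post-cue window and in the pre-cue baseline separately, and the ratio of
#' the two means is reported. Under the generator's ERD model the expected
#' ratio on a class's own channels and band is `1 - erd_depth` (the short
#' 0.5-s baseline makes the per-trial ratio a noisy, slightly upward-biased
#' estimate; [erd_attenuation()] pools trials for an unbiased read-out).
#'
#' @param ds a [trial_dataset()].
#' @param channels integer channel indices to average over.
#' @param band length-2 Hz interval.
#' @param seg_s Welch segment length in seconds; the default 0.5 s fits the
#'   0.5-s pre-cue baseline.
#' @return a tibble with columns `trial`, `label`, `ratio`.
#' @export
band_power_ratio <- function(ds, channels, band, seg_s = 0.5) {
  pw <- window_band_powers(ds, channels, band, seg_s)
  ratio <- rowMeans(pw$post) / rowMeans(pw$pre)
  tibble::tibble(trial = seq_along(ratio), label = ds$labels, ratio = ratio)
}

#' Pooled ERD attenuation estimate
#'
#' Mean post-cue band power over all trials and channels divided by the mean
#' pre-cue band power: an unbiased estimate of the generator's power
#' attenuation factor `1 - erd_depth` when applied to one class's trials on
#' that class's channels and band.
#'
#' @inheritParams band_power_ratio
#' @return scalar attenuation factor.
#' @export
erd_attenuation <- function(ds, channels, band, seg_s = 0.5) {
  pw <- window_band_powers(ds, channels, band, seg_s)
  mean(pw$post) / mean(pw$pre)
}

# Per-trial, per-channel Welch band powers in the pre- and post-cue windows.
window_band_powers <- function(ds, channels, band, seg_s) {
  stopifnot(inherits(ds, "trial_dataset"))
  n <- dim(ds$trials)[3]
  t_rel <- ds$t0_offset_s + (seq_len(n) - 1) / ds$fs
  pre <- which(t_rel < 0)
  post <- which(t_rel >= 0)
  n_tr <- dim(ds$trials)[1]
  bp <- function(samples) {
    m <- matrix(0, n_tr, length(channels))
    for (i in seq_len(n_tr))
      for (j in seq_along(channels))
        m[i, j] <- bandpower(ds$trials[i, channels[j], samples], ds$fs, band,
                             seg_s)
    m
  }
  list(pre = bp(pre), post = bp(post))
}

#' Band-power-ratio rule classifier
#'
#' A fixed (non-learned) decoder used as a physiological sanity baseline:
#' for each trial and each class it measures the mean post/pre band-power
#' ratio on that class's channels and band, and predicts the class with the
#' strongest desynchronization (smallest ratio).
#'
#' @param ds a [trial_dataset()].
#' @param class_topographies,bands as in [synthetic_spec()].
#' @param seg_s Welch segment length in seconds.
#' @return integer vector of predicted labels in `0 .. K - 1`.
#' @export
bandpower_rule_classify <- function(ds, class_topographies, bands, seg_s = 0.5) {
  stopifnot(inherits(ds, "trial_dataset"))
  k <- length(class_topographies)
  scores <- vapply(seq_len(k), function(j) {
    band_power_ratio(ds, class_topographies[[j]], bands[[j]], seg_s)$ratio
  }, numeric(dim(ds$trials)[1]))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  as.integer(apply(scores, 1, which.min) - 1L)
}
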