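# EDF (European Data Format) ingestion and cue-relative epoching.
#
# The reader/writer implement the fixed-form 16-bit EDF layout directly
# (ASCII header blocks + little-endian int16 data records with per-channel
# physical scaling). Event markers are taken from a plain-text sidecar table
# (columns onset_s, code) rather than embedded EDF+ annotations.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a continuous multichannel recording to an EDF file
#'
#' Samples are quantized to 16 bits over a per-channel symmetric physical
#' range, so the round trip through [read_edf()] is accurate to the
#' quantization step (range / 65535), not bit-exact.
#'
#' @param signals numeric matrix `[C, S]` in microvolts.
#' @param fs sampling rate in Hz (integer, shared by all channels).
#' @param path output file path.
#' @param channel_names optional character vector of length `C`.
#' @param record_duration_s data-record length in seconds; the recording is
#'   zero-padded to a whole number of records.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, channel_names = NULL,
                      record_duration_s = 1) {
  stopifnot(is.matrix(signals), fs == floor(fs), fs > 0)
  nc <- nrow(signals)
  if (is.null(channel_names)) channel_names <- sprintf("EEG%02d", seq_len(nc))
  spr <- as.integer(round(fs * record_duration_s))
  n_rec <- as.integer(ceiling(ncol(signals) / spr))
  total <- n_rec * spr
  if (total > ncol(signals))
    signals <- cbind(signals, matrix(0, nc, total - ncol(signals)))
  pmax_ <- pmax(apply(abs(signals), 1, max), 1) * 1.0001
  dig_min <- -32768L; dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (1L + nc), 8); wr("", 44); wr(n_rec, 8)
  wr(format(record_duration_s), 8); wr(nc, 4)
  for (nm in channel_names) wr(nm, 16)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(format(-pmax_[i], digits = 6), 8)
  for (i in seq_len(nc)) wr(format(pmax_[i], digits = 6), 8)
  for (i in seq_len(nc)) wr(dig_min, 8)
  for (i in seq_len(nc)) wr(dig_max, 8)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr(spr, 8)
  for (i in seq_len(nc)) wr("", 32)
  gain <- (2 * pmax_) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nc)) {
      dig <- round((signals[ch, cols] - (-pmax_[ch])) / gain[ch]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @return a list with `signals` (`[C, S]` matrix in physical units), `fs`,
#'   `channel_names`, `n_records` and `record_duration_s`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop_io(sprintf("not an EDF file (version field '%s'): %s",
                                      version, path))
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header byte count (recomputed from ns)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  if (is.na(nc) || nc < 1) stop_io("EDF header: invalid signal count")
  fld <- function(width) vapply(seq_len(nc), function(i) rd(width), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1)
    stop_io("EDF: channels with differing sampling rates are not supported")
  spr1 <- spr[1]
  fs <- spr1 / rec_dur
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  signals <- matrix(0, nc, n_rec * spr1)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr1 + 1):(r * spr1)
    for (ch in seq_len(nc)) {
      dig <- readBin(con, integer(), n = spr1, size = 2, endian = "little")
      if (length(dig) < spr1) stop_io("EDF: truncated data record")
      signals[ch, cols] <- (dig - dmin_[ch]) * gain[ch] + pmin_[ch]
    }
  }
  list(signals = signals, fs = fs, channel_names = labels,
       n_records = n_rec, record_duration_s = rec_dur)
}

#' Read / write a plain-text event table
#'
#' Tab-separated with header columns `onset_s` (cue time in seconds from
#' recording start) and `code` (integer event code).
#'
#' @param path file path.
#' @param events data frame with columns `onset_s`, `code`.
#' @return `read_event_table` returns a tibble; `write_event_table` returns
#'   `path` invisibly.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such event table: %s", path))
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "code") %in% names(ev)))
    stop_io("event table must have columns `onset_s` and `code`")
  tibble::as_tibble(ev)
}

#' @rdname read_event_table
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Epoch a continuous recording into cue-locked trials
#'
#' Cuts one trial per cue event, spanning `tmin_s .. tmax_s` relative to the
#' cue onset (half-open on the right: `round((tmax_s - tmin_s) * fs)`
#' samples). Epoching is deterministic: the same recording and parameters
#' always yield the identical dataset.
#'
#' @param signals numeric matrix `[C, S]`.
#' @param fs sampling rate in Hz.
#' @param events data frame with columns `onset_s`, `code`.
#' @param event_map named integer vector mapping event codes (names) to
#'   class labels `0 .. K - 1`.
#' @param tmin_s,tmax_s cue-relative epoch bounds in seconds.
#' @param channel_names,subject_id passed to [trial_dataset()].
#' @return a [trial_dataset()] with one trial per event, in event order.
#' @export
epoch_recording <- function(signals, fs, events, event_map,
                            tmin_s = -0.5, tmax_s = 4.0,
                            channel_names = NULL, subject_id = "S00") {
  stopifnot(is.matrix(signals))
  if (nrow(events) == 0)
    mid_stop("no cue events to epoch", "midecoder_empty_epoch_error")
  codes <- as.character(events$code)
  unknown <- setdiff(unique(codes), names(event_map))
  if (length(unknown) > 0)
    stop_mapping(sprintf("event codes with no mapping: %s",
                         paste(unknown, collapse = ", ")))
  n_samp <- as.integer(round((tmax_s - tmin_s) * fs))
  starts <- as.integer(round(events$onset_s * fs) + round(tmin_s * fs))  # 0-based
  bad <- which(starts < 0 | starts + n_samp > ncol(signals))
  if (length(bad) > 0)
    stop_geometry(sprintf(
      "epoch at onset %g s exceeds the recording (needs samples %d..%d of %d)",
      events$onset_s[bad[1]], starts[bad[1]] + 1, starts[bad[1]] + n_samp,
      ncol(signals)))
  n_ev <- nrow(events)
  trials <- array(0, dim = c(n_ev, nrow(signals), n_samp))
  for (i in seq_len(n_ev))
    trials[i, , ] <- signals[, (starts[i] + 1):(starts[i] + n_samp)]
  labels <- as.integer(event_map[codes])
  trial_dataset(trials, labels, fs = fs, t0_offset_s = tmin_s,
                channel_names = channel_names, subject_id = subject_id,
                n_classes = max(as.integer(event_map)) + 1L)
}

#' Load and epoch an EEG recording file
#'
#' Reads an EDF recording, resamples to `resample_to` Hz when the file rate
#' differs (polyphase resampling), and epochs around cue events. Events come
#' from `events` or, when `NULL`, from the plain-text sidecar table at
#' `<path>.events.tsv`. GDF files are not parsed; convert them to EDF plus an
#' event table first.
#'
#' @param path recording file path (`.edf`).
#' @param event_map named integer vector mapping event codes to labels.
#' @param tmin_s,tmax_s cue-relative epoch bounds in seconds.
#' @param events optional data frame with columns `onset_s`, `code`.
#' @param resample_to target sampling rate in Hz.
#' @param subject_id identifier; defaults to the file stem.
#' @return a [trial_dataset()].
#' @export
load_edf_gdf <- function(path, event_map, tmin_s = -0.5, tmax_s = 4.0,
                         events = NULL, resample_to = 250,
                         subject_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gdf")
    stop_io("GDF parsing is not implemented; convert the recording to EDF with a sidecar event table")
  rec <- read_edf(path)
  fs <- rec$fs
  signals <- rec$signals
  if (!isTRUE(all.equal(fs, resample_to))) {
    if (fs != floor(fs) || resample_to != floor(resample_to))
      stop_config("resampling requires integer source and target rates")
    g <- gcd_int(as.integer(resample_to), as.integer(fs))
    p <- resample_to / g; q <- fs / g
    signals <- t(apply(signals, 1, function(x) signal::resample(x, p, q)))
    fs <- resample_to
  }
  if (is.null(events)) {
    sidecar <- paste0(path, ".events.tsv")
    events <- read_event_table(sidecar)
  }
  if (is.null(subject_id)) subject_id <- tools::file_path_sans_ext(basename(path))
  epoch_recording(signals, fs, events, event_map, tmin_s, tmax_s,
                  channel_names = rec$channel_names, subject_id = subject_id)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
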