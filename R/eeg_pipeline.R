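#' Multichannel EEG recording container
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param rate Sampling rate in Hz.
#' @param channel_labels Channel names, one per row; defaults to the
#'   packaged 64-channel montage order when the row count matches.
#' @param events data.frame with columns `sample` (1-based sample index of
#'   stimulus onset), `sentence_id`, `condition_id`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, rate, channel_labels = NULL, events = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 64L) montage_labels()
                      else paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stopf("%d channel labels for %d rows", length(channel_labels), nrow(data))
  }
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  if (is.null(events)) {
    events <- data.frame(sample = integer(), sentence_id = character(),
                         condition_id = character())
  }
  if (!all(c("sample", "sentence_id", "condition_id") %in% names(events))) {
    stopf("events need columns sample, sentence_id, condition_id")
  }
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    stopf("event sample indices must lie within the recording")
  }
  structure(list(data = data, rate = rate, channel_labels = channel_labels,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$events)))
  invisible(x)
}

#' One stimulus-locked EEG epoch
#'
#' @param data channels x samples matrix (64 x 768 at the defaults).
#' @param t0 Epoch start relative to stimulus onset in seconds.
#' @param rate Sampling rate in Hz.
#' @param sentence_id,condition_id,participant_id Trial identifiers.
#' @return An `eeg_epoch` object.
#' @export
eeg_epoch <- function(data, t0 = -0.5, rate = 256,
                      sentence_id = NA, condition_id = NA, participant_id = NA) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stopf("epoch data must be finite")
  structure(list(data = data, t0 = t0, rate = rate, sentence_id = sentence_id,
                 condition_id = condition_id, participant_id = participant_id),
            class = "eeg_epoch")
}

# ---- file readers ----------------------------------------------------------

#' Read an EDF or BDF recording
#'
#' Minimal reader for EDF (16-bit) and BioSemi BDF (24-bit) continuous
#' recordings: parses the ASCII header, reads all data records, and converts
#' to physical units. Annotation channels are dropped. Stimulus events are
#' supplied separately via [read_events_csv()].
#'
#' @param path Path to the `.edf`/`.bdf` file.
#' @return An [eeg_recording()] without events.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("EDF/BDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  is_bdf <- magic[1] == as.raw(255)
  fld <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  for (n in c(80, 80, 8, 8)) fld(n)      # patient, recording, date, time
  fld(8)                                  # header bytes
  fld(44)                                 # reserved
  n_rec <- as.integer(fld(8))
  rec_dur <- as.numeric(fld(8))
  n_sig <- as.integer(fld(4))
  labels <- vapply(seq_len(n_sig), function(i) fld(16), "")
  for (n in c(80, 8)) for (i in seq_len(n_sig)) fld(n)  # transducer, unit
  phys_min <- vapply(seq_len(n_sig), function(i) as.numeric(fld(8)), 0)
  phys_max <- vapply(seq_len(n_sig), function(i) as.numeric(fld(8)), 0)
  dig_min <- vapply(seq_len(n_sig), function(i) as.numeric(fld(8)), 0)
  dig_max <- vapply(seq_len(n_sig), function(i) as.numeric(fld(8)), 0)
  for (i in seq_len(n_sig)) fld(80)       # prefiltering
  spr <- vapply(seq_len(n_sig), function(i) as.integer(fld(8)), 0L)
  for (i in seq_len(n_sig)) fld(32)       # reserved
  if (length(unique(spr)) != 1L) {
    stopf("%s: signals with mixed sampling rates are not supported", path)
  }
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  data <- matrix(0, sum(keep), n_rec * spr[1])
  col0 <- 0L
  for (r in seq_len(n_rec)) {
    ki <- 0L
    for (s in seq_len(n_sig)) {
      if (is_bdf) {
        raw3 <- readBin(con, "raw", 3L * spr[s])
        m <- matrix(as.integer(raw3), nrow = 3L)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
      } else {
        v <- readBin(con, "integer", spr[s], 2, signed = TRUE, endian = "little")
      }
      if (keep[s]) {
        ki <- ki + 1L
        data[ki, (col0 + 1L):(col0 + spr[s])] <- v * gain[s] + offset[s]
      }
    }
    col0 <- col0 + spr[1]
  }
  eeg_recording(data, spr[1] / rec_dur, channel_labels = labels[keep])
}

#' Read a plain binary matrix recording with a YAML sidecar
#'
#' The sidecar names the layout: `rate`, `labels` (list), `dtype`
#' (`float32`/`float64`), and optionally `events` (list of maps with
#' `sample`, `sentence_id`, `condition_id`). The data file is the
#' channels x samples matrix written column-major (all channels of sample 1,
#' then sample 2, ...) in little-endian order.
#'
#' @param data_path Path to the raw matrix file.
#' @param sidecar_path Path to the YAML sidecar; defaults to
#'   `paste0(data_path, ".yaml")`.
#' @return An [eeg_recording()].
#' @export
read_eeg_matrix <- function(data_path, sidecar_path = paste0(data_path, ".yaml")) {
  meta <- yaml::read_yaml(sidecar_path)
  labels <- unlist(meta$labels)
  n_ch <- length(labels)
  bytes <- if (identical(meta$dtype, "float32")) 4L else 8L
  n_val <- file.size(data_path) / bytes
  con <- file(data_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n_val, bytes, endian = "little")
  data <- matrix(x, nrow = n_ch)
  ev <- NULL
  if (!is.null(meta$events)) {
    ev <- do.call(rbind, lapply(meta$events, function(e) {
      data.frame(sample = as.integer(e$sample),
                 sentence_id = as.character(e$sentence_id),
                 condition_id = as.character(e$condition_id))
    }))
  }
  eeg_recording(data, meta$rate, labels, ev)
}

#' Read stimulus events from CSV
#'
#' @param path CSV with columns `sample`, `sentence_id`, `condition_id`.
#' @return data.frame of events.
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "sentence_id", "condition_id")
  if (!all(need %in% names(ev))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  ev$sample <- as.integer(ev$sample)
  ev
}

# ---- preprocessing ---------------------------------------------------------

#' Design the Hamming-windowed sinc FIR band-pass filter
#'
#' Linear-phase FIR with a Hamming window; length is
#' `ceil(3.3 / tb * rate)` (rounded up to an odd tap count) for transition
#' bandwidth `tb` in Hz, the conventional Hamming-window heuristic.
#'
#' @param rate Sampling rate in Hz.
#' @param band `c(low, high)` pass band in Hz.
#' @param tb Transition bandwidth in Hz (default 1, governed by the 1 Hz
#'   lower edge).
#' @return Numeric vector of filter coefficients (odd length).
#' @export
design_fir_bandpass <- function(rate, band = c(1, 57), tb = 1) {
  if (band[1] <= 0 || band[2] >= rate / 2 || band[1] >= band[2]) {
    stopf("band (%g, %g) Hz must lie strictly inside (0, %g) Hz",
          band[1], band[2], rate / 2)
  }
  n_tap <- ceiling(3.3 / tb * rate)
  if (n_tap %% 2L == 0L) n_tap <- n_tap + 1L
  as.numeric(signal::fir1(n_tap - 1L, band / (rate / 2), type = "pass",
                          window = signal::hamming(n_tap)))
}

# Magnitude response of an FIR filter at frequencies f (Hz).
fir_response <- function(b, f, rate) {
  k <- seq_along(b) - 1
  vapply(f, function(fi) {
    Mod(sum(b * exp(-2i * pi * fi * k / rate)))
  }, 0)
}

# Zero-net-phase application of a linear-phase FIR: one pass plus
# group-delay compensation, with reflection padding at the edges.
apply_fir_zero_phase <- function(x, b) {
  n <- length(x)
  d <- (length(b) - 1L) %/% 2L
  pad <- min(d, n - 1L)
  xe <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  y <- signal::fftfilt(b, c(xe, numeric(length(b))))
  y[(d + pad + 1L):(d + pad + n)]
}

#' Preprocess a raw EEG recording
#'
#' Resamples to `target_rate`, re-references to the channel average, and
#' band-pass filters with a zero-phase Hamming-windowed sinc FIR. Event
#' sample indices are rescaled (floor) to the new rate.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate Target rate in Hz (default 256).
#' @param band Pass band in Hz (default `c(1, 57)`).
#' @param tb FIR transition bandwidth in Hz (default 1).
#' @return A preprocessed [eeg_recording()] at `target_rate`.
#' @export
preprocess_eeg <- function(rec, target_rate = 256, band = c(1, 57), tb = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$rate) {
    stopf("target rate %g exceeds the recording rate %g", target_rate, rec$rate)
  }
  if (band[2] >= target_rate / 2) {
    stopf("band edge %g Hz is at or above the target Nyquist (%g Hz)",
          band[2], target_rate / 2)
  }
  data <- rec$data
  events <- rec$events
  if (target_rate != rec$rate) {
    frac <- frac_ratio(target_rate, rec$rate)
    data <- t(apply(data, 1, function(x) signal::resample(x, frac[1], frac[2])))
    ratio <- target_rate / rec$rate
    events$sample <- pmax(1L, as.integer(floor((events$sample - 1L) * ratio)) + 1L)
  }
  data <- sweep(data, 2, colMeans(data))               # average reference
  b <- design_fir_bandpass(target_rate, band, tb)
  message(sprintf("FIR band-pass %g-%g Hz, %d taps (tb = %g Hz), zero-phase",
                  band[1], band[2], length(b), tb))
  data <- t(apply(data, 1, apply_fir_zero_phase, b = b))
  eeg_recording(data, target_rate, rec$channel_labels, events)
}

frac_ratio <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per event over `window` seconds relative to stimulus
#' onset (default -0.5..2.5 s, i.e. 768 samples at 256 Hz). Events whose
#' window exceeds the recording bounds are skipped with a message, never
#' silently truncated.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param window `c(start, end)` in seconds relative to onset.
#' @param participant_id Stamped on every epoch.
#' @return List of [eeg_epoch()] objects.
#' @export
extract_epochs <- function(rec, window = c(-0.5, 2.5), participant_id = NA) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_pre <- round_half_away(-window[1] * rec$rate)
  n_tot <- round_half_away((window[2] - window[1]) * rec$rate)
  out <- list()
  for (i in seq_len(nrow(rec$events))) {
    ev <- rec$events[i, ]
    first <- ev$sample - n_pre
    last <- first + n_tot - 1L
    if (first < 1L || last > ncol(rec$data)) {
      message(sprintf("skipping event %d (%s): window [%d, %d] outside recording",
                      i, ev$sentence_id, first, last))
      next
    }
    out[[length(out) + 1L]] <- eeg_epoch(
      rec$data[, first:last, drop = FALSE], t0 = window[1], rate = rec$rate,
      sentence_id = ev$sentence_id, condition_id = ev$condition_id,
      participant_id = participant_id)
  }
  out
}

#' Amplitude-threshold artifact rejection
#'
#' Drops epochs containing any sample whose absolute amplitude exceeds
#' `threshold` microvolts; the removal count is reported via `message()`.
#'
#' @param epochs List of [eeg_epoch()] objects.
#' @param threshold Absolute amplitude threshold in microvolts (default 150).
#' @return The retained epochs.
#' @export
reject_artifacts <- function(epochs, threshold = 150) {
  if (threshold <= 0) stopf("threshold must be positive")
  keep <- vapply(epochs, function(e) max(abs(e$data)) <= threshold, logical(1))
  if (any(!keep)) {
    message(sprintf("rejected %d of %d epochs exceeding %g uV",
                    sum(!keep), length(epochs), threshold))
  }
  epochs[keep]
}
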