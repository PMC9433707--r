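#' Phoneme onset times for one sentence
#'
#' @param onsets Numeric vector of onset times in seconds relative to
#'   sentence onset; must be non-negative and strictly increasing.
#' @param sentence_id Identifier of the sentence.
#' @return A `phoneme_onsets` object.
#' @export
phoneme_onsets <- function(onsets, sentence_id = NA_character_) {
  onsets <- as.numeric(onsets)
  if (anyNA(onsets) || any(onsets < 0)) stopf("onsets must be non-negative")
  if (is.unsorted(onsets, strictly = TRUE)) {
    stopf("onsets must be strictly increasing")
  }
  structure(list(onsets = onsets, sentence_id = sentence_id),
            class = "phoneme_onsets")
}

#' Stimulus feature series
#'
#' A stimulus feature sampled on the EEG time base: the speech temporal
#' envelope (`ENV`), the phoneme-onset impulse train (`PH`), or their
#' element-wise product (`PHENV`).
#'
#' @param values Numeric vector of feature values.
#' @param rate Sampling rate in Hz.
#' @param kind One of `"ENV"`, `"PH"`, `"PHENV"`.
#' @param sentence_id Sentence identifier.
#' @return A `feature_series` object.
#' @export
feature_series <- function(values, rate, kind = c("ENV", "PH", "PHENV"),
                           sentence_id = NA_character_) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind %in% c("ENV", "PHENV") && any(values < 0)) {
    stopf("%s values must be non-negative", kind)
  }
  if (kind == "PH" && !all(values %in% c(0, 1))) {
    stopf("PH values must be 0 or 1")
  }
  structure(list(values = values, rate = rate, kind = kind,
                 sentence_id = sentence_id),
            class = "feature_series")
}

#' Speech temporal envelope (ENV)
#'
#' Full-wave rectification followed by a zero-phase low-pass filter (30 Hz
#' cutoff by default), resampled onto the EEG time base. Undershoot from the
#' zero-phase filter is clipped at zero.
#'
#' @param audio An [audio_waveform()].
#' @param cutoff Low-pass cutoff in Hz (default 30); must be below the audio
#'   Nyquist frequency.
#' @param out_rate Output rate in Hz (default 256, the EEG rate).
#' @param sentence_id Carried through to the output.
#' @return A [feature_series()] of kind `"ENV"` with
#'   `round(duration * out_rate)` samples.
#' @export
extract_envelope <- function(audio, cutoff = 30, out_rate = 256,
                             sentence_id = NA_character_) {
  stopifnot(inherits(audio, "audio_waveform"))
  if (cutoff >= audio$rate / 2) {
    stopf("cutoff %g Hz is at or above Nyquist (%g Hz)", cutoff, audio$rate / 2)
  }
  if (out_rate > audio$rate) {
    stopf("out_rate (%g) must not exceed the audio rate (%g)", out_rate, audio$rate)
  }
  env <- rectify_lowpass(audio$samples, audio$rate, cutoff)
  dur <- audio_duration(audio)
  n_out <- round_half_away(dur * out_rate)
  t_in <- (seq_along(env) - 1) / audio$rate
  t_out <- (seq_len(n_out) - 1) / out_rate
  vals <- stats::approx(t_in, env, xout = t_out, rule = 2)$y
  feature_series(pmax(vals, 0), out_rate, "ENV", sentence_id)
}

#' Phoneme-onset impulse train (PH)
#'
#' A zero sequence with a unit impulse at the sample index of each phoneme
#' onset (round-half-away-from-zero rounding of `onset * rate`; sample
#' indices are 0-based in this description, so onset 0 maps to the first
#' sample).
#'
#' @param onsets A [phoneme_onsets()] object (or numeric vector of seconds).
#' @param duration Sentence duration in seconds; all onsets must fall before
#'   it.
#' @param rate Output rate in Hz (default 256).
#' @return A [feature_series()] of kind `"PH"`.
#' @export
onset_impulse_train <- function(onsets, duration, rate = 256) {
  if (!inherits(onsets, "phoneme_onsets")) onsets <- phoneme_onsets(onsets)
  bad <- onsets$onsets >= duration
  if (any(bad)) {
    stopf("onset %g s is at or beyond the sentence duration (%g s)",
          onsets$onsets[which(bad)[1]], duration)
  }
  n <- round_half_away(duration * rate)
  vals <- numeric(n)
  idx <- round_half_away(onsets$onsets * rate) + 1L   # 0-based sample -> R index
  idx <- idx[idx >= 1L & idx <= n]
  vals[idx] <- 1
  feature_series(vals, rate, "PH", onsets$sentence_id)
}

#' Product of phoneme train and envelope (PHENV)
#'
#' Element-wise product of the `ENV` and `PH` feature series: the envelope
#' amplitude sampled at phoneme onsets.
#'
#' @param env A [feature_series()] of kind `"ENV"`.
#' @param ph A [feature_series()] of kind `"PH"` with the same length and
#'   rate.
#' @return A [feature_series()] of kind `"PHENV"`.
#' @export
phenv_product <- function(env, ph) {
  stopifnot(inherits(env, "feature_series"), inherits(ph, "feature_series"))
  if (env$kind != "ENV" || ph$kind != "PH") {
    stopf("phenv_product() needs an ENV and a PH series (got %s, %s)",
          env$kind, ph$kind)
  }
  if (length(env$values) != length(ph$values) || env$rate != ph$rate) {
    stopf("ENV and PH series are not aligned (lengths %d/%d, rates %g/%g)",
          length(env$values), length(ph$values), env$rate, ph$rate)
  }
  feature_series(env$values * ph$values, env$rate, "PHENV", env$sentence_id)
}

#' Read phoneme onsets from a TextGrid or TSV file
#'
#' For Praat TextGrids (long or short text format) the onsets are the start
#' times of non-empty intervals in the phoneme tier (the first interval tier
#' whose name contains "phon", case-insensitively, or else the first
#' interval tier). For TSV, column 1 holds onset seconds. Output is sorted
#' and deduplicated.
#'
#' @param path Path to the annotation file.
#' @param dialect `"auto"` (default; decided from the file content),
#'   `"textgrid"`, or `"tsv"`.
#' @param sentence_id Carried through to the output.
#' @return A [phoneme_onsets()] object.
#' @export
read_onsets <- function(path, dialect = c("auto", "textgrid", "tsv"),
                        sentence_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("onset file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("ooTextFile|TextGrid", lines[seq_len(min(3, length(lines)))])))
      "textgrid" else "tsv"
  }
  onsets <- if (dialect == "tsv") parse_onsets_tsv(lines, path)
            else parse_textgrid_onsets(lines, path)
  phoneme_onsets(sort(unique(onsets)), sentence_id)
}

parse_onsets_tsv <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(vapply(strsplit(lines, "[\t ,]+"),
                                             `[[`, "", 1L)))
  if (anyNA(vals)) {
    stopf("%s: line %d is not a number", path, which(is.na(vals))[1])
  }
  vals
}

# Parses both long-form TextGrids (named "xmin = ..." fields) and the
# compact short form (bare values in fixed order).
parse_textgrid_onsets <- function(lines, path) {
  txt <- trimws(lines)
  long_form <- any(grepl("^item\\s*\\[", txt)) || any(grepl("^intervals\\s*\\[", txt))
  tiers <- if (long_form) parse_textgrid_long(txt) else parse_textgrid_short(txt)
  tiers <- Filter(function(t) isTRUE(t$interval), tiers)
  if (length(tiers) == 0L) stopf("%s: no interval tier found", path)
  hit <- which(vapply(tiers, function(t) grepl("phon", t$name, ignore.case = TRUE),
                      logical(1)))
  tier <- tiers[[if (length(hit)) hit[1] else 1L]]
  keep <- nzchar(trimws(tier$text))
  if (!any(keep)) stopf("%s: phoneme tier has no labelled intervals", path)
  tier$xmin[keep]
}

parse_textgrid_long <- function(txt) {
  num_of <- function(line) as.numeric(sub(".*=\\s*", "", line))
  str_of <- function(line) gsub("^\"|\"$", "", sub(".*=\\s*", "", line))
  tier_starts <- grep("^item\\s*\\[\\s*[0-9]+\\s*\\]", txt)
  if (length(tier_starts) == 0L) return(list())
  bounds <- c(tier_starts, length(txt) + 1L)
  lapply(seq_along(tier_starts), function(i) {
    blk <- txt[bounds[i]:(bounds[i + 1L] - 1L)]
    cls <- str_of(blk[grep("^class\\s*=", blk)[1]])
    name_ln <- grep("^name\\s*=", blk)
    nm <- if (length(name_ln)) str_of(blk[name_ln[1]]) else ""
    iv <- grep("^intervals\\s*\\[", blk)
    xmin <- text <- c()
    for (j in iv) {
      sub_blk <- blk[j:min(j + 4L, length(blk))]
      xm <- grep("^xmin\\s*=", sub_blk)
      tx <- grep("^text\\s*=", sub_blk)
      if (length(xm) && length(tx)) {
        xmin <- c(xmin, num_of(sub_blk[xm[1]]))
        text <- c(text, str_of(sub_blk[tx[1]]))
      }
    }
    list(interval = identical(cls, "IntervalTier"), name = nm,
         xmin = xmin, text = text)
  })
}

parse_textgrid_short <- function(txt) {
  # short form: after the 2 header lines and file xmin/xmax/<exists>/size,
  # each tier is: "IntervalTier"/"TextTier", "name", xmin, xmax, n, then
  # triplets (xmin, xmax, "text") or pairs for point tiers.
  vals <- txt[nzchar(txt)]
  vals <- vals[-(1:2)]                      # file type / object class
  unq <- function(s) gsub("^\"|\"$", "", s)
  i <- 1L
  i <- i + 2L                               # global xmin, xmax
  if (grepl("exists", vals[i])) i <- i + 1L
  n_tiers <- as.integer(vals[i]); i <- i + 1L
  tiers <- vector("list", n_tiers)
  for (t in seq_len(n_tiers)) {
    cls <- unq(vals[i]); nm <- unq(vals[i + 1L]); i <- i + 4L  # class,name,xmin,xmax
    n_item <- as.integer(vals[i]); i <- i + 1L
    if (identical(cls, "IntervalTier")) {
      xmin <- text <- vector("numeric", 0)
      for (k in seq_len(n_item)) {
        xmin <- c(xmin, as.numeric(vals[i]))
        text <- c(text, unq(vals[i + 2L]))
        i <- i + 3L
      }
      tiers[[t]] <- list(interval = TRUE, name = nm, xmin = xmin, text = text)
    } else {
      i <- i + 2L * n_item
      tiers[[t]] <- list(interval = FALSE, name = nm)
    }
  }
  tiers
}

#' Place a feature series on the epoch time base
#'
#' Zero-pads a sentence feature into the full -0.5..2.5 s epoch window
#' (768 samples at 256 Hz) with the sentence onset at sample 128 (0-based),
#' so features align sample-for-sample with the post-onset part of an epoch.
#'
#' @param fs A [feature_series()] at the epoch rate.
#' @param n_samples Epoch length in samples (default 768).
#' @param onset_sample 0-based index of the sentence onset (default 128).
#' @return A [feature_series()] of length `n_samples`.
#' @export
feature_on_epoch_grid <- function(fs, n_samples = 768L, onset_sample = 128L) {
  stopifnot(inherits(fs, "feature_series"))
  vals <- numeric(n_samples)
  n_fit <- min(length(fs$values), n_samples - onset_sample)
  if (n_fit > 0) {
    vals[(onset_sample + 1L):(onset_sample + n_fit)] <- fs$values[seq_len(n_fit)]
  }
  feature_series(vals, fs$rate, fs$kind, fs$sentence_id)
}
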