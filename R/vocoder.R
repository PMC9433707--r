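#' Logarithmically spaced analysis filter bank
#'
#' Designs the band edges of an `n_channels`-band filter bank with
#' geometrically (log-) spaced edges between `low_edge` and `high_edge`,
#' the spacing used to spectrally degrade speech with a noise vocoder.
#' Fewer bands means coarser spectral resolution and lower intelligibility.
#'
#' @param n_channels Number of analysis bands (>= 1).
#' @param low_edge,high_edge Lowest/highest band edge in Hz; defaults
#'   200-5000 Hz, the speech band used for vocoded sentence stimuli.
#' @return A `filterbank_spec`: list with `n_channels`, `low_edge`,
#'   `high_edge` and `band_edges` (length `n_channels + 1`, strictly
#'   increasing, constant ratio between consecutive edges).
#' @examples
#' design_log_filterbank(2)$band_edges   # 200 1000 5000
#' @export
design_log_filterbank <- function(n_channels, low_edge = 200, high_edge = 5000) {
  if (length(n_channels) != 1L || is.na(n_channels) || n_channels < 1 ||
      n_channels != round(n_channels)) {
    stopf("`n_channels` must be a positive integer, got %s", format(n_channels)[1])
  }
  if (!is.finite(low_edge) || !is.finite(high_edge) ||
      low_edge <= 0 || high_edge <= low_edge) {
    stopf("band edges must satisfy 0 < low_edge < high_edge (got %s, %s)",
          format(low_edge), format(high_edge))
  }
  edges <- exp(seq(log(low_edge), log(high_edge), length.out = n_channels + 1L))
  edges[1] <- low_edge
  edges[n_channels + 1L] <- high_edge
  structure(
    list(n_channels = as.integer(n_channels), low_edge = low_edge,
         high_edge = high_edge, band_edges = edges),
    class = "filterbank_spec"
  )
}

# 4th-order Butterworth band-pass (two second-order prototype sections),
# applied forward-backward for zero phase.
bandpass_zero_phase <- function(x, low, high, rate, order = 2L) {
  w <- c(low, high) / (rate / 2)
  w[2] <- min(w[2], 0.999)
  bf <- signal::butter(order, w, type = "pass")
  signal::filtfilt(bf, x)
}

# Full-wave rectification + zero-phase Butterworth low-pass; shared between
# the vocoder's band envelopes and the stimulus envelope feature.
rectify_lowpass <- function(x, rate, cutoff = 30) {
  if (cutoff >= rate / 2) {
    stopf("envelope cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, rate / 2)
  }
  lp <- signal::butter(4, cutoff / (rate / 2), type = "low")
  env <- signal::filtfilt(lp, abs(x))
  pmax(env, 0)   # clip zero-phase undershoot
}

#' Noise-vocode a speech waveform
#'
#' Classic noise vocoder: the input is split into log-spaced frequency bands,
#' each band's temporal envelope (full-wave rectification + low-pass) is
#' imposed on a band-limited Gaussian white-noise carrier, and the modulated
#' bands are summed. The result keeps per-band envelopes but destroys
#' spectral fine structure; output RMS is matched to the input.
#'
#' @param audio An [audio_waveform()]; its rate must be at least twice the
#'   filter bank's upper edge.
#' @param spec A [design_log_filterbank()] spec.
#' @param seed Integer seed for the noise carriers; identical
#'   `(audio, spec, seed)` gives bit-identical output.
#' @param env_cutoff Envelope low-pass cutoff in Hz (default 30).
#' @return An [audio_waveform()] of the same length and rate.
#' @export
noise_vocode <- function(audio, spec, seed = 1L, env_cutoff = 30) {
  stopifnot(inherits(audio, "audio_waveform"), inherits(spec, "filterbank_spec"))
  if (audio$rate < 2 * spec$high_edge) {
    stopf("audio rate %g Hz is below Nyquist for the %g Hz band edge",
          audio$rate, spec$high_edge)
  }
  x <- audio$samples
  n <- length(x)
  edges <- spec$band_edges
  out <- numeric(n)
  with_seed(seed, {
    for (b in seq_len(spec$n_channels)) {
      band <- bandpass_zero_phase(x, edges[b], edges[b + 1L], audio$rate)
      env <- rectify_lowpass(band, audio$rate, env_cutoff)
      carrier <- stats::rnorm(n)
      carrier <- bandpass_zero_phase(carrier, edges[b], edges[b + 1L], audio$rate)
      mod <- env * carrier
      # re-band-pass the modulated carrier to confine envelope sidebands
      mod <- bandpass_zero_phase(mod, edges[b], edges[b + 1L], audio$rate)
      out <- out + mod
    }
  })
  in_rms <- rms(x)
  out_rms <- rms(out)
  if (in_rms > 0 && out_rms > 0) out <- out * (in_rms / out_rms)
  audio_waveform(out, audio$rate)
}
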