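# Synthetic-study generator: speech-like stimuli, phoneme onsets,
# psychometric behavioral scores, and forward-modelled EEG epochs whose
# cortical tracking of the stimulus features scales with intelligibility.
# The generator emits the same objects the real-data path consumes, so the
# full pipeline is testable without access to the original recordings.

#' Synthetic study configuration
#'
#' Defaults reproduce the study conditions: 87 participants, 10 sentences
#' (duration 1.8 +/- 0.2 s, 17-22 phonemes each, mean 18.6, sd 3.9),
#' 100 repeats per sentence, vocoder conditions of 2/3/4/5/8 channels plus
#' natural speech, EEG at 256 Hz.
#'
#' @param n_subjects Number of participants (default 87).
#' @param conditions Vocoder channel counts; `Inf` denotes natural speech.
#' @param n_sentences Number of sentences (default 10).
#' @param sentence_duration `c(mean, sd)` seconds (default 1.8, 0.2),
#'   clipped to 1.2..2.4 s.
#' @param phonemes `c(mean, sd)` phonemes per sentence (default 18.6, 3.9),
#'   truncated to 17..22.
#' @param repeats Repeats per sentence (default 100).
#' @param rate EEG rate in Hz (default 256).
#' @param audio_rate Stimulus audio rate in Hz (default 16000).
#' @param seed Master seed; the whole study regenerates bit-identically.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 87L, conditions = c(2, 3, 4, 5, 8, Inf),
                         n_sentences = 10L, sentence_duration = c(1.8, 0.2),
                         phonemes = c(18.6, 3.9), repeats = 100L, rate = 256,
                         audio_rate = 16000, seed = 1L) {
  stopifnot(n_subjects >= 1, n_sentences >= 1, repeats >= 1,
            all(sentence_duration > 0), rate > 0, audio_rate > 0)
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 n_sentences = as.integer(n_sentences),
                 sentence_duration = sentence_duration, phonemes = phonemes,
                 repeats = as.integer(repeats), rate = rate,
                 audio_rate = audio_rate, seed = seed),
            class = "synth_config")
}

#' Psychometric parameters linking vocoder channels to intelligibility
#'
#' A logistic in `log2(channel count)` (natural speech enters as an
#' effective 16-channel spectrum), anchored so the 2-channel and natural
#' condition means sit near the published 7.5% and 99.6%. Subject-level
#' variability is Gaussian jitter on the logit.
#'
#' @param slope Logit slope per doubling of channel count.
#' @param intercept Logit value at 1 channel.
#' @param natural_equiv Effective channel count of natural speech (16).
#' @param jitter_sd Subject-level logit jitter SD (default 1.0).
#' @param cell_sd Extra per-cell logit noise SD (default 0.3).
#' @param fixed_levels Optional map `condition index -> score`: overrides
#'   the logistic entirely (used by the scaled profile to pin exact class
#'   levels).
#' @return A `psychometric_params` list.
#' @export
psychometric_params <- function(slope = NULL, intercept = NULL,
                                natural_equiv = 16, jitter_sd = 1.0,
                                cell_sd = 0.3, fixed_levels = NULL) {
  if (is.null(slope) || is.null(intercept)) {
    # anchor: mean 7.5% at 2 channels, 99.6% for natural (16-equivalent)
    b <- (stats::qlogis(0.996) - stats::qlogis(0.075)) /
      (log2(natural_equiv) - log2(2))
    a <- stats::qlogis(0.075) - b * log2(2)
    if (is.null(slope)) slope <- b
    if (is.null(intercept)) intercept <- a
  }
  if (slope < 0) stopf("slope must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 natural_equiv = natural_equiv, jitter_sd = jitter_sd,
                 cell_sd = cell_sd, fixed_levels = fixed_levels),
            class = "psychometric_params")
}

#' Forward-model parameters for synthetic EEG
#'
#' Each epoch is `s(score) * (g_env * (kernel %*% ENV) + g_ph *
#' (kernel %*% PH))` on the informative channels plus 1/f background noise
#' everywhere, where `s(score) = score / 100` and the kernel is a biphasic
#' gamma-difference impulse response (latency ~100 ms).
#'
#' @param tracking_gain_env,tracking_gain_ph Response amplitudes in
#'   microvolts RMS at score 100 (defaults 2 and 2, chosen so single-trial
#'   feature-tracking correlations land near 0.15-0.25 against the 10 uV
#'   background, the upper range reported for envelope tracking).
#' @param informative_channels Labels carrying the response; default is a
#'   12-channel left temporal/centro-parietal block (contiguous in montage
#'   row order, mimicking the regional clustering of real tracking
#'   responses).
#' @param noise_exponent 1/f^a noise slope (default 1).
#' @param noise_scale Background noise RMS in microvolts (default 10).
#' @param kernel_latency,kernel_width Kernel latency and width in seconds.
#' @return A `forward_params` list.
#' @export
forward_params <- function(tracking_gain_env = 2, tracking_gain_ph = 2,
                           informative_channels = c(
                             "C1", "C3", "C5", "T7", "TP7", "CP5",
                             "CP3", "CP1", "P1", "P3", "P5", "P7"),
                           noise_exponent = 1, noise_scale = 10,
                           kernel_latency = 0.1, kernel_width = 0.08) {
  stopifnot(tracking_gain_env >= 0, tracking_gain_ph >= 0, noise_scale >= 0)
  structure(list(tracking_gain_env = tracking_gain_env,
                 tracking_gain_ph = tracking_gain_ph,
                 informative_channels = informative_channels,
                 noise_exponent = noise_exponent, noise_scale = noise_scale,
                 kernel_latency = kernel_latency, kernel_width = kernel_width),
            class = "forward_params")
}

#' Biphasic cortical response kernel
#'
#' Gamma-difference impulse response: a positive lobe peaking at `latency`
#' followed by a weaker negative rebound, normalized to unit peak.
#'
#' @param rate Sampling rate in Hz.
#' @param latency Peak latency in seconds (default 0.1).
#' @param width Lobe width parameter in seconds (default 0.08).
#' @return Numeric kernel (0..0.4 s support).
#' @export
response_kernel <- function(rate = 256, latency = 0.1, width = 0.08) {
  t <- seq(0, 0.4, by = 1 / rate)
  k1 <- 4
  h <- stats::dgamma(t, shape = k1, scale = latency / (k1 - 1)) -
    0.5 * stats::dgamma(t, shape = k1, scale = (latency + width) / (k1 - 1))
  h / max(abs(h))
}

# 1/f^a noise, one column per channel, each column scaled to unit RMS.
colored_noise_matrix <- function(n_samples, n_channels, exponent = 1) {
  wh <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
  fz <- stats::mvfft(wh)
  f <- c(0, seq_len(n_samples - 1))
  f <- pmin(f, n_samples - f)                     # two-sided frequency index
  shp <- ifelse(f == 0, 0, f^(-exponent / 2))
  x <- Re(stats::mvfft(fz * shp, inverse = TRUE)) / n_samples
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

#' Generate one synthetic sentence (audio + phoneme onsets)
#'
#' Amplitude-modulated pink-noise "speech": a 1/f carrier with syllabic
#' (3-6 Hz) modulation and a small energy burst at each phoneme onset.
#' Onset count follows the truncated 17..22 phoneme distribution; duration
#' is drawn from N(1.8, 0.2^2) clipped to 1.2..2.4 s.
#'
#' @param cfg A [synth_config()].
#' @param sentence_id Sentence identifier.
#' @param seed RNG seed.
#' @return List with `audio` ([audio_waveform()]) and `onsets`
#'   ([phoneme_onsets()]).
#' @export
gen_sentence <- function(cfg = synth_config(), sentence_id = "s01", seed = 1L) {
  with_seed(seed, {
    dur <- min(2.4, max(1.2, stats::rnorm(1, cfg$sentence_duration[1],
                                          cfg$sentence_duration[2])))
    n <- round_half_away(dur * cfg$audio_rate)
    t <- (seq_len(n) - 1) / cfg$audio_rate
    carrier <- colored_noise_matrix(n, 1L, exponent = 1)[, 1]
    syl_rate <- stats::runif(1, 3, 6)
    am <- 0.5 * (1 - cos(2 * pi * syl_rate * t + stats::runif(1, 0, 2 * pi)))
    n_ph <- min(22L, max(17L, as.integer(round_half_away(
      stats::rnorm(1, cfg$phonemes[1], cfg$phonemes[2])))))
    span <- c(0.05, dur - 0.15)
    base <- seq(span[1], span[2], length.out = n_ph)
    gap <- diff(span) / n_ph
    on <- base + stats::runif(n_ph, -0.3, 0.3) * gap
    on <- sort(on)
    on <- pmin(pmax(on, span[1]), span[2])
    while (any(diff(on) <= 1e-3)) on[which(diff(on) <= 1e-3) + 1L] <- on[which(diff(on) <= 1e-3) + 1L] + 1e-3
    burst <- numeric(n)
    for (o in on) {
      win <- max(1L, round((o - 0.06) * cfg$audio_rate)):
        min(n, round((o + 0.06) * cfg$audio_rate))
      burst[win] <- burst[win] + exp(-0.5 * ((t[win] - o) / 0.015)^2)
    }
    x <- carrier * (am + 0.5 * burst)
    x <- 0.9 * x / max(abs(x))
    list(audio = audio_waveform(x, cfg$audio_rate),
         onsets = phoneme_onsets(on, sentence_id))
  })
}

#' Generate behavioral scores for every participant x condition
#'
#' Scores follow the psychometric logistic with subject jitter, snapped to
#' the allowed 2.5-step grid (the three never-observed levels 30.0, 37.5
#' and 40.0 map to their nearest allowed neighbour). With
#' `psych$fixed_levels` set, condition `j` deterministically receives
#' `fixed_levels[j]`.
#'
#' @param cfg A [synth_config()].
#' @param psych A [psychometric_params()].
#' @param seed RNG seed.
#' @return data.frame with `participant`, `condition`, `channels`, `score`.
#' @export
gen_behavioral_scores <- function(cfg = synth_config(),
                                  psych = psychometric_params(), seed = 1L) {
  conds <- cfg$conditions
  cond_id <- ifelse(is.finite(conds), paste0("voc", conds), "natural")
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(cfg$n_subjects)) {
      subj <- sprintf("S%02d", s)
      jit <- stats::rnorm(1, 0, psych$jitter_sd)
      for (j in seq_along(conds)) {
        if (!is.null(psych$fixed_levels)) {
          sc <- psych$fixed_levels[j]
        } else {
          xch <- if (is.finite(conds[j])) conds[j] else psych$natural_equiv
          lg <- psych$intercept + psych$slope * log2(xch) + jit +
            stats::rnorm(1, 0, psych$cell_sd)
          sc <- snap_to_score_grid(100 * stats::plogis(lg))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          participant = subj, condition = cond_id[j], channels = conds[j],
          score = sc)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate forward-modelled EEG epoch pools
#'
#' For each participant x condition cell, builds `repeats * n_sentences`
#' epochs: the stimulus-locked response (response kernel convolved with the
#' sentence's ENV and PH features, each normalized to unit RMS over the
#' sentence span and scaled by its tracking gain and by
#' `s(score) = score / 100`) on the informative channels, plus 1/f noise on
#' all 64 channels. Epochs are 64 x 768 with the sentence onset at sample
#' 128.
#'
#' @param cfg A [synth_config()].
#' @param fm A [forward_params()].
#' @param features Named list `sentence_id -> list(ENV =, PH =)` of
#'   [feature_series()] on the epoch grid (see [synth_study()]).
#' @param scores data.frame from [gen_behavioral_scores()].
#' @param seed RNG seed.
#' @param lazy If TRUE (default) pools materialize on demand, keeping
#'   memory bounded; the draw is still deterministic per pool.
#' @return Named list (`participant|condition`) of [epoch_pool()] objects;
#'   each pool's epoch array carries a `sentence_ids` attribute.
#' @export
gen_eeg_epochs <- function(cfg = synth_config(), fm = forward_params(),
                           features, scores, seed = 1L, lazy = TRUE) {
  labels <- montage_labels()
  w_ch <- as.numeric(labels %in% fm$informative_channels)
  if (sum(w_ch) != length(fm$informative_channels)) {
    stopf("unknown informative channel(s): %s",
          paste(setdiff(fm$informative_channels, labels), collapse = ", "))
  }
  n_samp <- 768L
  onset <- 128L
  kern <- response_kernel(cfg$rate, fm$kernel_latency, fm$kernel_width)
  sids <- names(features)
  if (is.null(sids)) stopf("features must be a named list keyed by sentence_id")
  resp <- lapply(features, function(fl) {
    r <- numeric(n_samp)
    for (kind in c("ENV", "PH")) {
      f <- fl[[kind]]
      if (is.null(f)) stopf("features need ENV and PH per sentence")
      v <- if (inherits(f, "feature_series")) f$values else as.numeric(f)
      if (length(v) != n_samp) stopf("features must be on the 768-sample epoch grid")
      conv <- stats::convolve(v, rev(kern), type = "open")[seq_len(n_samp)]
      act <- conv[(onset + 1L):n_samp]
      s_rms <- rms(act)
      if (s_rms > 0) conv <- conv / s_rms
      gain <- if (kind == "ENV") fm$tracking_gain_env else fm$tracking_gain_ph
      r <- r + gain * conv
    }
    r
  })
  pool_factory <- function(pool_seed, sgain, sentence_seq, n_ep) {
    force(pool_seed); force(sgain); force(sentence_seq); force(n_ep)
    function() {
      sig_by_sid <- lapply(resp, function(r) outer(w_ch, sgain * r))
      arr <- array(0, dim = c(64L, n_samp, n_ep))
      chunk <- 16L
      with_seed(pool_seed, {
        for (e0 in seq(1L, n_ep, by = chunk)) {
          e1 <- min(n_ep, e0 + chunk - 1L)
          k <- e1 - e0 + 1L
          noise <- fm$noise_scale *
            colored_noise_matrix(n_samp, 64L * k, fm$noise_exponent)
          blk <- aperm(array(noise, c(n_samp, 64L, k)), c(2L, 1L, 3L))
          for (e in e0:e1) {
            arr[, , e] <- blk[, , e - e0 + 1L] + sig_by_sid[[sentence_seq[e]]]
          }
        }
      })
      attr(arr, "sentence_ids") <- sentence_seq
      arr
    }
  }
  pools <- list()
  for (i in seq_len(nrow(scores))) {
    subj <- scores$participant[i]
    cond <- scores$condition[i]
    score <- scores$score[i]
    key <- paste(subj, cond, sep = "|")
    n_ep <- cfg$repeats * cfg$n_sentences
    make_arr <- pool_factory(child_seed(seed, i), score / 100,
                             rep(sids, times = cfg$repeats), n_ep)
    pools[[key]] <- epoch_pool(
      if (lazy) make_arr else make_arr(), score = score,
      participant_id = subj, condition_id = cond, n_epochs = n_ep)
  }
  pools
}

#' Generate a complete synthetic study
#'
#' Orchestrates [gen_sentence()], feature extraction on the epoch grid,
#' [gen_behavioral_scores()] and [gen_eeg_epochs()]. Everything derives
#' deterministically from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param fm A [forward_params()].
#' @param psych A [psychometric_params()].
#' @param lazy Materialize epoch pools on demand (default TRUE).
#' @return List with `config`, `sentences` (audio + onsets), `features`
#'   (per sentence: ENV/PH/PHENV on the epoch grid), `scores`, `pools`,
#'   and `sentence_ids` (per pool, for [bootstrap_dataset()]).
#' @export
synth_study <- function(cfg = synth_config(), fm = forward_params(),
                        psych = psychometric_params(), lazy = TRUE) {
  sids <- sprintf("s%02d", seq_len(cfg$n_sentences))
  sentences <- lapply(seq_along(sids), function(i) {
    gen_sentence(cfg, sids[i], seed = child_seed(cfg$seed, 1000 + i))
  })
  names(sentences) <- sids
  features <- lapply(sentences, function(sn) {
    dur <- audio_duration(sn$audio)
    env <- extract_envelope(sn$audio, out_rate = cfg$rate,
                            sentence_id = sn$onsets$sentence_id)
    ph <- onset_impulse_train(sn$onsets, dur, cfg$rate)
    phenv <- phenv_product(env, ph)
    list(ENV = feature_on_epoch_grid(env),
         PH = feature_on_epoch_grid(ph),
         PHENV = feature_on_epoch_grid(phenv))
  })
  scores <- gen_behavioral_scores(cfg, psych, seed = child_seed(cfg$seed, 2))
  pools <- gen_eeg_epochs(cfg, fm, features, scores,
                          seed = child_seed(cfg$seed, 3), lazy = lazy)
  sentence_ids <- lapply(pools, function(p) rep(names(features), cfg$repeats))
  list(config = cfg, sentences = sentences, features = features,
       scores = scores, pools = pools, sentence_ids = sentence_ids)
}

#' Scaled study profile
#'
#' A desk-scale profile: 8 subjects, 20 repeats, and 5 conditions pinned to
#' the score levels 0, 25, 50, 75, 100 (5 distinct classes), for CPU-sized
#' end-to-end experiments.
#'
#' @param seed Master seed.
#' @param n_subjects,repeats Overrides (defaults 8 and 20).
#' @return List with `cfg` and `psych` to pass to [synth_study()].
#' @export
synth_scaled_profile <- function(seed = 1L, n_subjects = 8L, repeats = 20L) {
  list(cfg = synth_config(n_subjects = n_subjects,
                          conditions = c(2, 3, 4, 5, Inf),
                          repeats = repeats, seed = seed),
       psych = psychometric_params(fixed_levels = c(0, 25, 50, 75, 100)))
}

#' Extract per-pool feature vectors for a CSEP kind
#'
#' Convenience accessor: maps the `features` field of [synth_study()] to
#' the flat `sentence_id -> vector` list [bootstrap_dataset()] expects.
#'
#' @param study A [synth_study()] result.
#' @param kind `"ENV"`, `"PH"` or `"PHENV"`.
#' @return Named list of numeric vectors.
#' @export
study_features <- function(study, kind = c("ENV", "PH", "PHENV")) {
  kind <- match.arg(kind)
  lapply(study$features, function(fl) fl[[kind]])
}

#' Write a synthetic study to disk in the real-data formats
#'
#' Emits one WAV + onset TSV per sentence and a behavioral score CSV, so
#' synthetic stimuli are interchangeable with recorded ones.
#'
#' @param study A [synth_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(study$sentences)) {
    sn <- study$sentences[[sid]]
    write_wav(sn$audio, file.path(dir, paste0(sid, ".wav")))
    writeLines(format(sn$onsets$onsets, digits = 6),
               file.path(dir, paste0(sid, "_onsets.tsv")))
  }
  utils::write.csv(study$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  invisible(dir)
}
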