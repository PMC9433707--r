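small_cfg <- function(seed = 1) synth_config(n_subjects = 2,
                                             conditions = c(2, Inf),
                                             n_sentences = 2, repeats = 2,
                                             seed = seed)

test_that("synthetic sentences respect the phoneme and duration bounds", {
  counts <- durs <- numeric(60)
  for (i in 1:60) {
    sn <- gen_sentence(synth_config(), sprintf("s%02d", i), seed = i)
    counts[i] <- length(sn$onsets$onsets)
    durs[i] <- length(sn$audio$samples) / sn$audio$rate
  }
  expect_true(all(counts >= 17 & counts <= 22))
  expect_true(all(durs >= 1.2 & durs <= 2.4))

  a <- gen_sentence(synth_config(), "s01", seed = 5)
  b <- gen_sentence(synth_config(), "s01", seed = 5)
  expect_identical(a$audio$samples, b$audio$samples)
  expect_identical(a$onsets$onsets, b$onsets$onsets)
})

test_that("mean sentence duration matches the target distribution", {
  # durations drawn in gen_sentence follow clipped N(1.8, 0.2^2); check the
  # sample mean over many draws against a CLT band
  durs <- vapply(1:500, function(i) {
    length(gen_sentence(synth_config(n_sentences = 1), "s", seed = 10000 + i
                        )$audio$samples) / 16000
  }, 0)
  expect_lt(abs(mean(durs) - 1.8), 0.03)
})

test_that("behavioral scores stay on the allowed grid and match the anchors", {
  sc <- gen_behavioral_scores(synth_config(), seed = 3)
  expect_true(all(sc$score %in% score_levels()))
  expect_false(any(sc$score %in% c(30, 37.5, 40)))
  m2 <- mean(sc$score[sc$condition == "voc2"])
  mn <- mean(sc$score[sc$condition == "natural"])
  expect_lt(abs(m2 - 7.5), 5)
  expect_lt(abs(mn - 99.6), 5)
  # condition means are ordered by spectral resolution
  means <- tapply(sc$score, sc$condition, mean)
  expect_true(means["voc2"] < means["voc3"] & means["voc3"] < means["voc4"] &
                means["voc4"] < means["voc5"] & means["voc5"] < means["voc8"])
})

test_that("a flat psychometric function gives one shared condition mean", {
  psych0 <- psychometric_params(slope = 0, intercept = 0, jitter_sd = 0,
                                cell_sd = 0)
  sc <- gen_behavioral_scores(synth_config(n_subjects = 4), psych0, seed = 1)
  expect_length(unique(sc$score), 1L)
})

test_that("fixed score levels pin each condition to its class", {
  prof <- synth_scaled_profile(seed = 2, n_subjects = 2, repeats = 2)
  sc <- gen_behavioral_scores(prof$cfg, prof$psych, seed = 2)
  got <- tapply(sc$score, sc$condition, unique)
  expect_setequal(unlist(got), c(0, 25, 50, 75, 100))
})

test_that("noiseless zero-score epochs are exactly zero", {
  cfg <- small_cfg()
  prof_psych <- psychometric_params(fixed_levels = c(0, 0))
  study <- synth_study(cfg, forward_params(noise_scale = 0),
                       psych = prof_psych)
  arr <- csepnet:::materialize_pool(study$pools[[1]])
  expect_equal(max(abs(arr)), 0)
})

test_that("epoch pools regenerate bit-identically from the study seed", {
  s1 <- synth_study(small_cfg(7))
  s2 <- synth_study(small_cfg(7))
  expect_identical(s1$scores, s2$scores)
  expect_identical(csepnet:::materialize_pool(s1$pools[[2]]),
                   csepnet:::materialize_pool(s2$pools[[2]]))
  expect_true(all(vapply(s1$scores$score, function(s)
    any(vapply(s1$pools, function(p) p$score == s, TRUE)), TRUE)))
})

test_that("CSEP peak correlation rises with the score", {
  run_study <- function(noise) {
    cfg <- synth_config(n_subjects = 1, conditions = c(2, 3, 4, 5, 8),
                        n_sentences = 2, repeats = 10, seed = 4)
    synth_study(cfg, forward_params(noise_scale = noise),
                psych = psychometric_params(
                  fixed_levels = c(0, 25, 50, 75, 100)))
  }
  inf_rows <- which(montage_labels() %in%
                      forward_params()$informative_channels)
  # mean over informative channels of each channel's peak |r| in the
  # epoch-averaged CSEP
  peaks_of <- function(study) {
    feats <- lapply(study_features(study, "ENV"), function(f) f$values)
    p <- vapply(study$pools, function(p) {
      arr <- csepnet:::materialize_pool(p)
      sids <- attr(arr, "sentence_ids")
      acc <- 0
      for (e in seq_len(dim(arr)[3])) {
        acc <- acc + xcorr_matrix(arr[, , e], feats[[sids[e]]])
      }
      mean(apply(abs(acc[inf_rows, ] / dim(arr)[3]), 1, max))
    }, 0)
    scores <- vapply(study$pools, function(p) p$score, 0)
    unname(p[order(scores)])
  }
  # without noise, Pearson correlation is scale-invariant: the score-0 pool
  # is silent and every non-zero score attains the same (high) peak
  clean <- peaks_of(run_study(0))
  expect_equal(clean[1], 0)
  expect_true(all(clean[-1] > 0.5))
  expect_lt(max(clean[-1]) - min(clean[-1]), 1e-12)
  # against a fixed noise background the peak grows monotonically with the
  # score, because the signal-to-noise ratio does
  noisy <- peaks_of(run_study(10))
  expect_true(all(diff(noisy) > 0))
})

test_that("non-informative channels carry no feature-locked signal", {
  cfg <- synth_config(n_subjects = 1, conditions = c(8), n_sentences = 2,
                      repeats = 10, seed = 5)
  study <- synth_study(cfg, psych = psychometric_params(fixed_levels = 100))
  feats <- lapply(study_features(study, "ENV"), function(f) f$values)
  arr <- csepnet:::materialize_pool(study$pools[[1]])
  sids <- attr(arr, "sentence_ids")
  inf_rows <- which(montage_labels() %in%
                      forward_params()$informative_channels)
  n_ep <- dim(arr)[3]
  acc <- 0
  for (e in seq_len(n_ep)) {
    acc <- acc + xcorr_matrix(arr[, , e], feats[[sids[e]]])
  }
  acc <- acc / n_ep                        # signed average: noise cancels
  # null with the feature's time-locking broken but its autocorrelation
  # kept: random circular shifts (a plain sample shuffle whitens the
  # envelope and would understate the by-chance correlation level)
  withr::local_seed(6)
  null_means <- vapply(1:20, function(i) {
    sh <- sample(100:668, 1)
    f1 <- feats[[sids[1]]]
    f1 <- c(f1[(sh + 1):768], f1[1:sh])
    nacc <- 0
    for (e in seq_len(n_ep)) {
      nacc <- nacc + xcorr_matrix(arr[1:8, , e], f1)
    }
    mean(abs(nacc / n_ep))
  }, 0)
  q95 <- stats::quantile(null_means, 0.95)
  expect_lt(mean(abs(acc[-inf_rows, ])), q95 * 1.2)
  # informative channels clearly exceed the by-chance level
  expect_gt(mean(abs(acc[inf_rows, ])), q95 * 1.5)
})

test_that("the study emits interchangeable on-disk formats", {
  study <- synth_study(small_cfg(9))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "s01.wav")))
  wav <- read_wav(file.path(dir, "s01.wav"))
  expect_equal(wav$samples, study$sentences$s01$audio$samples,
               tolerance = 1e-6)
  on <- read_onsets(file.path(dir, "s01_onsets.tsv"))
  expect_equal(on$onsets, study$sentences$s01$onsets$onsets, tolerance = 1e-5)
  sc <- utils::read.csv(file.path(dir, "scores.csv"))
  expect_equal(nrow(sc), nrow(study$scores))
})
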