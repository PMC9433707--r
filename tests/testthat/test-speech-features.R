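test_that("envelope extraction follows the rectify + low-pass contract", {
  z <- audio_waveform(numeric(16000), 16000)
  env <- extract_envelope(z, out_rate = 256)
  expect_equal(env$values, numeric(256))
  expect_equal(env$kind, "ENV")

  # unit 1 kHz sine: mean of |sin| is 2/pi, which a 30 Hz low-pass recovers
  t <- (0:31999) / 16000
  sine <- audio_waveform(sin(2 * pi * 1000 * t), 16000)
  env2 <- extract_envelope(sine, out_rate = 256)
  interior <- env2$values[100:400]
  expect_true(all(abs(interior - 2 / pi) < 0.05 * 2 / pi))

  # resampling length contract at a non-integer duration
  a <- audio_waveform(stats::rnorm(17311), 16000)
  expect_length(extract_envelope(a, out_rate = 256)$values,
                round(17311 / 16000 * 256))
  expect_error(extract_envelope(a, cutoff = 9000), "Nyquist")
})

test_that("onset impulse train places unit impulses at rounded samples", {
  tr <- onset_impulse_train(c(0.1, 0.5), duration = 1.8, rate = 256)
  expect_length(tr$values, round(1.8 * 256))
  expect_equal(which(tr$values == 1) - 1L, c(26L, 128L))  # 0-based samples
  expect_equal(sum(tr$values), 2)

  expect_equal(onset_impulse_train(numeric(0), 1, 256)$values, numeric(256))
  expect_error(onset_impulse_train(c(0.1, 2.0), duration = 1.8),
               "2 s is at or beyond")
})

test_that("PHENV is the element-wise product with the expected support", {
  env <- feature_series(seq(0, 1, length.out = 256), 256, "ENV")
  ph0 <- feature_series(numeric(256), 256, "PH")
  expect_equal(phenv_product(env, ph0)$values, numeric(256))

  ph <- onset_impulse_train(c(0.2, 0.7), 1, 256)
  pe <- phenv_product(env, ph)
  expect_equal(pe$kind, "PHENV")
  on_idx <- which(ph$values == 1)
  expect_equal(pe$values[on_idx], env$values[on_idx])
  expect_true(all(pe$values[-on_idx] == 0))
  expect_lte(sum(pe$values != 0), sum(ph$values))
  expect_equal(sum(pe$values), sum(env$values[on_idx]))

  short_ph <- feature_series(c(1, numeric(99)), 256, "PH")
  expect_error(phenv_product(env, short_ph), "not aligned")
})

test_that("onsets load from TSV, sorted and deduplicated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0.50", "0.10", "0.50"), f)
  on <- read_onsets(f)
  expect_equal(on$onsets, c(0.1, 0.5))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0.1", "oops"), bad)
  expect_error(read_onsets(bad), "line 2")
})

test_that("onsets load from long- and short-form TextGrids", {
  long_tg <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", "xmax = 0.5", "tiers? <exists>", "size = 1", "item []:",
    "    item [1]:", '        class = "IntervalTier"',
    '        name = "phonemes"', "        xmin = 0", "        xmax = 0.5",
    "        intervals: size = 3",
    "        intervals [1]:", "            xmin = 0",
    "            xmax = 0.1", '            text = ""',
    "        intervals [2]:", "            xmin = 0.1",
    "            xmax = 0.3", '            text = "k"',
    "        intervals [3]:", "            xmin = 0.3",
    "            xmax = 0.5", '            text = "a"')
  f1 <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(long_tg, f1)
  expect_equal(read_onsets(f1)$onsets, c(0.1, 0.3))

  short_tg <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "0", "0.5", "<exists>", "1",
    '"IntervalTier"', '"phones"', "0", "0.5", "3",
    "0", "0.1", '""',
    "0.1", "0.3", '"k"',
    "0.3", "0.5", '"a"')
  f2 <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(short_tg, f2)
  expect_equal(read_onsets(f2)$onsets, c(0.1, 0.3))
})

test_that("features align on the epoch grid with onset at sample 128", {
  ph <- onset_impulse_train(0.0, duration = 1, rate = 256)
  g <- feature_on_epoch_grid(ph)
  expect_length(g$values, 768)
  expect_equal(which(g$values == 1) - 1L, 128L)
  expect_true(all(g$values[1:128] == 0))
})

test_that("envelope of a concatenation matches concatenated envelopes interiorly", {
  a <- make_speech_like(dur = 0.5, seed = 11)
  b <- make_speech_like(dur = 0.5, seed = 12)
  ab <- audio_waveform(c(a$samples, b$samples), a$rate)
  e_ab <- extract_envelope(ab, out_rate = 256)$values
  e_a <- extract_envelope(a, out_rate = 256)$values
  e_b <- extract_envelope(b, out_rate = 256)$values
  n <- length(e_a)
  guard <- 20   # samples near the junction affected by the filter
  interior_a <- seq_len(n - guard)
  expect_equal(e_ab[interior_a], e_a[interior_a], tolerance = 1e-2)
  interior_b <- (guard + 1):length(e_b)
  expect_equal(e_ab[n + interior_b], e_b[interior_b], tolerance = 1e-2)
})
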