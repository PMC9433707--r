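# A short synthetic recording with events, at a higher rate for resampling.
make_recording <- function(rate = 1024, dur = 12, n_events = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- rate * dur
    data <- matrix(stats::rnorm(64 * n, sd = 5), 64, n)
    ev_samples <- as.integer(seq(rate * 2, rate * (dur - 4), length.out = n_events))
    eeg_recording(data, rate, events = data.frame(
      sample = ev_samples,
      sentence_id = paste0("s", seq_len(n_events)),
      condition_id = "voc8"))
  })
}

test_that("preprocessing resamples, re-references and rescales events", {
  rec <- make_recording()
  out <- preprocess_eeg(rec, target_rate = 256, band = c(1, 57))
  expect_equal(out$rate, 256)
  expect_lte(abs(ncol(out$data) - ncol(rec$data) / 4), 1)
  expect_equal(out$events$sample, floor((rec$events$sample - 1L) / 4) + 1L)
  # average reference: per-sample channel mean is zero
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # channel order preserved
  expect_equal(out$channel_labels, montage_labels())
})

test_that("the FIR design attenuates 0.1 Hz drift by at least 20 dB", {
  b <- design_fir_bandpass(256, c(1, 57))
  resp <- csepnet:::fir_response(b, c(0.1, 10, 30), 256)
  expect_lt(20 * log10(resp[1]), -20)
  expect_equal(resp[2], 1, tolerance = 0.01)   # passband flat
  expect_equal(resp[3], 1, tolerance = 0.01)
})

test_that("band edges at or above Nyquist are rejected", {
  rec <- make_recording(rate = 256, dur = 8)
  expect_error(preprocess_eeg(rec, 256, band = c(1, 128)), "Nyquist")
  expect_error(preprocess_eeg(rec, 512), "exceeds")
})

test_that("filtering and average referencing commute", {
  withr::local_seed(2)
  data <- matrix(stats::rnorm(8 * 3000), 8, 3000)
  b <- design_fir_bandpass(256, c(1, 57))
  filt <- function(m) t(apply(m, 1, csepnet:::apply_fir_zero_phase, b = b))
  reref <- function(m) sweep(m, 2, colMeans(m))
  expect_equal(filt(reref(data)), reref(filt(data)), tolerance = 1e-6)
})

test_that("epoching yields 768-sample epochs and skips out-of-bounds events", {
  rec <- make_recording(rate = 256, dur = 12)
  epochs <- extract_epochs(rec, participant_id = "S01")
  expect_length(epochs, 2L)
  expect_equal(dim(epochs[[1]]$data), c(64L, 768L))
  expect_equal(epochs[[1]]$t0, -0.5)
  expect_equal(epochs[[1]]$participant_id, "S01")

  none <- eeg_recording(matrix(0, 64, 1000), 256)
  expect_length(extract_epochs(none), 0L)

  early <- eeg_recording(matrix(0, 64, 1000), 256, events = data.frame(
    sample = 128L, sentence_id = "s1", condition_id = "c"))
  expect_message(ep <- extract_epochs(early), "skipping")
  expect_length(ep, 0L)
})

test_that("epoch-then-filter agrees with filter-then-epoch away from edges", {
  withr::local_seed(3)
  ev <- 2048L
  data <- matrix(stats::rnorm(8 * 4096, sd = 5), 8, 4096)
  rec <- eeg_recording(data, 256, events = data.frame(
    sample = ev, sentence_id = "s1", condition_id = "voc8"))
  b <- design_fir_bandpass(256, c(1, 57))
  filtered <- rec
  filtered$data <- t(apply(rec$data, 1, csepnet:::apply_fir_zero_phase, b = b))
  ep_after <- extract_epochs(filtered)[[1]]$data
  # filter the raw epoch plus generous context, then cut the same window
  ctx <- (ev - 1500):(ev + 1500)
  seg <- t(apply(rec$data[, ctx], 1, csepnet:::apply_fir_zero_phase, b = b))
  ep_direct <- seg[, (1500 - 128 + 1):(1500 + 640)]
  expect_equal(ep_after, ep_direct, tolerance = 1e-4)
})

test_that("artifact rejection drops only epochs beyond the threshold", {
  clean <- replicate(3, eeg_epoch(matrix(stats::rnorm(64 * 768, sd = 10), 64, 768)),
                     simplify = FALSE)
  expect_length(reject_artifacts(clean, 150), 3L)

  spike <- clean
  spike[[2]]$data[5, 100] <- 500
  expect_message(kept <- reject_artifacts(spike, 100), "rejected 1 of 3")
  expect_length(kept, 2L)
  expect_length(reject_artifacts(spike, Inf), 3L)
  expect_error(reject_artifacts(clean, -1), "positive")
})

test_that("matrix + YAML sidecar recordings round-trip", {
  withr::local_seed(4)
  data <- matrix(stats::rnorm(64 * 500), 64, 500)
  dat_f <- withr::local_tempfile(fileext = ".bin")
  writeBin(as.vector(data), dat_f, size = 4, endian = "little")
  yaml::write_yaml(list(
    rate = 256, dtype = "float32", labels = as.list(montage_labels()),
    events = list(list(sample = 200, sentence_id = "s1", condition_id = "voc2"))),
    paste0(dat_f, ".yaml"))
  rec <- read_eeg_matrix(dat_f)
  expect_equal(rec$rate, 256)
  expect_equal(rec$data, data, tolerance = 1e-6)
  expect_equal(rec$events$sentence_id, "s1")
})

test_that("EDF recordings written by an independent writer load correctly", {
  # minimal EDF writer following the published header layout
  write_edf <- function(path, data, rate, labels, pmin, pmax) {
    con <- file(path, "wb")
    on.exit(close(con))
    pad <- function(x, n) {
      s <- formatC(as.character(x), width = -n)
      writeChar(substr(s, 1, n), con, eos = NULL)
    }
    ns <- nrow(data)
    n_rec <- ncol(data) / rate
    pad("0", 8); pad("patient", 80); pad("recording", 80)
    pad("01.01.20", 8); pad("00.00.00", 8)
    pad(256 + 256 * ns, 8); pad("", 44); pad(n_rec, 8); pad(1, 8); pad(ns, 4)
    for (l in labels) pad(l, 16)
    for (i in 1:ns) pad("", 80)
    for (i in 1:ns) pad("uV", 8)
    for (i in 1:ns) pad(pmin, 8)
    for (i in 1:ns) pad(pmax, 8)
    for (i in 1:ns) pad(-32768, 8)
    for (i in 1:ns) pad(32767, 8)
    for (i in 1:ns) pad("", 80)
    for (i in 1:ns) pad(rate, 8)
    for (i in 1:ns) pad("", 32)
    gain <- (pmax - pmin) / 65535
    for (r in seq_len(n_rec)) {
      for (s in seq_len(ns)) {
        seg <- data[s, ((r - 1) * rate + 1):(r * rate)]
        writeBin(as.integer(round((seg - pmin) / gain) - 32768), con,
                 size = 2, endian = "little")
      }
    }
  }
  withr::local_seed(5)
  data <- matrix(stats::rnorm(4 * 512, sd = 20), 4, 512)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(f, data, 256, c("Fz", "Cz", "Pz", "Oz"), -200, 200)
  rec <- read_edf(f)
  expect_equal(rec$rate, 256)
  expect_equal(rec$channel_labels, c("Fz", "Cz", "Pz", "Oz"))
  expect_equal(rec$data, data, tolerance = 0.02)
})

test_that("events CSV loads with the expected columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,sentence_id,condition_id", "512,s01,voc2"), f)
  ev <- read_events_csv(f)
  expect_equal(ev$sample, 512L)
  expect_error(read_events_csv({
    g <- withr::local_tempfile(fileext = ".csv")
    writeLines("a,b", g); g
  }), "expected columns")
})
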