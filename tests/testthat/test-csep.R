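test_that("the score grid has 38 allowed levels with rank class indices", {
  lv <- score_levels()
  expect_length(lv, 38L)
  expect_length(seq(0, 100, by = 2.5), 41L)
  expect_false(any(c(30, 37.5, 40) %in% lv))
  expect_equal(score_label(0)$class_index, 0L)
  expect_equal(score_label(100)$class_index, 37L)
  expect_equal(score_label(32.5)$class_index, match(32.5, lv) - 1L)
  expect_error(score_label(30), "not on the allowed")
  expect_error(score_label(1.3), "not on the allowed")
  expect_equal(snap_to_score_grid(c(29.9, 41, 99.2)), c(27.5, 42.5, 100))
})

test_that("xcorr matches the brute-force per-lag Pearson oracle", {
  withr::local_seed(7)
  for (i in 1:5) {
    x <- stats::rnorm(768)
    s <- stats::rnorm(768)
    expect_lt(max(abs(xcorr_series(x, s) - brute_xcorr(x, s, csep_lags()))),
              1e-10)
  }
})

test_that("xcorr recovers self-correlation, delays and orthogonality", {
  withr::local_seed(8)
  x <- stats::rnorm(768)
  lags <- csep_lags()
  r_self <- xcorr_series(x, x, lags)
  expect_equal(r_self[lags == 0], 1)

  # EEG delayed by 32 samples relative to the feature peaks at lag +32
  s <- x
  x_del <- c(rep(0, 32), x[1:736])
  expect_equal(lags[which.max(xcorr_series(x_del, s, lags))], 32L)

  t <- seq_len(768)
  r0 <- xcorr_series(sin(2 * pi * 8 * t / 768), cos(2 * pi * 8 * t / 768), lags)
  expect_lt(abs(r0[lags == 0]), 0.01)

  # constant (zero-variance) feature yields 0, not NaN
  expect_equal(xcorr_series(x, rep(1, 768), lags), rep(0, length(lags)))
})

test_that("ERP averaging honours draws, defaults and permutation invariance", {
  one <- matrix(stats::rnorm(64 * 768), 64, 768)
  pool <- array(rep(one, 80), dim = c(64, 768, 80))
  erp <- compute_erp(pool, seed = 1)
  expect_equal(erp$matrix, one)
  expect_equal(formals(compute_erp)$n_avg, 80L)

  pm <- array(c(one, -one), dim = c(64, 768, 2))
  expect_equal(compute_erp(pm, draws = c(1, 2, 1, 2))$matrix,
               matrix(0, 64, 768))

  arr <- make_epoch_array(n_ep = 7, seed = 2)
  full <- compute_erp(arr, draws = 1:7)$matrix
  perm <- compute_erp(arr, draws = c(4, 2, 7, 1, 3, 6, 5))$matrix
  expect_equal(full, perm)
  expect_error(compute_erp(array(0, c(64, 768, 0))), "empty")
})

test_that("CSEP images stay in [-1, 1] and localize an injected feature", {
  withr::local_seed(9)
  feat <- as.numeric(stats::filter(stats::rnorm(768), rep(1, 10), sides = 1))
  feat[is.na(feat)] <- 0
  arr <- make_epoch_array(n_ch = 16, n_ep = 6, seed = 3, scale = 0.1)
  for (e in 1:6) arr[7, , e] <- arr[7, , e] + feat
  sids <- rep("s1", 6)
  img <- compute_csep(arr, list(s1 = feat), n_avg = 40, seed = 4,
                      sentence_ids = sids, kind = "ENV")
  expect_true(all(img$matrix >= -1 & img$matrix <= 1))
  peaks <- apply(abs(img$matrix), 1, max)
  expect_equal(which.max(peaks), 7L)
  # verified against the brute-force oracle on the injected row
  r_oracle <- brute_xcorr(arr[7, , 1], feat, csep_lags())
  img1 <- compute_csep(arr, list(s1 = feat), draws = 1L, sentence_ids = sids,
                       kind = "ENV")
  expect_equal(img1$matrix[7, ], r_oracle, tolerance = 1e-10)

  expect_error(compute_csep(arr, list(other = feat), n_avg = 2, seed = 1,
                            sentence_ids = sids, kind = "ENV"),
               "no feature for sentence")
})

test_that("bootstrap datasets are balanced, sized and epoch-disjoint", {
  withr::local_seed(10)
  scores <- c(0, 25, 50, 75, 100)
  pools <- list()
  for (i in seq_along(scores)) {
    pools[[paste0("S01|c", i)]] <- epoch_pool(
      make_epoch_array(n_ch = 8, n_samp = 64, n_ep = 20, seed = i),
      score = scores[i], participant_id = "S01", condition_id = paste0("c", i))
  }
  ds <- bootstrap_dataset(pools, n_train = 100, n_test = 25, kind = "ERP",
                          n_avg = 10, seed = 5)
  expect_length(ds$train, 100L)
  expect_length(ds$test, 25L)

  lab_tr <- vapply(ds$train, function(i) i$label$score, 0)
  expect_setequal(unique(lab_tr), scores)
  counts <- table(factor(lab_tr, levels = scores))
  # uniform class draw: each count is Binomial(100, 1/5); 4 sigma band
  expect_true(all(abs(counts - 20) < 4 * sqrt(100 * 0.2 * 0.8) + 1))

  ids_tr <- unlist(lapply(ds$train, function(i) i$epoch_ids))
  ids_te <- unlist(lapply(ds$test, function(i) i$epoch_ids))
  expect_length(intersect(ids_tr, ids_te), 0L)

  single <- bootstrap_dataset(pools[3], n_train = 10, n_test = 5, kind = "ERP",
                              n_avg = 4, seed = 6)
  expect_true(all(vapply(single$train, function(i) i$label$score, 0) == 50))
})

test_that("bootstrap datasets are reproducible and lazy pools match eager ones", {
  arr <- make_epoch_array(n_ch = 8, n_samp = 64, n_ep = 15, seed = 20)
  mk <- function(ep) list(
    "S01|a" = epoch_pool(ep, score = 0, participant_id = "S01",
                         condition_id = "a", n_epochs = 15L),
    "S01|b" = epoch_pool(make_epoch_array(8, 64, 15, seed = 21), score = 100,
                         participant_id = "S01", condition_id = "b"))
  eager <- bootstrap_dataset(mk(arr), 20, 8, kind = "ERP", n_avg = 5, seed = 9)
  lazy <- bootstrap_dataset(mk(function() arr), 20, 8, kind = "ERP",
                            n_avg = 5, seed = 9)
  again <- bootstrap_dataset(mk(arr), 20, 8, kind = "ERP", n_avg = 5, seed = 9)
  expect_equal(lapply(eager$train, `[[`, "matrix"),
               lapply(lazy$train, `[[`, "matrix"))
  expect_identical(lapply(eager$train, `[[`, "matrix"),
                   lapply(again$train, `[[`, "matrix"))
})

test_that("rendering produces normalized 3-channel panels", {
  const <- feature_image(matrix(3.7, 64, 768), "ERP")
  r <- render_image(const, size = 64)
  expect_equal(dim(r), c(64L, 64L, 3L))
  expect_true(all(r == 0.5))

  img <- feature_image(make_epoch_array(n_ep = 1)[, , 1], "ERP")
  r2 <- render_image(img, size = 299)
  expect_equal(dim(r2), c(299L, 299L, 3L))
  expect_equal(min(r2), 0)
  expect_equal(max(r2), 1)
  expect_equal(r2[, , 1], r2[, , 3])
  expect_error(render_image(matrix(c(NA, 1:9), 2, 5)), "non-finite")
})
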