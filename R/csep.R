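# ERP / CSEP feature-image construction: the deep-learning features are
# 64 x 768 panels -- either an average of epochs (ERP) or an average of
# per-channel, per-lag Pearson correlation coefficients between epochs and a
# stimulus feature (CSEP).

#' The discrete intelligibility score grid
#'
#' Behavioral scores run 0..100% in 2.5% steps (41 levels); three levels
#' (30.0, 37.5, 40.0) were never observed, leaving 38 classes.
#'
#' @return Numeric vector of the 38 allowed scores, ascending.
#' @export
score_levels <- function() {
  setdiff(seq(0, 100, by = 2.5), c(30, 37.5, 40))
}

#' Score label with class index
#'
#' @param score A score on the allowed 2.5-step grid.
#' @return A `score_label`: list with `score` and 0-based `class_index`
#'   (rank of the score among the 38 allowed levels).
#' @export
score_label <- function(score) {
  lv <- score_levels()
  idx <- match(score, lv)
  if (is.na(idx)) {
    stopf("score %s is not on the allowed 2.5-step grid (30, 37.5, 40 excluded)",
          format(score))
  }
  structure(list(score = score, class_index = idx - 1L), class = "score_label")
}

#' Snap a raw percentage to the nearest allowed score level
#' @param x Numeric vector of raw percentages.
#' @return Scores on the allowed grid (ties between neighbours of an
#'   excluded level resolve downward).
#' @export
snap_to_score_grid <- function(x) {
  lv <- score_levels()
  lv[vapply(x, function(v) which.min(abs(lv - v)), 0L)]
}

#' Feature image (ERP or CSEP panel)
#'
#' @param matrix 64 x n_lags numeric matrix (ERP: microvolts vs time;
#'   CSEP: correlation coefficient vs lag).
#' @param kind `"ERP"`, `"ENV"`, `"PH"` or `"PHENV"`.
#' @param score Behavioral score on the allowed grid (or NA).
#' @param participant_id,condition_id Provenance identifiers.
#' @param epoch_ids Identifiers of the epochs averaged into this image.
#' @return A `feature_image` object.
#' @export
feature_image <- function(matrix, kind, score = NA, participant_id = NA,
                          condition_id = NA, epoch_ids = character()) {
  matrix <- as.matrix(matrix)
  if (any(!is.finite(matrix))) stopf("feature image values must be finite")
  if (kind != "ERP" && any(abs(matrix) > 1 + 1e-8)) {
    stopf("CSEP entries must lie in [-1, 1]")
  }
  label <- if (is.na(score)) NULL else score_label(score)
  structure(list(matrix = matrix, kind = kind, label = label,
                 participant_id = participant_id, condition_id = condition_id,
                 epoch_ids = epoch_ids),
            class = "feature_image")
}

#' Default CSEP lag grid
#'
#' 768 lags, -128..639 samples (-0.5 s to +2.496 s at 256 Hz), so that CSEP
#' panels share the 64 x 768 geometry of the ERP panels.
#' @return Integer vector of lags in samples.
#' @export
csep_lags <- function() -128:639

# ---- cross-correlation -----------------------------------------------------

#' Per-lag Pearson cross-correlation of one channel with a feature
#'
#' For each lag `l`, the Pearson correlation coefficient between `x(t)` and
#' `s(t - l)` over their overlapping samples. Lags with overlap below
#' `min_overlap` samples, or with zero variance in either segment, yield 0.
#'
#' @param x,s Numeric vectors of equal length.
#' @param lags Integer lags in samples (default [csep_lags()]).
#' @param min_overlap Minimum overlap in samples (default 8).
#' @return Numeric vector of correlation coefficients, one per lag.
#' @export
xcorr_series <- function(x, s, lags = csep_lags(), min_overlap = 8L) {
  drop(xcorr_matrix(matrix(x, nrow = 1L), s, lags, min_overlap))
}

#' Per-lag Pearson cross-correlation of every channel with a feature
#'
#' Vectorized multichannel version of [xcorr_series()]: all lag sums are
#' obtained from FFT cross-products and prefix sums, so the cost is
#' O(C N log N) rather than O(C N^2).
#'
#' @param X channels x samples matrix.
#' @param s Feature vector, `length(s) == ncol(X)`.
#' @param lags Integer lags in samples.
#' @param min_overlap Minimum overlap in samples (default 8).
#' @return channels x lags matrix of correlation coefficients in \[-1, 1\].
#' @export
xcorr_matrix <- function(X, s, lags = csep_lags(), min_overlap = 8L) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (length(s) != n) stopf("feature length %d != epoch length %d", length(s), n)
  if (any(abs(lags) >= n)) stopf("lags must satisfy |lag| < %d", n)
  C <- nrow(X)
  m <- stats::nextn(2L * n - 1L, 2)
  fs <- stats::fft(c(s, numeric(m - n)))
  fx <- stats::mvfft(rbind(t(X), matrix(0, m - n, C)))
  cc <- Re(stats::mvfft(fx * Conj(fs), inverse = TRUE)) / m   # m x C
  # cc[l + 1, ] (l >= 0) and cc[m + l + 1, ] (l < 0) hold sum_t x(t) s(t-l)
  cidx <- ifelse(lags >= 0L, lags + 1L, m + lags + 1L)
  sxy <- t(cc[cidx, , drop = FALSE])                          # C x L

  n_ov <- n - abs(lags)
  lo_t <- pmax(1L, 1L + lags)
  hi_t <- pmin(n, n + lags)
  csx <- cbind(0, t(apply(X, 1L, cumsum)))                    # C x (n+1)
  csxx <- cbind(0, t(apply(X^2, 1L, cumsum)))
  css <- c(0, cumsum(s))
  csss <- c(0, cumsum(s^2))
  sx <- csx[, hi_t + 1L, drop = FALSE] - csx[, lo_t, drop = FALSE]
  sxx <- csxx[, hi_t + 1L, drop = FALSE] - csxx[, lo_t, drop = FALSE]
  ss <- css[hi_t - lags + 1L] - css[lo_t - lags]
  sss <- csss[hi_t - lags + 1L] - csss[lo_t - lags]

  nmat <- matrix(n_ov, C, length(lags), byrow = TRUE)
  ssm <- matrix(ss, C, length(lags), byrow = TRUE)
  cov_xy <- sxy - sx * ssm / nmat
  var_x <- pmax(sxx - sx^2 / nmat, 0)
  var_s <- pmax(matrix(sss - ss^2 / n_ov, C, length(lags), byrow = TRUE), 0)
  denom <- sqrt(var_x * var_s)
  scale_tol <- (max(sxx) / n) * (max(sss) / n)
  r <- ifelse(denom <= sqrt(.Machine$double.eps * max(scale_tol, 1e-300)),
              0, cov_xy / denom)
  r[, n_ov < min_overlap] <- 0
  r <- pmin(1, pmax(-1, r))
  dim(r) <- c(C, length(lags))
  r
}

# ---- epoch pools & averaging ----------------------------------------------

#' A pool of epochs sharing one participant x condition cell
#'
#' @param epochs Either a 64 x 768 x n numeric array, a list of
#'   [eeg_epoch()] objects, or a zero-argument function returning such an
#'   array (lazy pool; then give `n_epochs`).
#' @param score Behavioral score of this cell (allowed grid).
#' @param participant_id,condition_id Cell identifiers.
#' @param n_epochs Number of epochs (required when `epochs` is a function).
#' @return An `epoch_pool` object.
#' @export
epoch_pool <- function(epochs, score, participant_id, condition_id,
                       n_epochs = NULL) {
  if (is.function(epochs)) {
    if (is.null(n_epochs)) stopf("lazy epoch pools need `n_epochs`")
  } else {
    epochs <- epochs_to_array(epochs)
    n_epochs <- dim(epochs)[3]
  }
  structure(list(epochs = epochs, n_epochs = as.integer(n_epochs),
                 score = score, participant_id = participant_id,
                 condition_id = condition_id),
            class = "epoch_pool")
}

epochs_to_array <- function(epochs) {
  if (is.array(epochs) && length(dim(epochs)) == 3L) return(epochs)
  stopifnot(is.list(epochs), length(epochs) > 0L)
  mats <- lapply(epochs, function(e) if (inherits(e, "eeg_epoch")) e$data else e)
  array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
}

materialize_pool <- function(pool) {
  if (is.function(pool$epochs)) pool$epochs() else pool$epochs
}

#' Event-related potential by bootstrap averaging
#'
#' Element-wise mean of `n_avg` epochs sampled with replacement from the
#' pool (the study design averages 80).
#'
#' @param epochs List of [eeg_epoch()], or a 64 x 768 x n array.
#' @param n_avg Number of epochs averaged (default 80).
#' @param seed RNG seed for the draw (`NULL` = current RNG stream).
#' @param draws Optional explicit epoch indices overriding the random draw.
#' @param score,participant_id,condition_id Stamped on the image.
#' @return A [feature_image()] of kind `"ERP"`.
#' @export
compute_erp <- function(epochs, n_avg = 80L, seed = NULL, draws = NULL,
                        score = NA, participant_id = NA, condition_id = NA) {
  arr <- epochs_to_array(epochs)
  n <- dim(arr)[3]
  if (n < 1L) stopf("empty epoch pool")
  if (is.null(draws)) {
    draws <- with_seed(seed, sample.int(n, n_avg, replace = TRUE))
  }
  m <- rowMeans(arr[, , draws, drop = FALSE], dims = 2L)
  feature_image(m, "ERP", score = score, participant_id = participant_id,
                condition_id = condition_id,
                epoch_ids = paste0("e", sort(unique(draws))))
}

#' Continuous speech-evoked potential (CSEP) image
#'
#' For each of `n_avg` epochs drawn with replacement, computes the
#' per-channel, per-lag Pearson correlation with that epoch's own sentence
#' feature, and averages the resulting 64 x 768 coefficient matrices.
#'
#' @param epochs List of [eeg_epoch()] objects (need `sentence_id`), or a
#'   64 x 768 x n array together with `sentence_ids`.
#' @param features Named list mapping `sentence_id` to a feature vector (or
#'   [feature_series()]) of length 768 on the epoch time base.
#' @param n_avg Number of epochs averaged (default 80).
#' @param lags Lag grid (default [csep_lags()]).
#' @param seed RNG seed for the draw (`NULL` = current RNG stream).
#' @param draws Optional explicit epoch indices.
#' @param sentence_ids Sentence id per array slice when `epochs` is an array.
#' @param kind Feature kind stamped on the image (`"ENV"`, `"PH"`,
#'   `"PHENV"`); inferred from the features when they are
#'   [feature_series()] objects.
#' @param cache Optional environment caching per-epoch correlation matrices
#'   under names `"e<i>"`.
#' @param score,participant_id,condition_id Stamped on the image.
#' @return A [feature_image()] with entries in \[-1, 1\].
#' @export
compute_csep <- function(epochs, features, n_avg = 80L, lags = csep_lags(),
                         seed = NULL, draws = NULL, sentence_ids = NULL,
                         kind = NULL, cache = NULL,
                         score = NA, participant_id = NA, condition_id = NA) {
  if (is.list(epochs) && !is.array(epochs)) {
    sentence_ids <- vapply(epochs, function(e) as.character(e$sentence_id), "")
  }
  arr <- epochs_to_array(epochs)
  n <- dim(arr)[3]
  if (n < 1L) stopf("empty epoch pool")
  if (is.null(sentence_ids) || length(sentence_ids) != n) {
    stopf("need one sentence_id per epoch")
  }
  fk <- vapply(features, function(f) if (inherits(f, "feature_series")) f$kind else NA_character_, "")
  if (is.null(kind)) kind <- if (all(!is.na(fk))) unique(fk)[1] else "ENV"
  fvals <- lapply(features, function(f) if (inherits(f, "feature_series")) f$values else as.numeric(f))
  missing_sid <- setdiff(unique(sentence_ids), names(fvals))
  if (length(missing_sid)) {
    stopf("no feature for sentence(s): %s", paste(missing_sid, collapse = ", "))
  }
  if (is.null(draws)) {
    draws <- with_seed(seed, sample.int(n, n_avg, replace = TRUE))
  }
  acc <- 0
  for (i in draws) {
    key <- paste0("e", i)
    m <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      mi <- xcorr_matrix(arr[, , i], fvals[[sentence_ids[i]]], lags)
      if (!is.null(cache)) cache[[key]] <- mi
      mi
    }
    acc <- acc + m
  }
  feature_image(acc / length(draws), kind, score = score,
                participant_id = participant_id, condition_id = condition_id,
                epoch_ids = paste0("e", sort(unique(draws))))
}

# Precompute per-epoch correlation matrices for one pool, batching all
# epochs that share a sentence through a single FFT call: rows of the
# stacked (channels * epochs) x samples matrix are independent in
# xcorr_matrix, so results are split back per epoch afterwards.
pool_xcorr_cache <- function(arr, fvals, sids, lags, need_idx) {
  cache <- new.env(parent = emptyenv())
  C <- dim(arr)[1]
  for (sid in unique(sids[need_idx])) {
    idx <- intersect(which(sids == sid), need_idx)
    stacked <- matrix(aperm(arr[, , idx, drop = FALSE], c(1L, 3L, 2L)),
                      nrow = C * length(idx))
    r <- xcorr_matrix(stacked, fvals[[sid]], lags)
    for (j in seq_along(idx)) {
      cache[[paste0("e", idx[j])]] <- r[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
    }
  }
  cache
}

# ---- bootstrap dataset -----------------------------------------------------

#' Bootstrap a class-balanced ERP/CSEP dataset with an 80/20 epoch split
#'
#' Each participant x condition pool is first split into disjoint train and
#' test epochs (`split_fraction` to train). Exemplars are then generated by
#' drawing a score class uniformly from the observed classes, a pool with
#' that label, and `n_avg` epochs (with replacement) from the pool's side;
#' train exemplars only ever touch train-side epochs and vice versa, so the
#' two sides share no epoch.
#'
#' @param pools Named list of [epoch_pool()] objects (lazy pools are
#'   materialized one at a time, so memory stays bounded).
#' @param n_train,n_test Number of exemplars per side (defaults 800 / 200).
#' @param kind `"ERP"`, `"ENV"`, `"PH"` or `"PHENV"`.
#' @param features Named list `sentence_id -> feature` (required for CSEP
#'   kinds); see [compute_csep()].
#' @param sentence_ids Named list `pool name -> character vector` of
#'   sentence ids per epoch (required for CSEP kinds with array pools).
#' @param n_avg Epochs averaged per exemplar (default 80).
#' @param lags Lag grid for CSEP kinds.
#' @param split_fraction Train fraction of each pool (default 0.8).
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return A `csep_dataset`: list with `train` and `test` lists of
#'   [feature_image()], plus `kind`, `split_fraction`, `seed`.
#' @export
bootstrap_dataset <- function(pools, n_train = 800L, n_test = 200L,
                              kind = c("ERP", "ENV", "PH", "PHENV"),
                              features = NULL, sentence_ids = NULL,
                              n_avg = 80L, lags = csep_lags(),
                              split_fraction = 0.8, seed = 1L) {
  kind <- match.arg(kind)
  if (n_train <= 0 || n_test <= 0) stopf("n_train and n_test must be positive")
  if (kind != "ERP" && is.null(features)) {
    stopf("CSEP kinds need `features`")
  }
  scores <- vapply(pools, function(p) p$score, 0)
  classes <- sort(unique(scores))
  # --- sampling plan, drawn up-front so lazy materialization order never
  #     affects reproducibility
  plan <- with_seed(seed, {
    splits <- lapply(pools, function(p) {
      perm <- sample.int(p$n_epochs)
      n_tr <- round(split_fraction * p$n_epochs)
      if (n_tr < 1L || n_tr >= p$n_epochs) {
        stopf("pool %s/%s has too few epochs (%d) for an %g/%g split",
              p$participant_id, p$condition_id, p$n_epochs,
              split_fraction, 1 - split_fraction)
      }
      list(train = sort(perm[seq_len(n_tr)]), test = sort(perm[-seq_len(n_tr)]))
    })
    draw_side <- function(n_side, side) {
      cls <- classes[sample.int(length(classes), n_side, replace = TRUE)]
      lapply(cls, function(cl) {
        cand <- which(scores == cl)
        pi <- if (length(cand) == 1L) cand else sample(cand, 1L)
        side_idx <- splits[[pi]][[side]]
        list(pool = pi,
             idx = side_idx[sample.int(length(side_idx), n_avg, replace = TRUE)])
      })
    }
    list(splits = splits,
         train = draw_side(n_train, "train"),
         test = draw_side(n_test, "test"))
  })
  # --- execute pool by pool
  out <- list(train = vector("list", n_train), test = vector("list", n_test))
  for (pi in seq_along(pools)) {
    jobs <- c(
      lapply(which(vapply(plan$train, function(e) e$pool, 0L) == pi),
             function(j) list(side = "train", j = j)),
      lapply(which(vapply(plan$test, function(e) e$pool, 0L) == pi),
             function(j) list(side = "test", j = j)))
    if (length(jobs) == 0L) next
    pool <- pools[[pi]]
    arr <- materialize_pool(pool)
    sids <- if (!is.null(sentence_ids)) sentence_ids[[names(pools)[pi]]] else
      attr(arr, "sentence_ids")
    cache <- if (kind == "ERP") new.env(parent = emptyenv()) else {
      fvals <- lapply(features, function(f)
        if (inherits(f, "feature_series")) f$values else as.numeric(f))
      needed <- sort(unique(unlist(lapply(jobs, function(job)
        plan[[job$side]][[job$j]]$idx))))
      pool_xcorr_cache(arr, fvals, sids, lags, needed)
    }
    for (job in jobs) {
      entry <- plan[[job$side]][[job$j]]
      img <- if (kind == "ERP") {
        compute_erp(arr, draws = entry$idx, score = pool$score,
                    participant_id = pool$participant_id,
                    condition_id = pool$condition_id)
      } else {
        compute_csep(arr, features, draws = entry$idx, lags = lags,
                     sentence_ids = sids, kind = kind, cache = cache,
                     score = pool$score,
                     participant_id = pool$participant_id,
                     condition_id = pool$condition_id)
      }
      img$epoch_ids <- paste0("p", pi, ":e", sort(unique(entry$idx)))
      out[[job$side]][[job$j]] <- img
    }
  }
  structure(list(train = out$train, test = out$test, kind = kind,
                 split_fraction = split_fraction, seed = seed,
                 classes = classes),
            class = "csep_dataset")
}

# ---- rendering -------------------------------------------------------------

#' Render a feature image for the classifier
#'
#' Bilinearly resizes the 64 x 768 panel to `size` x `size`, min-max
#' normalizes to \[0, 1\] (a constant panel maps to 0.5), and replicates the
#' result onto 3 identical channels. Bilinear resizing commutes with affine
#' rescaling, so normalizing after the resize is equivalent to the reverse
#' order followed by renormalization, and pins the output range exactly.
#'
#' @param img A [feature_image()] (or plain matrix).
#' @param size Output height/width in pixels (default 299).
#' @return A `rendered_image`: `size` x `size` x 3 array in \[0, 1\] with
#'   attributes `kind` and `score`.
#' @export
render_image <- function(img, size = 299L) {
  m <- if (inherits(img, "feature_image")) img$matrix else as.matrix(img)
  if (any(!is.finite(m))) stopf("cannot render non-finite values")
  rm2 <- bilinear_resize(m, size, size)
  rng <- range(rm2)
  px <- if (rng[1] == rng[2]) {
    matrix(0.5, size, size)
  } else {
    (rm2 - rng[1]) / (rng[2] - rng[1])
  }
  out <- array(px, dim = c(size, size, 3L))
  attr(out, "kind") <- if (inherits(img, "feature_image")) img$kind else NA
  attr(out, "score") <- if (inherits(img, "feature_image") && !is.null(img$label))
    img$label$score else NA
  class(out) <- "rendered_image"
  out
}

# Bilinear interpolation via row/column interpolation matrices
# (align-corners coordinate mapping).
bilinear_resize <- function(m, out_h, out_w) {
  interp_mat <- function(n_in, n_out) {
    if (n_in == 1L) return(matrix(1, n_out, 1L))
    pos <- seq(0, n_in - 1L, length.out = n_out)
    lo <- pmin(floor(pos), n_in - 2L)
    w <- pos - lo
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), lo + 1L)] <- 1 - w
    A[cbind(seq_len(n_out), lo + 2L)] <- A[cbind(seq_len(n_out), lo + 2L)] + w
    A
  }
  interp_mat(nrow(m), out_h) %*% m %*% t(interp_mat(ncol(m), out_w))
}

#' Stack rendered images into a 4-D array
#'
#' @param images List of `rendered_image` arrays of identical size.
#' @return List with `x` (H x W x 3 x N array) and `scores` (numeric).
#' @export
stack_rendered <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, dim = c(d, length(images)))
  scores <- rep(NA_real_, length(images))
  for (i in seq_along(images)) {
    x[, , , i] <- images[[i]]
    scores[i] <- attr(images[[i]], "score") %||% NA_real_
  }
  list(x = x, scores = scores)
}
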