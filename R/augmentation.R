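# Training-set augmentation on 64 x 768 feature images (before rendering, so
# the cutout window and dropped sensors keep their stated time/channel
# meaning): additive Gaussian noise at a fixed noise-to-signal RMS ratio,
# a temporal cutout refilled with matched Gaussian noise, or zeroing a
# random sensor subset. One approach is chosen per augmented copy.

#' Augmentation configuration
#'
#' @param nsr Noise-to-signal RMS ratio for additive noise (default 0.6).
#' @param cutout_s Cutout duration in seconds (default 0.625, about 20% of
#'   the 3 s epoch).
#' @param dropout_n Number of dropped sensors (default 12, about 20% of 64).
#' @param factor Expansion factor: each original yields `factor - 1`
#'   augmented copies plus itself (default 10, growing 800 to 8,000).
#' @param seed RNG seed for the whole augmentation pass.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(nsr = 0.6, cutout_s = 0.625, dropout_n = 12L,
                                factor = 10L, seed = 1L) {
  if (nsr < 0) stopf("nsr must be >= 0")
  if (cutout_s <= 0 || cutout_s > 3) stopf("cutout_s must be in (0, 3] s")
  if (dropout_n < 0 || dropout_n > 64) stopf("dropout_n must be in 0..64")
  if (factor < 1) stopf("factor must be >= 1")
  structure(list(nsr = nsr, cutout_s = cutout_s, dropout_n = as.integer(dropout_n),
                 factor = as.integer(factor), seed = seed),
            class = "augmentation_config")
}

img_matrix <- function(img) if (inherits(img, "feature_image")) img$matrix else as.matrix(img)

img_with_matrix <- function(img, m) {
  if (inherits(img, "feature_image")) {
    img$matrix <- m
    img
  } else m
}

#' Additive Gaussian noise at an exact noise-to-signal ratio
#'
#' The drawn i.i.d. Gaussian field is rescaled so that
#' `RMS(noise) / RMS(input)` equals `nsr` exactly for every draw.
#'
#' @param img A [feature_image()] or matrix.
#' @param nsr Noise-to-signal RMS ratio (default 0.6).
#' @param seed RNG seed (`NULL` = current stream).
#' @return Augmented image of the same type; label unchanged.
#' @export
add_gaussian_noise <- function(img, nsr = 0.6, seed = NULL) {
  if (nsr < 0) stopf("nsr must be >= 0")
  m <- img_matrix(img)
  if (nsr == 0) return(img)
  sig <- rms(m)
  if (sig == 0) stopf("noise-to-signal ratio is undefined for an all-zero image")
  noise <- with_seed(seed, matrix(stats::rnorm(length(m)), nrow(m), ncol(m)))
  noise <- noise * (nsr * sig / rms(noise))
  img_with_matrix(img, m + noise)
}

#' Temporal cutout
#'
#' Replaces one contiguous random window of `round(duration * rate)` columns
#' (all channels) with Gaussian noise matched to the image's global mean and
#' standard deviation; all other columns are untouched.
#'
#' @param img A [feature_image()] or matrix.
#' @param duration Cutout duration in seconds (default 0.625; must be <= 3).
#' @param rate Columns per second (default 256).
#' @param seed RNG seed (`NULL` = current stream).
#' @return Augmented image; label unchanged.
#' @export
temporal_cutout <- function(img, duration = 0.625, rate = 256, seed = NULL) {
  if (duration > 3) stopf("cutout duration must be <= 3 s")
  if (duration < 0) stopf("cutout duration must be >= 0")
  m <- img_matrix(img)
  width <- round_half_away(duration * rate)
  if (width == 0) return(img)
  if (width > ncol(m)) stopf("cutout (%d columns) exceeds the image width", width)
  mu <- mean(m)
  sdv <- stats::sd(as.vector(m))
  if (sdv == 0) sdv <- 1   # degenerate constant image: keep the cutout visible
  with_seed(seed, {
    start <- sample.int(ncol(m) - width + 1L, 1L)
    m[, start:(start + width - 1L)] <-
      stats::rnorm(nrow(m) * width, mean = mu, sd = sdv)
  })
  img_with_matrix(img, m)
}

#' Sensor dropout
#'
#' Sets a random subset of exactly `n_sensors` distinct channels (rows) to
#' zero.
#'
#' @param img A [feature_image()] or matrix.
#' @param n_sensors Number of dropped sensors (default 12; 0..n_channels).
#' @param seed RNG seed (`NULL` = current stream).
#' @return Augmented image; label unchanged.
#' @export
sensor_dropout <- function(img, n_sensors = 12L, seed = NULL) {
  m <- img_matrix(img)
  if (n_sensors < 0 || n_sensors > nrow(m)) {
    stopf("n_sensors must be in 0..%d", nrow(m))
  }
  if (n_sensors == 0) return(img)
  rows <- with_seed(seed, sample.int(nrow(m), n_sensors))
  m[rows, ] <- 0
  img_with_matrix(img, m)
}

#' Expand a training set by random augmentation
#'
#' Keeps every original and appends `factor - 1` augmented copies of each,
#' every copy produced by exactly one of the three approaches (Gaussian
#' noise, temporal cutout, sensor dropout) chosen uniformly at random.
#' Labels are copied unchanged. With 800 originals and the default factor
#' of 10 the output holds 8,000 images.
#'
#' @param train List of [feature_image()] objects (or matrices).
#' @param cfg An [augmentation_config()].
#' @param rate Columns per second for the cutout (default 256).
#' @return List of images of length `length(train) * cfg$factor`.
#' @export
augment_dataset <- function(train, cfg = augmentation_config(), rate = 256) {
  if (length(train) == 0L) stopf("empty training set")
  out <- vector("list", length(train) * cfg$factor)
  out[seq_along(train)] <- train
  k <- length(train)
  with_seed(cfg$seed, {
    for (i in seq_along(train)) {
      for (r in seq_len(cfg$factor - 1L)) {
        approach <- sample.int(3L, 1L)
        k <- k + 1L
        out[[k]] <- switch(approach,
          add_gaussian_noise(train[[i]], cfg$nsr),
          temporal_cutout(train[[i]], cfg$cutout_s, rate),
          sensor_dropout(train[[i]], cfg$dropout_n))
      }
    }
  })
  out
}
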