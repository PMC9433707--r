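# Occlusion-sensitivity attribution: slide a small occluding mask over the
# rendered input, record the drop in the true-class softmax probability, and
# aggregate the resulting sensitivity grid back onto the 64-electrode
# montage.

#' Occlusion-sensitivity map of one rendered image
#'
#' For every mask position on a `stride`-spaced grid, the `mask_size` x
#' `mask_size` patch (all 3 channels) is replaced by the `baseline` value
#' and the sensitivity is `p_class(original) - p_class(occluded)`. A
#' 299 x 299 input with mask and stride 5 gives a 60 x 60 grid.
#'
#' @param model A trained `csep_cnn`.
#' @param image A `rendered_image` (H x W x 3 array).
#' @param class_index 0-based class whose probability is tracked; defaults
#'   to the model's predicted class for the image.
#' @param mask_size,stride Occluder size and stride in pixels (default 5).
#' @param baseline Fill value for the occluded patch (default 0.5, the
#'   rendered-image midpoint).
#' @param batch_size Forward-pass chunk size.
#' @return An `occlusion_map`: list with `grid`
#'   (`ceil(H/stride)` x `ceil(W/stride)`), `mask_size`, `stride`,
#'   `class_index`, `input_size`, `p_original`.
#' @export
occlusion_map <- function(model, image, class_index = NULL, mask_size = 5L,
                          stride = 5L, baseline = 0.5, batch_size = 64L) {
  stopifnot(inherits(model, "csep_cnn"))
  if (mask_size <= 0 || stride <= 0) stopf("mask_size and stride must be positive")
  img <- unclass(image)
  attributes(img) <- list(dim = dim(image))
  d <- dim(img)
  if (length(d) != 3L || !all(d == model$spec$input_dim)) {
    stopf("image must be a %s array", paste(model$spec$input_dim, collapse = "x"))
  }
  h <- d[1]; w <- d[2]
  p0 <- drop(predict_cnn(model, array(img, c(d, 1L))))
  if (is.null(class_index)) class_index <- which.max(p0) - 1L
  gh <- ceiling(h / stride)
  gw <- ceiling(w / stride)
  grid <- matrix(0, gh, gw)
  cells <- expand.grid(gi = seq_len(gh), gj = seq_len(gw))
  for (s in seq(1L, nrow(cells), by = batch_size)) {
    e <- min(nrow(cells), s + batch_size - 1L)
    nb <- e - s + 1L
    xb <- array(0, c(d, nb))
    for (j in seq_len(nb)) {
      gi <- cells$gi[s + j - 1L]; gj <- cells$gj[s + j - 1L]
      occ <- img
      rows <- ((gi - 1L) * stride + 1L):min(h, (gi - 1L) * stride + mask_size)
      colz <- ((gj - 1L) * stride + 1L):min(w, (gj - 1L) * stride + mask_size)
      occ[rows, colz, ] <- baseline
      xb[, , , j] <- occ
    }
    pb <- predict_cnn(model, xb, batch_size = batch_size)
    for (j in seq_len(nb)) {
      grid[cells$gi[s + j - 1L], cells$gj[s + j - 1L]] <-
        p0[class_index + 1L] - pb[j, class_index + 1L]
    }
  }
  structure(list(grid = grid, mask_size = as.integer(mask_size),
                 stride = as.integer(stride),
                 class_index = as.integer(class_index),
                 input_size = c(h, w), p_original = p0[class_index + 1L]),
            class = "occlusion_map")
}

#' Average occlusion maps over a set of test images
#'
#' Computes [occlusion_map()] for each selected image at its true class and
#' averages the grids. By default only correctly classified images are
#' used; `max_images` bounds the cost.
#'
#' @param model A trained `csep_cnn`.
#' @param images List of rendered images (or H x W x 3 x N array).
#' @param class_indices True 0-based class index per image.
#' @param only_correct Keep only correctly classified images (default TRUE).
#' @param max_images Cap on the number of images occluded (default Inf).
#'   When capped, images are selected round-robin across the observed
#'   classes in descending class order: high-score trials carry the
#'   strongest stimulus-locked responses, so they are the most informative
#'   to occlude under a limited budget (score-0 trials contain no tracked
#'   signal at all).
#' @param ... Passed to [occlusion_map()].
#' @return An `occlusion_map` whose grid is the mean over images, with an
#'   `n_images` field.
#' @export
aggregate_occlusion <- function(model, images, class_indices,
                                only_correct = TRUE, max_images = Inf, ...) {
  x <- as_image_array(if (is.list(images) && !is.array(images))
    stack_rendered(images)$x else images, model$spec$input_dim)
  n <- dim(x)[4]
  stopifnot(length(class_indices) == n)
  keep <- seq_len(n)
  if (only_correct) {
    pred <- max.col(predict_cnn(model, x), ties.method = "first") - 1L
    keep <- which(pred == class_indices)
    if (length(keep) == 0L) stopf("no correctly classified images to occlude")
  }
  if (is.finite(max_images) && length(keep) > max_images) {
    cls <- class_indices[keep]
    ord <- order(-cls, seq_along(keep))
    round_of <- stats::ave(seq_along(ord), cls[ord], FUN = seq_along)
    keep <- keep[ord][order(round_of, -cls[ord])]
  }
  keep <- keep[seq_len(min(length(keep), max_images))]
  acc <- NULL
  for (i in keep) {
    om <- occlusion_map(model, x[, , , i], class_index = class_indices[i], ...)
    acc <- if (is.null(acc)) om else { acc$grid <- acc$grid + om$grid; acc }
  }
  acc$grid <- acc$grid / length(keep)
  acc$n_images <- length(keep)
  acc
}

#' Aggregate an occlusion map to per-electrode sensitivities
#'
#' Image rows are partitioned into 64 contiguous bands by proportional
#' rounding (band `c` covers rows `round((c-1) H/64)+1 .. round(c H/64)`).
#' Each occlusion grid row is weighted by its fractional row overlap with
#' the band, and the per-channel score is the overlap-weighted mean of the
#' (by default absolute) grid values over all lag columns. Weighting is
#' normalized per grid row, so total sensitivity is conserved: the
#' band-width-weighted mean of the channel scores equals the grid mean.
#'
#' @param map An [occlusion_map()].
#' @param montage An [load_montage()] data.frame (64 rows).
#' @param agg `"abs"` (default) or `"signed"` grid aggregation.
#' @return A `channel_sensitivity`: list with `score` (named numeric, one
#'   per channel), `labels`, `band_width` (in grid rows, summing to the
#'   grid row count).
#' @export
map_to_channels <- function(map, montage = load_montage(),
                            agg = c("abs", "signed")) {
  agg <- match.arg(agg)
  stopifnot(inherits(map, "occlusion_map"))
  n_ch <- nrow(montage)
  h <- map$input_size[1]
  gh <- nrow(map$grid)
  v <- if (agg == "abs") abs(map$grid) else map$grid
  rv <- rowMeans(v)                        # mean over lag columns per grid row
  # image-row extent of each grid row (clipped to the image)
  g_lo <- (seq_len(gh) - 1L) * map$stride + 1L
  g_hi <- pmin(h, seq_len(gh) * map$stride)
  g_rows <- g_hi - g_lo + 1L
  b_hi <- round(seq_len(n_ch) * h / n_ch)
  b_lo <- c(1L, utils::head(b_hi, -1L) + 1L)
  score <- numeric(n_ch)
  width <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    ov <- pmax(0L, pmin(b_hi[ch], g_hi) - pmax(b_lo[ch], g_lo) + 1L)
    wgt <- ov / g_rows                      # per-grid-row fractional overlap
    width[ch] <- sum(wgt)
    score[ch] <- sum(wgt * rv) / sum(wgt)
  }
  names(score) <- montage$label
  structure(list(score = score, labels = montage$label, band_width = width,
                 agg = agg),
            class = "channel_sensitivity")
}

#' Top-k contributing channels
#'
#' @param cs A [map_to_channels()] result.
#' @param k Number of channels (default 10). Ties break by montage order.
#' @return Character vector of `k` labels, descending sensitivity.
#' @export
topk_channels <- function(cs, k = 10L) {
  stopifnot(inherits(cs, "channel_sensitivity"))
  if (k < 1L || k > length(cs$score)) stopf("k must be in 1..%d", length(cs$score))
  ord <- order(-cs$score, seq_along(cs$score))
  cs$labels[ord[seq_len(k)]]
}

#' Render a topographic sensitivity map
#'
#' Draws the channel sensitivities on the 2-D head plane (inverse-distance
#' interpolation inside the head circle, electrode positions overlaid,
#' dark-to-bright color for low-to-high contribution) and writes PNG or SVG.
#'
#' @param cs A [map_to_channels()] result.
#' @param montage An [load_montage()] data.frame.
#' @param path Output file; extension selects the device (`.png`/`.svg`).
#' @param resolution Interpolation grid resolution (default 100).
#' @return `path`, invisibly.
#' @export
render_topomap <- function(cs, montage = load_montage(), path,
                           resolution = 100L) {
  stopifnot(inherits(cs, "channel_sensitivity"))
  if (!setequal(names(cs$score), montage$label)) {
    stopf("montage labels do not match the sensitivity labels")
  }
  s <- cs$score[montage$label]
  rng <- range(s)
  sv <- if (rng[1] == rng[2]) rep(0.5, length(s)) else (s - rng[1]) / diff(rng)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 6, height = 6)
  else grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  gx <- seq(-1.25, 1.25, length.out = resolution)
  gz <- matrix(NA_real_, resolution, resolution)
  for (i in seq_len(resolution)) {
    for (j in seq_len(resolution)) {
      if (gx[i]^2 + gx[j]^2 > 1.21^2) next
      d2 <- (montage$x - gx[i])^2 + (montage$y - gx[j])^2
      wgt <- 1 / pmax(d2, 1e-6)
      gz[i, j] <- sum(wgt * sv) / sum(wgt)
    }
  }
  pal <- grDevices::colorRampPalette(c("#1a0000", "#7f0000", "#ff2200",
                                       "#ffcc66"))(64)
  graphics::image(gx, gx, gz, col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "", asp = 1,
                  main = "Occlusion sensitivity")
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(1.2 * cos(th), 1.2 * sin(th))
  graphics::lines(c(-0.1, 0, 0.1), c(1.19, 1.3, 1.19))   # nose
  graphics::points(montage$x, montage$y, pch = 21,
                   bg = pal[pmax(1, ceiling(sv * 64))], cex = 1.2)
  # simple colorbar
  graphics::rect(1.05, seq(-1, 0.9, length.out = 64)[-64], 1.15,
                 seq(-1, 0.9, length.out = 64)[-1], col = pal, border = NA)
  graphics::text(1.1, c(-1.05, 0.95), sprintf("%.3g", rng), cex = 0.7)
  invisible(path)
}
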