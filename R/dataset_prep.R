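# Dataset preparation: seeded train/test splitting, fixed-size frame
# tiling with median-border padding, spike/background frame balancing
# and paired image/mask augmentation.

#' Split image ids into train and test sets
#'
#' Seeded random partition. The train size is `ratio * N` rounded half
#' up, so 292 ids at 80:20 give 234 train and 58 test. The two sets are
#' disjoint and their union is the input.
#'
#' @param ids character or integer vector of at least 2 ids.
#' @param ratio train fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train_ids` and `test_ids`.
#' @export
split_dataset <- function(ids, ratio = 0.8, seed = 1) {
  if (length(ids) < 2) stop("need at least 2 ids to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly in (0, 1)")
  set.seed(seed)
  n_train <- floor(ratio * length(ids) + 0.5)   # round half up
  shuffled <- sample(ids)
  list(train_ids = shuffled[seq_len(n_train)],
       test_ids = shuffled[-seq_len(n_train)])
}

median_border_color <- function(pixels) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  border <- c(which(row(matrix(0, H, W)) %in% c(1, H) |
                      col(matrix(0, H, W)) %in% c(1, W)))
  vapply(1:3, function(ch) stats::median(pixels[, , ch][border]), numeric(1))
}

#' Tile an image and its mask into fixed-size frames
#'
#' Non-overlapping `size x size` tiles; the right and bottom edges are
#' padded up to a multiple of `size` -- the image with the median border
#' colour (scenes have a near-uniform background), the mask with 0. The
#' frame count is `ceiling(H/size) * ceiling(W/size)`; a full-resolution
#' 2976 x 2560 frame at size 256 yields 12 x 10 = 120 frames. A frame is
#' a spike frame when its spike-pixel fraction reaches
#' `frame_threshold`.
#'
#' @param image a [spike_image()].
#' @param mask paired binary mask.
#' @param size tile side in pixels (>= 16).
#' @param frame_threshold spike-pixel fraction (of the tile area) above
#'   which a frame counts as a spike frame; default 0.5%.
#' @return list of frames, each with `pixels` (`size x size x 3`),
#'   `mask_crop`, `origin` (1-based row, col of the tile's top-left in
#'   the padded parent) and `is_spike_frame`.
#' @export
extract_frames <- function(image, mask, size = 256, frame_threshold = 0.005) {
  stopifnot(inherits(image, "spike_image"), size >= 16,
            all(dim(mask) == c(image$height, image$width)))
  H <- image$height; W <- image$width
  Hp <- ceiling(H / size) * size
  Wp <- ceiling(W / size) * size
  fill <- median_border_color(image$pixels)
  px <- array(rep(fill, each = Hp * Wp), dim = c(Hp, Wp, 3))
  px[1:H, 1:W, ] <- image$pixels
  mk <- matrix(0L, Hp, Wp)
  mk[1:H, 1:W] <- mask
  frames <- list()
  for (r0 in seq(1, Hp, by = size)) {
    for (c0 in seq(1, Wp, by = size)) {
      rows <- r0:(r0 + size - 1)
      cols <- c0:(c0 + size - 1)
      mc <- mk[rows, cols]
      frames[[length(frames) + 1]] <- list(
        pixels = px[rows, cols, , drop = FALSE],
        mask_crop = mc,
        origin = c(row = r0, col = c0),
        is_spike_frame = mean(mc) >= frame_threshold
      )
    }
  }
  frames
}

#' Reassemble frames into the original image and mask
#'
#' Inverse of [extract_frames()]: stitches the tiles by their origins and
#' drops the padding, reconstructing the image and mask exactly.
#'
#' @param frames output of [extract_frames()].
#' @param height,width size of the original (un-padded) image.
#' @return list with `pixels` and `mask`.
#' @export
stitch_frames <- function(frames, height, width) {
  size <- nrow(frames[[1]]$mask_crop)
  Hp <- max(vapply(frames, function(f) f$origin["row"], numeric(1))) + size - 1
  Wp <- max(vapply(frames, function(f) f$origin["col"], numeric(1))) + size - 1
  px <- array(0, dim = c(Hp, Wp, 3))
  mk <- matrix(0L, Hp, Wp)
  for (f in frames) {
    rows <- f$origin["row"]:(f$origin["row"] + size - 1)
    cols <- f$origin["col"]:(f$origin["col"] + size - 1)
    px[rows, cols, ] <- f$pixels
    mk[rows, cols] <- f$mask_crop
  }
  list(pixels = px[1:height, 1:width, , drop = FALSE],
       mask = mk[1:height, 1:width])
}

#' Balance spike and background frames
#'
#' Keeps every spike frame and subsamples the background frames (seeded,
#' without replacement) to `n_spike / ratio`, rounded to nearest. Frames
#' that are pure background -- nothing but the (noisy) backdrop colour,
#' detected by a per-channel standard deviation below `bg_sd_tol` -- are
#' dropped before sampling. If too few background frames remain they are
#' all kept, with a warning; with no spike frames at all an empty list is
#' returned with a warning.
#'
#' @param frames output of [extract_frames()].
#' @param ratio spike:background ratio (default 1, i.e. 1:1).
#' @param seed integer seed for the subsample.
#' @param bg_sd_tol intensity standard deviation (0--255 scale) below
#'   which a spike-free frame counts as pure background.
#' @return the balanced list of frames (spike frames first).
#' @export
balance_frames <- function(frames, ratio = 1, seed = 1, bg_sd_tol = 10) {
  stopifnot(ratio > 0)
  is_spike <- vapply(frames, function(f) f$is_spike_frame, logical(1))
  spike <- frames[is_spike]
  if (length(spike) == 0) {
    warning("no spike frames; returning empty list")
    return(list())
  }
  bg <- frames[!is_spike]
  informative <- vapply(bg, function(f) {
    max(vapply(1:3, function(ch) stats::sd(f$pixels[, , ch]), numeric(1))) >
      bg_sd_tol
  }, logical(1))
  bg <- bg[informative]
  n_bg <- round(length(spike) / ratio)
  set.seed(seed)
  if (length(bg) < n_bg) {
    warning("only ", length(bg), " informative background frames available (",
            n_bg, " requested); keeping all")
  } else {
    bg <- bg[sample(length(bg), n_bg)]
  }
  c(spike, bg)
}

# Bilinear sample of one channel at fractional coordinates; out-of-range
# points take the fill value.
bilinear_sample <- function(m, r, c, fill) {
  H <- nrow(m); W <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- rep(fill, length(ri))
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    out
  }
  (1 - fr) * (1 - fc) * get(r0, c0) + (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) + fr * fc * get(r0 + 1, c0 + 1)
}

#' Paired augmentation of an image and its mask
#'
#' One augmentation draw: a rotation by an angle uniform in
#' `rotation_range` degrees (bilinear for the image, nearest-neighbour
#' for the mask, so mask values stay in `{0, 1}`), an optional horizontal
#' flip applied to both or neither, and a brightness factor uniform in
#' `brightness_range` multiplying all image channels with clipping to
#' `[0, 255]` (the mask is unaffected by brightness). Rotation exposes
#' corner pixels, which are filled with the median border colour rather
#' than black, matching the uniform scene background.
#'
#' @param image a [spike_image()].
#' @param mask paired binary mask.
#' @param rotation_range degrees, default `c(-30, 30)`.
#' @param hflip allow a horizontal flip (drawn with probability 1/2).
#' @param brightness_range multiplicative range, default `c(0.5, 1.5)`;
#'   must be strictly positive.
#' @param seed integer seed for the three draws.
#' @return list with `image` ([spike_image()]) and `mask`.
#' @export
augment_pair <- function(image, mask, rotation_range = c(-30, 30),
                         hflip = TRUE, brightness_range = c(0.5, 1.5),
                         seed = 1) {
  stopifnot(inherits(image, "spike_image"),
            all(dim(mask) == c(image$height, image$width)))
  if (any(brightness_range <= 0)) {
    stop("brightness_range must be strictly positive")
  }
  set.seed(seed)
  angle <- stats::runif(1, rotation_range[1], rotation_range[2])
  do_flip <- hflip && stats::runif(1) < 0.5
  bright <- stats::runif(1, brightness_range[1], brightness_range[2])
  px <- image$pixels
  mk <- mask
  if (angle != 0) {
    H <- image$height; W <- image$width
    th <- angle * pi / 180
    ctr <- c((H + 1) / 2, (W + 1) / 2)
    g <- expand.grid(r = seq_len(H), c = seq_len(W))
    dr <- g$r - ctr[1]; dc <- g$c - ctr[2]
    # inverse mapping: rotate output coordinates back into the source
    sr <- ctr[1] + cos(th) * dr + sin(th) * dc
    sc <- ctr[2] - sin(th) * dr + cos(th) * dc
    fill <- median_border_color(px)
    px <- array(vapply(1:3, function(ch) {
      bilinear_sample(image$pixels[, , ch], sr, sc, fill[ch])
    }, numeric(H * W)), dim = c(H, W, 3))
    rn <- round(sr); cn <- round(sc)
    ok <- rn >= 1 & rn <= H & cn >= 1 & cn <= W
    mv <- rep(0L, H * W)
    mv[ok] <- mask[cbind(rn[ok], cn[ok])]
    mk <- matrix(mv, H, W)
  }
  if (do_flip) {
    px <- px[, ncol(mk):1, , drop = FALSE]
    mk <- mk[, ncol(mk):1, drop = FALSE]
  }
  px <- pmin(pmax(px * bright, 0), 255)
  list(image = spike_image(px, id = paste0(image$id, "_aug"),
                           view = image$view, phenotype = image$phenotype),
       mask = mk)
}
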