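# Seeded synthetic greenhouse scenes with exact ground truth. The
# generator emulates the statistical structure of side-view greenhouse
# imaging: a uniform blue background with sensor noise, a canopy of
# smooth curved leaf strokes, thin stem/tiller lines, and textured
# ellipse-plus-awn spikes in one of two colour regimes (GSGC: spike and
# canopy both green; YSYC: both yellow). Spikes fall into three
# categories: `top` (prominent above the canopy), `inner` (embedded in
# the leaf mass, partially covered by leaf strokes) and
# `occluded_emergent` (largely hidden behind an occluder). Everything is
# driven by a single integer seed, with no time-based state, so a scene
# is byte-identical across runs and platforms.

#' Scene configuration for the synthetic generator
#'
#' Defaults model a test-scale canvas of 512 x 595 pixels, the aspect
#' ratio of the full-resolution 2560 x 2976 side-view frames, with the
#' category mix at the proportions of the three spike categories in the
#' reference image set (80 top : 45 inner : 27 occluded/emergent out of
#' 152).
#'
#' @param height,width canvas size in pixels.
#' @param phenotype `"GSGC"` or `"YSYC"`.
#' @param n_spikes number of spikes to place.
#' @param category_mix named proportions over
#'   `top`, `inner`, `occluded_emergent`; must sum to 1.
#' @param n_leaves number of canopy leaf strokes.
#' @param n_stems number of thin stem/tiller lines.
#' @param spike_len_range range of the spike semi-major axis in pixels;
#'   the default suits the default canvas and scales down with it.
#' @param background_rgb background colour triple (0--255).
#' @param noise_sd Gaussian pixel noise standard deviation (intensity
#'   units, 0--255 scale).
#' @param seed integer seed.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(height = 595, width = 512, phenotype = c("GSGC", "YSYC"),
                         n_spikes = 5,
                         category_mix = c(top = 0.53, inner = 0.30,
                                          occluded_emergent = 0.17),
                         n_leaves = 12, n_stems = 3,
                         spike_len_range = c(16, 26),
                         background_rgb = c(30, 60, 150), noise_sd = 3,
                         seed = 1) {
  phenotype <- match.arg(phenotype)
  stopifnot(n_spikes >= 0, n_leaves >= 0, n_stems >= 0, noise_sd >= 0,
            length(spike_len_range) == 2, all(spike_len_range >= 6))
  if (abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix proportions must sum to 1")
  }
  if (!all(c("top", "inner", "occluded_emergent") %in% names(category_mix))) {
    stop("category_mix must name top, inner, occluded_emergent")
  }
  structure(
    list(height = height, width = width, phenotype = phenotype,
         n_spikes = n_spikes, category_mix = category_mix,
         n_leaves = n_leaves, n_stems = n_stems,
         spike_len_range = spike_len_range,
         background_rgb = background_rgb, noise_sd = noise_sd, seed = seed),
    class = "scene_config"
  )
}

hsv255 <- function(h, s, v) grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))

# Paint a set of pixels (n x 2 row/col matrix) into the canvas with an
# RGB triple per pixel (3 x n) and return the canvas.
paint <- function(canvas, rc, rgb) {
  for (ch in 1:3) {
    m <- canvas[, , ch]
    m[rc] <- rgb[ch, ]
    canvas[, , ch] <- m
  }
  canvas
}

# Pixels of a thick stroke along a quadratic Bezier curve.
stroke_pixels <- function(p0, p1, p2, width, H, W) {
  tt <- seq(0, 1, length.out = 4 * max(abs(p2 - p0)) + 8)
  pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
    outer(tt^2, p2)
  r <- max(width / 2, 0.5)
  off <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2 + 0.26, ]
  rr <- round(rep(pts[, 1], each = nrow(off)) + off$dr)
  cc <- round(rep(pts[, 2], each = nrow(off)) + off$dc)
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  unique(cbind(rr[ok], cc[ok]))
}

# Smoothly shaded organ colour: base HSV plus a gentle gradient along the
# row index. Returns a 3 x n matrix for the given pixels.
smooth_color <- function(rc, h, s, v) {
  shade <- 0.92 + 0.08 * (rc[, 1] %% 37) / 37
  grDevices::col2rgb(grDevices::hsv(h %% 1, s, pmin(v * shade, 1)))
}

palette_for <- function(phenotype) {
  if (phenotype == "GSGC") {
    list(leaf_h = c(0.25, 0.38), spike_h = c(0.26, 0.36),
         stem_h = c(0.27, 0.33), leaf_v = c(0.45, 0.65),
         spike_v = c(0.55, 0.80))
  } else {
    list(leaf_h = c(0.11, 0.17), spike_h = c(0.115, 0.165),
         stem_h = c(0.12, 0.16), leaf_v = c(0.55, 0.75),
         spike_v = c(0.65, 0.90))
  }
}

# Pixels of a textured spike: a rotated filled ellipse plus awns (short
# thin segments fanning out from the tip). Returns row/col pixels of the
# ellipse body and of the awns, plus a per-pixel grain intensity factor
# in [0.5, 1.5] that gives the body its high-frequency texture.
spike_geometry <- function(center, a, b, theta, H, W, rng_awns = 6) {
  margin <- ceiling(a + 2)
  rows <- max(1, floor(center[1] - margin)):min(H, ceiling(center[1] + margin))
  cols <- max(1, floor(center[2] - margin)):min(W, ceiling(center[2] + margin))
  g <- expand.grid(r = rows, c = cols)
  dr <- g$r - center[1]; dc <- g$c - center[2]
  u <- dr * cos(theta) + dc * sin(theta)     # along major axis
  w <- -dr * sin(theta) + dc * cos(theta)    # across
  inside <- (u / a)^2 + (w / b)^2 <= 1
  body <- cbind(g$r[inside], g$c[inside])
  grain <- 0.5 + 1.0 * ((sin(2 * pi * u[inside] / 3.4) *
                           sin(2 * pi * w[inside] / 2.6)) > 0)
  grain <- grain * stats::runif(length(grain), 0.85, 1.15)
  # awns from the upper tip
  tip <- c(center[1] - a * cos(theta), center[2] - a * sin(theta))
  awns <- NULL
  for (k in seq_len(rng_awns)) {
    ang <- theta + stats::runif(1, -0.5, 0.5)
    len <- stats::runif(1, 8, 15)
    tt <- seq(0, 1, length.out = 2 * len)
    rr <- round(tip[1] - tt * len * cos(ang))
    cc <- round(tip[2] - tt * len * sin(ang))
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    awns <- rbind(awns, cbind(rr[ok], cc[ok]))
  }
  if (!is.null(awns)) awns <- unique(awns)
  list(body = body, grain = pmin(grain, 1.5), awns = awns)
}

#' Generate one synthetic greenhouse scene with ground truth
#'
#' Deterministic for a fixed seed. Returns the rendered image, one
#' ground-truth box per spike tagged with its category, and the exact
#' binary mask of visible spike pixels. Boxes always cover the full
#' pre-occlusion extent of their spike (a partially hidden spike is still
#' one annotated object), while the mask contains only the pixels that
#' remain visible, so every box encloses at least one mask pixel and all
#' mask pixels lie inside the box union.
#'
#' @param config a [scene_config()].
#' @return a list of class `scene_truth` with `image` ([spike_image()]),
#'   `boxes` ([box_annotations()] with a `category` column), `mask`
#'   (binary matrix), `leaf_mask` (binary matrix of canopy pixels) and
#'   `stems` (list of row/col pixel matrices of the thin stem lines,
#'   useful for controlled false-positive experiments).
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  H <- config$height; W <- config$width
  pal <- palette_for(config$phenotype)
  canvas <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    canvas[, , ch] <- pmin(pmax(
      config$background_rgb[ch] + stats::rnorm(H * W, 0, config$noise_sd),
      0), 255)
  }
  # stems: thin near-vertical lines rising from the lower half
  stems <- list()
  for (k in seq_len(config$n_stems)) {
    c0 <- stats::runif(1, 0.1 * W, 0.9 * W)
    top_row <- stats::runif(1, 0.30 * H, 0.55 * H)
    p0 <- c(H, c0)
    p2 <- c(top_row, c0 + stats::runif(1, -0.05, 0.05) * W)
    p1 <- (p0 + p2) / 2 + c(0, stats::runif(1, -0.03, 0.03) * W)
    rc <- stroke_pixels(p0, p1, p2, width = 2.5, H = H, W = W)
    canvas <- paint(canvas, rc,
                    smooth_color(rc, stats::runif(1, pal$stem_h[1], pal$stem_h[2]),
                                 0.55, mean(pal$leaf_v) * 1.25))
    stems[[k]] <- rc
  }
  # canopy: smooth curved leaf strokes in the lower three quarters
  leaf_mask <- matrix(0L, H, W)
  draw_leaf <- function(p0, p1, p2, width) {
    rc <- stroke_pixels(p0, p1, p2, width, H, W)
    h <- stats::runif(1, pal$leaf_h[1], pal$leaf_h[2])
    v <- stats::runif(1, pal$leaf_v[1], pal$leaf_v[2])
    canvas <<- paint(canvas, rc, smooth_color(rc, h, stats::runif(1, 0.5, 0.75), v))
    leaf_mask[rc] <<- 1L
    rc
  }
  for (k in seq_len(config$n_leaves)) {
    base <- c(stats::runif(1, 0.75 * H, H), stats::runif(1, 0.05 * W, 0.95 * W))
    tip <- c(stats::runif(1, 0.28 * H, 0.75 * H),
             base[2] + stats::runif(1, -0.35, 0.35) * W)
    ctrl <- (base + tip) / 2 + c(stats::runif(1, -0.05, 0.05) * H,
                                 stats::runif(1, -0.15, 0.15) * W)
    draw_leaf(base, ctrl, tip, width = stats::runif(1, 5, 10))
  }
  # spikes
  boxes <- NULL
  mask <- matrix(0L, H, W)
  if (config$n_spikes > 0) {
    cats <- sample(names(config$category_mix), config$n_spikes,
                   replace = TRUE, prob = config$category_mix)
    placed_boxes <- list()
    for (s in seq_len(config$n_spikes)) {
      cat_s <- cats[s]
      a <- stats::runif(1, config$spike_len_range[1], config$spike_len_range[2])
      b <- a / stats::runif(1, 2.2, 3.2)
      theta <- stats::runif(1, -0.35, 0.35)
      ext <- a + 16          # spike extent incl. awns
      sep <- a + 8           # clash half-width between spike centres
      placed <- FALSE
      for (attempt in 1:1000) {
        row0 <- switch(cat_s,
          top = stats::runif(1, ext, max(ext + 1, 0.25 * H - 4)),
          inner = stats::runif(1, max(0.35 * H, ext), 0.75 * H),
          occluded_emergent = stats::runif(1, max(0.30 * H, ext), 0.70 * H))
        col0 <- stats::runif(1, ext, W - ext)
        bb <- c(row0 - sep, row0 + sep, col0 - sep, col0 + sep)
        clash <- any(vapply(placed_boxes, function(p) {
          bb[1] < p[2] && p[1] < bb[2] && bb[3] < p[4] && p[3] < bb[4]
        }, logical(1)))
        if (clash) next
        if (cat_s == "top") {
          rows <- max(1, floor(row0 - ext)):min(H, ceiling(row0 + a + 2))
          cols <- max(1, floor(col0 - b - 10)):min(W, ceiling(col0 + b + 10))
          if (sum(leaf_mask[rows, cols]) > 0) next
        }
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place spike ", s, " after 1000 attempts")
      placed_boxes[[length(placed_boxes) + 1]] <- bb
      geom <- spike_geometry(c(row0, col0), a, b, theta, H, W)
      h_s <- stats::runif(1, pal$spike_h[1], pal$spike_h[2])
      v_s <- stats::runif(1, pal$spike_v[1], pal$spike_v[2])
      nb <- nrow(geom$body)
      body_rgb <- grDevices::col2rgb(grDevices::hsv(
        h_s, stats::runif(nb, 0.45, 0.65), pmin(v_s * geom$grain, 1)))
      canvas <- paint(canvas, geom$body, body_rgb)
      spike_px <- geom$body
      if (!is.null(geom$awns) && nrow(geom$awns) > 0) {
        na_ <- nrow(geom$awns)
        awn_rgb <- grDevices::col2rgb(grDevices::hsv(
          h_s, 0.5, pmin(v_s * stats::runif(na_, 0.8, 1.3), 1)))
        canvas <- paint(canvas, geom$awns, awn_rgb)
        spike_px <- rbind(spike_px, geom$awns)
      }
      visible <- rep(TRUE, nrow(spike_px))
      if (cat_s == "inner") {
        # cross the spike with leaf strokes until >= 30% covered
        covered <- logical(nrow(spike_px))
        for (j in 1:3) {
          if (mean(covered) >= 0.30) break
          ang <- stats::runif(1, 0, pi)
          half <- c(cos(ang), sin(ang)) * (a + 12)
          lrc <- draw_leaf(c(row0, col0) - half,
                           c(row0, col0) + c(stats::runif(1, -6, 6),
                                             stats::runif(1, -6, 6)),
                           c(row0, col0) + half,
                           width = stats::runif(1, max(4, 0.8 * b), 1.6 * b))
          lm <- matrix(FALSE, H, W); lm[lrc] <- TRUE
          covered <- covered | lm[spike_px]
        }
        visible <- !covered
      } else if (cat_s == "occluded_emergent") {
        # erase 40-60% behind a big occluding blob of leaf colour
        dir <- stats::runif(1, 0, 2 * pi)
        occ_c <- c(row0 + 0.7 * a * cos(dir), col0 + 0.7 * a * sin(dir))
        rad <- 0.8 * a
        repeat {
          dr <- spike_px[, 1] - occ_c[1]; dc <- spike_px[, 2] - occ_c[2]
          hid <- dr^2 + dc^2 <= rad^2
          if (mean(hid) >= 0.40 || rad > 4 * a) break
          rad <- rad * 1.12
        }
        occ_rc <- {
          rows <- max(1, floor(occ_c[1] - rad)):min(H, ceiling(occ_c[1] + rad))
          cols <- max(1, floor(occ_c[2] - rad)):min(W, ceiling(occ_c[2] + rad))
          g <- expand.grid(r = rows, c = cols)
          keep <- (g$r - occ_c[1])^2 + (g$c - occ_c[2])^2 <= rad^2
          cbind(g$r[keep], g$c[keep])
        }
        canvas <- paint(canvas, occ_rc,
                        smooth_color(occ_rc,
                                     stats::runif(1, pal$leaf_h[1], pal$leaf_h[2]),
                                     0.6, stats::runif(1, pal$leaf_v[1], pal$leaf_v[2])))
        leaf_mask[occ_rc] <- 1L
        visible <- !hid
      }
      if (!any(visible)) visible[which.max(spike_px[, 1])] <- TRUE
      vis_px <- spike_px[visible, , drop = FALSE]
      mask[vis_px] <- 1L
      boxes <- rbind(boxes, data.frame(
        xmin = min(spike_px[, 2]) - 1, ymin = min(spike_px[, 1]) - 1,
        xmax = max(spike_px[, 2]), ymax = max(spike_px[, 1]),
        category = cat_s, stringsAsFactors = FALSE
      ))
    }
  }
  box_tab <- if (is.null(boxes)) box_annotations() else
    box_annotations(boxes$xmin, boxes$ymin, boxes$xmax, boxes$ymax,
                    category = boxes$category, image_size = c(H, W))
  img <- spike_image(canvas, id = sprintf("scene_%d", config$seed),
                     view = "side", phenotype = config$phenotype)
  structure(
    list(image = img, boxes = box_tab, mask = mask,
         leaf_mask = leaf_mask, stems = stems, config = config),
    class = "scene_truth"
  )
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes for every scene the PNG image, the VOC-XML box file and the
#' mask PNG, plus a `manifest.csv` (id, phenotype, spike counts per
#' category, per-image seed) and the generator configuration as YAML.
#' Per-image seeds are derived deterministically from the master seed, so
#' two runs with the same arguments produce identical datasets.
#'
#' @param config template [scene_config()]; its seed field is replaced by
#'   the derived per-image seeds.
#' @param n_images number of scenes.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest data.frame (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(config = scene_config(), n_images, out_dir,
                             seed = 1, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty (use overwrite = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(n_images)) {
    cfg <- config
    cfg$seed <- (seed * 1009 + i * 9973) %% 2147483647L
    sc <- generate_scene(cfg)
    id <- sprintf("scene_%04d", i)
    sc$image$id <- id
    write_image(sc$image, file.path(out_dir, paste0(id, ".png")))
    write_boxes(sc$boxes, file.path(out_dir, paste0(id, ".xml")),
                dialect = "voc_xml", image_size = c(cfg$height, cfg$width))
    write_mask(sc$mask, file.path(out_dir, paste0(id, "_mask.png")),
               encoding = "0255")
    tab <- table(factor(sc$boxes$category,
                        levels = c("top", "inner", "occluded_emergent")))
    rows[[i]] <- data.frame(
      id = id, phenotype = cfg$phenotype, n_spikes = nrow(sc$boxes),
      n_top = as.integer(tab["top"]), n_inner = as.integer(tab["inner"]),
      n_occluded_emergent = as.integer(tab["occluded_emergent"]),
      height = cfg$height, width = cfg$width, seed = cfg$seed,
      stringsAsFactors = FALSE
    )
  }
  manifest <- if (n_images > 0) do.call(rbind, rows) else
    data.frame(id = character(), phenotype = character(),
               n_spikes = integer(), n_top = integer(), n_inner = integer(),
               n_occluded_emergent = integer(), height = integer(),
               width = integer(), seed = integer())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  manifest
}
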