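# Per-spike trait extraction: 70 shape, colour and texture descriptors
# per segmented spike region, in a fixed, versioned registry so trait
# tables from different runs are column-compatible.

#' Extract labelled regions from a mask
#'
#' 8-connected components of at least `min_area` pixels, ordered
#' deterministically by centroid (row-major).
#'
#' @param mask binary matrix.
#' @param min_area minimum component area in pixels.
#' @return list of regions, each a list with `pixels` (linear indices into
#'   the mask), `coords` (n x 2 matrix of row, col), `area`, `centroid`
#'   and `bbox` (0-based half-open `xmin, ymin, xmax, ymax`).
#' @export
extract_regions <- function(mask, min_area = 1) {
  stopifnot(is.matrix(mask))
  if (sum(mask != 0) == 0) return(list())
  lab <- label_components8(mask)
  regions <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    if (length(idx) < min_area) next
    rc <- cbind(row = (idx - 1) %% nrow(mask) + 1,
                col = (idx - 1) %/% nrow(mask) + 1)
    regions[[length(regions) + 1]] <- list(
      pixels = idx, coords = rc, area = length(idx),
      centroid = c(row = mean(rc[, 1]), col = mean(rc[, 2])),
      bbox = c(xmin = min(rc[, 2]) - 1, ymin = min(rc[, 1]) - 1,
               xmax = max(rc[, 2]), ymax = max(rc[, 1]))
    )
  }
  if (length(regions) == 0) return(list())
  ord <- order(vapply(regions, function(r) r$centroid["row"], numeric(1)),
               vapply(regions, function(r) r$centroid["col"], numeric(1)))
  regions[ord]
}

#' The spike trait registry
#'
#' The fixed, versioned list of the 70 descriptors computed per spike
#' region: 12 shape, 32 colour and 26 texture descriptors. Shape
#' descriptors are invariant to recolouring; colour descriptors are
#' invariant to translation of the region. Hue statistics are circular
#' (mean resultant direction and circular standard deviation) to avoid
#' the 0/360 wrap artifact. The perimeter is a Cauchy--Crofton estimate
#' (exposed pixel-edge count scaled by pi/4), which is asymptotically
#' exact for smooth convex regions.
#'
#' @return data.frame with columns `name`, `family`
#'   (`shape`/`color`/`texture`) and `units`.
#' @export
trait_registry <- function() {
  shape <- c(area = "px^2", perimeter = "px", bbox_width = "px",
             bbox_height = "px", aspect_ratio = "ratio", extent = "ratio",
             solidity = "ratio", eccentricity = "ratio",
             major_axis_length = "px", minor_axis_length = "px",
             orientation = "rad", compactness = "ratio")
  color_stats <- as.vector(outer(c("mean", "sd", "min", "max"),
                                 c("R", "G", "B", "H", "S", "V"),
                                 function(s, ch) paste0(ch, "_", s)))
  color <- c(stats::setNames(rep("intensity", length(color_stats)), color_stats),
             stats::setNames(rep("proportion", 8), paste0("hue_hist_", 1:8)))
  laws <- names(laws_masks())
  texture <- c(
    stats::setNames(rep("energy", 18),
                    c(paste0("laws_", laws, "_mean"), paste0("laws_", laws, "_sd"))),
    stats::setNames(rep("glcm", 8),
                    as.vector(outer(c("contrast", "homogeneity", "energy",
                                      "correlation"),
                                    c("h", "v"),
                                    function(s, o) paste0("glcm_", s, "_", o))))
  )
  data.frame(
    name = c(names(shape), names(color), names(texture)),
    family = c(rep("shape", length(shape)), rep("color", length(color)),
               rep("texture", length(texture))),
    units = unname(c(shape, color, texture)),
    stringsAsFactors = FALSE
  )
}

# Cauchy-Crofton perimeter: pi/4 times the number of region pixel edges
# exposed to the background (image borders count as exposed).
region_perimeter <- function(bin) {
  p <- matrix(0L, nrow(bin) + 2, ncol(bin) + 2)
  p[2:(nrow(bin) + 1), 2:(ncol(bin) + 1)] <- bin
  core <- p[2:(nrow(bin) + 1), 2:(ncol(bin) + 1)]
  exposed <- (core & !p[1:nrow(bin), 2:(ncol(bin) + 1)]) +
    (core & !p[3:(nrow(bin) + 2), 2:(ncol(bin) + 1)]) +
    (core & !p[2:(nrow(bin) + 1), 1:ncol(bin)]) +
    (core & !p[2:(nrow(bin) + 1), 3:(ncol(bin) + 2)])
  sum(exposed) * pi / 4
}

# Convex hull area over the corners of the region's pixels (so a filled
# rectangle has solidity exactly 1).
hull_area <- function(rc) {
  pts <- rbind(
    cbind(rc[, 1] - 0.5, rc[, 2] - 0.5), cbind(rc[, 1] - 0.5, rc[, 2] + 0.5),
    cbind(rc[, 1] + 0.5, rc[, 2] - 0.5), cbind(rc[, 1] + 0.5, rc[, 2] + 0.5)
  )
  h <- grDevices::chull(pts)
  x <- pts[h, 2]; y <- pts[h, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

circ_stats <- function(hue) {
  ang <- 2 * pi * hue
  c_bar <- mean(cos(ang)); s_bar <- mean(sin(ang))
  rbar <- sqrt(c_bar^2 + s_bar^2)
  mu <- atan2(s_bar, c_bar) / (2 * pi)
  if (mu < 0) mu <- mu + 1
  sdv <- if (rbar > 0) sqrt(pmax(-2 * log(rbar), 0)) / (2 * pi) else NA_real_
  c(mean = mu, sd = sdv)
}

glcm_stats <- function(q, coords, mask_shape, offset, levels = 8) {
  # q: quantized gray matrix; pairs with both pixels inside the region
  inside <- matrix(FALSE, mask_shape[1], mask_shape[2])
  inside[coords] <- TRUE
  r2 <- coords[, 1] + offset[1]
  c2 <- coords[, 2] + offset[2]
  ok <- r2 >= 1 & r2 <= mask_shape[1] & c2 >= 1 & c2 <= mask_shape[2]
  ok[ok] <- inside[cbind(r2[ok], c2[ok])]
  if (!any(ok)) {
    # degenerate (e.g. 1-pixel region): uniform fallback
    return(c(contrast = 0, homogeneity = 1, energy = 1, correlation = 0))
  }
  i <- q[coords[ok, , drop = FALSE]]
  j <- q[cbind(r2[ok], c2[ok])]
  P <- matrix(0, levels, levels)
  for (t in seq_along(i)) P[i[t], j[t]] <- P[i[t], j[t]] + 1
  P <- (P + t(P)) / (2 * length(i))   # symmetric, normalised
  iv <- row(P); jv <- col(P)
  mu_i <- sum(iv * P); mu_j <- sum(jv * P)
  sd_i <- sqrt(sum((iv - mu_i)^2 * P)); sd_j <- sqrt(sum((jv - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((iv - mu_i) * (jv - mu_j) * P) / (sd_i * sd_j)
  } else 0
  c(contrast = sum((iv - jv)^2 * P),
    homogeneity = sum(P / (1 + (iv - jv)^2)),
    energy = sum(P^2),
    correlation = corr)
}

#' Compute the spike trait table
#'
#' One row per region with the 70 descriptors of [trait_registry()]:
#' shape from the region geometry, colour from the RGB and HSV
#' distributions of the region's pixels (with circular hue statistics and
#' an 8-bin hue histogram), texture from the mean and standard deviation
#' of the nine full-resolution Laws energy channels inside the region
#' plus four grey-level co-occurrence statistics at the horizontal and
#' vertical unit offsets. Single-pixel regions fall back to degenerate
#' texture values with a warning.
#'
#' @param image a [spike_image()].
#' @param regions output of [extract_regions()] on the paired mask.
#' @return data.frame: `region_id`, `image_id`, then the 70 registry
#'   columns in registry order.
#' @export
compute_traits <- function(image, regions) {
  stopifnot(inherits(image, "spike_image"))
  reg <- trait_registry()
  if (length(regions) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, nrow(reg) + 2))
    names(out) <- c("region_id", "image_id", reg$name)
    return(out)
  }
  gray <- rgb_to_gray(image$pixels)
  energies <- lapply(laws_convolve(gray), texture_energy, n = 1)
  q <- pmin(floor(gray * 8) + 1, 8)   # 8 grey levels for the GLCM
  rows <- lapply(seq_along(regions), function(ri) {
    r <- regions[[ri]]
    rc <- r$coords
    if (r$area < 2) warning("region ", ri, " is degenerate (single pixel); ",
                            "texture descriptors fall back to region values")
    bin <- matrix(0L, image$height, image$width)
    bin[rc] <- 1L
    mom <- region_moments(rc)
    per <- region_perimeter(bin)
    bw <- r$bbox["xmax"] - r$bbox["xmin"]
    bh <- r$bbox["ymax"] - r$bbox["ymin"]
    shape <- c(
      area = r$area, perimeter = per, bbox_width = unname(bw),
      bbox_height = unname(bh),
      aspect_ratio = mom$major_axis / max(mom$minor_axis, 1e-9),
      extent = r$area / (bw * bh),
      solidity = min(r$area / hull_area(rc), 1),
      eccentricity = mom$eccentricity,
      major_axis_length = mom$major_axis,
      minor_axis_length = mom$minor_axis,
      orientation = mom$orientation,
      compactness = 4 * pi * r$area / per^2
    )
    R <- image$pixels[, , 1][rc]; G <- image$pixels[, , 2][rc]
    B <- image$pixels[, , 3][rc]
    hsv <- grDevices::rgb2hsv(rbind(R, G, B), maxColorValue = 255)
    hue <- hsv[1, ]; sat <- hsv[2, ]; val <- hsv[3, ]
    cs <- circ_stats(hue)
    sdv <- function(x) if (length(x) > 1) stats::sd(x) else 0
    color <- c(
      mean(R), sdv(R), min(R), max(R),
      mean(G), sdv(G), min(G), max(G),
      mean(B), sdv(B), min(B), max(B),
      cs["mean"], if (is.na(cs["sd"])) 0 else cs["sd"], min(hue), max(hue),
      mean(sat), sdv(sat), min(sat), max(sat),
      mean(val), sdv(val), min(val), max(val),
      as.vector(table(cut(hue, seq(0, 1, by = 1 / 8), include.lowest = TRUE,
                          right = FALSE)) / length(hue))
    )
    law_mean <- vapply(energies, function(e) mean(e[rc]), numeric(1))
    law_sd <- vapply(energies, function(e) if (r$area > 1) stats::sd(e[rc]) else 0,
                     numeric(1))
    glcm <- c(glcm_stats(q, rc, dim(gray), c(0, 1)),
              glcm_stats(q, rc, dim(gray), c(1, 0)))
    vals <- c(shape, color, law_mean, law_sd, glcm)
    names(vals) <- reg$name
    cbind(data.frame(region_id = ri, image_id = image$id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  do.call(rbind, rows)
}
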