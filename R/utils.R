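# Internal numeric helpers shared across the texture, filtering and
# phenotyping code. All image matrices are row-major (H x W), values numeric.

#' @keywords internal
#' @noRd
pad_replicate <- function(x, top, bottom = top, left = top, right = top) {
  stopifnot(is.matrix(x))
  ri <- c(rep(1L, top), seq_len(nrow(x)), rep(nrow(x), bottom))
  ci <- c(rep(1L, left), seq_len(ncol(x)), rep(ncol(x), right))
  x[ri, ci, drop = FALSE]
}

# 2-D sliding-window filtering (cross-correlation): out(i,j) =
# sum_{u,v} k(u,v) x(i+u, j+v), with edge replication; output has the
# same size as the input. Equivalent to convolution with the
# point-reflected kernel, so filtering an impulse stamps the flipped
# kernel at its location. Kernel dimensions must be odd.
#' @keywords internal
#' @noRd
conv2_replicate <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  a <- (kr - 1L) %/% 2L
  b <- (kc - 1L) %/% 2L
  xp <- pad_replicate(x, a, a, b, b)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (u in -a:a) {
    for (v in -b:b) {
      k <- kernel[u + a + 1L, v + b + 1L]
      if (k == 0) next
      out <- out + k * xp[(1:H) + u + a, (1:W) + v + b, drop = FALSE]
    }
  }
  out
}

# Separable convolution with symmetric 1-D kernels (or generic 1-D kernels
# applied as convolution along rows then columns), edge replication.
#' @keywords internal
#' @noRd
conv_sep_replicate <- function(x, krow, kcol) {
  # krow applied along the row index (vertical), kcol along columns.
  a <- (length(krow) - 1L) %/% 2L
  b <- (length(kcol) - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  xp <- pad_replicate(x, a, a, 0L, 0L)
  tmp <- matrix(0, H, W)
  for (u in -a:a) {
    k <- krow[u + a + 1L]
    if (k == 0) next
    tmp <- tmp + k * xp[(1:H) + u + a, , drop = FALSE]
  }
  tp <- pad_replicate(tmp, 0L, 0L, b, b)
  out <- matrix(0, H, W)
  for (v in -b:b) {
    k <- kcol[v + b + 1L]
    if (k == 0) next
    out <- out + k * tp[, (1:W) + v + b, drop = FALSE]
  }
  out
}

# Mean over a (2n+1)x(2n+1) window with edge replication, via an integral
# image on the padded matrix (exact up to float rounding, O(HW)).
#' @keywords internal
#' @noRd
box_mean_replicate <- function(x, n) {
  stopifnot(n >= 1)
  H <- nrow(x); W <- ncol(x)
  xp <- pad_replicate(x, n)
  # summed-area table with a zero first row/col
  sat <- matrix(0, nrow(xp) + 1L, ncol(xp) + 1L)
  sat[-1, -1] <- apply(apply(xp, 2, cumsum), 1, cumsum) |> t()
  w <- 2L * n + 1L
  i1 <- 1:H; j1 <- 1:W
  s <- sat[i1 + w, j1 + w, drop = FALSE] - sat[i1, j1 + w, drop = FALSE] -
    sat[i1 + w, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]
  s / (w * w)
}

# Luminance in [0, 1] from an H x W x 3 array scaled 0..255.
#' @keywords internal
#' @noRd
rgb_to_gray <- function(pixels) {
  (0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]) / 255
}

# Nearest-neighbour upsampling of a matrix to a target size (used to bring
# half-resolution wavelet-domain features back to image resolution).
#' @keywords internal
#' @noRd
upsample_nearest <- function(x, height, width) {
  ri <- pmin(ceiling(seq_len(height) / (height / nrow(x))), nrow(x))
  ci <- pmin(ceiling(seq_len(width) / (width / ncol(x))), ncol(x))
  x[ri, ci, drop = FALSE]
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged afterwards with a small union-find pass.
#' @keywords internal
#' @noRd
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(mask != 0))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  merge_pairs <- function(a, b) {
    keep <- a != 0 & b != 0 & a != b
    if (!any(keep)) return(invisible())
    for (p in unique(paste(a[keep], b[keep]))) {
      ij <- as.integer(strsplit(p, " ")[[1]])
      ra <- find(ij[1]); rb <- find(ij[2])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  merge_pairs(lab[-H, -W], lab[-1, -1])   # down-right diagonal
  merge_pairs(lab[-1, -W], lab[-H, -1])   # up-right diagonal
  root <- vapply(seq_len(nlab), find, integer(1))
  root <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}

# Shape statistics of a pixel set given as an n x 2 matrix of (row, col)
# indices: central moments, axis lengths and eccentricity as used by the
# Frangi component filter and the trait extractor.
#' @keywords internal
#' @noRd
region_moments <- function(rc) {
  n <- nrow(rc)
  mr <- mean(rc[, 1]); mc <- mean(rc[, 2])
  dr <- rc[, 1] - mr; dc <- rc[, 2] - mc
  # pixel-grid covariance with the 1/12 term for unit-square pixels
  mu20 <- sum(dc^2) / n + 1 / 12
  mu02 <- sum(dr^2) / n + 1 / 12
  mu11 <- sum(dr * dc) / n
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  l2 <- max(l2, 0)
  list(
    centroid = c(row = mr, col = mc),
    major_axis = 4 * sqrt(l1),
    minor_axis = 4 * sqrt(l2),
    eccentricity = if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0,
    orientation = 0.5 * atan2(-2 * mu11, mu20 - mu02)
  )
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
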