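#' Level-1 Haar approximation (LL) subband
#'
#' Computes the approximation band of a one-level discrete wavelet
#' transform with the Haar basis, in the averaging normalisation: each
#' output value is the mean of a non-overlapping 2x2 block, so a constant
#' image maps to the same constant. Images with an odd number of rows or
#' columns are padded by edge replication before the transform.
#'
#' The LL band serves as the smoothed, half-resolution input of the
#' texture feature pipeline; the detail bands are not used.
#'
#' @param image_gray numeric `H x W` matrix, `H, W >= 2`.
#' @return a numeric matrix of size `ceiling(H/2) x ceiling(W/2)`.
#' @export
haar_ll <- function(image_gray) {
  if (!is.matrix(image_gray) || nrow(image_gray) < 2 || ncol(image_gray) < 2) {
    stop("image must be a matrix with at least 2 rows and 2 columns")
  }
  if (anyNA(image_gray) || any(!is.finite(image_gray))) {
    stop("image contains non-finite values")
  }
  x <- image_gray
  if (nrow(x) %% 2 == 1) x <- rbind(x, x[nrow(x), ])
  if (ncol(x) %% 2 == 1) x <- cbind(x, x[, ncol(x)])
  odd_r <- seq(1, nrow(x), by = 2)
  odd_c <- seq(1, ncol(x), by = 2)
  (x[odd_r, odd_c, drop = FALSE] + x[odd_r + 1, odd_c, drop = FALSE] +
      x[odd_r, odd_c + 1, drop = FALSE] + x[odd_r + 1, odd_c + 1, drop = FALSE]) / 4
}

#' The nine 3x3 Laws texture masks
#'
#' Outer products of the classic level, edge and spot vectors
#' `L3 = (1, 2, 1)`, `E3 = (-1, 0, 1)`, `S3 = (-1, 2, -1)`. Every mask with
#' an `E3` or `S3` factor sums to zero, so its response vanishes on
#' constant regions; only `L3L3` (a smoothing mask) has non-zero sum.
#'
#' @return a named list of nine 3x3 matrices in the fixed channel order
#'   `L3L3, L3E3, L3S3, E3L3, E3E3, E3S3, S3L3, S3E3, S3S3` (first factor
#'   along rows, second along columns).
#' @export
laws_masks <- function() {
  v <- list(L3 = c(1, 2, 1), E3 = c(-1, 0, 1), S3 = c(-1, 2, -1))
  out <- list()
  for (a in names(v)) {
    for (b in names(v)) {
      out[[paste0(a, b)]] <- outer(v[[a]], v[[b]])
    }
  }
  out
}

#' Convolve an image with the Laws mask set
#'
#' Applies each of the nine masks to the `(2n+1)^2` neighbourhood of every
#' pixel (sliding-window filtering, i.e. convolution with the
#' point-reflected mask; an impulse input therefore stamps the flipped
#' mask), with edge replication at the borders so the responses have the
#' same size as the input.
#'
#' @param image numeric matrix, at least 3x3, all values finite.
#' @param masks a mask set from [laws_masks()].
#' @return a named list of nine response matrices, same size as `image`,
#'   in the fixed channel order of [laws_masks()].
#' @export
laws_convolve <- function(image, masks = laws_masks()) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3) {
    stop("image must be a matrix of size at least 3 x 3")
  }
  if (anyNA(image) || any(!is.finite(image))) {
    stop("image contains non-finite values")
  }
  lapply(masks, function(k) conv2_replicate(image, k))
}

#' Texture energy by macro-window averaging
#'
#' Converts a raw filter response into a local energy map: the mean of the
#' absolute response over a `(2n+1) x (2n+1)` window centred at each
#' pixel, with edge replication at the borders. The window mean is
#' normalised by the full window area `(2n+1)^2`, so a constant response
#' of magnitude `c` yields energy `c` everywhere. Energies are
#' non-negative by construction.
#'
#' @param response numeric matrix (a Laws filter response).
#' @param n macro-window half-size; the window spans `2n+1` pixels.
#' @return a non-negative matrix of the same size.
#' @export
texture_energy <- function(response, n = 7) {
  if (n < 1) stop("n must be >= 1")
  if (n > min(dim(response)) / 2) {
    stop("macro-window half-size exceeds half the image extent")
  }
  # the summed-area table can leave values a few ulp below zero
  pmax(box_mean_replicate(abs(response), n), 0)
}

#' Assemble the per-pixel feature stack
#'
#' The feature chain of the shallow segmentation network: grayscale
#' conversion, optional Haar LL smoothing to half resolution, the nine
#' Laws convolutions, macro-window energy per channel, nearest-neighbour
#' upsampling back to image resolution when the wavelet step was used, and
#' optionally the raw R, G, B channels scaled to `[0, 1]`.
#'
#' @param image a [spike_image()].
#' @param use_dwt compute texture features on the half-resolution Haar LL
#'   band (default) rather than at full resolution.
#' @param n macro-window half-size passed to [texture_energy()].
#' @param include_color append the raw colour channels (default `TRUE`).
#' @return an object of class `pixel_features`: list with `features`
#'   (`H x W x K` array), `names` (length-`K` provenance vector) and the
#'   configuration used.
#' @export
assemble_pixel_features <- function(image, use_dwt = TRUE, n = 7,
                                    include_color = TRUE) {
  stopifnot(inherits(image, "spike_image"))
  gray <- rgb_to_gray(image$pixels)
  base <- if (use_dwt) haar_ll(gray) else gray
  responses <- laws_convolve(base)
  energies <- lapply(responses, texture_energy, n = n)
  if (use_dwt) {
    energies <- lapply(energies, upsample_nearest,
                       height = image$height, width = image$width)
  }
  nms <- paste0("energy_", names(energies))
  if (include_color) {
    energies <- c(energies,
                  list(R = image$pixels[, , 1] / 255,
                       G = image$pixels[, , 2] / 255,
                       B = image$pixels[, , 3] / 255))
    nms <- c(nms, "R", "G", "B")
  }
  feat <- array(unlist(energies, use.names = FALSE),
                dim = c(image$height, image$width, length(energies)))
  if (anyNA(feat) || any(!is.finite(feat))) {
    stop("non-finite values in feature stack")
  }
  structure(
    list(features = feat, names = nms,
         config = list(use_dwt = use_dwt, n = n,
                       include_color = include_color)),
    class = "pixel_features"
  )
}
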