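#' Construct an image record
#'
#' The package-internal image container: an `H x W x 3` numeric array of
#' 8-bit RGB values (0--255) plus identification metadata. Side-view
#' greenhouse frames carry a `view` tag and a phenotype tag distinguishing
#' the two colour regimes in which spike and canopy share a colour
#' fingerprint: GSGC (green spike, green canopy) and YSYC (yellow spike,
#' yellow canopy).
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 255]`.
#' @param id image identifier string.
#' @param view one of `"side"`, `"top"`, `"unknown"`.
#' @param phenotype one of `"GSGC"`, `"YSYC"`, `"unknown"`.
#' @return an object of class `spike_image` with fields `pixels`, `height`,
#'   `width`, `id`, `view`, `phenotype`.
#' @export
spike_image <- function(pixels, id = "image", view = "unknown",
                        phenotype = "unknown") {
  if (length(dim(pixels)) == 2) {
    pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  }
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] >= 1, dim(pixels)[2] >= 1)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  view <- match.arg(view, c("side", "top", "unknown"))
  phenotype <- match.arg(phenotype, c("GSGC", "YSYC", "unknown"))
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2],
         id = id, view = view, phenotype = phenotype),
    class = "spike_image"
  )
}

#' @export
print.spike_image <- function(x, ...) {
  cat(sprintf("<spike_image '%s'> %d x %d px, view=%s, phenotype=%s\n",
              x$id, x$height, x$width, x$view, x$phenotype))
  invisible(x)
}

#' Read an RGB image from PNG or JPEG
#'
#' Grayscale files are promoted to three identical channels; an alpha
#' channel, if present, is dropped. The image id is taken from the file
#' stem.
#'
#' @param path path to a decodable PNG or JPEG file.
#' @inheritParams spike_image
#' @return a [spike_image()].
#' @export
read_image <- function(path, view = "unknown", phenotype = "unknown") {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image '", path,
                                           "': ", conditionMessage(e)))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2) {
    dat <- array(rep(dat, 3), dim = c(dim(dat), 3))
  } else if (dim(dat)[3] > 3) {
    dat <- dat[, , 1:3, drop = FALSE]
  } else if (dim(dat)[3] == 1) {
    dat <- array(rep(dat[, , 1], 3), dim = c(dim(dat)[1:2], 3))
  }
  # EBImage stores x (columns) as the first dimension
  pixels <- aperm(dat, c(2, 1, 3)) * 255
  spike_image(pixels, id = sub("\\.[^.]*$", "", basename(path)),
              view = view, phenotype = phenotype)
}

#' Write an RGB image to PNG
#'
#' @param image a [spike_image()].
#' @param path output path (PNG).
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "spike_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Read a binary segmentation mask
#'
#' Masks follow the convention that spike pixels carry the value 1 and
#' background pixels the value 0. Files stored with a 0/255 encoding are
#' accepted: any pixel value greater than zero maps to 1. An RGB mask file
#' is accepted with a warning and binarised by the any-channel-positive
#' rule.
#'
#' @param path path to a grayscale PNG mask.
#' @return an integer `H x W` matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 3) {
    if (dim(dat)[3] > 1) {
      warning("RGB mask file; binarising by any-channel > 0")
    }
    dat <- do.call(pmax, lapply(seq_len(dim(dat)[3]), function(k) dat[, , k]))
  }
  m <- t(dat)
  mask <- matrix(0L, nrow(m), ncol(m))
  mask[m > 0] <- 1L
  mask
}

#' Write a binary segmentation mask to grayscale PNG
#'
#' @param mask integer matrix with values in `{0, 1}`.
#' @param path output path (PNG).
#' @param encoding `"01"` writes raw labels (spike pixels have gray value
#'   1), `"0255"` writes a human-visible mask (spike pixels 255).
#' @export
write_mask <- function(mask, path, encoding = c("0255", "01")) {
  encoding <- match.arg(encoding)
  if (!all(mask %in% c(0, 1))) {
    stop("mask values must be 0 or 1")
  }
  level <- if (encoding == "01") 1 / 255 else 1
  png::writePNG(matrix(as.numeric(mask) * level, nrow(mask), ncol(mask)),
                path)
  invisible(path)
}
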