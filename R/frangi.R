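# Multiscale Frangi vesselness and the component-level false-positive
# filter built on it. Spikes segment as compact blobs while leaf and
# tiller edges segment as long thin components; the Hessian-eigenvalue
# vesselness score separates the two geometries.

# Gaussian and Gaussian-derivative taps for a given sigma (radius 3*sigma).
gauss_taps <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  gxx <- (x^2 / sigma^4 - 1 / sigma^2) * g
  # zero-centre the truncated second-derivative taps so that a constant
  # image has an exactly zero Hessian
  gxx <- gxx - mean(gxx)
  list(g = g, gxx = gxx, gx = (-x / sigma^2) * g)
}

# Scale-normalised Hessian of a 2-D image at one Gaussian scale.
hessian_at_scale <- function(x, sigma) {
  t <- gauss_taps(sigma)
  s2 <- sigma^2
  list(
    hrr = s2 * conv_sep_replicate(x, t$gxx, t$g),
    hcc = s2 * conv_sep_replicate(x, t$g, t$gxx),
    hrc = s2 * conv_sep_replicate(x, t$gx, t$gx)
  )
}

#' Multiscale Frangi vesselness
#'
#' The standard 2-D Frangi line filter: at each Gaussian scale the
#' scale-normalised Hessian eigenvalues `lambda1, lambda2` (ordered
#' `|lambda1| <= |lambda2|`) give the blobness ratio
#' `R_B = lambda1/lambda2` and the structureness `S = sqrt(lambda1^2 +
#' lambda2^2)`; the response is
#' `exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 gamma^2)))`,
#' zeroed where the eigenvalue sign contradicts the configured polarity
#' (bright ridges require `lambda2 < 0`, dark ridges `lambda2 > 0`). The
#' final map is the per-pixel maximum over scales and lies in `[0, 1]`.
#'
#' @param image_gray numeric matrix (any intensity scale).
#' @param scales Gaussian sigmas in pixels; one response per scale.
#' @param beta blobness sensitivity.
#' @param gamma structureness sensitivity, or `"auto"` to use half the
#'   maximum structureness at each scale (a constant image then yields an
#'   all-zero map, with no division by zero).
#' @param bright_ridges detect bright lines on a dark background
#'   (default) or the reverse.
#' @return an object of class `vesselness_map`: list with `vesselness`
#'   (matrix in `[0, 1]`) and `scales`.
#' @export
frangi_vesselness <- function(image_gray, scales = c(1, 2, 3, 4),
                              beta = 0.5, gamma = "auto",
                              bright_ridges = TRUE) {
  stopifnot(is.matrix(image_gray), length(scales) >= 1, all(scales > 0))
  best <- matrix(0, nrow(image_gray), ncol(image_gray))
  for (sigma in scales) {
    h <- hessian_at_scale(image_gray, sigma)
    disc <- sqrt(((h$hrr - h$hcc) / 2)^2 + h$hrc^2)
    mid <- (h$hrr + h$hcc) / 2
    mu1 <- mid + disc
    mu2 <- mid - disc
    # order by absolute value: lambda2 is the larger-magnitude eigenvalue
    swap <- abs(mu1) > abs(mu2)
    lambda1 <- ifelse(swap, mu2, mu1)
    lambda2 <- ifelse(swap, mu1, mu2)
    S2 <- lambda1^2 + lambda2^2
    g2 <- if (identical(gamma, "auto")) {
      smax <- sqrt(max(S2))
      # guard: a (numerically) constant image has no structure at all
      if (smax < 1e-8) next
      (smax / 2)^2
    } else gamma^2
    rb2 <- ifelse(lambda2 == 0, 0, (lambda1 / lambda2)^2)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * g2)))
    v[if (bright_ridges) lambda2 > 0 else lambda2 < 0] <- 0
    v[lambda2 == 0] <- 0
    best <- pmax(best, v)
  }
  structure(list(vesselness = best, scales = scales), class = "vesselness_map")
}

#' Remove elongated high-vesselness components from a mask
#'
#' Deletes the connected components of a segmentation mask that look like
#' leaf or tiller edges rather than spikes: a component is removed only if
#' its mean vesselness, its eccentricity and its major-axis length all
#' exceed their thresholds. Operating on whole components (rather than
#' pixels) avoids perforating true spikes, which are compact. The output
#' mask is always a subset of the input mask.
#'
#' @param mask binary matrix (1 = spike candidate).
#' @param vesselness a [frangi_vesselness()] map of the same shape (or a
#'   bare matrix).
#' @param v_threshold minimum mean vesselness of a removed component.
#' @param ecc_threshold minimum eccentricity (0 = circle, 1 = line).
#' @param min_major_axis minimum major-axis length in pixels.
#' @return the filtered binary mask.
#' @export
suppress_linear_false_positives <- function(mask, vesselness,
                                            v_threshold = 0.15,
                                            ecc_threshold = 0.97,
                                            min_major_axis = 50) {
  v <- if (inherits(vesselness, "vesselness_map")) vesselness$vesselness else vesselness
  stopifnot(all(dim(mask) == dim(v)))
  if (sum(mask) == 0) return(mask)
  lab <- label_components8(mask)
  out <- mask
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    if (mean(v[idx]) < v_threshold) next
    rc <- cbind((idx - 1) %% nrow(mask) + 1, (idx - 1) %/% nrow(mask) + 1)
    mom <- region_moments(rc)
    if (mom$eccentricity >= ecc_threshold && mom$major_axis >= min_major_axis) {
      out[idx] <- 0L
    }
  }
  out
}

#' Remove small connected components
#'
#' @param mask binary matrix.
#' @param min_area components with fewer pixels than this are removed.
#' @return the cleaned binary mask (a subset of the input).
#' @export
clean_small_components <- function(mask, min_area = 50) {
  stopifnot(min_area >= 1)
  if (sum(mask) == 0 || min_area == 1) return(mask)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  out <- mask
  drop <- which(sizes < min_area)
  if (length(drop)) out[lab %in% drop] <- 0L
  out
}

#' Full segmentation post-filter
#'
#' Convenience wrapper chaining [clean_small_components()] and
#' [suppress_linear_false_positives()] on the prediction of a model, using
#' the vesselness of the input image's grayscale channel.
#'
#' @param mask predicted binary mask.
#' @param image the [spike_image()] the mask was predicted from.
#' @param min_area passed to [clean_small_components()].
#' @param scales,beta,gamma passed to [frangi_vesselness()].
#' @param v_threshold,ecc_threshold,min_major_axis passed to
#'   [suppress_linear_false_positives()].
#' @return the filtered binary mask.
#' @export
postfilter_mask <- function(mask, image, min_area = 50,
                            scales = c(1, 2, 3, 4), beta = 0.5,
                            gamma = "auto", v_threshold = 0.15,
                            ecc_threshold = 0.97, min_major_axis = 50) {
  v <- frangi_vesselness(rgb_to_gray(image$pixels), scales = scales,
                         beta = beta, gamma = gamma)
  m <- clean_small_components(mask, min_area)
  suppress_linear_false_positives(m, v, v_threshold = v_threshold,
                                  ecc_threshold = ecc_threshold,
                                  min_major_axis = min_major_axis)
}
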