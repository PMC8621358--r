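# Shallow pixel classifier: a single-hidden-layer network with logistic
# units mapping the Laws-energy/colour feature vector of each pixel to a
# spike probability. Training uses nnet's quasi-Newton optimiser (BFGS)
# with cross-entropy loss; prediction is a plain matrix forward pass so
# that models serialised to JSON need no fitted object.

#' Train the shallow spike/background pixel classifier
#'
#' Pixels are sampled class-balanced from the training masks
#' (`sample_per_class` spike pixels and as many background pixels, drawn
#' without replacement across all images under the given seed), features
#' are standardised by the training mean and standard deviation (stored in
#' the model), and a single-hidden-layer network with logistic hidden and
#' output units is fitted by quasi-Newton optimisation of the
#' cross-entropy loss until convergence or the epoch cap. Being
#' quasi-Newton, the optimiser has no learning-rate parameter. Training is
#' reproducible for a fixed seed.
#'
#' @param stacks list of [assemble_pixel_features()] outputs.
#' @param masks list of paired binary masks (1 = spike).
#' @param hidden number of hidden units.
#' @param epochs optimiser iteration cap.
#' @param sample_per_class number of pixels sampled from each class.
#' @param decay weight decay (L2) passed to the optimiser.
#' @param seed integer seed controlling sampling and weight initialisation.
#' @param threshold decision threshold on the output probability.
#' @return an object of class `shallow_ann`.
#' @export
train_pixel_classifier <- function(stacks, masks, hidden = 10, epochs = 500,
                                   sample_per_class = 8000, decay = 1e-4,
                                   seed = 1, threshold = 0.5) {
  stopifnot(length(stacks) == length(masks), length(stacks) >= 1)
  nms <- stacks[[1]]$names
  for (s in stacks) {
    if (!identical(s$names, nms)) stop("feature stacks disagree in layout")
  }
  n_spike <- sum(vapply(masks, function(m) sum(m == 1), numeric(1)))
  n_bg <- sum(vapply(masks, function(m) sum(m == 0), numeric(1)))
  if (n_spike == 0 || n_bg == 0) {
    stop("training requires both spike and background pixels")
  }
  set.seed(seed)
  per_image <- ceiling(sample_per_class / length(stacks))
  draw <- function(which_label) {
    rows <- list()
    for (i in seq_along(stacks)) {
      idx <- which(as.vector(masks[[i]]) == which_label)
      if (length(idx) == 0) next
      take <- sample(idx, min(per_image, length(idx)))
      K <- dim(stacks[[i]]$features)[3]
      X <- matrix(stacks[[i]]$features, ncol = K)[take, , drop = FALSE]
      rows[[length(rows) + 1]] <- X
    }
    X <- do.call(rbind, rows)
    X[seq_len(min(nrow(X), sample_per_class)), , drop = FALSE]
  }
  X1 <- draw(1L)
  X0 <- draw(0L)
  m <- min(nrow(X1), nrow(X0))   # keep the two classes exactly balanced
  X1 <- X1[seq_len(m), , drop = FALSE]
  X0 <- X0[seq_len(m), , drop = FALSE]
  X <- rbind(X1, X0)
  y <- c(rep(1, m), rep(0, m))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  fit <- nnet::nnet(x = Xs, y = y, size = hidden, entropy = TRUE,
                    maxit = epochs, decay = decay, trace = FALSE,
                    MaxNWts = 50000)
  structure(
    list(n = fit$n, wts = fit$wts, center = center, scale = scale,
         feature_names = nms, threshold = threshold,
         feature_config = stacks[[1]]$config,
         training = list(seed = seed, epochs = epochs, decay = decay,
                         hidden = hidden, sample_per_class = sample_per_class,
                         final_loss = fit$value,
                         n_train = nrow(X))),
    class = "shallow_ann"
  )
}

#' @export
print.shallow_ann <- function(x, ...) {
  cat(sprintf("<shallow_ann> %d-%d-1 logistic network, %d features, threshold %.2f\n",
              x$n[1], x$n[2], length(x$feature_names), x$threshold))
  invisible(x)
}

# Forward pass through the serialised weight vector (nnet layout: per
# hidden unit a bias then the input weights; then the output bias and the
# hidden-to-output weights).
ann_forward <- function(model, X) {
  K <- model$n[1]; h <- model$n[2]
  sigm <- function(z) 1 / (1 + exp(-z))
  W1 <- matrix(model$wts[seq_len(h * (K + 1))], nrow = K + 1)
  w2 <- model$wts[h * (K + 1) + seq_len(h + 1)]
  Z <- sigm(cbind(1, X) %*% W1)
  as.vector(sigm(cbind(1, Z) %*% w2))
}

#' Segment an image with a trained pixel classifier
#'
#' Assembles the feature stack with the configuration stored in the model,
#' standardises it with the training statistics and applies the network to
#' every pixel. The binary mask is the probability map thresholded at the
#' model's decision threshold.
#'
#' @param model a [train_pixel_classifier()] model.
#' @param image a [spike_image()], or a precomputed `pixel_features`
#'   object (which must match the model's feature layout).
#' @return list with `probability` (`H x W` matrix in `[0, 1]`) and `mask`
#'   (integer `H x W` matrix in `{0, 1}`).
#' @export
predict_segmentation <- function(model, image) {
  stopifnot(inherits(model, "shallow_ann"))
  stack <- if (inherits(image, "pixel_features")) image else {
    do.call(assemble_pixel_features, c(list(image), model$feature_config))
  }
  if (!identical(stack$names, model$feature_names)) {
    stop("feature stack does not match the model's feature layout")
  }
  d <- dim(stack$features)
  X <- matrix(stack$features, ncol = d[3])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  p <- matrix(ann_forward(model, Xs), d[1], d[2])
  mask <- matrix(0L, d[1], d[2])
  mask[p >= model$threshold] <- 1L
  list(probability = p, mask = mask)
}

#' Save or load a shallow ANN model as portable JSON
#'
#' The file stores layer sizes, the weight vector, the feature
#' standardisation statistics, provenance names and training metadata;
#' [read_ann()] reconstructs a model whose predictions are identical to
#' the original.
#'
#' @param model a `shallow_ann` model.
#' @param path JSON file path.
#' @export
write_ann <- function(model, path) {
  stopifnot(inherits(model, "shallow_ann"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ann
#' @export
read_ann <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$n <- as.integer(obj$n)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  obj$feature_config <- lapply(obj$feature_config, function(x) x)
  structure(obj, class = "shallow_ann")
}
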