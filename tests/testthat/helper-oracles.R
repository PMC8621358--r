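# Independent oracles used by the metric and texture tests. These are
# deliberately naive (nested loops, pixel enumeration, cutoff sweeps) and
# share no code with the package implementations they check.

# Pixel-enumeration IoU of two half-open integer boxes.
oracle_box_iou <- function(a, b) {
  grid_of <- function(z) {
    if (z$xmax <= z$xmin || z$ymax <= z$ymin) stop("degenerate")
    expand.grid(x = seq(z$xmin, z$xmax - 1), y = seq(z$ymin, z$ymax - 1))
  }
  ga <- grid_of(as.list(a)); gb <- grid_of(as.list(b))
  ka <- paste(ga$x, ga$y); kb <- paste(gb$x, gb$y)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# Greedy confidence-descending one-to-one matching, plain loops.
# Returns a logical TP flag per prediction in confidence order and that order.
oracle_match_order <- function(preds, gts, thr) {
  np <- nrow(preds); ng <- nrow(gts)
  iou <- matrix(0, np, max(ng, 1))
  if (ng > 0) {
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      iou[i, j] <- oracle_box_iou(preds[i, ], gts[j, ])
    }
  }
  best <- if (ng > 0) apply(iou, 1, max) else rep(0, np)
  ord <- order(-preds$confidence, -best, seq_len(np))
  used <- rep(FALSE, ng)
  tp <- logical(np)
  for (r in seq_along(ord)) {
    i <- ord[r]
    if (ng == 0) next
    bestj <- 0; bestv <- -1
    for (j in seq_len(ng)) {
      if (!used[j] && iou[i, j] >= thr - 1e-9 && iou[i, j] > bestv) {
        bestj <- j; bestv <- iou[i, j]
      }
    }
    if (bestj > 0) { used[bestj] <- TRUE; tp[r] <- TRUE }
  }
  list(tp = tp, order = ord)
}

# Brute-force interpolated AP: sweep every confidence cutoff, build the
# PR staircase from scratch at each cutoff, then integrate by the
# max-precision-at-recall>=r definition over the given recall points.
oracle_ap <- function(preds, gts, thr, points) {
  ng <- nrow(gts)
  if (ng == 0) stop("undefined")
  om <- oracle_match_order(preds, gts, thr)
  n <- nrow(preds)
  prec <- rec <- numeric(n)
  for (k in seq_len(n)) {
    tp_k <- sum(om$tp[seq_len(k)])
    prec[k] <- tp_k / k
    rec[k] <- tp_k / ng
  }
  ap <- 0
  for (r in points) {
    ok <- which(rec >= r - 1e-12)
    ap <- ap + (if (length(ok)) max(prec[ok]) else 0)
  }
  ap / length(points)
}

# Nested-loop sliding-window filter (mask applied over each pixel's
# neighbourhood) with edge replication.
oracle_conv2 <- function(x, k) {
  a <- (nrow(k) - 1) / 2; b <- (ncol(k) - 1) / 2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (u in -a:a) for (v in -b:b) {
      ii <- min(max(i + u, 1), H)
      jj <- min(max(j + v, 1), W)
      acc <- acc + k[u + a + 1, v + b + 1] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Random half-open boxes with confidences on a small canvas.
random_boxes <- function(n, canvas = 20, conf = TRUE) {
  if (n == 0) return(box_annotations())
  x1 <- sample(0:(canvas - 2), n, replace = TRUE)
  y1 <- sample(0:(canvas - 2), n, replace = TRUE)
  x2 <- pmin(x1 + sample(1:8, n, replace = TRUE), canvas)
  y2 <- pmin(y1 + sample(1:8, n, replace = TRUE), canvas)
  box_annotations(x1, y1, x2, y2,
                  confidence = if (conf) {
                    round(runif(n), 1)   # coarse grid so ties occur
                  } else NA_real_)
}

# A tiny flat test image with a textured square patch.
tiny_test_image <- function(seed = 1, size = 40) {
  set.seed(seed)
  px <- array(rep(c(30, 60, 150), each = size * size), dim = c(size, size, 3))
  patch <- 10:25
  for (ch in 1:3) {
    px[patch, patch, ch] <- 120 + 100 * (matrix(runif(length(patch)^2),
                                                length(patch)) > 0.5)
  }
  spike_image(px, id = sprintf("tiny_%d", seed))
}
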