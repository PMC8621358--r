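# Detection and segmentation evaluation: IoU box matching, precision /
# recall / accuracy / F1, PASCAL-VOC 11-point and COCO 101-point AP over
# the 0.50:0.05:0.95 IoU sweep, Dice/Jaccard mask scores and
# category-stratified reports.

#' Intersection over union of two boxes
#'
#' Boxes use the internal 0-based half-open convention, so areas are exact
#' pixel counts. Disjoint boxes score 0; degenerate (zero-area) boxes are
#' an error.
#'
#' @param a,b boxes: any objects with `xmin`, `ymin`, `xmax`, `ymax`
#'   fields (single rows of a [box_annotations()] table, lists or named
#'   vectors).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  area <- function(z) (z$xmax - z$xmin) * (z$ymax - z$ymin)
  a <- as.list(a); b <- as.list(b)
  if (area(a) <= 0 || area(b) <= 0) stop("degenerate box")
  iw <- min(a$xmax, b$xmax) - max(a$xmin, b$xmin)
  ih <- min(a$ymax, b$ymax) - max(a$ymin, b$ymin)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (area(a) + area(b) - inter)
}

iou_matrix <- function(preds, gts) {
  outer(seq_len(nrow(preds)), seq_len(nrow(gts)),
        Vectorize(function(i, j) box_iou(preds[i, ], gts[j, ])))
}

#' Greedy confidence-descending detection matching
#'
#' Predictions are processed in order of decreasing confidence (ties
#' broken by the higher best-IoU against the ground truth, then input
#' order); each prediction is matched to the unmatched ground-truth box of
#' highest IoU provided that IoU reaches the threshold, otherwise it
#' counts as a false positive. Unmatched ground-truth boxes are false
#' negatives. Matching is one-to-one. The true-negative count is defined
#' at image level only -- 1 for an image with no ground truth and no
#' predictions -- because spike detection has no pixel-level negative
#' unit.
#'
#' @param preds [box_annotations()] with confidences.
#' @param gts [box_annotations()] ground truth.
#' @param iou_threshold match acceptance threshold (default 0.5).
#' @return an object of class `match_result`: list with `matches`
#'   (data.frame `pred`, `gt`, `iou`), `pred_is_tp` (logical per
#'   prediction, in input order), counts `TP`, `FP`, `FN`, `TN`, and the
#'   threshold used.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  np <- nrow(preds); ng <- nrow(gts)
  if (np > 0 && anyNA(preds$confidence)) {
    stop("all predictions must carry a confidence")
  }
  matches <- data.frame(pred = integer(), gt = integer(), iou = numeric())
  pred_is_tp <- logical(np)
  if (np > 0 && ng > 0) {
    iou <- iou_matrix(preds, gts)
    best <- apply(iou, 1, max)
    order_idx <- order(-preds$confidence, -best, seq_len(np))
    taken <- logical(ng)
    for (i in order_idx) {
      cand <- which(!taken & iou[i, ] >= iou_threshold - 1e-9)
      if (length(cand) == 0) next
      j <- cand[which.max(iou[i, cand])]
      taken[j] <- TRUE
      pred_is_tp[i] <- TRUE
      matches <- rbind(matches,
                       data.frame(pred = i, gt = j, iou = iou[i, j]))
    }
  }
  TP <- sum(pred_is_tp)
  structure(
    list(matches = matches, pred_is_tp = pred_is_tp,
         TP = TP, FP = np - TP, FN = ng - TP,
         TN = as.integer(np == 0 && ng == 0),
         iou_threshold = iou_threshold),
    class = "match_result"
  )
}

#' Precision, recall, accuracy and F1 from matched counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `A = (TP+TN)/(TP+TN+FP+FN)` with
#' the image-level TN definition of [match_detections()], and
#' `F1 = 2PR/(P+R)`. Undefined ratios are reported as `NaN` with a
#' warning, never silently as 0, so degenerate reports are visibly
#' degenerate.
#'
#' @param m a `match_result`, or a list with fields `TP`, `FP`, `FN` and
#'   optionally `TN`.
#' @return named numeric vector `c(P, R, A, F1)`.
#' @export
detection_scores <- function(m) {
  TP <- m$TP; FP <- m$FP; FN <- m$FN; TN <- m$TN %||% 0
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NaN")
      return(NaN)
    }
    num / den
  }
  P <- safe(TP, TP + FP, "precision")
  R <- safe(TP, TP + FN, "recall")
  A <- safe(TP + TN, TP + TN + FP + FN, "accuracy")
  F1 <- if (is.nan(P) || is.nan(R) || (P + R) == 0) {
    if (!is.nan(P) && !is.nan(R)) {
      warning("F1 undefined (P + R = 0); reported as NaN")
    }
    NaN
  } else 2 * P * R / (P + R)
  c(P = P, R = R, A = A, F1 = F1)
}

# Cumulative precision/recall staircase over the dataset-wide confidence
# ranking, with per-image greedy matching at the given IoU threshold.
# preds/gts carry an image_id column; returns precision and recall
# sequences ordered by descending confidence.
pr_curve <- function(preds, gts, iou_threshold) {
  ng <- nrow(gts)
  if (ng == 0) stop("average precision is undefined with zero ground truths")
  np <- nrow(preds)
  if (np == 0) {
    return(list(precision = numeric(), recall = numeric(), n_gt = ng))
  }
  if (anyNA(preds$confidence)) stop("all predictions must carry a confidence")
  if (is.null(preds$image_id)) preds$image_id <- "img"
  if (is.null(gts$image_id)) gts$image_id <- "img"
  # best IoU per prediction for the confidence tie-break
  best <- numeric(np)
  iou_cache <- list()
  for (img in unique(preds$image_id)) {
    pi <- which(preds$image_id == img)
    gi <- which(gts$image_id == img)
    if (length(gi) == 0) { best[pi] <- 0; next }
    m <- iou_matrix(preds[pi, , drop = FALSE], gts[gi, , drop = FALSE])
    iou_cache[[as.character(img)]] <- list(pi = pi, gi = gi, iou = m)
    best[pi] <- apply(m, 1, max)
  }
  ord <- order(-preds$confidence, -best, seq_len(np))
  taken <- rep(FALSE, ng)
  tp <- logical(np)
  for (r in seq_along(ord)) {
    i <- ord[r]
    cache <- iou_cache[[as.character(preds$image_id[i])]]
    if (is.null(cache)) next
    row <- match(i, cache$pi)
    cand <- which(!taken[cache$gi] & cache$iou[row, ] >= iou_threshold - 1e-9)
    if (length(cand) == 0) next
    j <- cand[which.max(cache$iou[row, cand])]
    taken[cache$gi[j]] <- TRUE
    tp[r] <- TRUE
  }
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  list(precision = ctp / (ctp + cfp), recall = ctp / ng, n_gt = ng)
}

# Interpolated AP: mean over `points` recall levels of the maximum
# precision at recall >= r.
interp_ap <- function(precision, recall, points) {
  if (length(precision) == 0) return(0)
  vapply(points, function(r) {
    ok <- recall >= r - 1e-12
    if (!any(ok)) 0 else max(precision[ok])
  }, numeric(1)) |> mean()
}

#' PASCAL-VOC 11-point interpolated average precision
#'
#' The interpolated precision at recall level `r` is the maximum precision
#' attained at any recall `>= r`; AP is the mean of the interpolated
#' precision over the 11 equally spaced recall levels `0, 0.1, ..., 1`.
#'
#' @param preds predictions over the dataset: a [box_annotations()]-style
#'   data.frame with confidences and (for multi-image datasets) an
#'   `image_id` column.
#' @param gts ground-truth boxes, same layout.
#' @param iou_threshold IoU acceptance threshold (default 0.5).
#' @return AP in `[0, 1]`.
#' @export
ap_11point <- function(preds, gts, iou_threshold = 0.5) {
  pr <- pr_curve(preds, gts, iou_threshold)
  interp_ap(pr$precision, pr$recall, seq(0, 1, by = 0.1))
}

#' COCO-style average precision over the IoU sweep
#'
#' For each IoU threshold in `0.50, 0.55, ..., 0.95` the AP is computed by
#' interpolation at 101 recall points `0, 0.01, ..., 1`; the summary value
#' is the mean over the 10 thresholds.
#'
#' @inheritParams ap_11point
#' @return list with `ap_per_threshold` (named numeric, length 10),
#'   `mean_ap` and `thresholds`.
#' @export
ap_coco <- function(preds, gts) {
  thresholds <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thresholds, function(t) {
    pr <- pr_curve(preds, gts, t)
    interp_ap(pr$precision, pr$recall, seq(0, 1, by = 0.01))
  }, numeric(1))
  names(aps) <- sprintf("%.2f", thresholds)
  list(ap_per_threshold = aps, mean_ap = mean(aps), thresholds = thresholds)
}

#' Mean average precision over classes
#'
#' @param ap_per_class numeric vector of per-class AP values.
#' @return their arithmetic mean.
#' @export
mean_ap <- function(ap_per_class) {
  if (length(ap_per_class) == 0) stop("empty AP list")
  mean(ap_per_class)
}

#' Segmentation mask metrics
#'
#' Pixel-level overlap scores between a predicted and a ground-truth
#' binary mask: Dice `2|P∩G| / (|P|+|G|)` and Jaccard/IoU
#' `|P∩G| / |P∪G|` on the spike class; `aDC` and `mean_iou` average the
#' class-wise Dice and IoU over the spike and background classes; pixel
#' accuracy is the fraction of pixels labelled correctly. A class empty in
#' both masks scores 1 by convention.
#'
#' @param pred,gt binary matrices of equal shape.
#' @return named numeric vector
#'   `c(dice, jaccard, aDC, mean_iou, pixel_accuracy)`.
#' @export
mask_metrics <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("mask shapes differ")
  class_scores <- function(p, g) {
    inter <- sum(p & g)
    szp <- sum(p); szg <- sum(g)
    if (szp + szg == 0) return(c(dice = 1, iou = 1))
    c(dice = 2 * inter / (szp + szg),
      iou = inter / (szp + szg - inter))
  }
  spike <- class_scores(pred == 1, gt == 1)
  bg <- class_scores(pred == 0, gt == 0)
  c(dice = unname(spike["dice"]),
    jaccard = unname(spike["iou"]),
    aDC = unname((spike["dice"] + bg["dice"]) / 2),
    mean_iou = unname((spike["iou"] + bg["iou"]) / 2),
    pixel_accuracy = mean(pred == gt))
}

#' Category-stratified detection evaluation
#'
#' Matching is computed once globally at the given threshold; true
#' positives and false negatives are attributed to the category of their
#' ground-truth box, and each false positive to the category of its
#' nearest (highest-IoU) ground truth, or `"uncategorized"` when it
#' overlaps none. Per category the report carries the counts, precision,
#' recall, the 11-point AP restricted to that category's ground truths
#' and attributed predictions, and the mean confidence of matched true
#' positives (the probability column of category summary tables).
#'
#' @param preds predictions with confidences (optionally `image_id`).
#' @param gts ground truths, each carrying a `category` tag.
#' @param iou_threshold match threshold.
#' @return data.frame with one row per category.
#' @export
evaluate_by_category <- function(preds, gts, iou_threshold = 0.5) {
  if (nrow(gts) > 0 && anyNA(gts$category)) {
    stop("every ground-truth box needs a category tag")
  }
  if (is.null(preds$image_id)) preds$image_id <- "img"
  if (is.null(gts$image_id)) gts$image_id <- "img"
  np <- nrow(preds)
  pred_cat <- rep("uncategorized", np)
  pred_tp <- logical(np)
  gt_matched <- rep(FALSE, nrow(gts))
  pred_conf_gt <- rep(NA_real_, np)
  for (img in unique(c(preds$image_id, gts$image_id))) {
    pi <- which(preds$image_id == img)
    gi <- which(gts$image_id == img)
    if (length(pi) == 0) next
    m <- match_detections(preds[pi, , drop = FALSE],
                          gts[gi, , drop = FALSE], iou_threshold)
    if (nrow(m$matches) > 0) {
      pred_tp[pi[m$matches$pred]] <- TRUE
      gt_matched[gi[m$matches$gt]] <- TRUE
      pred_cat[pi[m$matches$pred]] <- gts$category[gi[m$matches$gt]]
    }
    # false positives inherit the category of their closest ground truth
    if (length(gi) > 0) {
      iou <- iou_matrix(preds[pi, , drop = FALSE], gts[gi, , drop = FALSE])
      for (k in which(!pred_tp[pi])) {
        if (max(iou[k, ]) > 0) {
          pred_cat[pi[k]] <- gts$category[gi[which.max(iou[k, ])]]
        }
      }
    }
  }
  cats <- sort(unique(c(gts$category, pred_cat[pred_tp | pred_cat != "uncategorized"])))
  cats <- setdiff(cats, NA)
  rows <- lapply(cats, function(ct) {
    gt_idx <- which(gts$category == ct)
    p_idx <- which(pred_cat == ct)
    TP <- sum(pred_tp[p_idx])
    FP <- length(p_idx) - TP
    FN <- length(gt_idx) - sum(gt_matched[gt_idx])
    ap <- if (length(gt_idx) > 0) {
      ap_11point(preds[p_idx, , drop = FALSE],
                 gts[gt_idx, , drop = FALSE], iou_threshold)
    } else NA_real_
    mean_conf <- if (TP > 0) mean(preds$confidence[p_idx][pred_tp[p_idx]]) else NA_real_
    data.frame(
      category = ct, n_gt = length(gt_idx), TP = TP, FP = FP, FN = FN,
      precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
      recall = if (length(gt_idx) > 0) (length(gt_idx) - FN) / length(gt_idx) else NA_real_,
      ap_11point = ap, mean_tp_confidence = mean_conf,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Detected regions of a mask as scored boxes
#'
#' Turns the connected components of a predicted segmentation mask into
#' detection boxes, scored by the mean predicted probability inside the
#' component. This is the bridge from the pixel classifier to the
#' detection metrics.
#'
#' @param mask binary matrix.
#' @param probability matching probability matrix (defaults to the mask
#'   itself, giving confidence 1 per component).
#' @param min_area drop components smaller than this.
#' @return a [box_annotations()] table with confidences.
#' @export
mask_to_boxes <- function(mask, probability = NULL, min_area = 25) {
  if (is.null(probability)) probability <- mask
  regions <- extract_regions(mask, min_area = min_area)
  if (length(regions) == 0) return(box_annotations())
  box_annotations(
    xmin = vapply(regions, function(r) r$bbox["xmin"], numeric(1)),
    ymin = vapply(regions, function(r) r$bbox["ymin"], numeric(1)),
    xmax = vapply(regions, function(r) r$bbox["xmax"], numeric(1)),
    ymax = vapply(regions, function(r) r$bbox["ymax"], numeric(1)),
    confidence = vapply(regions, function(r) {
      mean(probability[r$pixels])
    }, numeric(1))
  )
}
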