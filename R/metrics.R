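# Detection evaluation: greedy IoU matching, precision/recall, average
# precision (area under the monotone-envelope PR curve), mAP, and the
# background-aware confusion matrix.

#' Match detections against ground truth
#'
#' Detections are visited in descending score order within their class; a
#' detection is a true positive iff its IoU with some not-yet-matched
#' same-class ground-truth box reaches `iou_thresh` (the best such box is
#' consumed). Each ground truth is matched at most once.
#'
#' @param dets Detection data frame (`class_id`, `score`, `x1`..`y2`),
#'   single image.
#' @param gts Ground-truth data frame (`class_id`, `x1`..`y2`), same image.
#' @param iou_thresh Match threshold, default 0.5.
#' @return A `match_record`: `dets` with a logical `tp` column (score order)
#'   plus `fn` (unmatched ground truths per class) and `n_gt` per class.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  K_ids <- sort(unique(c(dets$class_id, gts$class_id)))
  tp <- logical(nrow(dets))
  matched_gt <- integer(nrow(dets)) # 0 = FP
  gt_used <- rep(FALSE, nrow(gts))
  ord <- order(-dets$score)
  for (i in ord) {
    cand <- which(!gt_used & gts$class_id == dets$class_id[i])
    if (!length(cand)) next
    ious <- as.numeric(box_iou(dets[i, , drop = FALSE],
                               gts[cand, , drop = FALSE]))
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      tp[i] <- TRUE
      gt_used[cand[j]] <- TRUE
      matched_gt[i] <- cand[j]
    }
  }
  fn <- vapply(K_ids, function(k)
    sum(!gt_used & gts$class_id == k), integer(1))
  n_gt <- vapply(K_ids, function(k) sum(gts$class_id == k), integer(1))
  rec <- dets
  rec$tp <- tp
  rec$matched_gt <- matched_gt
  structure(list(dets = rec[ord, , drop = FALSE],
                 fn = setNames(fn, K_ids), n_gt = setNames(n_gt, K_ids)),
            class = "match_record")
}

#' Precision and recall from matched detections
#'
#' `P = TP / (TP + FP)` and `R = TP / (TP + FN)`; a zero denominator yields
#' 0 with the corresponding `*_defined` flag set to FALSE.
#'
#' @param rec A `match_record` (or a list of them, pooled).
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn` and the
#'   `precision_defined` / `recall_defined` flags.
#' @export
precision_recall <- function(rec) {
  if (inherits(rec, "match_record")) rec <- list(rec)
  tp <- sum(vapply(rec, function(r) sum(r$dets$tp), numeric(1)))
  fp <- sum(vapply(rec, function(r) sum(!r$dets$tp), numeric(1)))
  fn <- sum(vapply(rec, function(r) sum(r$fn), numeric(1)))
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       tp = tp, fp = fp, fn = fn,
       precision_defined = tp + fp > 0, recall_defined = tp + fn > 0)
}

#' Average precision from scored TP/FP flags
#'
#' Builds the precision-recall curve by descending score and integrates the
#' monotone (all-point interpolated) envelope; `interpolation = "11point"`
#' uses the legacy 11-point average instead.
#'
#' @param scores Detection scores.
#' @param tp Logical TP flags aligned with `scores`.
#' @param n_gt Number of ground-truth boxes of the class (>= 1).
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, tp, n_gt,
                              interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  stop_if_not(n_gt >= 1, "average precision needs at least one ground truth")
  if (!length(scores)) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  if (interpolation == "11point") {
    return(mean(vapply(seq(0, 1, 0.1), function(r) {
      ok <- recall >= r
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1))))
  }
  # monotone envelope, rectangle integration over recall increments
  mrec <- c(0, recall, 1)
  mpre <- c(1, precision, 0)
  for (i in rev(seq_len(length(mpre) - 1L))) mpre[i] <- max(mpre[i], mpre[i + 1L])
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
}

#' Mean average precision over classes
#'
#' @param aps Named or plain numeric vector of per-class APs; `NA` entries
#'   (classes without ground truth) are excluded with a warning.
#' @return Unweighted mean AP.
#' @export
mean_ap <- function(aps) {
  if (anyNA(aps)) {
    warning("classes without ground truth excluded from mAP")
    aps <- aps[!is.na(aps)]
  }
  stop_if_not(length(aps) >= 1, "no class with ground truth")
  mean(aps)
}

#' Background-aware confusion matrix
#'
#' Detections above `conf_thresh` are greedily matched to ground truths by
#' IoU (class-agnostic, threshold `iou_thresh`); matched pairs increment
#' (predicted class, true class), unmatched ground truths the background
#' row, unmatched detections the background column. Columns (true classes)
#' are normalized to sum to 1 where nonzero.
#'
#' @param dets,gts Lists of per-image detection / ground-truth data frames
#'   (single data frames are promoted).
#' @param num_classes K; the matrix is (K+1) x (K+1) with the last
#'   row/column labeled `background`.
#' @param conf_thresh,iou_thresh Score and IoU thresholds (defaults 0.25,
#'   0.45).
#' @param normalize Column-normalize (default TRUE).
#' @return The confusion matrix (predicted in rows, true in columns).
#' @export
confusion_matrix <- function(dets, gts, num_classes = 5L,
                             conf_thresh = 0.25, iou_thresh = 0.45,
                             normalize = TRUE) {
  stop_if_not(conf_thresh >= 0 && conf_thresh <= 1 &&
                iou_thresh >= 0 && iou_thresh <= 1,
              "thresholds must be in [0, 1]")
  if (is.data.frame(dets)) dets <- list(dets)
  if (is.data.frame(gts)) gts <- list(gts)
  K <- num_classes
  M <- matrix(0, K + 1L, K + 1L)
  for (b in seq_along(dets)) {
    d <- dets[[b]]
    d <- d[d$score >= conf_thresh, , drop = FALSE]
    g <- gts[[b]]
    used_gt <- rep(FALSE, nrow(g))
    if (nrow(d)) {
      for (i in order(-d$score)) {
        cand <- which(!used_gt)
        hit <- FALSE
        if (length(cand)) {
          ious <- as.numeric(box_iou(d[i, , drop = FALSE],
                                     g[cand, , drop = FALSE]))
          j <- which.max(ious)
          if (ious[j] >= iou_thresh) {
            M[d$class_id[i] + 1L, g$class_id[cand[j]] + 1L] <-
              M[d$class_id[i] + 1L, g$class_id[cand[j]] + 1L] + 1
            used_gt[cand[j]] <- TRUE
            hit <- TRUE
          }
        }
        if (!hit) M[d$class_id[i] + 1L, K + 1L] <- M[d$class_id[i] + 1L, K + 1L] + 1
      }
    }
    for (j in which(!used_gt))
      M[K + 1L, g$class_id[j] + 1L] <- M[K + 1L, g$class_id[j] + 1L] + 1
  }
  if (normalize) {
    cs <- colSums(M)
    nz <- cs > 0
    M[, nz] <- sweep(M[, nz, drop = FALSE], 2L, cs[nz], `/`)
  }
  dimnames(M) <- list(pred = c(paste0("class", 0:(K - 1L)), "background"),
                      true = c(paste0("class", 0:(K - 1L)), "background"))
  M
}

#' Evaluate a detector on a labeled dataset
#'
#' Runs the model on every image, matches detections at `iou_thresh`, and
#' reports per-class and overall precision, recall and AP, the mAP, and the
#' background-aware confusion matrix.
#'
#' @param model A `pest_model` (or `pest_fit`).
#' @param data A dataset as returned by [load_yolo_dataset()] (fields
#'   `images`, `boxes`).
#' @param conf_thresh Score threshold for the detections entering the PR
#'   computation (kept low so the full PR curve is sampled).
#' @param nms_iou NMS IoU threshold.
#' @param iou_thresh TP match threshold (mAP@0.5 by default).
#' @param cm_conf Confidence threshold of the confusion matrix.
#' @return An `eval_report` with `per_class` (data frame), `precision`,
#'   `recall`, `map`, and `confusion`.
#' @export
evaluate_detector <- function(model, data, conf_thresh = 0.01, nms_iou = 0.45,
                              iou_thresh = 0.5, cm_conf = 0.25) {
  if (inherits(model, "pest_fit")) model <- model$model
  spec <- model$spec
  K <- spec$num_classes
  det_list <- gt_list <- vector("list", length(data$images))
  for (i in seq_along(data$images)) {
    img <- data$images[[i]]
    d <- dim(img)
    if (d[1] != spec$input_size || d[2] != spec$input_size) {
      lb <- letterbox(img, spec$input_size)
      img <- lb$image
      gt <- box_to_letterbox(norm_to_xyxy(data$boxes[[i]], d[2], d[1]),
                             lb$transform)
    } else {
      gt <- norm_to_xyxy(data$boxes[[i]], d[2], d[1])
    }
    fw <- model_forward(model, img, training = FALSE)
    dd <- decode(fw$preds, spec, conf_thresh)
    det_list[[i]] <- nms(dd, nms_iou)
    gt_list[[i]] <- gt
  }
  recs <- lapply(seq_along(det_list), function(i)
    match_detections(det_list[[i]], gt_list[[i]], iou_thresh))
  per_class <- lapply(0:(K - 1L), function(k) {
    scores <- unlist(lapply(recs, function(r)
      r$dets$score[r$dets$class_id == k]))
    tp <- unlist(lapply(recs, function(r) r$dets$tp[r$dets$class_id == k]))
    n_gt <- sum(vapply(gt_list, function(g) sum(g$class_id == k), numeric(1)))
    fp <- sum(!tp)
    tpn <- sum(tp)
    data.frame(class_id = k,
               class = spec$class_names[k + 1L] %||% paste0("class", k),
               n_gt = n_gt,
               precision = if (tpn + fp > 0) tpn / (tpn + fp) else 0,
               recall = if (n_gt > 0) tpn / n_gt else 0,
               ap = if (n_gt > 0) average_precision(scores, tp, n_gt) else NA_real_)
  })
  per_class <- do.call(rbind, per_class)
  pr <- precision_recall(recs)
  out <- list(per_class = per_class,
              precision = pr$precision, recall = pr$recall,
              map = mean_ap(per_class$ap),
              confusion = confusion_matrix(det_list, gt_list, K,
                                           conf_thresh = cm_conf,
                                           iou_thresh = nms_iou),
              iou_thresh = iou_thresh)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Detection evaluation (IoU %.2f): P %.3f  R %.3f  mAP %.3f\n",
              x$iou_thresh, x$precision, x$recall, x$map))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
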