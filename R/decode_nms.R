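# Prediction decoding and non-maximum suppression.
#
# Decode convention (the v5-style parameterization): for anchor a at cell
# (i, j) with stride s,
#   center = (2*sigmoid(txy) - 0.5 + (j, i)) * s
#   size   = (2*sigmoid(twh))^2 * anchor_wh
#   score  = sigmoid(obj) * sigmoid(best class logit)
# Pixel boxes use continuous coordinates with the origin at the image's
# top-left corner; pixel i spans [i-1, i].

#' Decode raw head outputs into detections
#'
#' @param preds List of raw per-scale predictions as returned by
#'   [model_forward()] (finest scale first).
#' @param spec The `pest_model_spec` the predictions came from.
#' @param conf_thresh Confidence threshold in `[0, 1]`; detections scoring
#'   below it are dropped.
#' @return A data frame with columns `image` (batch index), `class_id`
#'   (0-based), `score`, `x1`, `y1`, `x2`, `y2`.
#' @export
decode <- function(preds, spec, conf_thresh = 0.25) {
  stop_if_not(conf_thresh >= 0 && conf_thresh <= 1,
              "conf_thresh must be in [0, 1]")
  K <- spec$num_classes
  nc <- 5L + K
  res <- list()
  for (si in seq_along(preds)) {
    p <- preds[[si]]
    if (length(dim(p)) == 3L) dim(p) <- c(dim(p), 1L)
    d <- dim(p)
    H <- d[1]; W <- d[2]; B <- d[4]
    stride <- spec$strides[si]
    gx <- rep(rep(0:(W - 1L), each = H), times = 1L)
    gy <- rep(0:(H - 1L), times = W)
    for (b in seq_len(B)) {
      for (a in 1:3) {
        sl <- p[, , (a - 1L) * nc + seq_len(nc), b, drop = FALSE]
        dim(sl) <- c(H * W, nc)
        bx <- (2 * sigmoid(sl[, 1]) - 0.5 + gx) * stride
        by <- (2 * sigmoid(sl[, 2]) - 0.5 + gy) * stride
        bw <- (2 * sigmoid(sl[, 3]))^2 * spec$anchors[[si]][a, 1]
        bh <- (2 * sigmoid(sl[, 4]))^2 * spec$anchors[[si]][a, 2]
        obj <- sigmoid(sl[, 5])
        clp <- sigmoid(sl[, 5L + seq_len(K), drop = FALSE])
        best <- max.col(clp, ties.method = "first")
        score <- obj * clp[cbind(seq_len(H * W), best)]
        # sigmoid products are strictly below 1, so conf_thresh = 1 keeps nothing
        keep <- which(score >= conf_thresh)
        if (!length(keep)) next
        res[[length(res) + 1L]] <- data.frame(
          image = b, class_id = best[keep] - 1L, score = score[keep],
          x1 = bx[keep] - bw[keep] / 2, y1 = by[keep] - bh[keep] / 2,
          x2 = bx[keep] + bw[keep] / 2, y2 = by[keep] + bh[keep] / 2)
      }
    }
  }
  if (!length(res))
    return(data.frame(image = integer(0), class_id = integer(0),
                      score = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$image, -out$score), , drop = FALSE]
}

#' Pairwise IoU between two sets of xyxy boxes
#'
#' @param a,b Matrices (or data frames) with columns x1, y1, x2, y2.
#' @return An `nrow(a)` x `nrow(b)` IoU matrix.
#' @export
box_iou <- function(a, b) {
  a <- as.matrix(a[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  b <- as.matrix(b[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  iw <- pmax(outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax), 0)
  ih <- pmax(outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax), 0)
  inter <- iw * ih
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- outer(aa, ab, `+`) - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

#' Greedy class-wise non-maximum suppression
#'
#' Detections are visited in descending score order within each class; a
#' detection is suppressed if it overlaps an already-kept same-class
#' detection with IoU strictly above `iou_thresh`.
#'
#' @param dets Detection data frame (columns `class_id`, `score`, `x1`,
#'   `y1`, `x2`, `y2`; an `image` column, if present, partitions the input).
#' @param iou_thresh Suppression IoU threshold, default 0.45.
#' @return The surviving subset of `dets`.
#' @export
nms <- function(dets, iou_thresh = 0.45) {
  if (!nrow(dets)) return(dets)
  if ("image" %in% names(dets) && length(unique(dets$image)) > 1L) {
    parts <- split(dets, dets$image)
    out <- do.call(rbind, lapply(parts, nms, iou_thresh = iou_thresh))
    rownames(out) <- NULL
    return(out)
  }
  keep_all <- integer(0)
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    idx <- idx[order(-dets$score[idx])]
    kept <- integer(0)
    for (i in idx) {
      if (length(kept)) {
        ious <- box_iou(dets[i, , drop = FALSE], dets[kept, , drop = FALSE])
        if (any(ious > iou_thresh)) next
      }
      kept <- c(kept, i)
    }
    keep_all <- c(keep_all, kept)
  }
  out <- dets[sort(keep_all), , drop = FALSE]
  out[order(-out$score), , drop = FALSE]
}
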