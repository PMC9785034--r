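# Target assignment and the composite detection loss
#   total = loss_class + loss_object + loss_box
# summed over the detection layers. The box term is mean(1 - CIoU) over
# assigned anchor slots, the class term binary cross entropy with logits on
# the K class outputs of assigned slots, and the objectness term logistic
# cross entropy over all slots with the assigned slots' target set to the
# (detached, clamped) CIoU of their decoded box.

#' Complete IoU between pixel boxes
#'
#' `CIoU = IoU - rho^2 / c^2 - alpha * v` where `rho` is the center
#' distance, `c` the enclosing-box diagonal, `v` the squared normalized
#' arctan aspect-ratio gap and `alpha = v / ((1 - IoU) + v)`. Equals plain
#' IoU when the boxes share center and aspect ratio; identical boxes give 1.
#'
#' @param a,b Data frames or matrices with columns x1, y1, x2, y2 (rows are
#'   paired; the shorter side is recycled if it has one row).
#' @return Numeric vector of CIoU values in (-1, 1].
#' @export
ciou <- function(a, b) {
  A <- as.matrix(as.data.frame(a)[, c("x1", "y1", "x2", "y2")])
  B <- as.matrix(as.data.frame(b)[, c("x1", "y1", "x2", "y2")])
  if (nrow(A) == 1L && nrow(B) > 1L) A <- A[rep(1L, nrow(B)), , drop = FALSE]
  if (nrow(B) == 1L && nrow(A) > 1L) B <- B[rep(1L, nrow(A)), , drop = FALSE]
  wa <- A[, 3] - A[, 1]; ha <- A[, 4] - A[, 2]
  wb <- B[, 3] - B[, 1]; hb <- B[, 4] - B[, 2]
  stop_if_not(all(wa > 0 & ha > 0 & wb > 0 & hb > 0),
              "degenerate (zero-area) box")
  iw <- pmax(pmin(A[, 3], B[, 3]) - pmax(A[, 1], B[, 1]), 0)
  ih <- pmax(pmin(A[, 4], B[, 4]) - pmax(A[, 2], B[, 2]), 0)
  inter <- iw * ih
  un <- wa * ha + wb * hb - inter
  iou <- inter / un
  rho2 <- ((A[, 1] + A[, 3]) / 2 - (B[, 1] + B[, 3]) / 2)^2 +
          ((A[, 2] + A[, 4]) / 2 - (B[, 2] + B[, 4]) / 2)^2
  cw <- pmax(A[, 3], B[, 3]) - pmin(A[, 1], B[, 1])
  chh <- pmax(A[, 4], B[, 4]) - pmin(A[, 2], B[, 2])
  c2 <- cw^2 + chh^2
  v <- (4 / pi^2) * (atan(wb / hb) - atan(wa / ha))^2
  alpha <- v / ((1 - iou) + v + 1e-12)
  unname(iou - rho2 / c2 - alpha * v)
}

# CIoU and its gradient with respect to the *first* box in center-size form
# (px, py, pw, ph); the second box is fixed. alpha is treated as a constant
# (detached), the standard practice for this penalty. Verified against
# finite differences in the test suite.
ciou_cs_grad <- function(p, g) {
  px <- p[, 1]; py <- p[, 2]; pw <- p[, 3]; ph <- p[, 4]
  gx <- g[, 1]; gy <- g[, 2]; gw <- g[, 3]; gh <- g[, 4]
  p1x <- px - pw / 2; p2x <- px + pw / 2; p1y <- py - ph / 2; p2y <- py + ph / 2
  g1x <- gx - gw / 2; g2x <- gx + gw / 2; g1y <- gy - gh / 2; g2y <- gy + gh / 2
  iw <- pmax(pmin(p2x, g2x) - pmax(p1x, g1x), 0)
  ih <- pmax(pmin(p2y, g2y) - pmax(p1y, g1y), 0)
  I <- iw * ih
  U <- pw * ph + gw * gh - I
  iou <- I / U
  # subgradients of the intersection extents
  diw_dpx <- (p2x < g2x) - (p1x > g1x)
  diw_dpw <- 0.5 * (p2x < g2x) + 0.5 * (p1x > g1x)
  dih_dpy <- (p2y < g2y) - (p1y > g1y)
  dih_dph <- 0.5 * (p2y < g2y) + 0.5 * (p1y > g1y)
  pos <- function(z) ifelse(iw > 0 & ih > 0, z, 0)
  dI_dpx <- pos(ih * diw_dpx); dI_dpw <- pos(ih * diw_dpw)
  dI_dpy <- pos(iw * dih_dpy); dI_dph <- pos(iw * dih_dph)
  dIoU <- function(dI, dA) (dI * U - I * (dA - dI)) / U^2
  diou_dpx <- dIoU(dI_dpx, 0); diou_dpy <- dIoU(dI_dpy, 0)
  diou_dpw <- dIoU(dI_dpw, ph); diou_dph <- dIoU(dI_dph, pw)
  # center-distance penalty
  rho2 <- (px - gx)^2 + (py - gy)^2
  cw <- pmax(p2x, g2x) - pmin(p1x, g1x)
  chh <- pmax(p2y, g2y) - pmin(p1y, g1y)
  c2 <- cw^2 + chh^2
  dcw_dpx <- (p2x > g2x) - (p1x < g1x)
  dcw_dpw <- 0.5 * (p2x > g2x) + 0.5 * (p1x < g1x)
  dch_dpy <- (p2y > g2y) - (p1y < g1y)
  dch_dph <- 0.5 * (p2y > g2y) + 0.5 * (p1y < g1y)
  dpen <- function(drho2, dc2) (drho2 * c2 - rho2 * dc2) / c2^2
  dpen_dpx <- dpen(2 * (px - gx), 2 * cw * dcw_dpx)
  dpen_dpy <- dpen(2 * (py - gy), 2 * chh * dch_dpy)
  dpen_dpw <- dpen(0, 2 * cw * dcw_dpw)
  dpen_dph <- dpen(0, 2 * chh * dch_dph)
  # aspect-ratio penalty (alpha detached)
  delta <- atan(gw / gh) - atan(pw / ph)
  v <- (4 / pi^2) * delta^2
  alpha <- v / ((1 - iou) + v + 1e-12)
  dv_dpw <- -(8 / pi^2) * delta * ph / (pw^2 + ph^2)
  dv_dph <- (8 / pi^2) * delta * pw / (pw^2 + ph^2)
  list(ciou = iou - rho2 / c2 - alpha * v,
       grad = cbind(px = diou_dpx - dpen_dpx,
                    py = diou_dpy - dpen_dpy,
                    pw = diou_dpw - dpen_dpw - alpha * dv_dpw,
                    ph = diou_dph - dpen_dph - alpha * dv_dph))
}

#' Assign ground-truth boxes to anchors, cells and scales
#'
#' A label is assigned at a scale to every anchor whose size ratio satisfies
#' `max(w/aw, aw/w, h/ah, ah/h) < ratio_thresh`, in its containing cell plus
#' the two nearest neighbor cells (one horizontal, one vertical).
#'
#' @param labels A `norm_boxes` data frame (one image), or a list of them
#'   (a batch).
#' @param spec The `pest_model_spec` providing strides and anchors.
#' @param ratio_thresh Anchor size-ratio threshold, default 4.
#' @param input_size Pixel size labels are normalized against; defaults to
#'   `spec$input_size`.
#' @return A `target_assignment`: per scale, a data frame with columns
#'   `image`, `anchor` (1..3), `ci`, `cj` (0-based cell row/col), `gx`,
#'   `gy`, `gw`, `gh` (pixel ground truth) and `class_id`. Labels matched
#'   nowhere trigger a warning.
#' @export
assign_targets <- function(labels, spec, ratio_thresh = 4,
                           input_size = spec$input_size) {
  if (is.data.frame(labels)) labels <- list(labels)
  per_scale <- vector("list", length(spec$strides))
  n_unassigned <- 0L
  for (si in seq_along(spec$strides)) {
    stride <- spec$strides[si]
    grid <- input_size / stride
    anc <- spec$anchors[[si]]
    rows <- list()
    for (b in seq_along(labels)) {
      lb <- labels[[b]]
      if (!nrow(lb)) next
      gw <- lb$w * input_size; gh <- lb$h * input_size
      gx <- lb$cx * grid; gy <- lb$cy * grid # cell units
      for (a in 1:3) {
        r <- pmax(gw / anc[a, 1], anc[a, 1] / gw, gh / anc[a, 2], anc[a, 2] / gh)
        sel <- which(r < ratio_thresh)
        for (t in sel) {
          cj0 <- floor(gx[t]); ci0 <- floor(gy[t])
          cjs <- cj0; cis <- ci0
          fx <- gx[t] - cj0; fy <- gy[t] - ci0
          cj_n <- if (fx < 0.5) cj0 - 1 else cj0 + 1
          ci_n <- if (fy < 0.5) ci0 - 1 else ci0 + 1
          cand <- rbind(c(ci0, cj0), c(ci0, cj_n), c(ci_n, cj0))
          cand <- cand[cand[, 1] >= 0 & cand[, 1] < grid &
                         cand[, 2] >= 0 & cand[, 2] < grid, , drop = FALSE]
          rows[[length(rows) + 1L]] <- data.frame(
            image = b, anchor = a, ci = cand[, 1], cj = cand[, 2],
            gx = gx[t] * stride, gy = gy[t] * stride,
            gw = gw[t], gh = gh[t], class_id = lb$class_id[t], gt = t)
        }
      }
    }
    per_scale[[si]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(image = integer(0), anchor = integer(0), ci = integer(0),
                 cj = integer(0), gx = numeric(0), gy = numeric(0),
                 gw = numeric(0), gh = numeric(0), class_id = integer(0),
                 gt = integer(0))
  }
  # warn about labels no scale picked up
  for (b in seq_along(labels)) {
    lb <- labels[[b]]
    if (!nrow(lb)) next
    hit <- rep(FALSE, nrow(lb))
    for (si in seq_along(per_scale)) {
      ps <- per_scale[[si]]
      hit[unique(ps$gt[ps$image == b])] <- TRUE
    }
    n_unassigned <- n_unassigned + sum(!hit)
  }
  if (n_unassigned > 0L)
    warning(sprintf("%d label(s) not assigned at any scale (anchor ratio filter)",
                    n_unassigned))
  structure(list(per_scale = per_scale, n_images = length(labels),
                 input_size = input_size),
            class = "target_assignment")
}

.bce_logits <- function(z, t) {
  # numerically stable binary cross entropy with logits
  pmax(z, 0) - z * t + log1p(exp(-abs(z)))
}

#' Composite detection loss over all scales
#'
#' @param preds Raw per-scale head outputs from [model_forward()].
#' @param assignment A [assign_targets()] result for the same batch.
#' @param spec The model spec.
#' @param box_gain,cls_gain,obj_gain Term weights applied to the reported
#'   components; `total` is exactly their (already weighted) sum.
#' @param balance Per-scale objectness balance weights, finest scale first.
#' @param grad Also return `dpreds`, the loss gradient with respect to every
#'   raw head output (used by the training loop).
#' @return A `loss_report` list: `loss_box`, `loss_class`, `loss_object`,
#'   `total` (and `dpreds` when `grad = TRUE`).
#' @export
compute_loss <- function(preds, assignment, spec,
                         box_gain = 0.05, cls_gain = 0.5, obj_gain = 1.0,
                         balance = NULL, grad = FALSE) {
  K <- spec$num_classes
  nc <- 5L + K
  nsc <- length(spec$strides)
  balance <- balance %||%
    (if (nsc == 4L) c(4.0, 1.0, 0.4, 0.1) else c(4.0, 1.0, 0.4))
  lbox <- lcls <- lobj <- 0
  dpreds <- if (grad) vector("list", nsc) else NULL
  for (si in seq_len(nsc)) {
    p <- preds[[si]]
    if (length(dim(p)) == 3L) dim(p) <- c(dim(p), 1L)
    d <- dim(p)
    H <- d[1]; W <- d[2]; B <- d[4]
    stride <- spec$strides[si]
    anc <- spec$anchors[[si]]
    tobj <- array(0, dim = c(H, W, 3L, B))
    dp <- if (grad) array(0, dim = d) else NULL
    ps <- assignment$per_scale[[si]]
    n_t <- nrow(ps)
    if (n_t > 0L) {
      # linear indices of the assigned slots' channels
      ch0 <- (ps$anchor - 1L) * nc
      slot <- function(j) cbind(ps$ci + 1L, ps$cj + 1L, ch0 + j, ps$image)
      tx <- p[slot(1L)]; ty <- p[slot(2L)]
      tw <- p[slot(3L)]; th <- p[slot(4L)]
      sx <- sigmoid(tx); sy <- sigmoid(ty)
      sw <- sigmoid(tw); sh <- sigmoid(th)
      bx <- (2 * sx - 0.5 + ps$cj) * stride
      by <- (2 * sy - 0.5 + ps$ci) * stride
      bw <- (2 * sw)^2 * anc[ps$anchor, 1]
      bh <- (2 * sh)^2 * anc[ps$anchor, 2]
      cg <- ciou_cs_grad(cbind(bx, by, bw, bh),
                         cbind(ps$gx, ps$gy, ps$gw, ps$gh))
      lbox <- lbox + mean(1 - cg$ciou) * box_gain
      # objectness target: detached CIoU, clamped at 0
      tobj[cbind(ps$ci + 1L, ps$cj + 1L, ps$anchor, ps$image)] <-
        clamp(cg$ciou, 0, 1)
      # class BCE over K logits, one-hot targets
      zc <- vapply(seq_len(K), function(j) p[slot(5L + j)], numeric(n_t))
      zc <- matrix(zc, nrow = n_t)
      tc <- matrix(0, n_t, K)
      tc[cbind(seq_len(n_t), ps$class_id + 1L)] <- 1
      lcls <- lcls + mean(.bce_logits(zc, tc)) * cls_gain
      if (grad) {
        gb <- -cg$grad / n_t * box_gain # d mean(1-ciou) / d (bx,by,bw,bh)
        dtx <- gb[, 1] * 2 * sx * (1 - sx) * stride
        dty <- gb[, 2] * 2 * sy * (1 - sy) * stride
        dtw <- gb[, 3] * 8 * sw * sw * (1 - sw) * anc[ps$anchor, 1]
        dth <- gb[, 4] * 8 * sh * sh * (1 - sh) * anc[ps$anchor, 2]
        # accumulate (duplicated slots possible when neighbor cells coincide)
        acc <- function(j, val) {
          ix <- slot(j)
          for (u in seq_len(nrow(ix)))
            dp[ix[u, , drop = FALSE]] <<- dp[ix[u, , drop = FALSE]] + val[u]
        }
        acc(1L, dtx); acc(2L, dty); acc(3L, dtw); acc(4L, dth)
        dzc <- (sigmoid(zc) - tc) / (n_t * K) * cls_gain
        for (j in seq_len(K)) acc(5L + j, dzc[, j])
      }
    }
    zo <- p[, , (0:2) * nc + 5L, , drop = FALSE]
    lobj <- lobj + mean(.bce_logits(zo, tobj)) * obj_gain * balance[si]
    if (grad) {
      dzo <- (sigmoid(zo) - tobj) / length(zo) * obj_gain * balance[si]
      dp[, , (0:2) * nc + 5L, ] <- dp[, , (0:2) * nc + 5L, , drop = FALSE] + dzo
      dpreds[[si]] <- dp
    }
  }
  out <- list(loss_box = lbox, loss_class = lcls, loss_object = lobj,
              total = lbox + lcls + lobj)
  if (grad) out$dpreds <- dpreds
  class(out) <- "loss_report"
  out
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss: box %.5f + class %.5f + object %.5f = %.5f\n",
              x$loss_box, x$loss_class, x$loss_object, x$total))
  invisible(x)
}
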