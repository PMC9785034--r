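# Dataset-adapted anchors: k-means on ground-truth (w, h) pairs with the
# 1 - IoU(wh) distance, the standard auto-anchor recipe. The IoU of two
# sizes is computed with the boxes pinned to a common corner.

.iou_wh <- function(wh, cent) {
  iw <- outer(wh[, 1], cent[, 1], pmin)
  ih <- outer(wh[, 2], cent[, 2], pmin)
  inter <- iw * ih
  inter / (outer(wh[, 1] * wh[, 2], cent[, 1] * cent[, 2], `+`) - inter)
}

.kmeans_iou <- function(wh, k, seed, iters = 60L, restarts = 5L) {
  n <- nrow(wh)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      # k-means++ style seeding under the 1 - IoU distance
      cent <- wh[sample(n, 1L), , drop = FALSE]
      while (nrow(cent) < k) {
        d2 <- (1 - apply(.iou_wh(wh, cent), 1, max))^2
        if (sum(d2) <= 0) d2 <- rep(1, n)
        cent <- rbind(cent, wh[sample(n, 1L, prob = d2), ])
      }
      assign_prev <- rep(0L, n)
      for (it in seq_len(iters)) {
        a <- max.col(.iou_wh(wh, cent), ties.method = "first")
        if (all(a == assign_prev)) break
        assign_prev <- a
        for (j in seq_len(k)) {
          m <- a == j
          if (any(m)) cent[j, ] <- colMeans(wh[m, , drop = FALSE])
          else cent[j, ] <- wh[sample(n, 1L), ]
        }
      }
      fit <- mean(apply(.iou_wh(wh, cent), 1, max))
      if (is.null(best) || fit > best$fit) best <- list(cent = cent, fit = fit)
    }
  })
  best$cent
}

#' Compute dataset-adapted anchors by IoU k-means
#'
#' Clusters ground-truth box sizes (pixel w, h) into `num_anchors` centroids
#' under the 1 - IoU distance and assigns them to detection scales in
#' ascending-area triples (smallest anchors to the finest stride).
#'
#' @param wh Matrix or data frame of pixel box sizes, columns w and h.
#' @param num_anchors Total number of anchors (3 per scale).
#' @param strides Head strides, used for grouping and for the fallback table.
#' @param seed Integer seed for the clustering initialization.
#' @return List of 3 x 2 anchor matrices, one per stride, non-decreasing in
#'   area. With fewer boxes than `num_anchors` the default table is returned
#'   with a warning.
#' @export
compute_anchors <- function(wh, num_anchors = 12L, strides = c(4L, 8L, 16L, 32L),
                            seed = 0L) {
  wh <- as.matrix(wh)[, 1:2, drop = FALSE]
  stop_if_not(num_anchors == 3L * length(strides),
              "num_anchors must be 3 per detection scale")
  if (nrow(wh) < num_anchors) {
    warning("fewer boxes than anchors requested; using the default anchor table")
    return(default_anchors(strides))
  }
  stop_if_not(all(wh > 0), "box sizes must be positive")
  cent <- .kmeans_iou(wh, num_anchors, seed)
  cent <- cent[order(cent[, 1] * cent[, 2]), , drop = FALSE]
  out <- lapply(seq_along(strides), function(si) {
    m <- cent[(si - 1L) * 3L + 1:3, , drop = FALSE]
    dimnames(m) <- list(NULL, c("w", "h"))
    m
  })
  names(out) <- paste0("stride", strides)
  out
}
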