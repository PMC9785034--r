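# Independent CIoU implementation (separate authorship from the package's):
# computes the terms directly from corner coordinates.
ciou_oracle <- function(a, b) {
  inter_w <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  inter_h <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- inter_w * inter_h
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  iou <- inter / (area_a + area_b - inter)
  center_gap <- (mean(a[c(1, 3)]) - mean(b[c(1, 3)]))^2 +
    (mean(a[c(2, 4)]) - mean(b[c(2, 4)]))^2
  diag2 <- (max(a[3], b[3]) - min(a[1], b[1]))^2 +
    (max(a[4], b[4]) - min(a[2], b[2]))^2
  v <- 4 / pi^2 * (atan((b[3] - b[1]) / (b[4] - b[2])) -
                     atan((a[3] - a[1]) / (a[4] - a[2])))^2
  alpha <- v / (1 - iou + v + 1e-12)
  iou - center_gap / diag2 - alpha * v
}

test_that("CIoU: identical boxes give 1, distant same-shape boxes go negative", {
  b <- data.frame(x1 = 10, y1 = 10, x2 = 30, y2 = 40)
  expect_equal(ciou(b, b), 1)
  far <- data.frame(x1 = 300, y1 = 10, x2 = 320, y2 = 40)
  expect_lt(ciou(b, far), 0)
  # shared center and aspect ratio: penalties vanish, CIoU = IoU
  inner <- data.frame(x1 = 15, y1 = 17.5, x2 = 25, y2 = 32.5)
  expect_equal(ciou(b, inner), as.numeric(box_iou(b, inner)), tolerance = 1e-9)
  expect_error(ciou(b, data.frame(x1 = 0, y1 = 0, x2 = 0, y2 = 5)),
               "degenerate")
})

test_that("CIoU matches an independently coded evaluation on 1000 random pairs", {
  set.seed(10)
  n <- 1000
  a <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  A <- data.frame(x1 = a[, 1], y1 = a[, 2],
                  x2 = a[, 1] + runif(n, 1, 60), y2 = a[, 2] + runif(n, 1, 60))
  b <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  B <- data.frame(x1 = b[, 1], y1 = b[, 2],
                  x2 = b[, 1] + runif(n, 1, 60), y2 = b[, 2] + runif(n, 1, 60))
  got <- ciou(A, B)
  want <- vapply(seq_len(n), function(i)
    ciou_oracle(as.numeric(A[i, ]), as.numeric(B[i, ])), numeric(1))
  expect_lt(max(abs(got - want)), 1e-9)
  expect_true(all(got > -1 & got <= 1))
})

test_that("the CIoU gradient agrees with finite differences (alpha frozen)", {
  P <- asNamespace("pestdetect")
  set.seed(11)
  for (rep in 1:20) {
    p <- c(runif(2, 10, 40), runif(2, 5, 30))
    g <- c(runif(2, 10, 40), runif(2, 5, 30))
    r <- P$ciou_cs_grad(matrix(p, 1), matrix(g, 1))
    # frozen-alpha CIoU as a function of the prediction
    alpha0 <- {
      v <- 4 / pi^2 * (atan(g[3] / g[4]) - atan(p[3] / p[4]))^2
      x1 <- p[1] - p[3] / 2; x2 <- p[1] + p[3] / 2
      y1 <- p[2] - p[4] / 2; y2 <- p[2] + p[4] / 2
      gb <- c(g[1] - g[3] / 2, g[2] - g[4] / 2, g[1] + g[3] / 2, g[2] + g[4] / 2)
      iw <- max(0, min(x2, gb[3]) - max(x1, gb[1]))
      ih <- max(0, min(y2, gb[4]) - max(y1, gb[2]))
      iou <- iw * ih / (p[3] * p[4] + g[3] * g[4] - iw * ih)
      v / (1 - iou + v + 1e-12)
    }
    f <- function(q) {
      a <- data.frame(x1 = q[1] - q[3] / 2, y1 = q[2] - q[4] / 2,
                      x2 = q[1] + q[3] / 2, y2 = q[2] + q[4] / 2)
      b <- data.frame(x1 = g[1] - g[3] / 2, y1 = g[2] - g[4] / 2,
                      x2 = g[1] + g[3] / 2, y2 = g[2] + g[4] / 2)
      iou <- as.numeric(box_iou(a, b))
      rho2 <- (q[1] - g[1])^2 + (q[2] - g[2])^2
      cw <- max(a$x2, b$x2) - min(a$x1, b$x1)
      ch <- max(a$y2, b$y2) - min(a$y1, b$y1)
      v <- 4 / pi^2 * (atan(g[3] / g[4]) - atan(q[3] / q[4]))^2
      iou - rho2 / (cw^2 + ch^2) - alpha0 * v
    }
    eps <- 1e-6
    for (k in 1:4) {
      pp <- p; pp[k] <- pp[k] + eps
      pm <- p; pm[k] <- pm[k] - eps
      fd <- (f(pp) - f(pm)) / (2 * eps)
      expect_lt(abs(fd - r$grad[1, k]), 1e-4)
    }
  }
})

test_that("anchor-ratio assignment matches brute-force enumeration", {
  spec <- tiny_spec(num_classes = 5L)
  # a label exactly an anchor's size is assigned at that scale
  anc <- spec$anchors[[2]]
  lb <- norm_boxes(0L, 0.5, 0.5, anc[2, 1] / 64, anc[2, 2] / 64, K = 5L)
  asg <- assign_targets(lb, spec)
  expect_gt(nrow(asg$per_scale[[2]]), 0L)
  expect_true(2L %in% asg$per_scale[[2]]$anchor)
  # a label far larger than every anchor is assigned nowhere, with a warning
  big_spec <- spec
  big_spec$anchors <- lapply(spec$anchors, function(a) a / 200)
  expect_warning(asg2 <- assign_targets(norm_boxes(0L, 0.5, 0.5, 0.9, 0.9, K = 5L),
                                        big_spec), "not assigned")
  expect_true(all(vapply(asg2$per_scale, nrow, integer(1)) == 0L))

  # random labels: compare against direct enumeration over scales/anchors/cells
  set.seed(12)
  labs <- random_norm_boxes(8, K = 5L)
  asg3 <- suppressWarnings(assign_targets(labs, spec))
  for (si in seq_along(spec$strides)) {
    grid <- 64 / spec$strides[si]
    anc <- spec$anchors[[si]]
    want <- list()
    for (t in seq_len(nrow(labs))) {
      gw <- labs$w[t] * 64; gh <- labs$h[t] * 64
      gx <- labs$cx[t] * grid; gy <- labs$cy[t] * grid
      for (a in 1:3) {
        r <- max(gw / anc[a, 1], anc[a, 1] / gw, gh / anc[a, 2], anc[a, 2] / gh)
        if (r >= 4) next
        cj <- floor(gx); ci <- floor(gy)
        cells <- rbind(c(ci, cj),
                       c(ci, if (gx - cj < 0.5) cj - 1 else cj + 1),
                       c(if (gy - ci < 0.5) ci - 1 else ci + 1, cj))
        cells <- cells[cells[, 1] >= 0 & cells[, 1] < grid &
                         cells[, 2] >= 0 & cells[, 2] < grid, , drop = FALSE]
        for (q in seq_len(nrow(cells)))
          want[[length(want) + 1L]] <- c(a, cells[q, 1], cells[q, 2], t)
      }
    }
    want <- do.call(rbind, want)
    got <- asg3$per_scale[[si]]
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3], m[, 4]))
      expect_equal(key(cbind(got$anchor, got$ci, got$cj, got$gt)), key(want))
    }
  }
})

test_that("the composite loss is the exact sum of its three components", {
  set.seed(13)
  spec <- tiny_spec()
  nc <- 5L + spec$num_classes
  labs <- list(random_norm_boxes(2, K = 3L), random_norm_boxes(1, K = 3L))
  asg <- suppressWarnings(assign_targets(labs, spec))
  preds <- lapply(spec$strides, function(s) {
    H <- 64 / s
    array(rnorm(H * H * 3 * nc * 2), c(H, H, 3L * nc, 2L))
  })
  L <- compute_loss(preds, asg, spec)
  expect_identical(L$total, L$loss_box + L$loss_class + L$loss_object)
  expect_true(L$loss_box >= 0 && L$loss_class >= 0 && L$loss_object >= 0)
})

test_that("saturated-correct predictions drive the loss toward zero", {
  spec <- tiny_spec()
  K <- spec$num_classes
  nc <- 5L + K
  # ground truth at a cell center with exactly the anchor's size at scale 2
  si <- 2L
  stride <- spec$strides[si]
  grid <- 64 / stride
  anc <- spec$anchors[[si]]
  cx <- (2 + 0.5) / grid; cy <- (3 + 0.5) / grid
  lb <- norm_boxes(1L, cx, cy, anc[1, 1] / 64, anc[1, 2] / 64, K = K)
  spec_one <- spec
  # restrict anchors so only (scale 2, anchor 1) fires
  for (s in seq_along(spec_one$anchors))
    if (s != si) spec_one$anchors[[s]] <- spec_one$anchors[[s]] * 1e4
  spec_one$anchors[[si]][2:3, ] <- spec_one$anchors[[si]][2:3, ] * 1e4
  asg <- assign_targets(lb, spec_one)
  preds <- lapply(spec_one$strides, function(s) {
    H <- 64 / s
    array(c(-30), c(H, H, 3L * nc, 1L)) # objectness everywhere ~ 0
  })
  ps <- asg$per_scale[[si]]
  for (r in seq_len(nrow(ps))) {
    i <- ps$ci[r] + 1L; j <- ps$cj[r] + 1L
    ch <- (ps$anchor[r] - 1L) * nc
    # invert the decode: sigma(t) solving (2s-0.5+c)*stride = gx etc.
    sx <- (ps$gx[r] / stride - ps$cj[r] + 0.5) / 2
    sy <- (ps$gy[r] / stride - ps$ci[r] + 0.5) / 2
    preds[[si]][i, j, ch + 1, 1] <- qlogis(sx)
    preds[[si]][i, j, ch + 2, 1] <- qlogis(sy)
    preds[[si]][i, j, ch + 3, 1] <- qlogis(sqrt(ps$gw[r] / anc[ps$anchor[r], 1]) / 2)
    preds[[si]][i, j, ch + 4, 1] <- qlogis(sqrt(ps$gh[r] / anc[ps$anchor[r], 2]) / 2)
    preds[[si]][i, j, ch + 5, 1] <- 30 # objectness -> 1 (target CIoU = 1)
    preds[[si]][i, j, ch + 5 + 1:K, 1] <- -30
    preds[[si]][i, j, ch + 5 + ps$class_id[r] + 1L, 1] <- 30
  }
  L <- compute_loss(preds, asg, spec_one)
  expect_lt(L$loss_box, 1e-8)
  expect_lt(L$loss_class, 1e-8)
  expect_lt(L$loss_object, 1e-8)
})

test_that("moving a box toward its target strictly decreases the box loss", {
  spec <- tiny_spec()
  K <- spec$num_classes
  nc <- 5L + K
  si <- 2L
  stride <- spec$strides[si]
  grid <- 64 / stride
  anc <- spec$anchors[[si]]
  lb <- norm_boxes(0L, (3 + 0.5) / grid, (3 + 0.5) / grid,
                   anc[1, 1] / 64, anc[1, 2] / 64, K = K)
  asg <- suppressWarnings(assign_targets(lb, spec))
  base <- lapply(spec$strides, function(s) {
    H <- 64 / s
    array(0, c(H, H, 3L * nc, 1L))
  })
  # sweep tx at the containing cell from far (-3) to centered (0)
  ps <- asg$per_scale[[si]]
  main <- which(ps$ci == 3 & ps$cj == 3 & ps$anchor == 1)[1]
  expect_false(is.na(main))
  vals <- vapply(seq(-3, 0, length.out = 10), function(tx) {
    p <- base
    p[[si]][4, 4, 1, 1] <- tx
    compute_loss(p, asg, spec)$loss_box
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("per-slot box loss lies in [0, 2) and empty assignments are safe", {
  spec <- tiny_spec()
  nc <- 5L + spec$num_classes
  asg <- assign_targets(norm_boxes(K = 3L), spec)
  preds <- lapply(spec$strides, function(s) {
    H <- 64 / s
    array(rnorm(H * H * 3 * nc), c(H, H, 3L * nc, 1L))
  })
  L <- compute_loss(preds, asg, spec)
  expect_equal(L$loss_box, 0)
  expect_equal(L$loss_class, 0)
  expect_gt(L$loss_object, 0)
})
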