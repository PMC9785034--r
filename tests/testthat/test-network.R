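test_that("focus transform is a bijective 2x2 space-to-depth", {
  v <- 0.37
  const <- array(v, c(8, 8, 3))
  f <- focus_transform(const)
  expect_equal(dim(f), c(4L, 4L, 12L))
  expect_true(all(f == v))
  set.seed(1)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(focus_inverse(focus_transform(img)), img)
  expect_error(focus_transform(array(0, c(7, 8, 3))), "even")
})

test_that("head grids follow input / stride at several input sizes", {
  spec512 <- model_spec("proposed", input_size = 512L, widths = c(4, 4, 8, 8, 16))
  m <- build_model(spec512, seed = 1)
  x <- array(0, c(512, 512, 3))
  fw <- model_forward(m, x)
  expect_equal(vapply(fw$preds, function(p) dim(p)[1], numeric(1)),
               c(128, 64, 32, 16))
  expect_true(all(vapply(fw$preds, function(p) all(is.finite(p)), logical(1))))

  spec256 <- model_spec("proposed", input_size = 256L, widths = c(4, 4, 8, 8, 16))
  fw256 <- model_forward(build_model(spec256, seed = 1),
                         array(0, c(256, 256, 3)))
  expect_equal(vapply(fw256$preds, function(p) dim(p)[1], numeric(1)),
               c(64, 32, 16, 8))
  # doubling the input side quadruples every grid's cell count
  cells512 <- vapply(fw$preds, function(p) dim(p)[1] * dim(p)[2], numeric(1))
  cells256 <- vapply(fw256$preds, function(p) dim(p)[1] * dim(p)[2], numeric(1))
  expect_equal(cells512, 4 * cells256)
})

test_that("decode inverts to cell centers and anchor sizes at zero logits", {
  spec <- tiny_spec()
  K <- spec$num_classes
  nc <- 5L + K
  H <- 64L / spec$strides[1]
  p <- array(0, c(H, H, 3L * nc, 1L))
  # zero logits: sigma(0) = 0.5 -> center at cell center, size = anchor
  dd <- decode(list(p), spec, conf_thresh = 0)
  a1 <- spec$anchors[[1]]
  stride <- spec$strides[1]
  cell <- dd[dd$class_id == 0 & abs(dd$x2 - dd$x1 - a1[1, 1]) < 1e-9, ][1, ]
  cx <- (cell$x1 + cell$x2) / 2
  expect_equal((cx / stride) %% 1, 0.5)
  expect_equal(cell$x2 - cell$x1, unname(a1[1, 1]))
  expect_equal(cell$y2 - cell$y1, unname(a1[1, 2]))
  # threshold 1 keeps nothing (sigmoid scores are strictly below 1)
  expect_equal(nrow(decode(list(p), spec, conf_thresh = 1)), 0L)
})

test_that("decode equals a cell-by-cell loop-nest oracle on random logits", {
  set.seed(2)
  spec <- tiny_spec()
  K <- spec$num_classes
  nc <- 5L + K
  si <- 2L
  H <- 64L / spec$strides[si]
  p <- array(rnorm(H * H * 3 * nc), c(H, H, 3L * nc, 1L))
  preds <- lapply(seq_along(spec$strides), function(s)
    if (s == si) p else array(-20, c(64 / spec$strides[s], 64 / spec$strides[s],
                                     3L * nc, 1L)))
  got <- decode(preds, spec, conf_thresh = 0.001)
  got <- got[order(got$score), ]
  sg <- function(z) 1 / (1 + exp(-z))
  rows <- list()
  for (a in 1:3) for (i in 1:H) for (j in 1:H) {
    ch <- (a - 1L) * nc
    tx <- p[i, j, ch + 1, 1]; ty <- p[i, j, ch + 2, 1]
    tw <- p[i, j, ch + 3, 1]; th <- p[i, j, ch + 4, 1]
    obj <- sg(p[i, j, ch + 5, 1])
    cl <- sg(p[i, j, ch + 5 + 1:K, 1])
    k <- which.max(cl)
    score <- obj * cl[k]
    if (score < 0.001) next
    bx <- (2 * sg(tx) - 0.5 + (j - 1)) * spec$strides[si]
    by <- (2 * sg(ty) - 0.5 + (i - 1)) * spec$strides[si]
    bw <- (2 * sg(tw))^2 * spec$anchors[[si]][a, 1]
    bh <- (2 * sg(th))^2 * spec$anchors[[si]][a, 2]
    rows[[length(rows) + 1L]] <- c(k - 1, score, bx - bw / 2, by - bh / 2,
                                   bx + bw / 2, by + bh / 2)
  }
  oracle <- do.call(rbind, rows)
  oracle <- oracle[order(oracle[, 2]), , drop = FALSE]
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$class_id, oracle[, 1])
  expect_lt(max(abs(cbind(got$score, got$x1, got$y1, got$x2, got$y2) -
                      oracle[, c(2, 3, 4, 5, 6)])), 1e-9)
})

test_that("greedy NMS matches an O(n^2) brute-force suppressor", {
  brute_nms <- function(dets, thr) {
    keep <- logical(nrow(dets))
    ord <- order(-dets$score)
    for (i in ord) {
      ok <- TRUE
      for (j in which(keep)) {
        if (dets$class_id[j] != dets$class_id[i]) next
        if (box_iou(dets[i, , drop = FALSE], dets[j, , drop = FALSE]) > thr)
          ok <- FALSE
      }
      keep[i] <- ok
    }
    which(keep)
  }
  one <- data.frame(class_id = 0L, score = 0.7, x1 = 0, y1 = 0, x2 = 5, y2 = 5)
  expect_equal(nrow(nms(one)), 1L)
  two <- rbind(one, transform(one, score = 0.9))
  kept <- nms(two)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 0.9)
  set.seed(3)
  for (rep in 1:3) {
    dets <- random_dets(200)
    got <- nms(dets, 0.45)
    want <- dets[sort(brute_nms(dets, 0.45)), ]
    expect_equal(got[order(got$x1, got$score), -1] * 1.0,
                 want[order(want$x1, want$score), -1] * 1.0,
                 ignore_attr = TRUE)
    iou_mat <- box_iou(got, got)
    same <- outer(got$class_id, got$class_id, `==`)
    diag(iou_mat) <- 0
    expect_true(all(iou_mat[same] <= 0.45 + 1e-12))
  }
})

test_that("anchor clustering recovers planted size clusters within 5%", {
  planted <- cbind(w = c(6, 10, 14, 20, 28, 38, 52, 70, 95, 130, 175, 230),
                   h = c(8, 12, 18, 24, 34, 46, 62, 84, 115, 150, 200, 260))
  set.seed(4)
  wh <- planted[rep(1:12, each = 40), ] * matrix(runif(2 * 480, 0.98, 1.02), ncol = 2)
  anc <- compute_anchors(wh, seed = 1)
  cents <- do.call(rbind, anc)
  areas <- cents[, 1] * cents[, 2]
  expect_true(all(diff(areas) >= -1e-9)) # sorted by area
  ord <- order(planted[, 1] * planted[, 2])
  rel <- abs(cents - planted[ord, ]) / planted[ord, ]
  expect_lt(max(rel), 0.05)
})

test_that("anchor clustering is degenerate-safe and falls back when data-poor", {
  wh <- matrix(51.2, nrow = 30, ncol = 2)
  anc <- compute_anchors(wh, seed = 0)
  expect_true(all(abs(do.call(rbind, anc) - 51.2) < 1e-9))
  expect_warning(a2 <- compute_anchors(matrix(10, 5, 2), seed = 0), "default")
  expect_equal(a2, default_anchors(c(4L, 8L, 16L, 32L)))
})

test_that("built models agree with the analytic parameter count", {
  spec <- tiny_spec()
  m <- tiny_model()
  expect_equal(model_num_params(m), count_params(spec))
  sb <- model_spec("baseline", input_size = 64, widths = c(4, 4, 8, 8, 16))
  expect_equal(model_num_params(build_model(sb, seed = 1)), count_params(sb))
})
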