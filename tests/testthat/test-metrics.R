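test_that("matching: perfect detections are all TP, missing ones all FN", {
  gts <- data.frame(class_id = c(0L, 1L, 1L),
                    x1 = c(0, 20, 50), y1 = c(0, 20, 50),
                    x2 = c(10, 35, 70), y2 = c(10, 35, 70))
  dets <- cbind(gts, score = c(0.9, 0.8, 0.7))
  rec <- match_detections(dets, gts)
  expect_true(all(rec$dets$tp))
  expect_equal(sum(rec$fn), 0)
  rec0 <- match_detections(dets[0, ], gts)
  expect_equal(sum(rec0$fn), 3)
})

test_that("each ground truth is matched at most once (duplicates become FP)", {
  gt <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  dup <- data.frame(class_id = 0L, score = c(0.9, 0.8),
                    x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  rec <- match_detections(dup, gt)
  expect_equal(sum(rec$dets$tp), 1)
  expect_equal(rec$dets$tp[order(-rec$dets$score)], c(TRUE, FALSE))
})

test_that("matching agrees with a brute-force greedy reference on random instances", {
  brute_match <- function(dets, gts, thr) {
    used <- rep(FALSE, nrow(gts))
    tp <- logical(nrow(dets))
    for (i in order(-dets$score)) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(gts))) {
        if (used[j] || gts$class_id[j] != dets$class_id[i]) next
        iou <- as.numeric(box_iou(dets[i, , drop = FALSE], gts[j, , drop = FALSE]))
        if (iou > best) { best <- iou; bj <- j }
      }
      if (bj > 0 && best >= thr) { tp[i] <- TRUE; used[bj] <- TRUE }
    }
    tp
  }
  set.seed(20)
  for (rep in 1:5) {
    dets <- random_dets(30)
    gts <- random_dets(20)[, -2]
    rec <- match_detections(dets, gts, 0.5)
    want <- brute_match(dets, gts, 0.5)
    ord <- order(-dets$score)
    expect_equal(rec$dets$tp, want[ord])
    expect_equal(sum(rec$fn), nrow(gts) - sum(want))
  }
})

test_that("precision and recall follow their definitions", {
  rec <- structure(list(dets = data.frame(score = runif(4),
                                          tp = c(TRUE, TRUE, TRUE, FALSE)),
                        fn = c(`0` = 0L), n_gt = c(`0` = 3L)),
                   class = "match_record")
  pr <- precision_recall(rec)
  expect_equal(pr$precision, 0.75) # TP=3, FP=1
  rec2 <- structure(list(dets = data.frame(score = runif(8),
                                           tp = rep(TRUE, 8)),
                         fn = c(`0` = 2L), n_gt = c(`0` = 10L)),
                    class = "match_record")
  expect_equal(precision_recall(rec2)$recall, 0.8) # TP=8, FN=2
  empty <- structure(list(dets = data.frame(score = numeric(0),
                                            tp = logical(0)),
                          fn = c(`0` = 0L), n_gt = c(`0` = 0L)),
                     class = "match_record")
  pr0 <- precision_recall(empty)
  expect_equal(pr0$precision, 0)
  expect_false(pr0$precision_defined)
})

test_that("AP equals a brute-force PR integration on the 5-detection toy set", {
  # rectangle-summation oracle over the monotone envelope
  ap_oracle <- function(scores, tp, n_gt) {
    ord <- order(-scores)
    tp <- tp[ord]
    rec <- cumsum(tp) / n_gt
    pre <- cumsum(tp) / seq_along(tp)
    area <- 0
    grid <- sort(unique(c(0, rec)))
    for (i in seq_len(length(grid) - 1)) {
      r_hi <- grid[i + 1]
      p_best <- max(c(0, pre[rec >= r_hi]))
      area <- area + (r_hi - grid[i]) * p_best
    }
    area
  }
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  flags <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(average_precision(scores, flags, n_gt = 3),
               ap_oracle(scores, flags, 3))
  expect_equal(average_precision(0.9, TRUE, n_gt = 1), 1)
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    s <- runif(n)
    f <- runif(n) < 0.5
    ngt <- sum(f) + sample(0:5, 1)
    if (ngt == 0) next
    expect_equal(average_precision(s, f, ngt), ap_oracle(s, f, ngt),
                 tolerance = 1e-12)
  }
})

test_that("AP is invariant to monotone score transforms; mAP averages classes", {
  set.seed(22)
  s <- runif(20)
  f <- runif(20) < 0.4
  a1 <- average_precision(s, f, 10)
  a2 <- average_precision(plogis(3 * s - 1), f, 10)
  expect_equal(a1, a2)
  expect_equal(mean_ap(c(1.0, 0.5)), 0.75)
  expect_equal(mean_ap(c(a = 0.2, b = 0.6, c = 0.7)),
               mean_ap(c(c = 0.7, a = 0.2, b = 0.6)))
  expect_warning(m <- mean_ap(c(0.5, NA)), "excluded")
  expect_equal(m, 0.5)
})

test_that("confusion matrix: perfect detections give a unit diagonal", {
  gts <- data.frame(class_id = 0:2,
                    x1 = c(0, 30, 60), y1 = c(0, 30, 60),
                    x2 = c(10, 45, 80), y2 = c(10, 45, 80))
  dets <- cbind(gts, score = 0.9)
  M <- confusion_matrix(dets, gts, num_classes = 3L)
  expect_equal(diag(M)[1:3], rep(1, 3), ignore_attr = TRUE)
  M0 <- confusion_matrix(dets[0, ], gts, num_classes = 3L)
  expect_equal(M0[4, 1:3], rep(1, 3), ignore_attr = TRUE) # background row
})

test_that("confusion matrix equals a direct recount and columns sum to 1", {
  recount <- function(dets, gts, K, conf, iou) {
    M <- matrix(0, K + 1, K + 1)
    d <- dets[dets$score >= conf, , drop = FALSE]
    used <- rep(FALSE, nrow(gts))
    for (i in order(-d$score)) {
      bi <- 0; best <- iou
      for (j in seq_len(nrow(gts))) {
        if (used[j]) next
        o <- as.numeric(box_iou(d[i, , drop = FALSE], gts[j, , drop = FALSE]))
        if (o >= best) { best <- o; bi <- j }
      }
      if (bi > 0) { M[d$class_id[i] + 1, gts$class_id[bi] + 1] <-
        M[d$class_id[i] + 1, gts$class_id[bi] + 1] + 1; used[bi] <- TRUE }
      else M[d$class_id[i] + 1, K + 1] <- M[d$class_id[i] + 1, K + 1] + 1
    }
    for (j in which(!used)) M[K + 1, gts$class_id[j] + 1] <-
      M[K + 1, gts$class_id[j] + 1] + 1
    M
  }
  set.seed(23)
  for (rep in 1:5) {
    dets <- random_dets(25)
    gts <- random_dets(15)[, -2]
    M <- confusion_matrix(dets, gts, num_classes = 3L, normalize = FALSE)
    want <- recount(dets, gts, 3L, 0.25, 0.45)
    expect_equal(unname(M), want)
    Mn <- confusion_matrix(dets, gts, num_classes = 3L)
    cs <- colSums(Mn)
    expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
  }
})
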