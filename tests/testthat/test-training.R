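test_that("a single epoch returns a checkpoint and a 1-row history", {
  data <- overfit_fixture()
  four <- list(images = data$images[1:4], boxes = data$boxes[1:4],
               ids = data$ids[1:4])
  wh <- do.call(rbind, lapply(four$boxes, function(b) cbind(b$w, b$h))) * 64
  anc <- suppressWarnings(compute_anchors(rbind(wh, wh, wh, wh), seed = 0))
  spec <- model_spec("proposed", input_size = 64L, widths = c(4, 4, 8, 8, 16),
                     depth_mult = 0.12, anchors = anc)
  fit <- suppressWarnings(train_detector(
    build_model(spec, seed = 1), four,
    config = train_config(epochs = 1L, batch_size = 2L, augment = FALSE,
                          seed = 1L)))
  expect_s3_class(fit, "pest_fit")
  expect_equal(nrow(fit$history), 1L)
  expect_true(all(c("loss_box", "loss_class", "loss_object", "map") %in%
                    names(fit$history)))
  expect_true(is.finite(fit$history$loss_total))
  p <- file.path(tempdir(), "fit.rds")
  save_checkpoint(fit, p)
  expect_s3_class(load_checkpoint(p), "pest_fit")
})

test_that("training is deterministic under a fixed seed", {
  data <- overfit_fixture()
  four <- list(images = data$images[c(1, 6, 11, 16)],
               boxes = data$boxes[c(1, 6, 11, 16)],
               ids = data$ids[c(1, 6, 11, 16)])
  spec <- model_spec("proposed", input_size = 64L, widths = c(4, 4, 8, 8, 16),
                     depth_mult = 0.12)
  cfg <- train_config(epochs = 2L, batch_size = 2L, seed = 7L, augment = TRUE)
  f1 <- suppressWarnings(train_detector(build_model(spec, seed = 7), four,
                                        config = cfg))
  f2 <- suppressWarnings(train_detector(build_model(spec, seed = 7), four,
                                        config = cfg))
  expect_equal(f1$history, f2$history)
  f3 <- suppressWarnings(train_detector(build_model(spec, seed = 8), four,
                                        config = train_config(epochs = 2L,
                                                              batch_size = 2L,
                                                              seed = 8L)))
  expect_false(isTRUE(all.equal(f1$history$loss_total, f3$history$loss_total)))
})

test_that("augmentation keeps boxes consistent with the transformed image", {
  P <- asNamespace("pestdetect")
  set.seed(30)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  boxes <- random_norm_boxes(3, K = 5L)
  # pure horizontal flip mirrors centers
  a <- with_flip <- NULL
  set.seed(1)
  a <- P$augment_image(img, boxes, flip_prob = 1, jitter = 0)
  expect_equal(a$boxes$cx, 1 - boxes$cx)
  expect_equal(a$boxes$cy, boxes$cy)
  expect_equal(a$image[, 64:1, ], img)
  # jitter preserves validity
  for (i in 1:10) {
    b <- P$augment_image(img, boxes, flip_prob = 0.5, jitter = 0.1)
    expect_equal(dim(b$image), dim(img))
    if (nrow(b$boxes)) expect_silent(validate_norm_boxes(b$boxes, K = 5L))
  }
})

test_that("the SGD step applies momentum and decays only kernels", {
  P <- asNamespace("pestdetect")
  spec <- tiny_spec()
  m <- tiny_model(seed = 2)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  labs <- list(random_norm_boxes(1, K = 3L), random_norm_boxes(1, K = 3L))
  asg <- suppressWarnings(assign_targets(labs, spec))
  fw <- model_forward(m, x, training = TRUE)
  loss <- compute_loss(fw$preds, asg, spec, grad = TRUE)
  grads <- model_backward(fw$model, fw, loss$dpreds)
  st <- P$sgd_step(fw$model, grads, vector("list", length(m$nodes)),
                   lr = 0.01, momentum = 0.9, wd = 0)
  w0 <- m$nodes[[1]]$unit$params$conv$w
  w1 <- st$model$nodes[[1]]$unit$params$conv$w
  g <- grads[[1]]$unit$conv$w
  expect_equal(w1, w0 - 0.01 * g, tolerance = 1e-12)
  # velocity carried to the next step
  st2 <- P$sgd_step(st$model, grads, st$velocity, lr = 0.01, momentum = 0.9,
                    wd = 0)
  w2 <- st2$model$nodes[[1]]$unit$params$conv$w
  expect_equal(w2, w1 - 0.01 * (0.9 * g + g), tolerance = 1e-12)
})

test_that("predict letterboxes arbitrary image sizes back to the original frame", {
  m <- tiny_model(seed = 3)
  img <- array(runif(100 * 80 * 3), c(100, 80, 3))
  dd <- predict(m, img, conf_thresh = 0.2)
  expect_true(is.data.frame(dd))
  expect_true(all(c("class", "score", "x1", "y1", "x2", "y2") %in% names(dd)))
  lst <- predict(m, list(img, img), conf_thresh = 0.99)
  expect_equal(length(lst), 2L)
})
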