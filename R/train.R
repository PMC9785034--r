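# Training: SGD with momentum and weight decay over the hand-derived
# backward pass, per-epoch validation mAP, and best-mAP checkpointing.

#' Training configuration
#'
#' @param epochs Number of epochs T (default 200).
#' @param batch_size Images per SGD step (default 10).
#' @param lr Initial learning rate (SGD), default 0.01.
#' @param momentum SGD momentum, default 0.937.
#' @param weight_decay L2 penalty on convolution/FC kernels (not biases or
#'   batch-norm affine terms), default 5e-4.
#' @param lr_schedule `"cosine"` (decay to `final_lr_frac * lr`) or
#'   `"constant"`.
#' @param final_lr_frac Final fraction of `lr` under the cosine schedule.
#' @param warmup_epochs Epochs of linear learning-rate warmup (0 disables).
#' @param augment Augmentation mode: `TRUE` (or `"online"`) draws a fresh
#'   random flip/jitter per image per epoch; `"offline"` expands the
#'   training set once with `offline_copies` augmented copies per image
#'   before the epoch loop (the pseudo-code ordering: augment, then train);
#'   `FALSE` disables augmentation.
#' @param offline_copies Augmented copies per source image in offline mode.
#' @param flip_prob Probability of a horizontal flip.
#' @param jitter Scale-jitter range; each image is rescaled by a factor in
#'   `[1 - jitter, 1 + jitter]` and re-cropped/padded to size.
#' @param seed Seed controlling shuffling, augmentation and initialization.
#' @param eval_conf Confidence threshold of the per-epoch validation pass.
#' @param box_gain,cls_gain,obj_gain Loss-term weights passed to
#'   [compute_loss()].
#' @param ratio_thresh Anchor size-ratio threshold of the target assignment.
#' @param target_map Optional early-stop threshold: training stops once
#'   validation mAP reaches it (the epoch budget `epochs` is the cap).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 10L, lr = 0.01,
                         momentum = 0.937, weight_decay = 5e-4,
                         lr_schedule = c("cosine", "constant"),
                         final_lr_frac = 0.1,
                         warmup_epochs = 0L,
                         augment = TRUE, flip_prob = 0.5, jitter = 0.1,
                         offline_copies = 2L,
                         seed = 0L, eval_conf = 0.01,
                         box_gain = 0.05, cls_gain = 0.5, obj_gain = 1.0,
                         ratio_thresh = 4, target_map = NULL) {
  stop_if_not(epochs >= 1L, "need at least one epoch")
  stop_if_not(batch_size >= 1L, "batch size must be >= 1")
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = lr, momentum = momentum, weight_decay = weight_decay,
              lr_schedule = match.arg(lr_schedule),
              final_lr_frac = final_lr_frac,
              warmup_epochs = as.integer(warmup_epochs),
              augment = augment, flip_prob = flip_prob,
              offline_copies = as.integer(offline_copies),
              jitter = jitter, seed = as.integer(seed),
              eval_conf = eval_conf,
              box_gain = box_gain, cls_gain = cls_gain, obj_gain = obj_gain,
              ratio_thresh = ratio_thresh, target_map = target_map)
  class(cfg) <- "train_config"
  cfg
}

## ---- SGD over parameter trees ---------------------------------------------

# One momentum-SGD step on a (params, grads, velocity) leaf triple. Weight
# decay applies only to leaves named "w" (conv kernels and FC weights).
.sgd_tree <- function(p, g, v, lr, momentum, wd) {
  if (is.numeric(p)) stop("internal: .sgd_tree expects named lists at the top")
  for (nm in names(p)) {
    if (is.null(p[[nm]]) || is.null(g[[nm]])) next
    if (is.list(p[[nm]])) {
      r <- .sgd_tree(p[[nm]], g[[nm]], v[[nm]] %||% list(), lr, momentum, wd)
      p[[nm]] <- r$p
      v[[nm]] <- r$v
    } else {
      grad <- g[[nm]]
      if (nm == "w") grad <- grad + wd * p[[nm]]
      vel <- momentum * (v[[nm]] %||% 0) + grad
      p[[nm]] <- p[[nm]] - lr * vel
      v[[nm]] <- vel
    }
  }
  list(p = p, v = v)
}

sgd_step <- function(model, grads, velocity, lr, momentum, wd) {
  for (i in seq_along(model$nodes)) {
    if (is.null(grads[[i]])) next
    tree <- node_param_tree(model$nodes[[i]])
    r <- .sgd_tree(tree, grads[[i]], velocity[[i]] %||% list(), lr, momentum, wd)
    model$nodes[[i]] <- node_set_param_tree(model$nodes[[i]], r$p)
    velocity[[i]] <- r$v
  }
  list(model = model, velocity = velocity)
}

## ---- augmentation ---------------------------------------------------------

augment_image <- function(img, boxes, flip_prob, jitter) {
  d <- dim(img)
  if (runif(1) < flip_prob) {
    img <- img[, d[2]:1, , drop = FALSE]
    if (nrow(boxes)) boxes$cx <- 1 - boxes$cx
  }
  if (jitter > 0) {
    f <- runif(1, 1 - jitter, 1 + jitter)
    nh <- max(32L, as.integer(round(d[1] * f)))
    nw <- max(32L, as.integer(round(d[2] * f)))
    rs <- cpp_resize_bilinear(img, dim(img), nh, nw)
    out <- array(0.5, dim = d)
    if (f >= 1) { # center crop
      r0 <- (nh - d[1]) %/% 2L; c0 <- (nw - d[2]) %/% 2L
      out <- rs[r0 + seq_len(d[1]), c0 + seq_len(d[2]), , drop = FALSE]
      if (nrow(boxes)) {
        boxes$cx <- (boxes$cx * nw - c0) / d[2]
        boxes$cy <- (boxes$cy * nh - r0) / d[1]
        boxes$w <- boxes$w * nw / d[2]
        boxes$h <- boxes$h * nh / d[1]
      }
    } else { # center pad
      r0 <- (d[1] - nh) %/% 2L; c0 <- (d[2] - nw) %/% 2L
      out[r0 + seq_len(nh), c0 + seq_len(nw), ] <- rs
      if (nrow(boxes)) {
        boxes$cx <- (boxes$cx * nw + c0) / d[2]
        boxes$cy <- (boxes$cy * nh + r0) / d[1]
        boxes$w <- boxes$w * nw / d[2]
        boxes$h <- boxes$h * nh / d[1]
      }
    }
    img <- out
    if (nrow(boxes)) { # drop boxes pushed (almost) out of the canvas
      x1 <- clamp(boxes$cx - boxes$w / 2, 0, 1)
      x2 <- clamp(boxes$cx + boxes$w / 2, 0, 1)
      y1 <- clamp(boxes$cy - boxes$h / 2, 0, 1)
      y2 <- clamp(boxes$cy + boxes$h / 2, 0, 1)
      keep <- (x2 - x1) > 1e-3 & (y2 - y1) > 1e-3
      boxes <- boxes[keep, , drop = FALSE]
      if (nrow(boxes)) {
        x1 <- x1[keep]; x2 <- x2[keep]; y1 <- y1[keep]; y2 <- y2[keep]
        boxes$cx <- (x1 + x2) / 2; boxes$cy <- (y1 + y2) / 2
        boxes$w <- x2 - x1; boxes$h <- y2 - y1
      }
    }
  }
  list(image = img, boxes = boxes)
}

## ---- training loop --------------------------------------------------------

#' Train a pest detector
#'
#' Runs the epoch loop: shuffle, augment, forward, composite loss, SGD step;
#' after each epoch the model is evaluated on the validation set and the
#' weights with the highest validation mAP@0.5 are retained.
#'
#' @param model A `pest_model` from [build_model()].
#' @param train_data,val_data Datasets as returned by [load_yolo_dataset()];
#'   images must already be at the model's input size.
#' @param config A [train_config()].
#' @return A `pest_fit`: `model` (best weights), `last_model`, `history`
#'   (per-epoch data frame with losses, P, R and mAP), `best_epoch`,
#'   `config`.
#' @export
train_detector <- function(model, train_data, val_data = train_data,
                           config = train_config()) {
  stop_if_not(length(train_data$images) >= 1L, "empty training set")
  stop_if_not(length(val_data$images) >= 1L, "empty validation set")
  spec <- model$spec
  velocity <- vector("list", length(model$nodes))
  history <- NULL
  best <- list(map = -Inf, model = model, epoch = 0L)
  set.seed(config$seed)
  online_aug <- isTRUE(config$augment) || identical(config$augment, "online")
  if (identical(config$augment, "offline")) {
    # expand the training set once with augmented copies, then iterate
    imgs <- train_data$images
    bxs <- train_data$boxes
    for (k in seq_len(config$offline_copies)) {
      for (i in seq_along(train_data$images)) {
        a <- augment_image(train_data$images[[i]], train_data$boxes[[i]],
                           config$flip_prob, config$jitter)
        imgs[[length(imgs) + 1L]] <- a$image
        bxs[[length(bxs) + 1L]] <- a$boxes
      }
    }
    train_data <- list(images = imgs, boxes = bxs)
  }
  n <- length(train_data$images)
  for (epoch in seq_len(config$epochs)) {
    lr <- if (config$lr_schedule == "cosine") {
      frac <- if (config$epochs > 1L) (epoch - 1) / (config$epochs - 1) else 0
      config$lr * (config$final_lr_frac +
                     (1 - config$final_lr_frac) * (1 + cos(pi * frac)) / 2)
    } else config$lr
    if (config$warmup_epochs > 0L && epoch <= config$warmup_epochs)
      lr <- lr * epoch / (config$warmup_epochs + 1)
    ord <- sample(n)
    ep_loss <- c(box = 0, cls = 0, obj = 0, total = 0)
    n_batches <- 0L
    for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      imgs <- vector("list", length(bs))
      lbls <- vector("list", length(bs))
      for (k in seq_along(bs)) {
        img <- train_data$images[[bs[k]]]
        bx <- train_data$boxes[[bs[k]]]
        if (online_aug) {
          a <- augment_image(img, bx, config$flip_prob, config$jitter)
          img <- a$image; bx <- a$boxes
        }
        imgs[[k]] <- img
        lbls[[k]] <- bx
      }
      d <- dim(imgs[[1]])
      batch <- array(0, dim = c(d[1], d[2], 3L, length(bs)))
      for (k in seq_along(bs)) batch[, , , k] <- imgs[[k]]
      asg <- suppressWarnings(
        assign_targets(lbls, spec, ratio_thresh = config$ratio_thresh,
                       input_size = d[1]))
      fw <- model_forward(model, batch, training = TRUE)
      model <- fw$model
      loss <- compute_loss(fw$preds, asg, spec,
                           box_gain = config$box_gain,
                           cls_gain = config$cls_gain,
                           obj_gain = config$obj_gain, grad = TRUE)
      if (!is.finite(loss$total))
        stop(sprintf("training diverged at epoch %d (loss %s); reduce lr",
                     epoch, format(loss$total)), call. = FALSE)
      grads <- model_backward(model, fw, loss$dpreds)
      st <- sgd_step(model, grads, velocity, lr, config$momentum,
                     config$weight_decay)
      model <- st$model
      velocity <- st$velocity
      ep_loss <- ep_loss + c(loss$loss_box, loss$loss_class,
                             loss$loss_object, loss$total)
      n_batches <- n_batches + 1L
    }
    ep_loss <- ep_loss / n_batches
    ev <- evaluate_detector(model, val_data, conf_thresh = config$eval_conf)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr,
      loss_box = ep_loss[1], loss_class = ep_loss[2],
      loss_object = ep_loss[3], loss_total = ep_loss[4],
      precision = ev$precision, recall = ev$recall, map = ev$map))
    if (is.finite(ev$map) && ev$map > best$map)
      best <- list(map = ev$map, model = model, epoch = epoch)
    if (!is.null(config$target_map) && is.finite(ev$map) &&
        ev$map >= config$target_map) break
  }
  rownames(history) <- NULL
  fit <- list(model = best$model, last_model = model, history = history,
              best_epoch = best$epoch, best_map = best$map, config = config,
              spec = spec, class_names = spec$class_names)
  class(fit) <- "pest_fit"
  fit
}

## ---- S3 interface ---------------------------------------------------------

#' @export
print.pest_fit <- function(x, ...) {
  cat(sprintf("<pest_fit> %d epoch(s), best val mAP@0.5 %.3f at epoch %d\n",
              nrow(x$history), x$best_map, x$best_epoch))
  print(x$spec)
  invisible(x)
}

#' @export
summary.pest_fit <- function(object, ...) {
  h <- object$history
  cat(sprintf("Training summary: %d epochs, final loss %.4f (box %.4f, class %.4f, object %.4f)\n",
              nrow(h), tail(h$loss_total, 1), tail(h$loss_box, 1),
              tail(h$loss_class, 1), tail(h$loss_object, 1)))
  cat(sprintf("Best validation mAP@0.5: %.3f (epoch %d); final P %.3f R %.3f\n",
              object$best_map, object$best_epoch,
              tail(h$precision, 1), tail(h$recall, 1)))
  invisible(object)
}

#' @export
plot.pest_fit <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$epoch, h$loss_total, type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss", ...)
  lines(h$epoch, h$loss_box, lty = 2)
  lines(h$epoch, h$loss_object, lty = 3)
  legend("topright", c("total", "box", "object"), lty = 1:3, bty = "n")
  plot(h$epoch, h$map, type = "l", xlab = "epoch", ylab = "score",
       ylim = c(0, 1), main = "validation metrics", ...)
  lines(h$epoch, h$precision, lty = 2)
  lines(h$epoch, h$recall, lty = 3)
  legend("bottomright", c("mAP@0.5", "precision", "recall"),
         lty = 1:3, bty = "n")
  invisible(x)
}

#' @export
coef.pest_fit <- function(object, ...) {
  trees <- lapply(object$model$nodes, node_param_tree)
  names(trees) <- paste0("layer", seq_along(trees))
  trees[!vapply(trees, is.null, logical(1))]
}

#' Detect pests in images
#'
#' Letterboxes each image to the model's input size, runs the network,
#' decodes and applies class-wise NMS, and maps boxes back to the original
#' pixel frame.
#'
#' @param object A `pest_fit` or `pest_model`.
#' @param images One image array or a list of them.
#' @param conf_thresh Confidence threshold (default 0.25).
#' @param nms_iou NMS IoU threshold (default 0.45).
#' @param ... Unused.
#' @return A list of per-image detection data frames with a `class` name
#'   column (a single data frame for a single image input).
#' @export
predict.pest_fit <- function(object, images, conf_thresh = 0.25,
                             nms_iou = 0.45, ...) {
  predict.pest_model(object$model, images, conf_thresh, nms_iou, ...)
}

#' @rdname predict.pest_fit
#' @export
predict.pest_model <- function(object, images, conf_thresh = 0.25,
                               nms_iou = 0.45, ...) {
  single <- !is.list(images)
  if (single) images <- list(images)
  spec <- object$spec
  out <- lapply(images, function(img) {
    img <- as_rgb_array(img)
    lb <- letterbox(img, spec$input_size)
    fw <- model_forward(object, lb$image, training = FALSE)
    dd <- nms(decode(fw$preds, spec, conf_thresh), nms_iou)
    dd <- box_from_letterbox(dd, lb$transform)
    dd$class <- spec$class_names[dd$class_id + 1L]
    dd$image <- NULL
    dd
  })
  if (single) out[[1]] else out
}
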