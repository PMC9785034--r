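# YOLO-format label IO, dataset splitting and letterboxing.
#
# A set of normalized boxes is a data frame with columns `class_id` (0-based
# integer), `cx`, `cy` (center as a fraction of image width/height in [0,1])
# and `w`, `h` (size fractions in (0,1]). Label files carry one
# "class cx cy w h" row per object.

#' Construct and validate a set of normalized boxes
#'
#' @param class_id Integer vector of 0-based class ids.
#' @param cx,cy,w,h Numeric vectors: box center and size as fractions of the
#'   image side.
#' @param K Class count; `class_id` must be in `[0, K)`.
#' @return A validated data frame of class `norm_boxes`.
#' @export
norm_boxes <- function(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                       w = numeric(0), h = numeric(0), K = 5L) {
  df <- data.frame(class_id = as.integer(class_id), cx = cx, cy = cy,
                   w = w, h = h)
  validate_norm_boxes(df, K)
}

#' @rdname norm_boxes
#' @param boxes A data frame with the `norm_boxes` columns.
#' @export
validate_norm_boxes <- function(boxes, K = 5L) {
  stop_if_not(all(c("class_id", "cx", "cy", "w", "h") %in% names(boxes)),
              "boxes need columns class_id, cx, cy, w, h")
  with(boxes, {
    stop_if_not(all(is.finite(cx)) && all(is.finite(cy)) &&
                  all(is.finite(w)) && all(is.finite(h)),
                "non-finite box coordinates")
    stop_if_not(all(class_id >= 0L & class_id < K),
                "class_id out of range [0, %d)", K)
    stop_if_not(all(cx >= 0 & cx <= 1 & cy >= 0 & cy <= 1),
                "box centers must lie in [0, 1]")
    stop_if_not(all(w > 0 & w <= 1 & h > 0 & h <= 1),
                "box sizes must lie in (0, 1]")
  })
  class(boxes) <- unique(c("norm_boxes", class(boxes)))
  boxes
}

#' Read YOLO-format labels
#'
#' @param text Label-file contents as a single string (or character vector of
#'   lines), or a path to an existing file.
#' @param K Class count used for validation.
#' @return A `norm_boxes` data frame, one row per nonblank input line, order
#'   preserved.
#' @export
read_yolo_labels <- function(text, K = 5L) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rows <- lapply(seq_along(lines), function(i) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) return(NULL)
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 5L || anyNA(v))
      stop(sprintf("malformed label line %d: '%s'", i, lines[i]), call. = FALSE)
    v
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(norm_boxes(K = K))
  m <- do.call(rbind, rows)
  norm_boxes(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], K = K)
}

#' Write YOLO-format labels
#'
#' Boxes whose corners would fall outside the image after denormalization are
#' clamped to the unit square before writing. Numeric fields use 6-decimal
#' fixed formatting, so `read_yolo_labels(write_yolo_labels(b))` reproduces
#' `b` to 1e-6.
#'
#' @param boxes A `norm_boxes` data frame.
#' @param path Optional path; when given the text is also written to disk.
#' @return The label-file contents, invisibly when `path` is given.
#' @export
write_yolo_labels <- function(boxes, path = NULL) {
  boxes <- validate_norm_boxes(boxes, K = max(c(boxes$class_id, 0L)) + 1L)
  if (nrow(boxes)) {
    x1 <- pmax(boxes$cx - boxes$w / 2, 0); x2 <- pmin(boxes$cx + boxes$w / 2, 1)
    y1 <- pmax(boxes$cy - boxes$h / 2, 0); y2 <- pmin(boxes$cy + boxes$h / 2, 1)
    txt <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id,
                   (x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
    out <- paste(txt, collapse = "\n")
  } else out <- ""
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Split identifiers into train/validation/test sets
#'
#' Identifiers are sorted, shuffled under `seed`, and allocated
#' `floor(f_train * N)` to train, `floor(f_val * N)` to validation and the
#' remainder to test — deterministic in the identifier *set*, regardless of
#' input order.
#'
#' @param ids Character (or coercible) vector of unique identifiers, N >= 3.
#' @param fractions Numeric triple summing to 1; default `c(0.7, 0.2, 0.1)`.
#' @param seed Integer shuffle seed.
#' @param stratify Optional factor of the same length as `ids`; when given,
#'   the floor rule is applied within each level.
#' @return `list(train, val, test)` of disjoint identifier vectors.
#' @export
split_dataset <- function(ids, fractions = c(0.7, 0.2, 0.1), seed = 0L,
                          stratify = NULL) {
  ids <- as.character(ids)
  stop_if_not(!anyDuplicated(ids), "identifiers must be unique")
  n <- length(ids)
  stop_if_not(n >= 3L, "need at least 3 identifiers to split")
  stop_if_not(length(fractions) == 3L && abs(sum(fractions) - 1) < 1e-9,
              "fractions must be a length-3 vector summing to 1")
  if (!is.null(stratify)) {
    stop_if_not(length(stratify) == n, "stratify must match ids in length")
    o <- order(ids)
    parts <- split(ids[o], as.factor(stratify)[o])
    sub <- lapply(seq_along(parts), function(i)
      split_one(parts[[i]], fractions, seed + i - 1L, allow_empty_test = TRUE))
    out <- list(train = unlist(lapply(sub, `[[`, "train"), use.names = FALSE),
                val = unlist(lapply(sub, `[[`, "val"), use.names = FALSE),
                test = unlist(lapply(sub, `[[`, "test"), use.names = FALSE))
    stop_if_not(length(out$test) > 0L, "test split is empty; too few ids")
    return(out)
  }
  split_one(ids, fractions, seed, allow_empty_test = FALSE)
}

split_one <- function(ids, fractions, seed, allow_empty_test) {
  n <- length(ids)
  perm <- with_seed(seed, sample(sort(ids)))
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (!allow_empty_test)
    stop_if_not(n_test > 0L, "test split would be empty for N = %d", n)
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = if (n_test > 0L) perm[n_train + n_val + seq_len(n_test)]
              else character(0))
}

#' Letterbox an image to a square working size
#'
#' Rescales with preserved aspect ratio (bilinear) and pads with neutral gray
#' to `target` x `target`. The returned transform maps pixel-space boxes
#' between the original and letterboxed frames bijectively on the image
#' region.
#'
#' @param image H x W x 3 array in `[0, 1]` (grayscale is promoted).
#' @param target Output side, default 512.
#' @param fill Padding value, default 0.5.
#' @return `list(image, transform)`; the transform holds `scale`, `pad_x`,
#'   `pad_y` and the original size.
#' @export
letterbox <- function(image, target = 512L, fill = 0.5) {
  image <- as_rgb_array(image)
  d <- dim(image)
  stop_if_not(d[1] > 0L && d[2] > 0L, "empty image")
  scale <- min(target / d[1], target / d[2])
  nh <- max(1L, as.integer(round(d[1] * scale)))
  nw <- max(1L, as.integer(round(d[2] * scale)))
  resized <- if (nh == d[1] && nw == d[2]) image else
    cpp_resize_bilinear(image, dim(image), nh, nw)
  pad_y <- (target - nh) %/% 2L
  pad_x <- (target - nw) %/% 2L
  out <- array(fill, dim = c(target, target, 3L))
  out[pad_y + seq_len(nh), pad_x + seq_len(nw), ] <- resized
  tf <- list(scale = scale, pad_x = pad_x, pad_y = pad_y,
             orig_h = d[1], orig_w = d[2], target = as.integer(target))
  class(tf) <- "letterbox_transform"
  list(image = out, transform = tf)
}

#' Map pixel boxes into / out of the letterboxed frame
#'
#' @param boxes Data frame or matrix with columns x1, y1, x2, y2 in pixel
#'   coordinates.
#' @param transform A `letterbox_transform` from [letterbox()].
#' @return Boxes in the other frame (same shape).
#' @export
box_to_letterbox <- function(boxes, transform) {
  b <- boxes
  b[, c("x1", "x2")] <- boxes[, c("x1", "x2")] * transform$scale + transform$pad_x
  b[, c("y1", "y2")] <- boxes[, c("y1", "y2")] * transform$scale + transform$pad_y
  b
}

#' @rdname box_to_letterbox
#' @export
box_from_letterbox <- function(boxes, transform) {
  b <- boxes
  b[, c("x1", "x2")] <- (boxes[, c("x1", "x2")] - transform$pad_x) / transform$scale
  b[, c("y1", "y2")] <- (boxes[, c("y1", "y2")] - transform$pad_y) / transform$scale
  b
}

#' Convert between normalized center-size boxes and pixel xyxy boxes
#'
#' @param boxes `norm_boxes` data frame (for `norm_to_xyxy`) or a data frame
#'   with x1..y2 pixel columns (for `xyxy_to_norm`).
#' @param width,height Image size in pixels.
#' @return The converted data frame (class ids preserved).
#' @export
norm_to_xyxy <- function(boxes, width, height) {
  data.frame(class_id = boxes$class_id,
             x1 = (boxes$cx - boxes$w / 2) * width,
             y1 = (boxes$cy - boxes$h / 2) * height,
             x2 = (boxes$cx + boxes$w / 2) * width,
             y2 = (boxes$cy + boxes$h / 2) * height)
}

#' @rdname norm_to_xyxy
#' @export
xyxy_to_norm <- function(boxes, width, height) {
  norm_boxes(boxes$class_id,
             (boxes$x1 + boxes$x2) / 2 / width,
             (boxes$y1 + boxes$y2) / 2 / height,
             (boxes$x2 - boxes$x1) / width,
             (boxes$y2 - boxes$y1) / height,
             K = max(c(boxes$class_id, 0L)) + 1L)
}

#' Read and write PNG images as arrays
#'
#' @param path File path. Writing rounds to 8-bit depth.
#' @return `read_image`: an H x W x 3 array in `[0, 1]`.
#' @export
read_image <- function(path) {
  as_rgb_array(png::readPNG(path))
}

#' @rdname read_image
#' @param image H x W x 3 array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp(as_rgb_array(image), 0, 1), path)
  invisible(path)
}

#' Read a dataset configuration file
#'
#' Parses the `data.yaml` written by [build_dataset()] (class names, class
#' count, image/label locations).
#'
#' @param path Path to the YAML file.
#' @return A named list with at least `names` and `nc`.
#' @export
read_dataset_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stop_if_not(!is.null(cfg$names), "dataset config lacks class names")
  cfg$names <- unlist(cfg$names)
  cfg$nc <- cfg$nc %||% length(cfg$names)
  cfg
}
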