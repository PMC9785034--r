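# Synthetic pest scenes.
#
# Each of the five classes is drawn as a parametric glyph with a
# class-distinctive body plan (aspect ratio, appendage count, hue family)
# over a procedurally textured background whose hue is drawn from the same
# earth-tone families, so objects are deliberately low-contrast. Distractor
# blobs (clutter) reuse the object hue families without being labeled. The
# emitted normalized box is the tight bounding box of the glyph's rendered
# support, so labels agree with the foreground mask by construction.

#' Scene generator configuration
#'
#' @param image_size Square canvas side in pixels (default 512).
#' @param class_names Class glyph families; the five pest classes by default.
#' @param objects_per_image Integer range `c(min, max)` of objects per scene.
#' @param object_size_fraction Range of glyph body length as a fraction of
#'   the image side; sampling is biased toward the small end (see
#'   `size_bias`).
#' @param size_bias Exponent > 1 biases sampled sizes toward the minimum;
#'   the default 2 keeps most objects in the small-object regime.
#' @param clutter_level In `[0, 1]`; scales the number of unlabeled
#'   background distractors sharing the object hue families.
#' @param texture_level Scales the background texture amplitude (smooth
#'   illumination field and high-frequency speckle); 1 is the full-texture
#'   default, 0 a flat background.
#' @param mixed_classes If TRUE, objects after the first may come from any
#'   class; by default every object in a scene is the primary class.
#' @param seed Base seed; image i of a dataset uses child seed `seed + i`.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = 512L,
                         class_names = PEST_CLASSES,
                         objects_per_image = c(1L, 4L),
                         object_size_fraction = c(0.04, 0.25),
                         size_bias = 2,
                         clutter_level = 0.5,
                         texture_level = 1,
                         mixed_classes = FALSE,
                         seed = 0L) {
  stop_if_not(image_size >= 32L, "image_size too small")
  stop_if_not(length(objects_per_image) == 2L &&
                objects_per_image[1] <= objects_per_image[2] &&
                objects_per_image[1] >= 0L,
              "objects_per_image must be an ordered nonnegative range")
  stop_if_not(length(object_size_fraction) == 2L &&
                0 < object_size_fraction[1] &&
                object_size_fraction[1] <= object_size_fraction[2] &&
                object_size_fraction[2] <= 1,
              "object_size_fraction must be an ordered range in (0, 1]")
  stop_if_not(clutter_level >= 0 && clutter_level <= 1,
              "clutter_level must be in [0, 1]")
  stop_if_not(texture_level >= 0, "texture_level must be nonnegative")
  cfg <- list(image_size = as.integer(image_size), class_names = class_names,
              objects_per_image = as.integer(objects_per_image),
              object_size_fraction = object_size_fraction,
              size_bias = size_bias, clutter_level = clutter_level,
              texture_level = texture_level,
              mixed_classes = isTRUE(mixed_classes), seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

## ---- drawing primitives ---------------------------------------------------

# All primitives return an S x S logical mask. `rr`/`cc` are row/col grids.
.ellipse_mask <- function(rr, cc, r0, c0, a, b, theta) {
  dx <- cc - c0; dy <- rr - r0
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

.segment_mask <- function(rr, cc, r1, c1, r2, c2, thick) {
  vx <- c2 - c1; vy <- r2 - r1
  len2 <- vx^2 + vy^2
  if (len2 < 1e-12) return(.ellipse_mask(rr, cc, r1, c1, thick, thick, 0))
  t <- clamp(((cc - c1) * vx + (rr - r1) * vy) / len2, 0, 1)
  px <- c1 + t * vx; py <- r1 + t * vy
  (cc - px)^2 + (rr - py)^2 <= (thick / 2)^2
}

.hsv_col <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h %% 1, clamp(s, 0, 1),
                                               clamp(v, 0, 1)))) / 255
}

# class hue families (earth tones shared with the background texture)
.CLASS_HUES <- list(ants = 0.05, grasshopper = 0.30, palm_weevil = 0.02,
                    shield_bug = 0.09, wasps = 0.13)

# Body-plan glyphs. Each returns a list of primitives (mask + rgb color),
# drawn in order; the object mask is the union of all primitive supports.
# `s` is the body length in pixels, theta the body-axis orientation.
.glyph <- function(class_name, rr, cc, r0, c0, s, theta) {
  hue <- .CLASS_HUES[[class_name]] %||% runif(1)
  pt <- function(dx, dy) c(r0 + dx * sin(theta) + dy * cos(theta),
                           c0 + dx * cos(theta) - dy * sin(theta))
  ell <- function(dx, dy, a, b, col, rel = 0)
    { p <- pt(dx, dy); list(mask = .ellipse_mask(rr, cc, p[1], p[2], a, b,
                                                 theta + rel), col = col) }
  seg <- function(d1, e1, d2, e2, thick, col) {
    p <- pt(d1, e1); q <- pt(d2, e2)
    list(mask = .segment_mask(rr, cc, p[1], p[2], q[1], q[2], thick), col = col)
  }
  th <- max(1.2, 0.035 * s) # appendage thickness
  prims <- switch(class_name,
    ants = {
      body <- .hsv_col(hue + runif(1, -0.02, 0.02), 0.7, 0.25)
      dark <- .hsv_col(hue, 0.75, 0.16)
      legs <- lapply(c(-1, 1), function(sd) lapply(c(-0.12, 0, 0.12), function(dx)
        seg(dx, sd * 0.05 * s, dx + 0.08 * s * sign(dx + 0.01), sd * 0.22 * s,
            th, dark)))
      c(unlist(legs, recursive = FALSE),
        list(ell(-0.30 * s, 0, 0.20 * s, 0.12 * s, body),
             ell(0, 0, 0.12 * s, 0.08 * s, body),
             ell(0.24 * s, 0, 0.11 * s, 0.09 * s, dark),
             seg(0.30 * s, 0.03 * s, 0.45 * s, 0.10 * s, th * 0.8, dark),
             seg(0.30 * s, -0.03 * s, 0.45 * s, -0.10 * s, th * 0.8, dark)))
    },
    grasshopper = {
      body <- .hsv_col(hue + runif(1, -0.03, 0.03), 0.6, 0.45)
      dark <- .hsv_col(hue, 0.65, 0.3)
      c(list(ell(0, 0, 0.42 * s, 0.10 * s, body),
             ell(0.40 * s, 0, 0.09 * s, 0.07 * s, dark),
             seg(0.44 * s, 0.02 * s, 0.55 * s, 0.06 * s, th * 0.7, dark),
             seg(0.44 * s, -0.02 * s, 0.55 * s, -0.06 * s, th * 0.7, dark)),
        lapply(c(-1, 1), function(sd)
          seg(-0.10 * s, sd * 0.08 * s, -0.30 * s, sd * 0.26 * s,
              th * 1.4, dark)),
        lapply(c(-1, 1), function(sd)
          seg(-0.30 * s, sd * 0.26 * s, -0.44 * s, sd * 0.10 * s, th, dark)))
    },
    palm_weevil = {
      body <- .hsv_col(hue + runif(1, -0.015, 0.015), 0.8, 0.28)
      dark <- .hsv_col(hue, 0.85, 0.18)
      list(ell(-0.05 * s, 0, 0.32 * s, 0.18 * s, body),
           ell(0.28 * s, 0, 0.10 * s, 0.09 * s, dark),
           seg(0.34 * s, 0, 0.50 * s, -0.05 * s, th * 1.1, dark),
           ell(-0.05 * s, 0, 0.26 * s, 0.10 * s, dark))
    },
    shield_bug = {
      body <- .hsv_col(hue + runif(1, -0.03, 0.03), 0.55, 0.38)
      dark <- .hsv_col(hue, 0.6, 0.26)
      c(lapply(c(-1, 1), function(sd) lapply(c(-0.15, 0, 0.15), function(dx)
          seg(dx * s, sd * 0.12 * s, dx * s + 0.05 * s, sd * 0.30 * s,
              th * 0.9, dark))) |> unlist(recursive = FALSE),
        list(ell(0, 0, 0.30 * s, 0.26 * s, body),
             ell(-0.12 * s, 0, 0.18 * s, 0.20 * s, dark),
             ell(0.28 * s, 0, 0.08 * s, 0.07 * s, dark)))
    },
    wasps = {
      body <- .hsv_col(hue + runif(1, -0.01, 0.01), 0.9, 0.7)
      dark <- .hsv_col(0.10, 0.6, 0.08)
      wing <- .hsv_col(0.55, 0.05, 0.75)
      list(ell(0.02 * s, 0.12 * s, 0.18 * s, 0.06 * s, wing, rel = 0.6),
           ell(0.02 * s, -0.12 * s, 0.18 * s, 0.06 * s, wing, rel = -0.6),
           ell(-0.22 * s, 0, 0.24 * s, 0.11 * s, body),
           ell(-0.18 * s, 0, 0.025 * s, 0.11 * s, dark),
           ell(-0.32 * s, 0, 0.025 * s, 0.10 * s, dark),
           ell(0.08 * s, 0, 0.13 * s, 0.10 * s, dark),
           ell(0.28 * s, 0, 0.08 * s, 0.07 * s, dark))
    },
    # unknown class names get a generic oval so user-supplied lists work
    list(ell(0, 0, 0.35 * s, 0.2 * s, .hsv_col(hue, 0.6, 0.4)))
  )
  prims
}

.render_background <- function(S, rr, cc, clutter, class_names,
                               texture = 1) {
  hue <- runif(1, 0.02, 0.33) # same earth-tone band as the glyph families
  base <- .hsv_col(hue, runif(1, 0.25, 0.5), runif(1, 0.35, 0.6))
  img <- array(0, dim = c(S, S, 3L))
  # low-frequency illumination + high-frequency speckle, shared across channels
  lowf <- matrix(0, S, S)
  for (i in 1:3) {
    fx <- runif(1, 0.5, 3); fy <- runif(1, 0.5, 3); ph <- runif(1, 0, 2 * pi)
    lowf <- lowf + sin(2 * pi * (fx * cc + fy * rr) / S + ph) / 3
  }
  speck <- matrix(rnorm(S * S, sd = 0.045 * texture), S, S)
  for (ch in 1:3)
    img[, , ch] <- clamp(base[ch] * (1 + 0.18 * texture * lowf) + speck, 0, 1)
  n_d <- round(clutter * 10)
  for (i in seq_len(n_d)) { # unlabeled distractors in the object hue family
    dh <- .CLASS_HUES[[sample(class_names, 1)]] %||% hue
    col <- .hsv_col(dh + runif(1, -0.02, 0.02), runif(1, 0.4, 0.7),
                    runif(1, 0.25, 0.55))
    a <- runif(1, 1.5, max(2.5, 0.03 * S)); b <- a * runif(1, 0.3, 1)
    m <- .ellipse_mask(rr, cc, runif(1, 1, S), runif(1, 1, S), a, b,
                       runif(1, 0, pi))
    w <- runif(1, 0.35, 0.7) # low-contrast blend
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[m] <- (1 - w) * pl[m] + w * col[ch]
      img[, , ch] <- pl
    }
  }
  img
}

#' Render one labeled synthetic scene
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; identical `(config, seed)` pairs give
#'   byte-identical output.
#' @param primary_class Class name of the scene's primary object (defaults to
#'   a seeded random choice).
#' @return A list with `image` (S x S x 3 array in `[0, 1]`, 8-bit
#'   quantized), `boxes` (a `norm_boxes` data frame), `masks` (one logical
#'   foreground mask per box) and `seed`.
#' @export
render_scene <- function(config = scene_config(), seed = config$seed,
                         primary_class = NULL) {
  S <- config$image_size
  K <- length(config$class_names)
  with_seed(seed, {
    tmpl <- matrix(0, S, S)
    rr <- row(tmpl); cc <- col(tmpl)
    primary_class <- primary_class %||% sample(config$class_names, 1)
    stop_if_not(primary_class %in% config$class_names,
                "unknown class name '%s'", primary_class)
    img <- .render_background(S, rr, cc, config$clutter_level,
                              config$class_names,
                              config$texture_level %||% 1)
    n_obj <- if (config$objects_per_image[1] == config$objects_per_image[2])
      config$objects_per_image[1] else
      sample(config$objects_per_image[1]:config$objects_per_image[2], 1)
    boxes <- NULL
    masks <- list()
    for (oi in seq_len(n_obj)) {
      cls <- if (oi == 1L || !config$mixed_classes) primary_class else
        sample(config$class_names, 1)
      f <- config$object_size_fraction
      frac <- f[1] * (f[2] / f[1])^(runif(1)^config$size_bias)
      s <- frac * S
      placed <- FALSE
      for (attempt in seq_len(100L)) {
        theta <- runif(1, 0, 2 * pi)
        margin <- 0.62 * s + 2
        if (2 * margin >= S) break
        r0 <- runif(1, margin, S - margin)
        c0 <- runif(1, margin, S - margin)
        prims <- .glyph(cls, rr, cc, r0, c0, s, theta)
        m <- Reduce(`|`, lapply(prims, `[[`, "mask"))
        rows <- range(which(rowSums(m) > 0))
        cols <- range(which(colSums(m) > 0))
        if (rows[1] < 1 || cols[1] < 1 || rows[2] > S || cols[2] > S ||
            !any(m)) next
        for (p in prims) {
          shade <- runif(1, 0.92, 1.08)
          for (ch in 1:3) {
            pl <- img[, , ch]
            pl[p$mask] <- clamp(p$col[ch] * shade, 0, 1)
            img[, , ch] <- pl
          }
        }
        # tight bbox of the rendered support; pixel i spans [i-1, i]
        bx <- data.frame(class_id = match(cls, config$class_names) - 1L,
                         x1 = cols[1] - 1, y1 = rows[1] - 1,
                         x2 = cols[2], y2 = rows[2])
        boxes <- rbind(boxes, bx)
        masks[[length(masks) + 1L]] <- m
        placed <- TRUE
        break
      }
      if (!placed && n_obj > 0L)
        message(sprintf("scene seed %d: object %d could not be placed, skipped",
                        seed, oi))
    }
    img <- round(img * 255) / 255 # 8-bit quantization, matches PNG round-trip
    boxes <- if (is.null(boxes)) norm_boxes(K = K) else
      xyxy_to_norm(boxes, S, S)
    boxes <- validate_norm_boxes(boxes, K = K)
    list(image = img, boxes = boxes, masks = masks, seed = seed,
         primary_class = primary_class)
  })
}

#' Per-class image counts of the emulated five-class pest collection
#'
#' The per-class image counts this generator emulates by default:
#' 392 ants, 315 grasshopper, 148 palm_weevil, 392 shield_bug and 318 wasps
#' images (1565 in total).
#'
#' @return Named integer vector of images per class.
#' @export
default_class_counts <- function() {
  c(ants = 392L, grasshopper = 315L, palm_weevil = 148L,
    shield_bug = 392L, wasps = 318L)
}

#' Generate a synthetic dataset in YOLO layout
#'
#' Writes `images/<id>.png` and `labels/<id>.txt` pairs plus a
#' `manifest.json` (seeds, counts, config) and a `data.yaml` dataset config.
#' Image i uses child seed `config$seed + i`, so datasets are reproducible
#' and extendable. Each image's primary object belongs to its bookkeeping
#' class; with `mixed_classes = TRUE` additional objects may differ.
#'
#' @param per_class_counts Named vector: images per class (names must be in
#'   `config$class_names`). Defaults to [default_class_counts()].
#' @param config A [scene_config()].
#' @param dir Output directory.
#' @return A `synthetic_dataset` list: `dir`, `ids`, `counts`, `manifest`.
#' @export
build_dataset <- function(per_class_counts = default_class_counts(),
                          config = scene_config(), dir) {
  stop_if_not(!is.null(names(per_class_counts)) &&
                all(nzchar(names(per_class_counts))),
              "per_class_counts must be named by class")
  unknown <- setdiff(names(per_class_counts), config$class_names)
  stop_if_not(length(unknown) == 0L, "unknown class name(s): %s",
              paste(unknown, collapse = ", "))
  stop_if_not(all(per_class_counts >= 0L), "counts must be nonnegative")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  ids <- character(0)
  counter <- 0L
  for (cls in names(per_class_counts)) {
    for (i in seq_len(per_class_counts[[cls]])) {
      counter <- counter + 1L
      id <- sprintf("%s_%05d", cls, i)
      sc <- render_scene(config, seed = config$seed + counter,
                         primary_class = cls)
      write_image(sc$image, file.path(dir, "images", paste0(id, ".png")))
      write_yolo_labels(sc$boxes, file.path(dir, "labels", paste0(id, ".txt")))
      ids <- c(ids, id)
    }
  }
  manifest <- list(base_seed = config$seed, n_images = counter,
                   child_seeds = if (counter) config$seed + seq_len(counter)
                                 else integer(0),
                   counts = as.list(per_class_counts),
                   class_names = config$class_names,
                   image_size = config$image_size)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  yaml::write_yaml(list(path = normalizePath(dir),
                        train = "images", val = "images",
                        nc = length(config$class_names),
                        names = as.list(config$class_names)),
                   file.path(dir, "data.yaml"))
  out <- list(dir = dir, ids = ids,
              counts = per_class_counts, manifest = manifest,
              class_names = config$class_names)
  class(out) <- "synthetic_dataset"
  out
}

#' Load a YOLO-layout dataset into memory
#'
#' @param dir Directory containing `images/` and `labels/` subdirectories.
#' @param ids Optional identifier subset; defaults to every image present.
#' @param K Class count for label validation.
#' @return List with `images` (arrays), `boxes` (`norm_boxes` per image) and
#'   `ids`.
#' @export
load_yolo_dataset <- function(dir, ids = NULL, K = 5L) {
  files <- list.files(file.path(dir, "images"), pattern = "\\.png$")
  all_ids <- sub("\\.png$", "", files)
  ids <- ids %||% all_ids
  stop_if_not(all(ids %in% all_ids), "missing images for some identifiers")
  images <- lapply(ids, function(id)
    read_image(file.path(dir, "images", paste0(id, ".png"))))
  boxes <- lapply(ids, function(id) {
    p <- file.path(dir, "labels", paste0(id, ".txt"))
    if (file.exists(p)) read_yolo_labels(p, K = K) else norm_boxes(K = K)
  })
  list(images = images, boxes = boxes, ids = ids)
}
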