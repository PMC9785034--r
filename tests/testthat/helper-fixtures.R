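# Shared fixtures, built in code. Heavy objects are cached per test run.

.fixtures <- new.env(parent = emptyenv())

# A small four-scale spec (input 64) with narrow widths for fast forward
# and backward passes in unit tests.
tiny_spec <- function(num_classes = 3L, widths = c(4L, 4L, 8L, 8L, 16L)) {
  model_spec("proposed", input_size = 64L, widths = widths,
             num_classes = num_classes,
             class_names = paste0("c", seq_len(num_classes) - 1L))
}

tiny_model <- function(seed = 1L, ...) {
  key <- paste0("model_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_model(tiny_spec(...), seed = seed)
  .fixtures[[key]]
}

# Random normalized boxes for round-trip and assignment properties.
random_norm_boxes <- function(n, K = 5L) {
  w <- runif(n, 0.02, 0.5)
  h <- runif(n, 0.02, 0.5)
  norm_boxes(sample(0:(K - 1L), n, replace = TRUE),
             cx = runif(n, w / 2, 1 - w / 2),
             cy = runif(n, h / 2, 1 - h / 2),
             w = w, h = h, K = K)
}

# Random detection / ground-truth frames for matching and NMS oracles.
random_dets <- function(n, K = 3L, size = 100) {
  x1 <- runif(n, 0, size * 0.8); y1 <- runif(n, 0, size * 0.8)
  data.frame(class_id = sample(0:(K - 1L), n, replace = TRUE),
             score = runif(n),
             x1 = x1, y1 = y1,
             x2 = x1 + runif(n, 2, size * 0.3),
             y2 = y1 + runif(n, 2, size * 0.3))
}

# The 20-image single-object training fixture shared by the training tests
# and the convergence acceptance check (64 px scenes, one glyph each).
overfit_fixture <- function() {
  if (is.null(.fixtures$overfit)) {
    dir <- file.path(tempdir(), "pestdetect-overfit")
    if (!dir.exists(file.path(dir, "images"))) {
      cfg <- scene_config(image_size = 64L, objects_per_image = c(1L, 1L),
                          object_size_fraction = c(0.35, 0.60),
                          size_bias = 1, clutter_level = 0, seed = 1L)
      counts <- c(ants = 4L, grasshopper = 4L, palm_weevil = 4L,
                  shield_bug = 4L, wasps = 4L)
      build_dataset(counts, cfg, dir)
    }
    .fixtures$overfit <- load_yolo_dataset(dir)
  }
  .fixtures$overfit
}
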