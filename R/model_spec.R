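# Architecture specification.
#
# Two variants are described as static layer graphs:
#
# * "baseline": the unmodified small one-stage detector (CSP backbone,
#   SPP, PANet neck, three heads at strides 8/16/32).
# * "proposed": the extended model — the shallow stage stacks the
#   convolution + CSP pair three times after the focus stem, every backbone
#   CSP block carries a selective-kernel attention layer, the neck upsamples
#   one extra step to stride 4, and a fourth head detects on the
#   high-resolution grid (strides 4/8/16/32).
#
# Channel widths are the usual 64/128/256/512/1024 progression scaled by
# `width_mult`; CSP repeat counts are 3/9/9/3 scaled by `depth_mult`. The
# default width multiplier is calibrated so that the analytic FLOP count of
# the proposed model at 512 x 512 input lands at 4.8 GFLOPs (MAC x 2); see
# the methods vignette.

PEST_CLASSES <- c("ants", "grasshopper", "palm_weevil", "shield_bug", "wasps")
DEFAULT_STAGE_WIDTHS <- c(16L, 30L, 56L, 112L, 224L) # calibrated; see vignette

DEFAULT_DEPTH_MULT <- 0.33

.row <- function(module, from = -1L, cout = NA_integer_, k = 1L, stride = 1L,
                 n = 1L, sk = FALSE, shortcut = TRUE) {
  list(module = module, from = as.integer(from), cout = cout, k = k,
       stride = stride, n = n, sk = sk, shortcut = shortcut)
}

#' Default anchor table
#'
#' Three pixel-space (w, h) anchors per detection scale, areas increasing
#' with stride. Used when no dataset-adapted anchors are supplied; see
#' [compute_anchors()] for the k-means adaptation.
#'
#' @param strides Integer vector of head strides.
#' @return List of 3 x 2 matrices, one per scale.
#' @export
default_anchors <- function(strides) {
  mults <- matrix(c(1.5, 2.0, 2.8, 2.2, 3.0, 4.5), ncol = 2, byrow = TRUE)
  lapply(strides, function(s) {
    m <- mults * s
    colnames(m) <- c("w", "h")
    m
  })
}

#' Build a detector architecture specification
#'
#' @param variant `"proposed"` (extended shallow CSP + SK attention + four
#'   heads) or `"baseline"` (unmodified small model, three heads).
#' @param num_classes Number of object classes K.
#' @param input_size Square input side in pixels; must be divisible by 32.
#' @param width_mult,depth_mult Channel-width and block-depth multipliers.
#' @param anchors Optional anchor list (3 x 2 matrix per scale) overriding
#'   [default_anchors()].
#' @param reduction Selective-kernel bottleneck reduction ratio.
#' @param class_names Optional class names (length `num_classes`).
#' @param widths Optional explicit stage channel widths (length 5, even
#'   integers); overrides `width_mult`. The default is the calibrated
#'   vector `DEFAULT_STAGE_WIDTHS`.
#' @return A `pest_model_spec` object: the resolved layer graph plus head
#'   strides and anchors.
#' @export
model_spec <- function(variant = c("proposed", "baseline"),
                       num_classes = 5L,
                       input_size = 512L,
                       width_mult = NULL,
                       depth_mult = DEFAULT_DEPTH_MULT,
                       anchors = NULL,
                       reduction = 16,
                       class_names = NULL,
                       widths = NULL) {
  variant <- match.arg(variant)
  input_size <- as.integer(input_size)
  num_classes <- as.integer(num_classes)
  stop_if_not(input_size %% 32L == 0L, "input_size must be divisible by 32")
  stop_if_not(num_classes >= 1L, "need at least one class")
  w <- if (!is.null(widths)) {
    stop_if_not(length(widths) == 5L && all(widths %% 2 == 0) && all(widths > 0),
                "widths must be 5 positive even integers")
    as.integer(widths)
  } else if (!is.null(width_mult)) {
    vapply(c(64, 128, 256, 512, 1024) * width_mult, make_divisible, integer(1))
  } else DEFAULT_STAGE_WIDTHS
  width_mult <- width_mult %||% mean(w / c(64, 128, 256, 512, 1024))
  dn <- function(base) max(1L, as.integer(round(base * depth_mult)))
  n1 <- dn(3); n3 <- dn(9)

  if (variant == "baseline") {
    rows <- list(
      .row("focus", 0L, w[1], k = 3L),              # 1  stride 2
      .row("conv", 1L, w[2], k = 3L, stride = 2L),  # 2  stride 4
      .row("csp", 2L, w[2], n = n1),                # 3
      .row("conv", 3L, w[3], k = 3L, stride = 2L),  # 4  stride 8
      .row("csp", 4L, w[3], n = n3),                # 5
      .row("conv", 5L, w[4], k = 3L, stride = 2L),  # 6  stride 16
      .row("csp", 6L, w[4], n = n3),                # 7
      .row("conv", 7L, w[5], k = 3L, stride = 2L),  # 8  stride 32
      .row("spp", 8L, w[5]),                        # 9
      .row("csp", 9L, w[5], n = n1),                # 10
      .row("conv", 10L, w[4], k = 1L),              # 11
      .row("upsample", 11L),                        # 12
      .row("concat", c(12L, 7L)),                   # 13
      .row("csp", 13L, w[4], n = n1, shortcut = FALSE), # 14
      .row("conv", 14L, w[3], k = 1L),              # 15
      .row("upsample", 15L),                        # 16
      .row("concat", c(16L, 5L)),                   # 17
      .row("csp", 17L, w[3], n = n1, shortcut = FALSE), # 18 P3
      .row("conv", 18L, w[3], k = 3L, stride = 2L), # 19
      .row("concat", c(19L, 15L)),                  # 20
      .row("csp", 20L, w[4], n = n1, shortcut = FALSE), # 21 P4
      .row("conv", 21L, w[4], k = 3L, stride = 2L), # 22
      .row("concat", c(22L, 11L)),                  # 23
      .row("csp", 23L, w[5], n = n1, shortcut = FALSE), # 24 P5
      .row("head", 18L), .row("head", 21L), .row("head", 24L)
    )
    head_from <- c(18L, 21L, 24L)
    strides <- c(8L, 16L, 32L)
  } else {
    rows <- list(
      .row("focus", 0L, w[1], k = 3L),              # 1  stride 2
      .row("conv", 1L, w[2], k = 3L, stride = 2L),  # 2  stride 4
      .row("csp", 2L, w[2], n = n1, sk = TRUE),     # 3
      .row("conv", 3L, w[2], k = 3L),               # 4  (shallow stack x2)
      .row("csp", 4L, w[2], n = n1, sk = TRUE),     # 5
      .row("conv", 5L, w[2], k = 3L),               # 6  (shallow stack x3)
      .row("csp", 6L, w[2], n = n1, sk = TRUE),     # 7  P2 feature, stride 4
      .row("conv", 7L, w[3], k = 3L, stride = 2L),  # 8  stride 8
      .row("csp", 8L, w[3], n = n3, sk = TRUE),     # 9
      .row("conv", 9L, w[4], k = 3L, stride = 2L),  # 10 stride 16
      .row("csp", 10L, w[4], n = n3, sk = TRUE),    # 11
      .row("conv", 11L, w[5], k = 3L, stride = 2L), # 12 stride 32
      .row("spp", 12L, w[5]),                       # 13
      .row("csp", 13L, w[5], n = n1, sk = TRUE),    # 14
      .row("conv", 14L, w[4], k = 1L),              # 15
      .row("upsample", 15L),                        # 16
      .row("concat", c(16L, 11L)),                  # 17
      .row("csp", 17L, w[4], n = n1, shortcut = FALSE), # 18
      .row("conv", 18L, w[3], k = 1L),              # 19
      .row("upsample", 19L),                        # 20
      .row("concat", c(20L, 9L)),                   # 21
      .row("csp", 21L, w[3], n = n1, shortcut = FALSE), # 22
      .row("conv", 22L, w[2], k = 1L),              # 23
      .row("upsample", 23L),                        # 24 -> stride 4
      .row("concat", c(24L, 7L)),                   # 25 fuse shallow feature
      .row("csp", 25L, w[2], n = n1, shortcut = FALSE), # 26 P2
      .row("conv", 26L, w[2], k = 3L, stride = 2L), # 27
      .row("concat", c(27L, 23L)),                  # 28
      .row("csp", 28L, w[3], n = n1, shortcut = FALSE), # 29 P3
      .row("conv", 29L, w[3], k = 3L, stride = 2L), # 30
      .row("concat", c(30L, 19L)),                  # 31
      .row("csp", 31L, w[4], n = n1, shortcut = FALSE), # 32 P4
      .row("conv", 32L, w[4], k = 3L, stride = 2L), # 33
      .row("concat", c(33L, 15L)),                  # 34
      .row("csp", 34L, w[5], n = n1, shortcut = FALSE), # 35 P5
      .row("head", 26L), .row("head", 29L), .row("head", 32L), .row("head", 35L)
    )
    head_from <- c(26L, 29L, 32L, 35L)
    strides <- c(4L, 8L, 16L, 32L)
  }

  rows <- .resolve_shapes(rows, input_size, num_classes)
  spec <- list(
    variant = variant, num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    width_mult = width_mult, depth_mult = depth_mult,
    widths = w, reduction = reduction,
    layers = rows, head_from = head_from, strides = strides,
    anchors = anchors %||% default_anchors(strides),
    class_names = class_names %||%
      (if (num_classes == 5L) PEST_CLASSES else paste0("class", seq_len(num_classes) - 1L))
  )
  stop_if_not(length(spec$anchors) == length(strides) &&
                all(vapply(spec$anchors, nrow, integer(1)) == 3L),
              "anchors must provide a 3 x 2 matrix per detection scale")
  class(spec) <- "pest_model_spec"
  spec
}

# Resolve per-row input channels, output channels and spatial stride.
.resolve_shapes <- function(rows, input_size, num_classes) {
  cs <- integer(length(rows)) # output channels per row
  ss <- integer(length(rows)) # cumulative stride per row
  chan_of <- function(i) if (i == 0L) 3L else cs[i]
  stride_of <- function(i) if (i == 0L) 1L else ss[i]
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    f <- r$from
    f[f < 0L] <- i - 1L
    r$from <- f
    cin <- sum(vapply(f, chan_of, integer(1)))
    st <- stride_of(f[1])
    r$cin <- cin
    if (r$module == "focus") {
      r$cin <- 4L * chan_of(f[1]); st <- st * 2L
    } else if (r$module == "conv") {
      st <- st * r$stride
    } else if (r$module == "upsample") {
      r$cout <- cin; st <- st %/% 2L
    } else if (r$module == "concat") {
      r$cout <- cin
    } else if (r$module == "head") {
      r$cout <- 3L * (5L + num_classes)
    }
    cs[i] <- r$cout
    ss[i] <- st
    r$out_stride <- st
    rows[[i]] <- r
  }
  rows
}

#' @export
print.pest_model_spec <- function(x, ...) {
  cat(sprintf("<pest_model_spec> variant=%s  input=%d  classes=%d\n",
              x$variant, x$input_size, x$num_classes))
  cat(sprintf("  width_mult=%.3f depth_mult=%.2f  widths: %s\n",
              x$width_mult, x$depth_mult, paste(x$widths, collapse = "/")))
  cat(sprintf("  %d graph rows, %d counted layers, heads at strides %s\n",
              length(x$layers), layer_count(x),
              paste(x$strides, collapse = "/")))
  invisible(x)
}
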