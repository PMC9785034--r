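`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round a channel width to a hardware-friendly multiple
#'
#' Channel widths produced by the width multiplier are rounded up to the
#' nearest multiple of `divisor` (never below `divisor` itself), the usual
#' convention when scaling convolutional widths.
#'
#' @param x Proposed (possibly fractional) channel count.
#' @param divisor Rounding granularity, default 4.
#' @return Integer channel count.
#' @keywords internal
make_divisible <- function(x, divisor = 2L) {
  max(divisor, as.integer(ceiling(x / divisor) * divisor))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}

# Ensure an image-like array is H x W x C with C = 3 (grayscale promoted).
as_rgb_array <- function(img) {
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  stop_if_not(length(dim(img)) == 3L && dim(img)[3] == 3L,
              "expected an H x W x 3 image array")
  img
}

# Add (or assert) a trailing batch dimension; returns list(x4, had_batch).
as_batched <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    list(x = x, batched = FALSE)
  } else if (length(d) == 4L) {
    list(x = x, batched = TRUE)
  } else stop("feature maps must be H x W x C or H x W x C x B arrays")
}
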