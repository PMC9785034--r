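#' Save and load detector checkpoints
#'
#' A checkpoint bundles the weights, the architecture spec and the anchor
#' table (and, for fits, the training history), serialized with `saveRDS`.
#'
#' @param object A `pest_model` or `pest_fit`.
#' @param path Destination file.
#' @return `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(object, path) {
  stop_if_not(inherits(object, "pest_model") || inherits(object, "pest_fit"),
              "can only checkpoint pest_model or pest_fit objects")
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stop_if_not(inherits(obj, "pest_model") || inherits(obj, "pest_fit"),
              "file does not contain a detector checkpoint")
  obj
}
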