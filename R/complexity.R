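# Architecture-level accounting: parameters, counted layers and FLOPs, all
# derived analytically from the layer graph (shape walk), so they are exact
# and independent of any built weights.
#
# Conventions: one multiply-accumulate counts as 2 FLOPs; a convolution
# contributes 2 * k^2 * Cin * Cout * Hout * Wout. Elementwise work
# (batch-norm, activations, pooling comparisons) is excluded by default and
# available behind `include_elementwise`. The layer count counts each graph
# module once: the focus stem, every conv/BN-act unit, every CSP block,
# every selective-kernel layer, SPP, every upsample, every concat and every
# detection head.

.as_spec <- function(x) {
  if (inherits(x, "pest_model")) x$spec else {
    stop_if_not(inherits(x, "pest_model_spec"), "need a model or model spec")
    x
  }
}

# per-unit helpers (FLOPs at spatial size h*w; params)
.fl_conv <- function(k, cin, cout, hw, elem) {
  2 * k^2 * cin * cout * hw + if (elem) 3 * cout * hw else 0 # BN (2) + act (1)
}
.pm_convunit <- function(k, cin, cout) k^2 * cin * cout + 2 * cout
.pm_sk <- function(ch, d) {
  9 * ch^2 + 25 * ch^2 + (ch * d + d) + 2 * d + (d * ch + ch)
}
.fl_sk <- function(ch, d, hw, elem) {
  2 * (9 + 25) * ch^2 * hw + 2 * ch * d + 2 * d * ch +
    if (elem) (hw * ch + 2 * ch + 3 * d) else 0 # GAP + scale + BN/ReLU
}

.walk_complexity <- function(spec, input_size, include_elementwise = FALSE) {
  fl <- 0; pm <- 0
  elem <- include_elementwise
  d_sk <- function(ch) max(ch %/% spec$reduction, 8L)
  for (r in spec$layers) {
    hw <- (input_size / r$out_stride)^2
    switch(r$module,
      focus = {
        fl <- fl + .fl_conv(r$k, r$cin, r$cout, hw, elem)
        pm <- pm + .pm_convunit(r$k, r$cin, r$cout)
      },
      conv = {
        fl <- fl + .fl_conv(r$k, r$cin, r$cout, hw, elem)
        pm <- pm + .pm_convunit(r$k, r$cin, r$cout)
      },
      csp = {
        ch <- r$cout %/% 2L
        fl <- fl + .fl_conv(1, r$cin, ch, hw, elem) * 2 +
          r$n * (.fl_conv(1, ch, ch, hw, elem) + .fl_conv(3, ch, ch, hw, elem)) +
          .fl_conv(1, 2 * ch, r$cout, hw, elem)
        pm <- pm + 2 * .pm_convunit(1, r$cin, ch) +
          r$n * (.pm_convunit(1, ch, ch) + .pm_convunit(3, ch, ch)) +
          .pm_convunit(1, 2 * ch, r$cout)
        if (r$sk) {
          fl <- fl + .fl_sk(ch, d_sk(ch), hw, elem)
          pm <- pm + .pm_sk(ch, d_sk(ch))
        }
      },
      spp = {
        ch <- r$cin %/% 2L
        fl <- fl + .fl_conv(1, r$cin, ch, hw, elem) +
          .fl_conv(1, 4 * ch, r$cout, hw, elem) +
          if (elem) sum((c(5, 9, 13)^2 - 1) * ch * hw) else 0
        pm <- pm + .pm_convunit(1, r$cin, ch) + .pm_convunit(1, 4 * ch, r$cout)
      },
      head = {
        fl <- fl + 2 * r$cin * r$cout * hw + if (elem) r$cout * hw else 0
        pm <- pm + r$cin * r$cout + r$cout
      },
      upsample = , concat = NULL)
  }
  list(flops = fl, params = pm)
}

#' Analytic FLOP count of a detector architecture
#'
#' @param model A `pest_model` or `pest_model_spec`.
#' @param input_size Square input side; defaults to the spec's.
#' @param include_elementwise Also count batch-norm, activation and pooling
#'   elementwise operations (excluded by default).
#' @return GFLOPs (FLOPs / 1e9), multiply-accumulate counted as 2.
#' @export
count_flops <- function(model, input_size = NULL, include_elementwise = FALSE) {
  spec <- .as_spec(model)
  input_size <- input_size %||% spec$input_size
  stop_if_not(input_size %% 32 == 0, "input_size must be divisible by 32")
  .walk_complexity(spec, input_size, include_elementwise)$flops / 1e9
}

#' Analytic parameter count of a detector architecture
#'
#' Counts convolution kernels, head biases, batch-norm affine pairs and the
#' selective-kernel FC layers from layer shapes alone; agrees with the
#' number of weights [build_model()] allocates.
#'
#' @inheritParams count_flops
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  spec <- .as_spec(model)
  .walk_complexity(spec, spec$input_size)$params
}

#' Module-count of an architecture
#'
#' Counts each graph module once: focus stem, conv units, CSP blocks,
#' selective-kernel layers, SPP, upsamples, concats and detection heads.
#'
#' @inheritParams count_flops
#' @return Integer layer count.
#' @export
layer_count <- function(model) {
  spec <- .as_spec(model)
  sum(vapply(spec$layers, function(r)
    switch(r$module, csp = 1L + as.integer(r$sk), 1L), integer(1)))
}

#' Layer-count difference between two architectures
#'
#' @param model_a,model_b Models or specs built under the same counting
#'   convention.
#' @return `layer_count(model_b) - layer_count(model_a)`.
#' @export
layer_delta <- function(model_a, model_b) {
  layer_count(model_b) - layer_count(model_a)
}

#' Complexity report table
#'
#' One row per model: parameters, counted layers, GFLOPs at `input_size`,
#' and the assumed checkpoint size (parameters at half precision,
#' `params * 2 / 2^20` MB).
#'
#' @param models Named list of `pest_model` / `pest_model_spec` objects.
#' @param input_size Input side used for the FLOP column (default 512).
#' @param path Optional CSV output path.
#' @return A data frame with columns `model`, `params`, `layers`, `gflops`,
#'   `size_mb`.
#' @export
complexity_report <- function(models, input_size = 512L, path = NULL) {
  if (inherits(models, "pest_model") || inherits(models, "pest_model_spec"))
    models <- list(model = models)
  if (!length(models)) {
    out <- data.frame(model = character(0), params = numeric(0),
                      layers = integer(0), gflops = numeric(0),
                      size_mb = numeric(0))
    if (!is.null(path)) write.csv(out, path, row.names = FALSE)
    return(out)
  }
  rows <- lapply(seq_along(models), function(i) {
    s <- .as_spec(models[[i]])
    data.frame(model = names(models)[i] %||% paste0("model", i),
               params = count_params(s),
               layers = layer_count(s),
               gflops = count_flops(s, input_size),
               size_mb = count_params(s) * 2 / 2^20)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
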