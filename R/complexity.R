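# Analytic accounting of trainable parameters and multiply-accumulate
# operations, computed from the same layer plan the model is built from.

plan_param_count <- function(row) {
  switch(row$kind,
         conv = row$k^2 * (row$cin %/% row$groups) * row$cout +
           if (row$bias) row$cout else 0,
         bn = 2 * row$cout,
         0)
}

plan_mac_count <- function(row, h, w, convention) {
  oe <- row$cout * (h / row$scale) * (w / row$scale)
  if (row$kind == "conv") {
    macs <- oe * (row$cin %/% row$groups) * row$k^2
    if (convention == "profiler" && row$bias) macs <- macs + oe
    return(macs)
  }
  if (convention == "conv_only") return(0)
  switch(row$kind,
         bn = 2 * oe,
         relu = oe,
         pool = oe,
         upsample = oe,
         0)
}

complexity_report <- function(layers) {
  structure(list(
    layers = layers,
    total_params = sum(layers$params),
    total_macs = sum(layers$macs),
    params_M = round(sum(layers$params) / 1e6, 2),
    flops_G = round(sum(layers$macs) / 1e9, 2)
  ), class = "complexity_report")
}

#' Count trainable parameters
#'
#' Enumerates every learnable tensor (convolution weights, the head bias,
#' batch-norm scale and shift) analytically from the layer plan.  The result
#' agrees exactly with brute-force enumeration of the model's parameter
#' registry (`sum(lengths(model$params))`).
#'
#' @param model A built model (or an [arch_config()], which is built plan-only).
#' @return A `complexity_report` with per-layer rows, the total count, and
#'   `params_M` (millions, two decimals).
#' @export
count_parameters <- function(model) {
  plan <- if (inherits(model, "arch_config")) net_plan(model) else model$plan
  layers <- data.frame(
    name = vapply(plan, `[[`, "", "name"),
    kind = vapply(plan, `[[`, "", "kind"),
    params = vapply(plan, plan_param_count, 0),
    macs = NA_real_
  )
  complexity_report(layers)
}

#' Count multiply-accumulate operations of a forward pass
#'
#' For every convolution, one MAC per output element per kernel tap
#' (`out_elements * (in_channels / groups) * k^2`).  Under the default
#' `"profiler"` convention -- the accounting used by the common FLOP
#' profilers for this class of model, and the one this package reports --
#' the cheap per-element operations are also charged: batch normalization at
#' 2 per element, ReLU at 1, max pooling and bilinear upsampling at 1 per
#' output element, and a convolution bias at 1 per output element.  The
#' `"conv_only"` convention charges convolutions alone.  The spatial shift is
#' free under both.
#'
#' @param model A built model (or an [arch_config()]).
#' @param input_shape Input as `c(channels, height, width)`; height and width
#'   must be divisible by 16.
#' @param convention `"profiler"` (default) or `"conv_only"`.
#' @return A `complexity_report`; `flops_G` is the total in units of 1e9,
#'   rounded to two decimals.
#' @export
count_macs <- function(model, input_shape = c(3L, 256L, 256L),
                       convention = c("profiler", "conv_only")) {
  convention <- match.arg(convention)
  cfg <- if (inherits(model, "arch_config")) model else model$cfg
  plan <- if (inherits(model, "arch_config")) net_plan(model) else model$plan
  h <- input_shape[2]; w <- input_shape[3]
  if (h %% 16 != 0 || w %% 16 != 0)
    stop("input height and width must be divisible by 16")
  if (input_shape[1] != cfg$in_channels)
    stop("input_shape channels do not match the model")
  layers <- data.frame(
    name = vapply(plan, `[[`, "", "name"),
    kind = vapply(plan, `[[`, "", "kind"),
    params = vapply(plan, plan_param_count, 0),
    macs = vapply(plan, plan_mac_count, 0, h = h, w = w,
                  convention = convention)
  )
  complexity_report(layers)
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("total parameters: %d (%.2f M)\n",
              as.integer(x$total_params), x$params_M))
  if (!all(is.na(x$layers$macs)))
    cat(sprintf("total MACs: %.0f (%.2f G)\n", x$total_macs, x$flops_G))
  by_kind <- stats::aggregate(params ~ kind, data = x$layers, FUN = sum)
  for (i in seq_len(nrow(by_kind)))
    cat(sprintf("  %-9s %10d params\n", by_kind$kind[i],
                as.integer(by_kind$params[i])))
  invisible(x)
}
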