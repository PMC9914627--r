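#' Count trainable parameters
#'
#' Exact number of trainable scalars in a model: convolution and
#' transposed-convolution kernels and biases, batch-normalisation scale and
#' shift, and CBAM perceptron/convolution weights. Batch-normalisation
#' running statistics are buffers, not parameters, and are excluded.
#'
#' @param model an [arch_config()], a model plan, or an assembled model
#'   from [assemble_model()].
#' @return integer scalar.
#' @seealso [params_millions()] for the conventional "M" reporting.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "arch_config")) model <- build_model_plan(model)
  if (inherits(model, "model_graph")) {
    return(sum(vapply(model$params, length, numeric(1))))
  }
  if (!is.null(model$ops)) return(plan_param_count(model))
  stop_prunet("cannot count parameters of this object", "prunet_bad_model")
}

#' @rdname count_parameters
#' @param digits decimal places for the millions-scale report.
#' @export
params_millions <- function(model, digits = 2) {
  round(count_parameters(model) / 1e6, digits)
}

#' Published parameter counts used for convention calibration
#'
#' The parameter counts, in millions, published for the four variants at
#' encoder widths 64..1024 and for three of them at the reduced widths
#' 8..128 (the attention variant rounds to the same value as the plain
#' pruned model in the small regime). These are the calibration targets for
#' [calibrate_conventions()].
#' @return a data.frame with columns `variant`, `attention`, `regime`,
#'   `target_m`.
#' @export
reference_param_counts <- function() {
  data.frame(
    variant = c("unet", "unet3plus", "unet3plus_pruned", "unet3plus_pruned",
                "unet", "unet3plus", "unet3plus_pruned"),
    attention = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    regime = c(rep("large", 4L), rep("small", 3L)),
    target_m = c(32.92, 25.71, 21.00, 21.02, 0.60, 0.40, 0.33),
    stringsAsFactors = FALSE
  )
}

regime_widths <- function(regime) {
  switch(regime,
    large = c(64L, 128L, 256L, 512L, 1024L),
    small = c(8L, 16L, 32L, 64L, 128L),
    stop_prunet(sprintf("unknown widths regime '%s'", regime), "prunet_bad_regime")
  )
}

#' Calibrate unstated architectural conventions against published counts
#'
#' Searches the documented finite convention space ([convention_space()])
#' for the `convention_set` minimising the total absolute deviation, in
#' millions of parameters, between [count_parameters()] and the published
#' counts of all listed variants simultaneously. A single set is chosen for
#' all regimes: the small-width counts are evaluated with the same set as
#' the large-width ones, never re-fit. The per-variant residuals of the
#' winning set are always reported; ties are broken by enumeration order.
#'
#' @param target_counts a data.frame like [reference_param_counts()]:
#'   columns `variant`, `attention` (logical), `regime` (`"large"` or
#'   `"small"`), `target_m` (millions).
#' @param in_channels input channels used when building each candidate.
#' @return an object of class `convention_calibration`: a list with
#'   `conventions` (the winning set), `residuals` (data.frame with the
#'   computed count, target and residual per variant), `total_deviation`,
#'   and `search` (total deviation of every candidate set).
#' @export
calibrate_conventions <- function(target_counts = reference_param_counts(),
                                  in_channels = 3L) {
  stopifnot(is.data.frame(target_counts),
            all(c("variant", "attention", "regime", "target_m") %in%
                  names(target_counts)),
            nrow(target_counts) >= 1L)
  space <- convention_space()
  counts_for <- function(cv) {
    vapply(seq_len(nrow(target_counts)), function(r) {
      cfg <- arch_config(
        variant = target_counts$variant[r],
        attention = target_counts$attention[r],
        encoder_widths = regime_widths(target_counts$regime[r]),
        in_channels = in_channels,
        conventions = cv
      )
      count_parameters(cfg) / 1e6
    }, numeric(1))
  }
  withCallingHandlers(
    devs <- vapply(space, function(cv) {
      sum(abs(counts_for(cv) - target_counts$target_m))
    }, numeric(1)),
    message = function(m) invokeRestart("muffleMessage")
  )
  best <- which.min(devs)
  cv <- space[[best]]
  counts <- suppressMessages(counts_for(cv))
  residuals <- data.frame(
    target_counts[c("variant", "attention", "regime")],
    target_m = target_counts$target_m,
    count_m = round(counts, 4),
    residual_m = round(counts - target_counts$target_m, 4)
  )
  structure(
    list(
      conventions = cv,
      residuals = residuals,
      total_deviation = devs[best],
      search = data.frame(
        set = seq_along(space),
        conv_bias = vapply(space, `[[`, logical(1), "conv_bias"),
        batchnorm_in_branches = vapply(space, `[[`, logical(1),
                                       "batchnorm_in_branches"),
        upsample_mode = vapply(space, `[[`, character(1), "upsample_mode"),
        fusion_rule = vapply(space, `[[`, character(1),
                             "decoder_fusion_out_channels"),
        total_deviation = devs
      )
    ),
    class = "convention_calibration"
  )
}

#' @export
print.convention_calibration <- function(x, ...) {
  cat(sprintf(
    "<convention_calibration> best of %d sets, total |deviation| %.4f M\n",
    nrow(x$search), x$total_deviation
  ))
  print(x$conventions)
  cat("residuals (computed - published, M):\n")
  print(x$residuals, row.names = FALSE)
  invisible(x)
}

#' Per-layer model summary
#'
#' One row per operation of the model graph: its name, type, output
#' tensor, output channel count, the spatial scale of its output relative
#' to the input (1 = full resolution, 4 = down-sampled by 4, ...) and its
#' parameter count. The `params` column sums to [count_parameters()].
#' @param model an [arch_config()], plan or assembled model.
#' @return a data.frame.
#' @export
model_summary <- function(model) {
  if (inherits(model, "arch_config")) model <- build_model_plan(model)
  if (inherits(model, "model_graph")) model <- model$plan
  chan <- c(input = model$config$in_channels)
  scale <- c(input = 1)
  rows <- lapply(model$ops, function(op) {
    cin <- unname(chan[op$inputs[1L]])
    cout <- switch(op$type,
      conv = op$attrs$cout,
      convt2 = op$attrs$cout,
      concat = sum(unname(chan[op$inputs])),
      cbam = op$attrs$channels,
      cin
    )
    sc <- unname(scale[op$inputs[1L]]) * switch(op$type,
      maxpool = op$attrs$factor,
      upsample = 1 / op$attrs$factor,
      convt2 = 0.5,
      1
    )
    chan[op$output] <<- cout
    scale[op$output] <<- sc
    data.frame(
      layer = op$id, type = op$type, output = op$output,
      out_channels = cout, scale = sc,
      params = if (length(op$params)) {
        sum(vapply(op$params, prod, numeric(1)))
      } else {
        0
      },
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @rdname model_summary
#' @param path CSV destination.
#' @export
write_model_summary <- function(model, path) {
  utils::write.csv(model_summary(model), path, row.names = FALSE)
  invisible(path)
}
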