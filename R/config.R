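#' Architectural conventions left open by the published network descriptions
#'
#' U-shaped segmentation papers rarely pin down every construction detail
#' that affects the trainable-parameter count: whether convolutions carry a
#' bias when followed by batch normalisation, whether the per-branch
#' rescale-transform includes its own normalisation, how the classic UNet
#' decoder up-samples, and how wide the decoder fusion convolution is. A
#' `convention_set` records one concrete choice for each of these degrees of
#' freedom; it is serialised alongside every reported parameter count so a
#' count is never quoted without the conventions that produced it.
#'
#' @param conv_bias logical; do 3x3/2x2 convolutions that are followed by a
#'   batch-normalisation layer carry a bias term? (The output head always
#'   has a bias: it feeds the sigmoid directly.)
#' @param batchnorm_in_branches logical; do the per-source branch transforms
#'   of the multi-scale decoders include batch normalisation?
#' @param upsample_mode `"bilinear"` (bilinear interpolation followed by a
#'   3x3 convolution in the classic UNet decoder; branch transforms always
#'   up-sample bilinearly) or `"transposed"` (2x2 stride-2 transposed
#'   convolution).
#' @param fusion_rule width of the decoder fusion convolution output:
#'   `"branch_times_n"` (branch width times the number of sources actually
#'   concatenated) or `"branch_times_levels"` (branch width times the total
#'   number of levels `N`, the fixed-width rule of the original full-scale
#'   design, e.g. 320 = 64 x 5).
#' @param encoder_convs_per_block number of 3x3 conv+BN+ReLU units per
#'   encoder block (fixed at 2 in this family).
#' @return an object of class `convention_set`.
#' @export
convention_set <- function(conv_bias = FALSE,
                           batchnorm_in_branches = FALSE,
                           upsample_mode = c("bilinear", "transposed"),
                           fusion_rule = c("branch_times_n", "branch_times_levels"),
                           encoder_convs_per_block = 2L) {
  upsample_mode <- match.arg(upsample_mode)
  fusion_rule <- match.arg(fusion_rule)
  stopifnot(is.logical(conv_bias), length(conv_bias) == 1L,
            is.logical(batchnorm_in_branches), length(batchnorm_in_branches) == 1L,
            identical(as.integer(encoder_convs_per_block), 2L))
  structure(
    list(
      conv_bias = conv_bias,
      encoder_convs_per_block = 2L,
      upsample_mode = upsample_mode,
      decoder_fusion_out_channels = fusion_rule,
      final_head = "1x1 convolution with bias, sigmoid activation",
      batchnorm_in_branches = batchnorm_in_branches
    ),
    class = "convention_set"
  )
}

#' Default conventions
#'
#' The repository default is the convention set selected by
#' [calibrate_conventions()] against the published parameter counts of the
#' four variants (see the methods vignette): bias-free convolutions,
#' no batch normalisation inside branch transforms, bilinear up-sampling,
#' and fusion width equal to branch width times the number of concatenated
#' sources.
#' @return a `convention_set`.
#' @export
default_conventions <- function() {
  convention_set(
    conv_bias = FALSE, batchnorm_in_branches = FALSE,
    upsample_mode = "bilinear", fusion_rule = "branch_times_n"
  )
}

#' Enumerate the documented finite convention space
#'
#' The calibration search space: all combinations of conv bias on/off,
#' branch batch-normalisation on/off, bilinear vs transposed up-sampling in
#' the classic decoder, and the two fusion-width rules (16 sets).
#' @return a list of `convention_set` objects.
#' @export
convention_space <- function() {
  grid <- expand.grid(
    conv_bias = c(TRUE, FALSE),
    batchnorm_in_branches = c(TRUE, FALSE),
    upsample_mode = c("bilinear", "transposed"),
    fusion_rule = c("branch_times_n", "branch_times_levels"),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    convention_set(
      conv_bias = grid$conv_bias[i],
      batchnorm_in_branches = grid$batchnorm_in_branches[i],
      upsample_mode = grid$upsample_mode[i],
      fusion_rule = grid$fusion_rule[i]
    )
  })
}

#' @export
print.convention_set <- function(x, ...) {
  cat("<convention_set>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, as.character(x[[nm]])))
  invisible(x)
}

#' Configuration of one model variant
#'
#' Declarative description of a member of the U-shaped family, sufficient to
#' build the network graph and count its parameters.
#'
#' @param variant `"unet"`, `"unet3plus"` or `"unet3plus_pruned"`.
#' @param attention logical; insert a CBAM block in every decoder (intended
#'   for the pruned variant; other combinations are built but flagged).
#' @param encoder_widths strictly increasing positive integers, one per
#'   level (bottleneck last); length `N >= 3`.
#' @param in_channels,out_channels input image channels (default 3) and
#'   output probability channels (default 1).
#' @param branch_width common channel count every skip source is projected
#'   to before concatenation (default `encoder_widths[1]`).
#' @param cbam_reduction,cbam_kernel CBAM channel-attention reduction ratio
#'   (default 16) and spatial-attention kernel size (odd, default 7).
#' @param conventions a [convention_set()].
#' @return an object of class `arch_config`.
#' @examples
#' arch_config("unet3plus_pruned", attention = TRUE,
#'             encoder_widths = c(8, 16, 32, 64, 128))
#' @export
arch_config <- function(variant = c("unet", "unet3plus", "unet3plus_pruned"),
                        attention = FALSE,
                        encoder_widths = c(64L, 128L, 256L, 512L, 1024L),
                        in_channels = 3L,
                        out_channels = 1L,
                        branch_width = NULL,
                        cbam_reduction = 16L,
                        cbam_kernel = 7L,
                        conventions = default_conventions()) {
  variant <- match.arg(variant)
  encoder_widths <- as.integer(encoder_widths)
  if (length(encoder_widths) < 3L || any(encoder_widths <= 0L) ||
      any(diff(encoder_widths) <= 0L)) {
    stop_prunet(
      "`encoder_widths` must be >= 3 strictly increasing positive integers",
      "prunet_bad_widths"
    )
  }
  stopifnot(is_count(in_channels), is_count(out_channels),
            is_count(cbam_reduction), is_count(cbam_kernel),
            cbam_kernel %% 2 == 1, inherits(conventions, "convention_set"))
  branch_width <- as.integer(branch_width %||% encoder_widths[1])
  stopifnot(is_count(branch_width))
  if (attention && variant != "unet3plus_pruned") {
    log_msg(sprintf(
      "note: attention=TRUE with variant '%s' is unusual (CBAM was designed for the pruned decoders); building anyway",
      variant
    ))
  }
  structure(
    list(
      variant = variant, attention = isTRUE(attention),
      encoder_widths = encoder_widths,
      in_channels = as.integer(in_channels),
      out_channels = as.integer(out_channels),
      branch_width = branch_width,
      cbam_reduction = as.integer(cbam_reduction),
      cbam_kernel = as.integer(cbam_kernel),
      conventions = conventions
    ),
    class = "arch_config"
  )
}

#' @export
print.arch_config <- function(x, ...) {
  cat(sprintf(
    "<arch_config> %s%s, widths %s, in=%d out=%d, branch=%d\n",
    x$variant, if (x$attention) "+cbam" else "",
    paste(x$encoder_widths, collapse = ">"),
    x$in_channels, x$out_channels, x$branch_width
  ))
  invisible(x)
}

#' Read/write an architecture configuration
#'
#' Round-trips an [arch_config()] (including its convention set) through a
#' YAML or JSON file; the format is chosen from the file extension.
#' @param config an `arch_config`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_arch_config` returns `path` invisibly;
#'   `read_arch_config` returns an `arch_config`.
#' @export
write_arch_config <- function(config, path) {
  stopifnot(inherits(config, "arch_config"))
  x <- unclass(config)
  x$conventions <- unclass(x$conventions)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_arch_config
#' @export
read_arch_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cv <- x$conventions
  fusion_rule <- cv$decoder_fusion_out_channels %||% cv$fusion_rule
  arch_config(
    variant = x$variant, attention = isTRUE(x$attention),
    encoder_widths = unlist(x$encoder_widths),
    in_channels = x$in_channels %||% 3L,
    out_channels = x$out_channels %||% 1L,
    branch_width = x$branch_width,
    cbam_reduction = x$cbam_reduction %||% 16L,
    cbam_kernel = x$cbam_kernel %||% 7L,
    conventions = convention_set(
      conv_bias = isTRUE(cv$conv_bias),
      batchnorm_in_branches = isTRUE(cv$batchnorm_in_branches),
      upsample_mode = cv$upsample_mode,
      fusion_rule = fusion_rule
    )
  )
}
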