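#' Skip-connection topology of a U-shaped segmentation network
#'
#' Computes, for every decoder level, the ordered list of feature-map
#' sources feeding that decoder, together with the rescaling each source
#' needs. Three variants are supported:
#'
#' * `"unet"` — the classic U-shape: decoder `i` receives the same-level
#'   encoder `en_i` and the next-deeper decoder `de_{i+1}`.
#' * `"unet3plus"` — full-scale skip connections: decoder `i` receives every
#'   shallower/same-level encoder `en_1..en_i` (down-sampled to scale `i`)
#'   and every deeper decoder `de_{i+1}..de_N` (up-sampled to scale `i`).
#' * `"unet3plus_pruned"` — the pruned multi-scale topology: decoder `i > 1`
#'   keeps only the same-level encoder `en_i`, the next-deeper decoder
#'   `de_{i+1}`, and the encoder two levels shallower `en_{i-2}` (when it
#'   exists); decoder 1 receives `en_1` plus the up-sampled decoders
#'   `de_2..de_{N-2}`.
#'
#' Level `N` is the bottleneck: `de_N` is identically the encoder output
#' `en_N` and has no decoder block of its own.
#'
#' Each source is a list with fields `role` (`"encoder"` or `"decoder"`),
#' `level`, `scale` (signed power of two: `2^k` means down-sample by `2^k`,
#' `-2^k` up-sample by `2^k`, `1` same scale) and `transform` (`"S"` for the
#' same-scale conv+norm+activation branch, `"M"` for max-pool-then-transform,
#' `"U"` for upsample-then-transform).
#'
#' @param variant one of `"unet"`, `"unet3plus"`, `"unet3plus_pruned"`.
#' @param n_levels total number of levels `N` (>= 3) including the bottleneck.
#' @return an object of class `skip_topology`: a list with one element per
#'   decoder level `1..N-1`, each an ordered list of sources.
#' @examples
#' topo <- build_skip_topology("unet3plus_pruned", 5)
#' topo[[3]] # en1 down x4, en3 same scale, de4 up x2
#' @export
build_skip_topology <- function(variant, n_levels) {
  if (!is_count(n_levels) || n_levels < 3) {
    stop_prunet(
      sprintf("`n_levels` must be an integer >= 3, got %s", deparse(n_levels)),
      "prunet_bad_levels"
    )
  }
  variants <- c("unet", "unet3plus", "unet3plus_pruned")
  if (!is.character(variant) || length(variant) != 1L || !variant %in% variants) {
    stop_prunet(
      sprintf(
        "unknown variant %s; expected one of %s",
        deparse(variant), paste(dQuote(variants, FALSE), collapse = ", ")
      ),
      "prunet_unknown_variant"
    )
  }
  N <- as.integer(n_levels)
  src <- function(role, level, target) {
    d <- level - target
    list(
      role = role, level = level,
      scale = if (d == 0) 1L else if (d < 0) as.integer(2^(-d)) else -as.integer(2^d),
      transform = if (d == 0) "S" else if (d < 0) "M" else "U"
    )
  }
  topo <- vector("list", N - 1L)
  for (i in seq_len(N - 1L)) {
    topo[[i]] <- switch(variant,
      unet = list(src("encoder", i, i), src("decoder", i + 1L, i)),
      unet3plus = c(
        lapply(seq_len(i), function(j) src("encoder", j, i)),
        lapply(seq(i + 1L, N), function(k) src("decoder", k, i))
      ),
      unet3plus_pruned = if (i == 1L) {
        c(
          list(src("encoder", 1L, 1L)),
          if (N - 2L >= 2L) {
            lapply(seq(2L, N - 2L), function(k) src("decoder", k, 1L))
          }
        )
      } else {
        c(
          list(src("encoder", i, i), src("decoder", i + 1L, i)),
          if (i - 2L >= 1L) list(src("encoder", i - 2L, i))
        )
      }
    )
  }
  structure(topo, class = "skip_topology", variant = variant, n_levels = N)
}

#' @export
print.skip_topology <- function(x, ...) {
  cat(sprintf(
    "<skip_topology> variant=%s, N=%d\n",
    attr(x, "variant"), attr(x, "n_levels")
  ))
  for (i in seq_along(x)) {
    labs <- vapply(x[[i]], function(s) {
      tag <- if (s$role == "encoder") "en" else "de"
      resc <- if (s$scale == 1L) {
        ""
      } else if (s$scale > 0) {
        sprintf(" v%d", s$scale)
      } else {
        sprintf(" ^%d", -s$scale)
      }
      sprintf("%s(%s%d%s)", s$transform, tag, s$level, resc)
    }, character(1))
    cat(sprintf("  de%d <- %s\n", i, paste(labs, collapse = ", ")))
  }
  invisible(x)
}

# Compact description used by tests and summaries: e.g. "en1,en3,de4".
topology_signature <- function(topo) {
  vapply(topo, function(srcs) {
    paste(vapply(srcs, function(s) {
      sprintf("%s%d", if (s$role == "encoder") "en" else "de", s$level)
    }, character(1)), collapse = ",")
  }, character(1))
}
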