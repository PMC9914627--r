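#' @keywords internal
#' @useDynLib prunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_prunet <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "prunet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

log_msg <- function(..., verbose = getOption("prunet.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x) && x > 0

#' Seed an expression locally
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so that model initialisation and data generation do not
#' perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific 31-bit seed from a base seed, stable across
# platforms (avoids consuming the caller's RNG).
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}
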