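# Stable per-parameter seeding: weights are drawn under a seed derived from
# the parameter's full name, so two models built from the same seed share
# identical weights for every layer they have in common (e.g. with and
# without attention blocks).
name_hash <- function(name) {
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 2147483647
  h
}

init_param <- function(pname, dims, seed) {
  s <- (derive_seed(seed, 0) + name_hash(pname)) %% 2147483647
  with_seed(s, {
    if (grepl("\\.(b|bs|beta)$", pname)) {
      rep(0, prod(dims))
    } else if (grepl("\\.gamma$", pname)) {
      rep(1, prod(dims))
    } else if (grepl("\\.w1$", pname)) {
      matrix(stats::rnorm(prod(dims), 0, sqrt(2 / dims[1])), dims[1], dims[2])
    } else if (grepl("\\.w2$", pname)) {
      matrix(stats::rnorm(prod(dims), 0, sqrt(2 / dims[1])), dims[1], dims[2])
    } else {
      # conv-style weight (k, k, cin, cout): He-normal on fan-in
      fan_in <- prod(dims[-length(dims)])
      array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
    }
  })
}

#' Assemble a trainable model
#'
#' Builds the network graph described by an [arch_config()] and allocates
#' its weights (He-normal initialisation, deterministic given `seed`;
#' parameters shared between two configurations receive identical initial
#' values under the same seed). The bottleneck feature map is reused
#' directly as the deepest decoder source; no decoder block exists at the
#' bottleneck level.
#'
#' @param config an [arch_config()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `model_graph` with elements `plan`, `params`
#'   (named list of arrays), `buffers` (batch-norm running statistics) and
#'   `config`.
#' @export
assemble_model <- function(config, seed = 1L) {
  plan <- build_model_plan(config)
  params <- list()
  buffers <- list()
  for (op in plan$ops) {
    for (pname in names(op$params)) {
      full <- paste(op$id, pname, sep = ".")
      params[[full]] <- init_param(full, op$params[[pname]], seed)
    }
    if (op$type == "bn") {
      buffers[[op$id]] <- list(
        mean = rep(0, op$attrs$channels),
        var = rep(1, op$attrs$channels)
      )
    }
  }
  structure(
    list(plan = plan, params = params, buffers = buffers, config = config,
         seed = as.integer(seed)),
    class = "model_graph"
  )
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf(
    "<model_graph> %s%s, widths %s, %s parameters (%.2f M)\n",
    x$config$variant, if (x$config$attention) "+cbam" else "",
    paste(x$config$encoder_widths, collapse = ">"),
    format(count_parameters(x), big.mark = ","), params_millions(x)
  ))
  invisible(x)
}

op_params <- function(model, op) {
  out <- list()
  for (pname in names(op$params)) {
    out[[pname]] <- model$params[[paste(op$id, pname, sep = ".")]]
  }
  out
}

validate_input_batch <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  d <- dim(x)
  if (length(d) != 4L) {
    stop_prunet("input must be an (H, W, batch, channels) array",
                "prunet_bad_input")
  }
  div <- model$plan$divisor
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    stop_prunet(
      sprintf(
        "input height and width must be divisible by %d (2^(N-1) for N=%d levels); got %dx%d",
        div, model$plan$n_levels, d[1], d[2]
      ),
      "prunet_bad_size"
    )
  }
  if (d[4] != model$config$in_channels) {
    stop_prunet(
      sprintf("expected %d input channels, got %d",
              model$config$in_channels, d[4]),
      "prunet_bad_channels"
    )
  }
  x
}

#' Forward pass
#'
#' Runs a batch through the network. Probabilities come from a sigmoid
#' head, so every output value is strictly inside (0, 1), and the output
#' spatial size equals the input size.
#'
#' @param model a [assemble_model()] result.
#' @param x input array `(H, W, batch, channels)` (a single `(H, W,
#'   channels)` image is promoted to a batch of one).
#' @param training logical; use batch statistics (and update running
#'   statistics) in the normalisation layers.
#' @param keep_cache keep per-op caches for a subsequent backward pass.
#' @return a list with `out` (probability array `(H, W, batch,
#'   out_channels)`), `model` (updated running statistics when training)
#'   and, if requested, `cache` and `tensors`.
#' @export
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  x <- validate_input_batch(model, x)
  tensors <- list(input = x)
  caches <- vector("list", length(model$plan$ops))
  for (oi in seq_along(model$plan$ops)) {
    op <- model$plan$ops[[oi]]
    pars <- op_params(model, op)
    res <- switch(op$type,
      conv = conv_fwd(tensors[[op$inputs]], pars$w, pars$b),
      convt2 = convt2_fwd(tensors[[op$inputs]], pars$w, pars$b),
      bn = {
        r <- bn_fwd(tensors[[op$inputs]], pars$gamma, pars$beta,
                    model$buffers[[op$id]], training)
        if (training) model$buffers[[op$id]] <- r$state
        r
      },
      relu = relu_fwd(tensors[[op$inputs]]),
      sigmoid = sigmoid_fwd(tensors[[op$inputs]]),
      maxpool = maxpool_fwd(tensors[[op$inputs]], op$attrs$factor),
      upsample = upsample_fwd(tensors[[op$inputs]], op$attrs$factor),
      concat = concat_fwd(tensors[op$inputs]),
      cbam = cbam_fwd(tensors[[op$inputs]], pars),
      stop_prunet(sprintf("unknown op type '%s'", op$type), "prunet_bad_op")
    )
    tensors[[op$output]] <- res$out
    if (keep_cache) caches[[oi]] <- res$cache
  }
  out <- list(out = tensors$prob, model = model)
  if (keep_cache) {
    out$cache <- caches
    out$tensors <- tensors
  }
  out
}

#' @export
predict.model_graph <- function(object, x, ...) {
  model_forward(object, x, training = FALSE)$out
}

# Backward pass: propagates d(loss)/d(prob) through the graph, returning
# gradients for every parameter (same names/shapes as model$params).
model_backward <- function(model, fw, dprob) {
  grads_t <- list(prob = dprob)
  grads_p <- list()
  add_grad <- function(lst, name, val) {
    if (is.null(lst[[name]])) lst[[name]] <- val else lst[[name]] <- lst[[name]] + val
    lst
  }
  set_pgrad <- function(op, pname, val) {
    grads_p[[paste(op$id, pname, sep = ".")]] <<- val
  }
  ops <- model$plan$ops
  for (oi in rev(seq_along(ops))) {
    op <- ops[[oi]]
    g <- grads_t[[op$output]]
    if (is.null(g)) next
    pars <- op_params(model, op)
    cache <- fw$cache[[oi]]
    if (op$type == "conv") {
      r <- conv_bwd(g, pars$w, cache, has_bias = !is.null(pars$b))
      set_pgrad(op, "w", r$dw)
      if (!is.null(pars$b)) set_pgrad(op, "b", r$db)
      grads_t <- add_grad(grads_t, op$inputs, r$dx)
    } else if (op$type == "convt2") {
      r <- convt2_bwd(g, pars$w, cache, has_bias = !is.null(pars$b))
      set_pgrad(op, "w", r$dw)
      if (!is.null(pars$b)) set_pgrad(op, "b", r$db)
      grads_t <- add_grad(grads_t, op$inputs, r$dx)
    } else if (op$type == "bn") {
      r <- bn_bwd(g, pars$gamma, cache)
      set_pgrad(op, "gamma", r$dgamma)
      set_pgrad(op, "beta", r$dbeta)
      grads_t <- add_grad(grads_t, op$inputs, r$dx)
    } else if (op$type == "relu") {
      grads_t <- add_grad(grads_t, op$inputs, relu_bwd(g, cache))
    } else if (op$type == "sigmoid") {
      grads_t <- add_grad(grads_t, op$inputs, sigmoid_bwd(g, cache))
    } else if (op$type == "maxpool") {
      grads_t <- add_grad(grads_t, op$inputs, maxpool_bwd(g, cache))
    } else if (op$type == "upsample") {
      grads_t <- add_grad(grads_t, op$inputs, upsample_bwd(g, cache))
    } else if (op$type == "concat") {
      parts <- concat_bwd(g, cache)
      for (j in seq_along(op$inputs)) {
        grads_t <- add_grad(grads_t, op$inputs[j], parts[[j]])
      }
    } else if (op$type == "cbam") {
      r <- cbam_bwd(g, pars, cache)
      set_pgrad(op, "w1", r$dw1)
      set_pgrad(op, "w2", r$dw2)
      set_pgrad(op, "ws", r$dws)
      set_pgrad(op, "bs", r$dbs)
      grads_t <- add_grad(grads_t, op$inputs, r$dx)
    }
    grads_t[[op$output]] <- NULL # free
  }
  grads_p
}

# Stack a list of segmentation samples into (H, W, batch, C) image and
# (H, W, batch) mask arrays.
batch_from_samples <- function(samples) {
  stopifnot(length(samples) >= 1L)
  d <- dim(samples[[1]]$image)
  B <- length(samples)
  x <- array(0, c(d[1], d[2], B, d[3]))
  y <- array(0, c(d[1], d[2], B))
  for (b in seq_len(B)) {
    x[, , b, ] <- samples[[b]]$image
    y[, , b] <- samples[[b]]$mask
  }
  list(x = x, y = y)
}
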