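# Model graphs are static plans: an ordered list of primitive ops, each
# naming its input/output tensors and the shapes of its parameters. The
# same plan drives weight allocation, the forward/backward executor and
# parameter counting (a plan can be counted without allocating weights).

new_op <- function(id, type, inputs, output, params = list(), attrs = list()) {
  list(id = id, type = type, inputs = inputs, output = output,
       params = params, attrs = attrs)
}

conv_params <- function(k, cin, cout, bias) {
  p <- list(w = c(k, k, cin, cout))
  if (bias) p$b <- cout
  p
}

# One conv + BN + ReLU unit; `bn`/`act` can be switched off for fusion
# convs (BN yes, ReLU deferred past CBAM) and branch transforms.
add_cbr <- function(ops, id, input, output, k, cin, cout, bias, bn = TRUE,
                    act = TRUE) {
  tmp <- paste0(output, ".c")
  ops[[length(ops) + 1L]] <- new_op(
    paste0(id, ".conv"), "conv", input, if (bn || act) tmp else output,
    conv_params(k, cin, cout, bias), list(k = k, cin = cin, cout = cout)
  )
  if (bn) {
    tmp2 <- if (act) paste0(output, ".n") else output
    ops[[length(ops) + 1L]] <- new_op(
      paste0(id, ".bn"), "bn", tmp, tmp2,
      list(gamma = cout, beta = cout), list(channels = cout)
    )
    tmp <- tmp2
  }
  if (act) {
    ops[[length(ops) + 1L]] <- new_op(paste0(id, ".relu"), "relu", tmp, output)
  }
  ops
}

# Build the full op plan for one architecture configuration.
build_model_plan <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  cv <- config$conventions
  w <- config$encoder_widths
  N <- length(w)
  bias <- cv$conv_bias
  ops <- list()

  # --- encoder ---
  a <- config$in_channels
  input <- "input"
  for (l in seq_len(N)) {
    mid <- sprintf("en%d.m", l)
    ops <- add_cbr(ops, sprintf("enc%d.1", l), input, mid, 3L, a, w[l], bias)
    ops <- add_cbr(ops, sprintf("enc%d.2", l), mid, sprintf("en%d", l), 3L,
                   w[l], w[l], bias)
    a <- w[l]
    if (l < N) {
      ops[[length(ops) + 1L]] <- new_op(
        sprintf("pool%d", l), "maxpool", sprintf("en%d", l),
        sprintf("pool%d", l), attrs = list(factor = 2L)
      )
      input <- sprintf("pool%d", l)
    }
  }

  topo <- build_skip_topology(config$variant, N)
  # channel count of each tensor de1..deN (deN is the bottleneck = enN)
  dch <- integer(N)
  dch[N] <- w[N]
  tensor_of <- function(s) {
    if (s$role == "encoder") sprintf("en%d", s$level) else sprintf("de%d", s$level)
  }

  if (config$variant == "unet") {
    for (i in seq(N - 1L, 1L)) {
      deeper <- if (i + 1L == N) sprintf("en%d", N) else sprintf("de%d", i + 1L)
      up <- sprintf("up%d", i)
      if (cv$upsample_mode == "transposed") {
        ops[[length(ops) + 1L]] <- new_op(
          sprintf("dec%d.up", i), "convt2", deeper, up,
          c(list(w = c(2L, 2L, w[i + 1L], w[i])), if (bias) list(b = w[i])),
          list(cin = w[i + 1L], cout = w[i])
        )
      } else {
        ups <- paste0(up, ".s")
        ops[[length(ops) + 1L]] <- new_op(
          sprintf("dec%d.ups", i), "upsample", deeper, ups,
          attrs = list(factor = 2L)
        )
        ops <- add_cbr(ops, sprintf("dec%d.up", i), ups, up, 3L,
                       w[i + 1L], w[i], bias)
      }
      cat_t <- sprintf("cat%d", i)
      ops[[length(ops) + 1L]] <- new_op(
        sprintf("dec%d.cat", i), "concat", c(sprintf("en%d", i), up), cat_t,
        attrs = list(channels = c(w[i], w[i]))
      )
      mid <- sprintf("de%d.m", i)
      ops <- add_cbr(ops, sprintf("dec%d.1", i), cat_t, mid, 3L, 2L * w[i], w[i], bias)
      ops <- add_cbr(ops, sprintf("dec%d.2", i), mid, sprintf("de%d", i), 3L,
                     w[i], w[i], bias)
      dch[i] <- w[i]
    }
  } else {
    bw <- config$branch_width
    for (i in seq(N - 1L, 1L)) {
      srcs <- topo[[i]]
      nb <- length(srcs)
      br_names <- character(nb)
      for (j in seq_len(nb)) {
        s <- srcs[[j]]
        src_t <- tensor_of(s)
        if (s$role == "decoder" && s$level == N) src_t <- sprintf("en%d", N)
        src_ch <- if (s$role == "encoder") w[s$level] else dch[s$level]
        br <- sprintf("br%d_%s%d", i, substr(s$role, 1L, 2L), s$level)
        cur <- src_t
        if (s$transform == "M") {
          rs <- paste0(br, ".p")
          ops[[length(ops) + 1L]] <- new_op(
            sprintf("dec%d.src%d.pool", i, j), "maxpool", cur, rs,
            attrs = list(factor = s$scale)
          )
          cur <- rs
        } else if (s$transform == "U") {
          rs <- paste0(br, ".u")
          ops[[length(ops) + 1L]] <- new_op(
            sprintf("dec%d.src%d.ups", i, j), "upsample", cur, rs,
            attrs = list(factor = -s$scale)
          )
          cur <- rs
        }
        ops <- add_cbr(ops, sprintf("dec%d.src%d", i, j), cur, br, 3L,
                       src_ch, bw, bias, bn = cv$batchnorm_in_branches)
        br_names[j] <- br
      }
      fus_out <- if (cv$decoder_fusion_out_channels == "branch_times_n") {
        bw * nb
      } else {
        bw * N
      }
      cat_t <- sprintf("cat%d", i)
      ops[[length(ops) + 1L]] <- new_op(
        sprintf("dec%d.cat", i), "concat", br_names, cat_t,
        attrs = list(channels = rep(bw, nb))
      )
      fus_t <- sprintf("fus%d", i)
      ops <- add_cbr(ops, sprintf("dec%d.fuse", i), cat_t, fus_t, 3L,
                     bw * nb, fus_out, bias, bn = TRUE, act = FALSE)
      cur <- fus_t
      if (config$attention) {
        att_t <- sprintf("att%d", i)
        hid <- max(1L, fus_out %/% config$cbam_reduction)
        if (fus_out %% config$cbam_reduction != 0L) {
          log_msg(sprintf(
            "decoder %d: channels %d not divisible by reduction %d; hidden width clamped to %d",
            i, fus_out, config$cbam_reduction, hid
          ))
        }
        ops[[length(ops) + 1L]] <- new_op(
          sprintf("dec%d.cbam", i), "cbam", cur, att_t,
          list(w1 = c(fus_out, hid), w2 = c(hid, fus_out),
               ws = c(config$cbam_kernel, config$cbam_kernel, 2L, 1L), bs = 1L),
          list(channels = fus_out, hidden = hid, kernel = config$cbam_kernel)
        )
        cur <- att_t
      }
      ops[[length(ops) + 1L]] <- new_op(
        sprintf("dec%d.relu", i), "relu", cur, sprintf("de%d", i)
      )
      dch[i] <- fus_out
    }
  }

  ops[[length(ops) + 1L]] <- new_op(
    "head.conv", "conv", "de1", "logit",
    list(w = c(1L, 1L, dch[1L], config$out_channels), b = config$out_channels),
    list(k = 1L, cin = dch[1L], cout = config$out_channels)
  )
  ops[[length(ops) + 1L]] <- new_op("head.sigmoid", "sigmoid", "logit", "prob")

  list(ops = ops, config = config, topology = topo, decoder_channels = dch,
       n_levels = N, divisor = as.integer(2^(N - 1L)))
}

# Trainable parameter count of a plan (no weights needed).
plan_param_count <- function(plan) {
  sum(vapply(plan$ops, function(op) {
    if (length(op$params) == 0L) return(0)
    sum(vapply(op$params, prod, numeric(1)))
  }, numeric(1)))
}
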