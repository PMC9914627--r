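# Closed-form parameter counting, derived independently of the package's
# graph builder: straight arithmetic over the block structure.

cf_conv <- function(k, cin, cout, bias, bn) {
  k * k * cin * cout + (if (bias) cout else 0) + (if (bn) 2 * cout else 0)
}

cf_encoder <- function(w, cin, bias) {
  tot <- 0
  a <- cin
  for (wl in w) {
    tot <- tot + cf_conv(3, a, wl, bias, TRUE) + cf_conv(3, wl, wl, bias, TRUE)
    a <- wl
  }
  tot
}

closed_form_count <- function(variant, widths, attention = FALSE,
                              in_channels = 3, cv = default_conventions()) {
  N <- length(widths)
  bias <- cv$conv_bias
  tot <- cf_encoder(widths, in_channels, bias)
  if (variant == "unet") {
    for (i in (N - 1):1) {
      tot <- tot + if (cv$upsample_mode == "transposed") {
        cf_conv(2, widths[i + 1], widths[i], bias, FALSE)
      } else {
        cf_conv(3, widths[i + 1], widths[i], bias, TRUE)
      }
      tot <- tot + cf_conv(3, 2 * widths[i], widths[i], bias, TRUE) +
        cf_conv(3, widths[i], widths[i], bias, TRUE)
    }
    return(tot + cf_conv(1, widths[1], 1, TRUE, FALSE))
  }
  bw <- widths[1]
  topo <- build_skip_topology(variant, N)
  dch <- integer(N)
  dch[N] <- widths[N]
  for (i in (N - 1):1) {
    srcs <- topo[[i]]
    nb <- length(srcs)
    fo <- if (cv$decoder_fusion_out_channels == "branch_times_n") {
      bw * nb
    } else {
      bw * N
    }
    for (s in srcs) {
      sc <- if (s$role == "encoder") widths[s$level] else dch[s$level]
      tot <- tot + cf_conv(3, sc, bw, bias, cv$batchnorm_in_branches)
    }
    tot <- tot + cf_conv(3, bw * nb, fo, bias, TRUE)
    if (attention) {
      hid <- max(1, fo %/% 16)
      tot <- tot + fo * hid * 2 + 7 * 7 * 2 + 1
    }
    dch[i] <- fo
  }
  tot + cf_conv(1, dch[1], 1, TRUE, FALSE)
}
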