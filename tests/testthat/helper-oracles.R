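# Independent brute-force oracles, written as direct transcriptions of the
# definitions (nested loops / dense matrices), deliberately sharing no code
# with the package implementation.

# Plain nested-loop stride-1 same-padding convolution on (H, W, B, C).
naive_conv <- function(x, w, b = NULL) {
  d <- dim(x)
  k <- dim(w)[1]
  p <- (k - 1) / 2
  cout <- dim(w)[4]
  out <- array(0, c(d[1], d[2], d[3], cout))
  for (co in seq_len(cout)) {
    for (bb in seq_len(d[3])) {
      for (i in seq_len(d[1])) {
        for (j in seq_len(d[2])) {
          acc <- if (is.null(b)) 0 else b[co]
          for (ci in seq_len(d[4])) {
            for (dy in seq_len(k)) {
              for (dx in seq_len(k)) {
                ii <- i + dy - 1 - p
                jj <- j + dx - 1 - p
                if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
                  acc <- acc + x[ii, jj, bb, ci] * w[dy, dx, ci, co]
                }
              }
            }
          }
          out[i, j, bb, co] <- acc
        }
      }
    }
  }
  out
}

sigmoid_ref <- function(z) 1 / (1 + exp(-z))

# Channel attention per the definition: shared perceptron on global average
# and global max descriptors, summed, sigmoid. Single sample (H, W, C).
naive_channel_attention <- function(f, w1, w2) {
  C <- dim(f)[3]
  avg <- vapply(seq_len(C), function(c) mean(f[, , c]), numeric(1))
  mx <- vapply(seq_len(C), function(c) max(f[, , c]), numeric(1))
  mlp <- function(v) {
    h <- pmax(as.vector(v %*% w1), 0)
    as.vector(h %*% w2)
  }
  sigmoid_ref(mlp(avg) + mlp(mx))
}

# Spatial attention: channel mean/max maps, k x k sliding window conv with
# zero padding, sigmoid. Single sample (H, W, C).
naive_spatial_attention <- function(f, ws, bs) {
  d <- dim(f)
  k <- dim(ws)[1]
  p <- (k - 1) / 2
  mean_map <- apply(f, c(1, 2), mean)
  max_map <- apply(f, c(1, 2), max)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      acc <- bs
      for (dy in seq_len(k)) {
        for (dx in seq_len(k)) {
          ii <- i + dy - 1 - p
          jj <- j + dx - 1 - p
          if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
            acc <- acc + mean_map[ii, jj] * ws[dy, dx, 1, 1] +
              max_map[ii, jj] * ws[dy, dx, 2, 1]
          }
        }
      }
      out[i, j] <- sigmoid_ref(acc)
    }
  }
  out
}

naive_cbam <- function(f, pars) {
  mc <- naive_channel_attention(f, pars$w1, pars$w2)
  f1 <- f
  for (c in seq_len(dim(f)[3])) f1[, , c] <- f[, , c] * mc[c]
  ms <- naive_spatial_attention(f1, pars$ws, pars$bs)
  f2 <- f1
  for (c in seq_len(dim(f)[3])) f2[, , c] <- f1[, , c] * ms
  f2
}

# Central finite-difference gradient of a scalar function.
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
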