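# Numerical primitives. All feature maps are 4-D arrays laid out as
# (H, W, batch, channels): with channels last, every k x k convolution tap
# is a contiguous (H*W*B) x C_in matrix and the convolution is a sum of k^2
# BLAS matrix products -- no per-call permutes. Each primitive has a
# forward returning (out, cache) and a backward mapping the output gradient
# to input/parameter gradients.

zeros4 <- function(d) array(0, d)

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- zeros4(c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  out
}

## ---- convolution (stride 1, same padding; compiled im2col + GEMM) ----

conv_fwd <- function(x, w, b = NULL) {
  stopifnot(dim(x)[4] == dim(w)[3])
  list(out = .conv2d_fwd(x, w, b), cache = list(x = x))
}

conv_bwd <- function(grad, w, cache, has_bias) {
  .conv2d_bwd(grad, cache$x, w, has_bias)
}

## ---- transposed convolution, kernel 2 stride 2 (doubles H and W) ----

convt2_fwd <- function(x, w, b = NULL) {
  d <- dim(x)
  cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- d[1]; W <- d[2]; B <- d[3]
  xm <- matrix(x, ncol = cin)
  out <- zeros4(c(2L * H, 2L * W, B, cout))
  for (dy in 1:2) {
    for (dx in 1:2) {
      o <- xm %*% matrix(w[dy, dx, , ], cin, cout)
      out[seq(dy, 2L * H, 2L), seq(dx, 2L * W, 2L), , ] <-
        array(o, c(H, W, B, cout))
    }
  }
  if (!is.null(b)) {
    out <- out + rep(b, each = 4L * H * W * B)
  }
  list(out = out, cache = list(xm = xm, d = d))
}

convt2_bwd <- function(grad, w, cache, has_bias) {
  d <- cache$d
  cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- d[1]; W <- d[2]; B <- d[3]
  dxm <- matrix(0, H * W * B, cin)
  dw <- array(0, dim(w))
  for (dy in 1:2) {
    for (dx in 1:2) {
      g <- matrix(grad[seq(dy, 2L * H, 2L), seq(dx, 2L * W, 2L), , ,
                       drop = FALSE], ncol = cout)
      dw[dy, dx, , ] <- crossprod(cache$xm, g)
      dxm <- dxm + g %*% t(matrix(w[dy, dx, , ], cin, cout))
    }
  }
  list(dx = array(dxm, c(H, W, B, cin)), dw = dw,
       db = if (has_bias) colSums(matrix(grad, ncol = cout)) else NULL)
}

## ---- max pooling, window = stride = s ----

maxpool_fwd <- function(x, s) {
  d <- dim(x)
  stopifnot(d[1] %% s == 0L, d[2] %% s == 0L)
  Ho <- d[1] %/% s; Wo <- d[2] %/% s
  out <- array(-Inf, c(Ho, Wo, d[3], d[4]))
  idx <- array(0L, c(Ho, Wo, d[3], d[4]))
  t <- 0L
  for (a in seq_len(s)) {
    for (b in seq_len(s)) {
      t <- t + 1L
      sl <- x[seq(a, d[1], s), seq(b, d[2], s), , , drop = FALSE]
      upd <- sl > out
      out[upd] <- sl[upd]
      idx[upd] <- t
    }
  }
  list(out = out, cache = list(idx = idx, d = d, s = s))
}

maxpool_bwd <- function(grad, cache) {
  d <- cache$d; s <- cache$s
  dx <- zeros4(d)
  t <- 0L
  for (a in seq_len(s)) {
    for (b in seq_len(s)) {
      t <- t + 1L
      sl <- grad * (cache$idx == t)
      dx[seq(a, d[1], s), seq(b, d[2], s), , ] <- sl
    }
  }
  dx
}

## ---- bilinear upsampling by an integer factor (half-pixel centres) ----

bilinear_matrix <- function(n_in, s) {
  n_out <- n_in * s
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) / s - 0.5   # 0-based source coordinate
    i0 <- floor(src)
    f <- src - i0
    lo <- min(max(i0, 0), n_in - 1)
    hi <- min(max(i0 + 1, 0), n_in - 1)
    A[i, lo + 1] <- A[i, lo + 1] + (1 - f)
    A[i, hi + 1] <- A[i, hi + 1] + f
  }
  A
}

apply_rows <- function(x, A) {
  d <- dim(x)
  y <- A %*% matrix(x, d[1], prod(d[2:4]))
  array(y, c(nrow(A), d[2:4]))
}

upsample_fwd <- function(x, s) {
  d <- dim(x)
  A <- bilinear_matrix(d[1], s)
  Bm <- bilinear_matrix(d[2], s)
  y <- apply_rows(x, A)
  y <- aperm(y, c(2L, 1L, 3L, 4L))
  y <- apply_rows(y, Bm)
  y <- aperm(y, c(2L, 1L, 3L, 4L))
  list(out = y, cache = list(A = A, Bm = Bm, d = d))
}

upsample_bwd <- function(grad, cache) {
  g <- apply_rows(grad, t(cache$A))
  g <- aperm(g, c(2L, 1L, 3L, 4L))
  g <- apply_rows(g, t(cache$Bm))
  aperm(g, c(2L, 1L, 3L, 4L))
}

## ---- batch normalisation (per channel over H, W, batch) ----

bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  C <- d[4]
  xm <- matrix(x, ncol = C)
  n <- prod(d[1:3])
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    va <- colMeans(xc^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
    xc <- xm - rep(mu, each = n)
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- xc * rep(ivar, each = n)
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = array(out, d), state = state,
       cache = list(xhat = xhat, ivar = ivar, d = d))
}

bn_bwd <- function(grad, gamma, cache) {
  d <- cache$d
  C <- d[4]
  n <- prod(d[1:3])
  gm <- matrix(grad, ncol = C)
  dbeta <- colSums(gm)
  dgamma <- colSums(gm * cache$xhat)
  dxhat <- gm * rep(gamma, each = n)
  # dx = (ivar/n) * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (n * dxhat - rep(s1, each = n) - cache$xhat * rep(s2, each = n)) *
    rep(cache$ivar / n, each = n)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

## ---- activations ----

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(grad, cache) grad * cache

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, cache = y)
}
sigmoid_bwd <- function(grad, cache) grad * cache * (1 - cache)

## ---- channel concatenation ----

concat_fwd <- function(xs) {
  d <- dim(xs[[1]])
  chs <- vapply(xs, function(x) dim(x)[4], integer(1))
  out <- zeros4(c(d[1:3], sum(chs)))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[4]
    out[, , , (at + 1L):(at + cc)] <- x
    at <- at + cc
  }
  list(out = out, cache = chs)
}

concat_bwd <- function(grad, chs) {
  out <- vector("list", length(chs))
  at <- 0L
  for (j in seq_along(chs)) {
    out[[j]] <- grad[, , , (at + 1L):(at + chs[j]), drop = FALSE]
    at <- at + chs[j]
  }
  out
}
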