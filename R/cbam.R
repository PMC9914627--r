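#' Convolutional block attention (CBAM)
#'
#' Sequential channel-then-spatial attention. Channel attention pools the
#' feature map globally by average and by maximum, pushes both descriptors
#' through a shared two-layer perceptron with a reduction bottleneck
#' (`C -> C/r -> C`, no biases), sums them, and applies a sigmoid, giving
#' one gain per channel. The channel-refined map is then pooled across
#' channels (mean and max), the two maps are convolved with a single odd
#' k x k kernel (with bias), and a sigmoid gives one gain per pixel. Both
#' gains act multiplicatively: `F' = Mc (x) F`, `F'' = Ms (x) F'`.
#'
#' These user-facing functions accept a single feature map `(H, W, C)` or a
#' batch `(H, W, batch, C)`; weights are taken from a [cbam_weights()]
#' bundle (or drawn from `seed` when omitted).
#'
#' @name cbam
NULL

#' CBAM weight bundle
#'
#' @param channels number of input channels `C`.
#' @param reduction channel bottleneck ratio `r` (hidden width
#'   `max(1, C %/% r)`; a non-divisible `C` is clamped and logged).
#' @param kernel odd spatial kernel size.
#' @param seed integer seed for the He-normal initialisation.
#' @return list with `w1` (`C x hidden`), `w2` (`hidden x C`), `ws`
#'   (`k x k x 2 x 1`), `bs` (length-1 bias).
#' @export
cbam_weights <- function(channels, reduction = 16L, kernel = 7L, seed = 1L) {
  if (kernel %% 2L == 0L) {
    stop_prunet("spatial attention kernel must be odd", "prunet_even_kernel")
  }
  hid <- max(1L, channels %/% reduction)
  if (channels %% reduction != 0L) {
    log_msg(sprintf(
      "channels %d not divisible by reduction %d; hidden width clamped to %d",
      channels, reduction, hid
    ))
  }
  with_seed(seed, list(
    w1 = matrix(stats::rnorm(channels * hid, 0, sqrt(2 / channels)),
                channels, hid),
    w2 = matrix(stats::rnorm(hid * channels, 0, sqrt(2 / hid)),
                hid, channels),
    ws = array(stats::rnorm(kernel * kernel * 2, 0, sqrt(2 / (kernel^2 * 2))),
               c(kernel, kernel, 2L, 1L)),
    bs = 0
  ))
}

as_batch4 <- function(f) {
  if (length(dim(f)) == 3L) {
    d <- dim(f)
    dim(f) <- c(d[1], d[2], 1L, d[3])
    attr(f, "was3d") <- TRUE
  } else if (length(dim(f)) != 4L) {
    stop_prunet("feature map must be (H, W, C) or (H, W, batch, C)",
                "prunet_bad_feature_map")
  }
  if (any(dim(f) == 0L)) {
    stop_prunet("empty feature map", "prunet_empty_feature_map")
  }
  f
}

## ---- internal forward/backward cores (batch layout) ----

mlp_fwd <- function(a, w1, w2) {
  h_pre <- a %*% w1
  h <- pmax(h_pre, 0)
  list(out = h %*% w2, h = h)
}

ca_fwd <- function(x, w1, w2) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, nrow = hw)            # columns ordered (batch, channel)
  avg <- matrix(colMeans(xm), d[3], d[4])
  amax_idx <- apply(xm, 2L, which.max)
  amax <- matrix(xm[cbind(amax_idx, seq_along(amax_idx))], d[3], d[4])
  fa <- mlp_fwd(avg, w1, w2)
  fm <- mlp_fwd(amax, w1, w2)
  mc <- 1 / (1 + exp(-(fa$out + fm$out)))
  list(mc = mc, cache = list(avg = avg, amax = amax, amax_idx = amax_idx,
                             ha = fa$h, hm = fm$h, mc = mc, d = d))
}

ca_bwd <- function(dmc, x, w1, w2, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  dpre <- dmc * cache$mc * (1 - cache$mc)
  dw2 <- crossprod(cache$ha, dpre) + crossprod(cache$hm, dpre)
  dha <- (dpre %*% t(w2)) * (cache$ha > 0)
  dhm <- (dpre %*% t(w2)) * (cache$hm > 0)
  dw1 <- crossprod(cache$avg, dha) + crossprod(cache$amax, dhm)
  davg <- dha %*% t(w1)
  dmax <- dhm %*% t(w1)
  dx <- array(rep(as.vector(davg) / hw, each = hw), d)
  dxv <- as.vector(dx)
  pos <- cache$amax_idx + (seq_along(cache$amax_idx) - 1L) * hw
  dxv[pos] <- dxv[pos] + as.vector(dmax)
  list(dx = array(dxv, d), dw1 = dw1, dw2 = dw2)
}

sa_fwd <- function(x, ws, bs) {
  d <- dim(x)
  C <- d[4]
  xm <- matrix(x, ncol = C)
  mean_map <- rowMeans(xm)
  max_map <- xm[, 1L]
  max_idx <- rep(1L, length(max_map))
  if (C > 1L) {
    for (cc in 2:C) {
      upd <- xm[, cc] > max_map
      max_map[upd] <- xm[upd, cc]
      max_idx[upd] <- cc
    }
  }
  pooled <- array(c(mean_map, max_map), c(d[1:3], 2L))
  cv <- conv_fwd(pooled, ws, bs)
  sg <- sigmoid_fwd(cv$out)
  list(ms = sg$out,
       cache = list(conv = cv$cache, ms = sg$out, max_idx = max_idx, d = d))
}

sa_bwd <- function(dms, ws, cache) {
  d <- cache$d
  C <- d[4]
  hwb <- prod(d[1:3])
  dpre <- dms * cache$ms * (1 - cache$ms)
  cb <- conv_bwd(dpre, ws, cache$conv, has_bias = TRUE)
  dmean <- as.vector(cb$dx[, , , 1L])
  dmax <- as.vector(cb$dx[, , , 2L])
  dxv <- rep(dmean / C, times = C)
  pos <- seq_len(hwb) + (cache$max_idx - 1L) * hwb
  dxv[pos] <- dxv[pos] + dmax
  list(dx = array(dxv, d), dws = cb$dw, dbs = cb$db)
}

cbam_fwd <- function(x, pars) {
  d <- dim(x)
  hw <- d[1] * d[2]
  ca <- ca_fwd(x, pars$w1, pars$w2)
  f1 <- x * rep(as.vector(ca$mc), each = hw)
  sa <- sa_fwd(f1, pars$ws, pars$bs)
  out <- f1 * as.vector(sa$ms)
  list(out = out,
       cache = list(x = x, f1 = f1, ca = ca, sa = sa, d = d))
}

cbam_bwd <- function(grad, pars, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  ms_v <- as.vector(cache$sa$ms)
  dms <- array(rowSums(matrix(grad * cache$f1, ncol = d[4])), c(d[1:3], 1L))
  df1 <- grad * ms_v
  sb <- sa_bwd(dms, pars$ws, cache$sa$cache)
  df1 <- df1 + sb$dx
  dmc <- matrix(colSums(matrix(df1 * cache$x, nrow = hw)), d[3], d[4])
  dx <- df1 * rep(as.vector(cache$ca$mc), each = hw)
  cb <- ca_bwd(dmc, cache$x, pars$w1, pars$w2, cache$ca$cache)
  dx <- dx + cb$dx
  list(dx = dx, dw1 = cb$dw1, dw2 = cb$dw2, dws = sb$dws, dbs = sb$dbs)
}

## ---- user-facing functional API ----

#' @rdname cbam
#' @param f input feature map, `(H, W, C)` or `(H, W, batch, C)`.
#' @param weights a [cbam_weights()] bundle; drawn from `seed` when `NULL`.
#' @param reduction,kernel,seed see [cbam_weights()].
#' @return `channel_attention`: the channel map `Mc`, a length-`C` vector
#'   (or `batch x C` matrix); values strictly in (0, 1).
#' @export
channel_attention <- function(f, weights = NULL, reduction = 16L, seed = 1L) {
  f <- as_batch4(f)
  C <- dim(f)[4]
  weights <- weights %||% cbam_weights(C, reduction, seed = seed)
  mc <- ca_fwd(f, weights$w1, weights$w2)$mc
  if (isTRUE(attr(f, "was3d"))) as.vector(mc) else mc
}

#' @rdname cbam
#' @param f_prime channel-refined feature map.
#' @return `spatial_attention`: the spatial map `Ms`, `(H, W)` (or
#'   `(H, W, batch)`); values strictly in (0, 1).
#' @export
spatial_attention <- function(f_prime, weights = NULL, kernel = 7L, seed = 1L) {
  if (kernel %% 2L == 0L) {
    stop_prunet("spatial attention kernel must be odd", "prunet_even_kernel")
  }
  f_prime <- as_batch4(f_prime)
  weights <- weights %||%
    cbam_weights(dim(f_prime)[4], kernel = kernel, seed = seed)
  ms <- sa_fwd(f_prime, weights$ws, weights$bs)$ms
  d <- dim(f_prime)
  if (isTRUE(attr(f_prime, "was3d"))) {
    array(ms, d[1:2])
  } else {
    array(ms, d[1:3])
  }
}

#' @rdname cbam
#' @return `apply_cbam`: the refined feature map `F''`, same shape as `f`.
#' @export
apply_cbam <- function(f, weights = NULL, reduction = 16L, kernel = 7L,
                       seed = 1L) {
  f4 <- as_batch4(f)
  weights <- weights %||%
    cbam_weights(dim(f4)[4], reduction, kernel, seed = seed)
  out <- cbam_fwd(f4, weights)$out
  if (isTRUE(attr(f4, "was3d"))) array(out, dim(f)) else out
}
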