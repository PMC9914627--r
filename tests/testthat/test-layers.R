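# Layer primitives against brute-force oracles and finite differences.

test_that("convolution matches the nested-loop oracle", {
  set.seed(11)
  for (k in c(1L, 3L, 7L)) {
    x <- array(rnorm(6 * 7 * 2 * 3), c(6, 7, 2, 3))
    w <- array(rnorm(k * k * 3 * 2) * 0.4, c(k, k, 3, 2))
    b <- rnorm(2)
    expect_equal(prunet:::conv_fwd(x, w, b)$out, naive_conv(x, w, b),
                 tolerance = 1e-12)
    expect_equal(prunet:::conv_fwd(x, w, NULL)$out, naive_conv(x, w, NULL),
                 tolerance = 1e-12)
  }
})

test_that("convolution backward matches finite differences", {
  set.seed(12)
  x <- array(rnorm(5 * 6 * 2 * 3), c(5, 6, 2, 3))
  w <- array(rnorm(3 * 3 * 3 * 4) * 0.3, c(3, 3, 3, 4))
  b <- rnorm(4)
  gy <- array(rnorm(5 * 6 * 2 * 4), c(5, 6, 2, 4))
  fw <- prunet:::conv_fwd(x, w, b)
  bw <- prunet:::conv_bwd(gy, w, fw$cache, TRUE)
  expect_equal(bw$dx,
               numeric_grad(function(z) sum(prunet:::conv_fwd(z, w, b)$out * gy), x),
               tolerance = 1e-6)
  expect_equal(bw$dw,
               numeric_grad(function(z) sum(prunet:::conv_fwd(x, z, b)$out * gy), w),
               tolerance = 1e-6)
  expect_equal(bw$db,
               as.vector(numeric_grad(function(z) sum(prunet:::conv_fwd(x, w, z)$out * gy), b)),
               tolerance = 1e-6)
})

test_that("transposed convolution doubles the spatial size and has exact gradients", {
  set.seed(13)
  x <- array(rnorm(3 * 4 * 2 * 3), c(3, 4, 2, 3))
  w <- array(rnorm(2 * 2 * 3 * 2) * 0.3, c(2, 2, 3, 2))
  b <- rnorm(2)
  fw <- prunet:::convt2_fwd(x, w, b)
  expect_equal(dim(fw$out), c(6L, 8L, 2L, 2L))
  gy <- array(rnorm(length(fw$out)), dim(fw$out))
  bw <- prunet:::convt2_bwd(gy, w, fw$cache, TRUE)
  expect_equal(bw$dx,
               numeric_grad(function(z) sum(prunet:::convt2_fwd(z, w, b)$out * gy), x),
               tolerance = 1e-6)
  expect_equal(bw$dw,
               numeric_grad(function(z) sum(prunet:::convt2_fwd(x, z, b)$out * gy), w),
               tolerance = 1e-6)
})

test_that("max pooling takes blockwise maxima and routes gradients to them", {
  set.seed(14)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  for (s in c(2L, 4L)) {
    fw <- prunet:::maxpool_fwd(x, s)
    ref <- apply(x, c(3, 4), function(m) {
      n <- nrow(m) / s
      out <- matrix(0, n, ncol(m) / s)
      for (i in seq_len(nrow(out))) {
        for (j in seq_len(ncol(out))) {
          out[i, j] <- max(m[((i - 1) * s + 1):(i * s), ((j - 1) * s + 1):(j * s)])
        }
      }
      out
    })
    expect_equal(as.vector(fw$out),
                 as.vector(array(ref, c(8 / s, 8 / s, 2, 3))),
                 tolerance = 1e-12)
    gy <- array(rnorm(length(fw$out)), dim(fw$out))
    bw <- prunet:::maxpool_bwd(gy, fw$cache)
    expect_equal(bw,
                 numeric_grad(function(z) sum(prunet:::maxpool_fwd(z, s)$out * gy), x),
                 tolerance = 1e-6)
  }
})

test_that("bilinear upsampling is linear with an exact adjoint backward", {
  set.seed(15)
  x <- array(rnorm(4 * 5 * 2 * 3), c(4, 5, 2, 3))
  for (s in c(2L, 4L)) {
    fw <- prunet:::upsample_fwd(x, s)
    expect_equal(dim(fw$out), c(4L * s, 5L * s, 2L, 3L))
    # constant fields upsample to the same constant
    ones <- array(1, dim(x))
    expect_equal(prunet:::upsample_fwd(ones, s)$out,
                 array(1, c(4 * s, 5 * s, 2, 3)), tolerance = 1e-12)
    gy <- array(rnorm(length(fw$out)), dim(fw$out))
    bw <- prunet:::upsample_bwd(gy, fw$cache)
    # adjoint identity <Ax, y> = <x, A'y>
    expect_equal(sum(fw$out * gy), sum(x * bw), tolerance = 1e-10)
  }
})

test_that("batch normalisation standardises channels and backpropagates exactly", {
  set.seed(16)
  x <- array(rnorm(4 * 4 * 3 * 3, mean = 2, sd = 3), c(4, 4, 3, 3))
  gam <- runif(3, 0.5, 1.5)
  bet <- rnorm(3)
  st <- list(mean = rep(0, 3), var = rep(1, 3))
  fw <- prunet:::bn_fwd(x, rep(1, 3), rep(0, 3), st, training = TRUE)
  xm <- matrix(fw$out, ncol = 3)
  expect_equal(colMeans(xm), rep(0, 3), tolerance = 1e-8)
  pop_sd <- sqrt(colMeans(xm^2))
  expect_equal(pop_sd, rep(1, 3), tolerance = 1e-3)
  fw2 <- prunet:::bn_fwd(x, gam, bet, st, training = TRUE)
  gy <- array(rnorm(length(x)), dim(x))
  bw <- prunet:::bn_bwd(gy, gam, fw2$cache)
  expect_equal(bw$dx,
               numeric_grad(function(z) {
                 sum(prunet:::bn_fwd(z, gam, bet, st, TRUE)$out * gy)
               }, x),
               tolerance = 1e-5)
  expect_equal(bw$dgamma,
               as.vector(numeric_grad(function(z) {
                 sum(prunet:::bn_fwd(x, z, bet, st, TRUE)$out * gy)
               }, gam)),
               tolerance = 1e-6)
  # eval mode uses the running statistics, not the batch
  ev <- prunet:::bn_fwd(x, gam, bet, list(mean = rep(0, 3), var = rep(1, 3)),
                        training = FALSE)
  expect_equal(ev$out,
               array(rep(gam, each = 48) * matrix(x, ncol = 3) /
                       sqrt(1 + 1e-5) + rep(bet, each = 48), dim(x)),
               tolerance = 1e-12)
})

test_that("soft Dice loss gradient matches finite differences", {
  set.seed(17)
  p <- array(runif(64, 0.05, 0.95), c(8, 8))
  g <- array(rbinom(64, 1, 0.4), c(8, 8))
  gr <- prunet:::soft_dice_grad(p, g, eps = 1)
  expect_equal(gr,
               numeric_grad(function(z) as.numeric(soft_dice_loss(z, g, 1)), p),
               tolerance = 1e-6)
})
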