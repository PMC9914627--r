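# Parameter accounting: closed-form unit counts, frozen whole-model counts
# under the default conventions, and the scaling/ordering properties.

test_that("unit blocks count as their closed forms", {
  # 3x3 conv 1->1 with bias (9 + 1) plus BN over one channel (2) = 12
  expect_equal(cf_conv(3, 1, 1, TRUE, TRUE), 12)
  # CBAM block at C = 64, r = 16: shared perceptron 64->4->64 without
  # biases plus a 7x7 spatial conv on 2 pooled maps with bias
  wts <- cbam_weights(64, 16, 7)
  expect_equal(sum(lengths(wts)), 2 * (64 * 4) + (7 * 7 * 2 + 1))
  expect_equal(sum(lengths(wts)), 611)
})

test_that("whole-model counts equal the independent closed-form arithmetic", {
  wb <- c(64, 128, 256, 512, 1024)
  ws <- c(8, 16, 32, 64, 128)
  cases <- list(
    list("unet", FALSE), list("unet3plus", FALSE),
    list("unet3plus_pruned", FALSE), list("unet3plus_pruned", TRUE)
  )
  for (cv in list(default_conventions(),
                  convention_set(conv_bias = TRUE,
                                 batchnorm_in_branches = TRUE,
                                 upsample_mode = "transposed",
                                 fusion_rule = "branch_times_levels"))) {
    for (cs in cases) {
      for (w in list(wb, ws)) {
        cfg <- suppressMessages(
          arch_config(cs[[1]], attention = cs[[2]], encoder_widths = w,
                      conventions = cv)
        )
        expect_equal(
          count_parameters(cfg),
          closed_form_count(cs[[1]], w, attention = cs[[2]], cv = cv)
        )
      }
    }
  }
})

test_that("default-convention counts are frozen", {
  wb <- c(64, 128, 256, 512, 1024)
  ws <- c(8, 16, 32, 64, 128)
  expect_equal(count_parameters(arch_config("unet", encoder_widths = wb)),
               34520193)
  expect_equal(count_parameters(arch_config("unet3plus", encoder_widths = wb)),
               26960129)
  expect_equal(
    count_parameters(arch_config("unet3plus_pruned", encoder_widths = wb)),
    21650433
  )
  expect_equal(
    count_parameters(suppressMessages(
      arch_config("unet3plus_pruned", attention = TRUE, encoder_widths = wb)
    )),
    21666701
  )
  expect_equal(params_millions(arch_config("unet", encoder_widths = ws)), 0.54)
  expect_equal(params_millions(arch_config("unet3plus", encoder_widths = ws)),
               0.42)
  expect_equal(
    params_millions(arch_config("unet3plus_pruned", encoder_widths = ws)),
    0.34
  )
})

test_that("counting an assembled model agrees with counting its plan", {
  cfg <- arch_config("unet3plus_pruned", encoder_widths = c(4, 8, 16))
  m <- assemble_model(cfg, seed = 1)
  expect_equal(count_parameters(m), count_parameters(cfg))
  sm <- model_summary(m)
  expect_equal(sum(sm$params), count_parameters(cfg))
  p <- withr::local_tempfile(fileext = ".csv")
  write_model_summary(m, p)
  expect_equal(sum(utils::read.csv(p)$params), count_parameters(cfg))
})

test_that("pruning strictly shrinks the network for any widths under any conventions", {
  widths_list <- list(c(16, 32, 64, 128, 256), c(4, 8, 16, 32, 64),
                      c(8, 16, 32, 64, 128), c(64, 128, 256, 512, 1024))
  for (cv in convention_space()[c(1, 6, 11, 16)]) {
    for (w in widths_list) {
      cu <- count_parameters(arch_config("unet", encoder_widths = w,
                                         conventions = cv))
      c3 <- count_parameters(arch_config("unet3plus", encoder_widths = w,
                                         conventions = cv))
      cp <- count_parameters(arch_config("unet3plus_pruned",
                                         encoder_widths = w,
                                         conventions = cv))
      expect_true(cp < c3)
      expect_true(c3 < cu)
    }
  }
})

test_that("attention is parameter-cheap: CBAM adds under 0.5% at full width", {
  wb <- c(64, 128, 256, 512, 1024)
  cp <- count_parameters(arch_config("unet3plus_pruned", encoder_widths = wb))
  ca <- count_parameters(suppressMessages(
    arch_config("unet3plus_pruned", attention = TRUE, encoder_widths = wb)
  ))
  expect_true(ca > cp)
  expect_lt((ca - cp) / cp, 0.005)
})

test_that("doubling encoder widths roughly quadruples the conv-weight load", {
  conv_weight_count <- function(cfg) {
    plan <- prunet:::build_model_plan(cfg)
    sum(vapply(plan$ops, function(op) {
      if (!is.null(op$params$w)) prod(op$params$w) else 0
    }, numeric(1)))
  }
  w1 <- c(8, 16, 32, 64, 128)
  for (v in c("unet", "unet3plus", "unet3plus_pruned")) {
    a <- conv_weight_count(arch_config(v, encoder_widths = w1))
    b <- conv_weight_count(arch_config(v, encoder_widths = 2 * w1))
    expect_gte(b / a, 3.5)
    expect_lte(b / a, 4.0)
  }
})
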