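# Hand-enumerated fixtures and the algebraic identities between the
# overlap indicators.

# 4x4 fixture: GT has 3 foreground pixels, SR has 3, overlapping in 2.
fixture_masks <- function() {
  gt <- matrix(0, 4, 4)
  gt[1, 1] <- gt[1, 2] <- gt[2, 1] <- 1
  sr <- matrix(0, 4, 4)
  sr[1, 1] <- sr[2, 1] <- sr[3, 3] <- 1
  list(gt = gt, sr = sr)
}

test_that("confusion counts and the six indicators match the hand enumeration", {
  f <- fixture_masks()
  cc <- confusion_counts(f$sr, f$gt)
  expect_equal(cc$TP, 2)
  expect_equal(cc$FP, 1)
  expect_equal(cc$FN, 1)
  expect_equal(cc$TN, 12)
  pm <- pixel_metrics(cc)
  expect_equal(pm[["ACC"]], 14 / 16)
  expect_equal(pm[["PRE"]], 2 / 3)
  expect_equal(pm[["SE"]], 2 / 3)
  expect_equal(pm[["F1"]], 2 / 3)
  om <- overlap_metrics(f$sr, f$gt)
  expect_equal(om[["JS"]], 0.5)
  expect_equal(om[["DC"]], 2 / 3)
})

test_that("perfect, complementary and empty predictions hit the boundary values", {
  f <- fixture_masks()
  cc <- confusion_counts(f$gt, f$gt)
  expect_equal(cc$FP + cc$FN, 0)
  expect_equal(unname(pixel_metrics(cc)), rep(1, 4))
  expect_equal(unname(overlap_metrics(f$gt, f$gt)), c(1, 1))
  comp <- 1 - f$gt
  cc2 <- confusion_counts(comp, f$gt)
  expect_equal(cc2$TP, 0)
  expect_equal(cc2$TN, 0)
  empty <- matrix(0, 4, 4)
  expect_equal(unname(overlap_metrics(empty, empty)), c(1, 1))
})

test_that("soft Dice loss reproduces the closed-form cases", {
  g <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 0), 3, 3)
  expect_equal(as.numeric(soft_dice_loss(g, g, eps = 1e-9)), 0,
               tolerance = 1e-8)
  disj <- 1 - g
  expect_equal(as.numeric(soft_dice_loss(disj, g, eps = 1e-9)), 1,
               tolerance = 1e-8)
  gt <- matrix(0, 4, 4); gt[1:4, 1] <- 1        # |GT| = 4
  sr <- matrix(0, 4, 4); sr[3:4, 1] <- 1; sr[3:4, 2] <- 1 # |SR| = 4, overlap 2
  expect_equal(as.numeric(soft_dice_loss(sr, gt, eps = 1e-12)), 0.5,
               tolerance = 1e-10)
  expect_error(soft_dice_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)),
               class = "prunet_shape_mismatch")
})

test_that("soft Dice loss falls as probabilities move toward the target", {
  set.seed(21)
  g <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  losses <- vapply(seq(0, 1, 0.25), function(a) {
    as.numeric(soft_dice_loss(p + a * (g - p), g))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("binarization uses the >= boundary rule and is monotone in the threshold", {
  expect_equal(binarize(matrix(0.6, 2, 2), 0.5), matrix(1L, 2, 2))
  expect_equal(binarize(matrix(0.5, 2, 2), 0.5), matrix(1L, 2, 2))
  set.seed(22)
  p <- matrix(runif(100), 10, 10)
  masks <- lapply(c(0.2, 0.4, 0.6, 0.8), function(th) binarize(p, th))
  for (i in 1:3) expect_true(all(masks[[i + 1]] <= masks[[i]]))
})

test_that("F1 equals DC and DC = 2JS/(1+JS) for any binarized pair", {
  set.seed(23)
  for (r in 1:200) {
    gt <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    sr <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    om <- overlap_metrics(sr, gt)
    pm <- pixel_metrics(confusion_counts(sr, gt))
    if (sum(sr) + sum(gt) > 0) {
      expect_equal(pm[["F1"]], om[["DC"]], tolerance = 1e-12)
    }
    expect_equal(om[["DC"]], 2 * om[["JS"]] / (1 + om[["JS"]]),
                 tolerance = 1e-12)
    expect_true(om[["JS"]] <= om[["DC"]] + 1e-15)
    expect_true(all(c(pm, om) >= 0 & c(pm, om) <= 1))
  }
})

test_that("aggregation averages per image and pools counts globally", {
  f <- fixture_masks()
  r1 <- metric_record(f$sr, f$gt)
  r2 <- metric_record(f$gt, f$gt)
  agg <- aggregate_metrics(rbind(r1, r2))
  expect_equal(agg$DC[agg$scope == "per_image_mean"], (2 / 3 + 1) / 2)
  # identical records aggregate to themselves
  same <- aggregate_metrics(rbind(r1, r1))
  expect_equal(same$DC[same$scope == "per_image_mean"], r1$DC)
  expect_equal(same$DC[same$scope == "global"], r1$DC)
  expect_error(aggregate_metrics(r1[0, ]), class = "prunet_empty_records")
})

test_that("pooled-count and per-image-mean scopes diverge for unequal image sizes", {
  big_gt <- matrix(1, 10, 10)
  big_sr <- matrix(0, 10, 10)
  big_sr[1:5, ] <- 1                       # DC = 2*50/150 = 2/3
  small_gt <- matrix(1, 2, 2)
  small_sr <- matrix(1, 2, 2)              # DC = 1
  recs <- rbind(metric_record(big_sr, big_gt), metric_record(small_sr, small_gt))
  agg <- aggregate_metrics(recs)
  mean_dc <- agg$DC[agg$scope == "per_image_mean"]
  global_dc <- agg$DC[agg$scope == "global"]
  expect_equal(mean_dc, (2 / 3 + 1) / 2)
  expect_equal(global_dc, 2 * 54 / (104 + 54))
  expect_false(isTRUE(all.equal(mean_dc, global_dc)))
})

test_that("metric tables are written in the conventional column order", {
  tab <- data.frame(fold = c("1-fold", "Average"), ACC = c(0.9, 0.9),
                    PRE = c(0.8, 0.8), SE = c(0.7, 0.7), F1 = c(0.75, 0.75),
                    JS = c(0.6, 0.6), DC = c(0.75, 0.75))
  p <- withr::local_tempfile(fileext = ".csv")
  j <- withr::local_tempfile(fileext = ".json")
  write_metric_table(tab, csv = p, json = j)
  back <- utils::read.csv(p, check.names = FALSE)
  expect_equal(names(back),
               c("fold", "ACC", "PRE", "SE", "F1-Score", "JS", "DC"))
  expect_equal(jsonlite::read_json(j, simplifyVector = TRUE)$ACC, c(0.9, 0.9))
})
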