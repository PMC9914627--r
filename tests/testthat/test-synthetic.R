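# The synthetic generator: determinism, profile contracts, learnability,
# augmentation and folder IO.

test_that("generation is bitwise deterministic and honours the sample invariants", {
  d1 <- generate_dataset("skin_like", 10, size = 64, seed = 42)
  d2 <- generate_dataset("skin_like", 10, size = 64, seed = 42)
  expect_identical(d1, d2)
  d3 <- generate_dataset("skin_like", 10, size = 64, seed = 43)
  expect_false(identical(d1, d3))
  for (s in d1) {
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(all(is.finite(s$image)) && all(s$image >= 0 & s$image <= 1))
    expect_equal(dim(s$image), c(64L, 64L, 3L))
    expect_equal(dim(s$mask), c(64L, 64L))
  }
  expect_error(generate_dataset("skin_like", 2, size = 60),
               "divisible by 16", class = "prunet_bad_size")
})

test_that("lung-like masks contain exactly two connected bright regions", {
  ds <- generate_dataset("lung_like", 20, size = 64, seed = 7)
  for (s in ds) {
    lab <- EBImage::bwlabel(s$mask)
    expect_equal(max(lab), 2)
  }
})

test_that("profiles respect their declared foreground fraction and contrast", {
  for (pname in c("skin_like", "breast_like", "lung_like")) {
    prof <- generator_profile(pname)
    ds <- generate_dataset(prof, 40, size = 64, seed = 11)
    fracs <- vapply(ds, function(s) mean(s$mask), numeric(1))
    expect_true(all(fracs >= prof$fg_range[1] & fracs <= prof$fg_range[2]))
  }
  # skin-like contrast: fg brighter than bg by at least the declared gap
  prof <- generator_profile("skin_like")
  ds <- generate_dataset(prof, 200, size = 64, seed = 12)
  gaps <- vapply(ds, function(s) {
    img <- s$image[, , 1]
    mean(img[s$mask == 1]) - mean(img[s$mask == 0])
  }, numeric(1))
  expect_gte(mean(gaps > prof$contrast), 0.95)
})

test_that("a plain Otsu threshold already segments skin-like scenes well above chance", {
  ds <- generate_dataset("skin_like", 10, size = 64, seed = 13)
  dcs <- vapply(ds, function(s) {
    img <- s$image[, , 1]
    th <- EBImage::otsu(EBImage::Image(img))
    overlap_metrics((img >= th) * 1, s$mask)[["DC"]]
  }, numeric(1))
  expect_gt(mean(dcs), 0.7)
})

test_that("augmentation is mask-consistent, involutive and inert at ratio 0", {
  s <- generate_dataset("skin_like", 1, size = 64, seed = 3)[[1]]
  expect_identical(augment_pair(s, ratio = 0), s)
  flipped_twice <- augment_pair(augment_pair(s, transform = "hflip"),
                                transform = "hflip")
  expect_identical(flipped_twice, s)
  for (tr in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    a <- augment_pair(s, transform = tr)
    expect_equal(sum(a$mask), sum(s$mask))
    # image and mask are transformed identically: foreground stays brighter
    expect_equal(mean(a$image[, , 1][a$mask == 1]),
                 mean(s$image[, , 1][s$mask == 1]))
  }
  # rotating four times restores the original
  r <- s
  for (i in 1:4) r <- augment_pair(r, transform = "rot90")
  expect_identical(r, s)
})

test_that("datasets round-trip through PNG folders with binary masks", {
  ds <- generate_dataset("lung_like", 3, size = 32, seed = 5)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- load_folder_dataset(file.path(dir, "images"),
                              file.path(dir, "masks"), size = 32)
  expect_length(back, 3)
  for (i in seq_along(back)) {
    expect_true(all(back[[i]]$mask %in% c(0, 1)))
    expect_equal(back[[i]]$mask, ds[[i]]$mask)
    expect_equal(dim(back[[i]]$image), c(32L, 32L, 3L))
    expect_lt(max(abs(back[[i]]$image - ds[[i]]$image)), 1 / 128)
  }
  # resizing path: load at half resolution
  half <- load_folder_dataset(file.path(dir, "images"),
                              file.path(dir, "masks"), size = 16)
  expect_equal(dim(half[[1]]$image), c(16L, 16L, 3L))
  expect_true(all(half[[1]]$mask %in% c(0, 1)))
})

test_that("grayscale images are replicated and unmatched stems rejected", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "images"))
  dir.create(file.path(dir, "masks"))
  img <- matrix(runif(32 * 32), 32, 32)
  png::writePNG(img, file.path(dir, "images", "a.png"))
  png::writePNG((img > 0.5) * 1, file.path(dir, "masks", "a.png"))
  ds <- load_folder_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                            size = 32)
  expect_equal(dim(ds[[1]]$image), c(32L, 32L, 3L))
  expect_equal(ds[[1]]$image[, , 1], ds[[1]]$image[, , 3])
  png::writePNG(img, file.path(dir, "images", "b.png"))
  expect_error(
    load_folder_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                        size = 32),
    "unmatched stems.*b", class = "prunet_unmatched_stems"
  )
})

test_that("generation scales to many small samples quickly", {
  t0 <- proc.time()[["elapsed"]]
  ds <- generate_dataset("skin_like", 1000, size = 64, seed = 99)
  expect_length(ds, 1000)
  expect_lt(proc.time()[["elapsed"]] - t0, 60)
})
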