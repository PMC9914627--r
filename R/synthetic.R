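#' Synthetic segmentation profiles
#'
#' Parameter bundles describing three families of synthetic image/mask
#' pairs that mimic the statistical character of common biomedical
#' segmentation benchmarks:
#'
#' * `skin_like` — one large irregular bright lesion on a textured,
#'   darker skin-like background (dermoscopy-style).
#' * `breast_like` — one small low-contrast dark (hypoechoic) lesion in a
#'   speckled background, ultrasound-style.
#' * `lung_like` — exactly two large smooth bright regions on a dark
#'   background, lung-CT-style.
#'
#' The `contrast` field is the declared minimum absolute difference
#' between mean foreground and mean background intensity; `polarity` is
#' +1 for bright lesions and -1 for dark ones. `fg_range` is the declared
#' range of the mask foreground fraction.
#'
#' @param name one of `"skin_like"`, `"breast_like"`, `"lung_like"`.
#' @param ... overrides for individual profile fields (profiles are
#'   configuration, not hard-coded: difficulty can be tuned).
#' @return an object of class `generator_profile`.
#' @export
generator_profile <- function(name = c("skin_like", "breast_like", "lung_like"),
                              ...) {
  name <- match.arg(name)
  base <- switch(name,
    skin_like = list(
      n_lesions = 1L, radius = 0.28, irregularity = 0.15, aspect = c(0.7, 1.3),
      fg_mean = 0.75, bg_mean = 0.35, texture = 0.06, noise_sd = 0.05,
      speckle_sd = 0, contrast = 0.25, polarity = 1, fg_range = c(0.08, 0.45)
    ),
    breast_like = list(
      n_lesions = 1L, radius = 0.16, irregularity = 0.12, aspect = c(0.7, 1.3),
      fg_mean = 0.32, bg_mean = 0.50, texture = 0.04, noise_sd = 0.02,
      speckle_sd = 0.25, contrast = 0.10, polarity = -1,
      fg_range = c(0.02, 0.25)
    ),
    lung_like = list(
      n_lesions = 2L, radius = 0.17, irregularity = 0.05, aspect = c(0.8, 1.6),
      fg_mean = 0.75, bg_mean = 0.15, texture = 0.03, noise_sd = 0.03,
      speckle_sd = 0, contrast = 0.40, polarity = 1, fg_range = c(0.10, 0.50)
    )
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  structure(c(list(name = name), base), class = "generator_profile")
}

# Rasterize one perturbed-ellipse blob. Returns a logical (size x size)
# mask. `centre` in [0,1]^2 fractional coordinates; `r0` fractional radius.
blob_mask <- function(size, centre, r0, irregularity, aspect) {
  co <- seq(0.5 / size, 1 - 0.5 / size, length.out = size)
  dx <- outer(co - centre[1], rep(1, size))
  dy <- outer(rep(1, size), co - centre[2])
  ax <- stats::runif(1, aspect[1], aspect[2])
  ay <- stats::runif(1, aspect[1], aspect[2])
  theta <- atan2(dy / ay, dx / ax)
  rr <- sqrt((dx / ax)^2 + (dy / ay)^2)
  rad <- r0
  for (k in 2:5) {
    a <- stats::rnorm(1, 0, irregularity / k)
    ph <- stats::runif(1, 0, 2 * pi)
    rad <- rad + r0 * a * cos(k * theta + ph)
  }
  rr <= pmax(rad, 0.02)
}

# Smooth random background texture: coarse normal field, bilinearly
# upsampled to full resolution.
texture_field <- function(size, amplitude, coarse = 8L) {
  n <- max(2L, size %/% coarse)
  f <- matrix(stats::rnorm(n * n), n, n)
  A <- bilinear_matrix(n, size %/% n)
  up <- A %*% f %*% t(A)
  amplitude * up[seq_len(size), seq_len(size), drop = FALSE]
}

generate_sample <- function(profile, size, channels, seed) {
  with_seed(seed, {
    # mask: retry with rescaled radius until the foreground fraction is in
    # the declared range. Two-lesion profiles confine each lesion to its
    # own half (one empty line between them), so the two regions stay
    # disconnected like the two lung fields around the mediastinum.
    two <- profile$n_lesions == 2L
    centres <- if (two) {
      list(
        c(stats::runif(1, 0.22, 0.3), stats::runif(1, 0.4, 0.6)),
        c(stats::runif(1, 0.7, 0.78), stats::runif(1, 0.4, 0.6))
      )
    } else {
      lapply(seq_len(profile$n_lesions), function(i) {
        c(stats::runif(1, 0.35, 0.65), stats::runif(1, 0.35, 0.65))
      })
    }
    half <- size %/% 2L
    clips <- if (two) list(seq_len(half - 1L), seq(half + 1L, size))
    r0 <- profile$radius
    mask <- NULL
    for (try in 1:25) {
      m <- matrix(FALSE, size, size)
      for (li in seq_along(centres)) {
        b <- blob_mask(size, centres[[li]], r0, profile$irregularity,
                       profile$aspect)
        if (two) {
          keep <- matrix(FALSE, size, size)
          keep[clips[[li]], ] <- TRUE
          b <- b & keep
        }
        m <- m | b
      }
      frac <- mean(m)
      ok_components <- !two ||
        (any(m[clips[[1L]], ]) && any(m[clips[[2L]], ]))
      if (frac >= profile$fg_range[1] && frac <= profile$fg_range[2] &&
            ok_components) {
        mask <- m
        break
      }
      r0 <- r0 * if (frac < profile$fg_range[1]) 1.2 else 0.85
    }
    if (is.null(mask)) mask <- m
    img <- matrix(profile$bg_mean, size, size) +
      texture_field(size, profile$texture)
    img[mask] <- profile$fg_mean + 0.5 * texture_field(size, profile$texture)[mask]
    if (profile$speckle_sd > 0) {
      img <- img * (1 + profile$speckle_sd * matrix(stats::rnorm(size^2), size, size))
    }
    img <- img + matrix(stats::rnorm(size^2, 0, profile$noise_sd), size, size)
    img <- pmin(pmax(img, 0), 1)
    image <- array(rep(img, channels), c(size, size, channels))
    structure(
      list(image = image, mask = matrix(as.numeric(mask), size, size),
           profile = profile$name,
           source = list(type = "synthetic", seed = seed)),
      class = "seg_sample"
    )
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Draws `n` image/mask pairs from a [generator_profile()]. Each sample
#' uses its own seed derived from `seed` and its index, so the dataset is
#' bitwise-reproducible and order-independent.
#'
#' @param profile a [generator_profile()] or a profile name.
#' @param n number of samples (>= 1).
#' @param size square image side; must be divisible by 16 so the images
#'   can be pushed through a 5-level network.
#' @param seed integer seed.
#' @param channels image channel count (default 3; the grayscale scene is
#'   replicated).
#' @return a list of `seg_sample` objects (class `seg_dataset`).
#' @export
generate_dataset <- function(profile, n, size = 256L, seed = 1L,
                             channels = 3L) {
  if (is.character(profile)) profile <- generator_profile(profile)
  stopifnot(inherits(profile, "generator_profile"), is_count(n))
  if (size %% 16L != 0L) {
    stop_prunet(
      sprintf("size must be divisible by 16 (network down-sampling); got %d",
              size),
      "prunet_bad_size"
    )
  }
  lapply(seq_len(n), function(i) {
    generate_sample(profile, size, channels, derive_seed(seed, i))
  })
}

rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]

apply_transform_mat <- function(m, transform) {
  switch(transform,
    none = m,
    hflip = m[, ncol(m):1, drop = FALSE],
    vflip = m[nrow(m):1, , drop = FALSE],
    rot90 = rot90_mat(m),
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = rot90_mat(rot90_mat(rot90_mat(m)))
  )
}

apply_transform_sample <- function(sample, transform) {
  if (transform == "none") return(sample)
  d <- dim(sample$image)
  img <- array(0, if (transform %in% c("rot90", "rot270")) {
    c(d[2], d[1], d[3])
  } else {
    d
  })
  for (cc in seq_len(d[3])) {
    img[, , cc] <- apply_transform_mat(sample$image[, , cc], transform)
  }
  sample$image <- img
  sample$mask <- apply_transform_mat(sample$mask, transform)
  sample
}

#' Randomly augment an image/mask pair
#'
#' With probability `ratio` applies one random element of \{horizontal
#' flip, vertical flip, rotation by 90/180/270 degrees\} to image and mask
#' identically; otherwise returns the sample unchanged. Uses the current
#' RNG stream.
#'
#' @param sample a `seg_sample`.
#' @param ratio application probability in `[0, 1]`.
#' @param transform optional forced transform (bypasses the random draw):
#'   one of `"hflip"`, `"vflip"`, `"rot90"`, `"rot180"`, `"rot270"`.
#' @return the (possibly transformed) `seg_sample`.
#' @export
augment_pair <- function(sample, ratio = 0.5, transform = NULL) {
  stopifnot(ratio >= 0, ratio <= 1)
  if (!is.null(transform)) {
    return(apply_transform_sample(sample, match.arg(
      transform, c("hflip", "vflip", "rot90", "rot180", "rot270")
    )))
  }
  if (ratio > 0 && stats::runif(1) <= ratio) {
    tr <- sample(c("hflip", "vflip", "rot90", "rot180", "rot270"), 1L)
    sample <- apply_transform_sample(sample, tr)
  }
  sample
}

#' Load a paired image/mask folder dataset
#'
#' Reads PNG/JPEG images and their masks, matched by file stem, resizes
#' images with bilinear interpolation and masks with nearest-neighbour,
#' and thresholds the masks to binary at half their maximum. Grayscale
#' images are replicated to `channels`; non-image files are skipped with a
#' log message; stems present on only one side abort with the full list.
#'
#' @param images_dir,masks_dir directories of image and mask files.
#' @param size target square side (divisible by 16).
#' @param channels output image channels.
#' @return a list of `seg_sample` objects.
#' @export
load_folder_dataset <- function(images_dir, masks_dir, size = 256L,
                                channels = 3L) {
  if (size %% 16L != 0L) {
    stop_prunet("size must be divisible by 16", "prunet_bad_size")
  }
  list_imgs <- function(dir) {
    all <- list.files(dir)
    ok <- grepl("\\.(png|jpe?g)$", all, ignore.case = TRUE)
    if (any(!ok)) {
      log_msg(sprintf("skipping non-image files in %s: %s", dir,
                      paste(all[!ok], collapse = ", ")))
    }
    f <- all[ok]
    stats::setNames(file.path(dir, f), sub("\\.[^.]+$", "", f))
  }
  imgs <- list_imgs(images_dir)
  msks <- list_imgs(masks_dir)
  only_i <- setdiff(names(imgs), names(msks))
  only_m <- setdiff(names(msks), names(imgs))
  if (length(only_i) || length(only_m)) {
    stop_prunet(
      sprintf(
        "unmatched stems: images without masks [%s]; masks without images [%s]",
        paste(only_i, collapse = ", "), paste(only_m, collapse = ", ")
      ),
      "prunet_unmatched_stems"
    )
  }
  # EBImage stores images x-first; transpose back to (row, column)
  t_img <- function(a) {
    if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
  }
  lapply(names(imgs), function(stem) {
    im <- EBImage::readImage(imgs[[stem]])
    im <- EBImage::resize(im, w = size, h = size)
    a <- t_img(as.array(im))
    if (length(dim(a)) == 2L) {
      a <- array(rep(a, channels), c(dim(a), channels))
    } else if (dim(a)[3] > channels) {
      a <- a[, , seq_len(channels), drop = FALSE]
    } else if (dim(a)[3] < channels) {
      a <- array(rep(a[, , 1L], channels), c(dim(a)[1:2], channels))
    }
    mk <- EBImage::readImage(msks[[stem]])
    mk <- EBImage::resize(mk, w = size, h = size, filter = "none")
    m <- t_img(as.array(mk))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    mx <- max(m)
    m <- if (mx > 0) (m >= 0.5 * mx) * 1 else m * 0
    structure(
      list(image = pmin(pmax(a, 0), 1), mask = matrix(m, size, size),
           profile = "folder", source = list(type = "file", path = imgs[[stem]])),
      class = "seg_sample"
    )
  })
}

#' Write a dataset to image/mask folders with a manifest
#'
#' Writes each sample as 8-bit PNGs under `dir/images` and `dir/masks`
#' plus a `manifest.csv` (path, split, profile, seed).
#' @param dataset a list of `seg_sample` objects.
#' @param dir output directory.
#' @param split optional character vector of split labels per sample.
#' @return the manifest data.frame, invisibly.
#' @export
write_dataset <- function(dataset, dir, split = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  split <- split %||% rep("train", length(dataset))
  rows <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    stem <- sprintf("sample_%04d", i)
    ip <- file.path(dir, "images", paste0(stem, ".png"))
    mp <- file.path(dir, "masks", paste0(stem, ".png"))
    png::writePNG(s$image, ip)
    png::writePNG(s$mask, mp)
    data.frame(
      path = ip, mask = mp, split = split[i], profile = s$profile,
      seed = if (identical(s$source$type, "synthetic")) s$source$seed else NA,
      stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
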