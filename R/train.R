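#' Training configuration
#'
#' Defaults follow the common protocol for this model family: ADAM with
#' learning rate 2e-4 and weight decay 1e-4, Dice loss on probabilities,
#' data-augmentation probability 0.5 per sample, 200 epochs, binarization
#' threshold 0.5. Desk-scale overrides (fewer epochs, smaller batches) are
#' recorded verbatim in the run manifest.
#'
#' @param learning_rate ADAM step size.
#' @param weight_decay L2 penalty added to the gradient.
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param augmentation_ratio per-sample probability of applying a random
#'   flip/right-angle rotation during training.
#' @param threshold binarization threshold for evaluation.
#' @param dice_eps smoothing constant of the Dice loss.
#' @param seed integer seed controlling shuffling and augmentation.
#' @param deterministic logical; seed the full training loop so repeated
#'   runs are bitwise identical.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, weight_decay = 1e-4,
                         epochs = 200L, batch_size = 8L,
                         augmentation_ratio = 0.5, threshold = 0.5,
                         dice_eps = 1, seed = 1L, deterministic = TRUE) {
  stopifnot(learning_rate > 0, weight_decay >= 0, epochs >= 0,
            is_count(batch_size), augmentation_ratio >= 0,
            augmentation_ratio <= 1, threshold > 0, threshold < 1)
  structure(
    list(
      learning_rate = learning_rate, weight_decay = weight_decay,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      augmentation_ratio = augmentation_ratio, threshold = threshold,
      dice_eps = dice_eps, seed = as.integer(seed),
      deterministic = isTRUE(deterministic)
    ),
    class = "train_config"
  )
}

#' k-fold cross-validation split
#'
#' Partitions `1..n` into `k` disjoint validation index sets whose sizes
#' differ by at most one; deterministic given `seed`.
#' @param n number of samples (`n >= k`).
#' @param k number of folds (`k >= 2`).
#' @param seed integer seed.
#' @return a list of `k` integer vectors.
#' @export
kfold_split <- function(n, k, seed = 1L) {
  stopifnot(is_count(n), is_count(k), k >= 2)
  if (n < k) {
    stop_prunet(sprintf("cannot split %d samples into %d folds", n, k),
                "prunet_bad_split")
  }
  perm <- with_seed(derive_seed(seed, 17L), sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  unname(split(perm, rep(seq_len(k), times = sizes)))
}

# ADAM update; state carries first/second moments and the step counter.
adam_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (wd > 0) g <- g + wd * params[[nm]]
    m <- beta1 * state$m[[nm]] + (1 - beta1) * g
    v <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}

# Mean per-image soft Dice loss over a batch plus its gradient wrt the
# probability tensor (H, W, B, 1).
batch_dice <- function(prob, y, eps) {
  B <- dim(prob)[3]
  loss <- 0
  grad <- array(0, dim(prob))
  for (b in seq_len(B)) {
    p <- prob[, , b, 1L]
    g <- y[, , b]
    loss <- loss + as.numeric(soft_dice_loss(p, g, eps))
    grad[, , b, 1L] <- soft_dice_grad(p, g, eps) / B
  }
  list(loss = loss / B, grad = grad)
}

#' Train a model
#'
#' Optimizes the soft Dice loss with ADAM under a [train_config()]. Every
#' epoch shuffles the training set, applies per-sample augmentation, and
#' records the mean training loss; when `valid` samples are given, Dice
#' and pixel accuracy on them are traced each epoch as well. Fully
#' reproducible when `config$deterministic` is set. A non-finite loss
#' aborts with a diagnostic.
#'
#' @param model an [assemble_model()] result.
#' @param samples non-empty list of `seg_sample` training pairs.
#' @param config a [train_config()].
#' @param valid optional list of validation `seg_sample`s.
#' @return list with `model` (trained) and `history` (class
#'   `train_history`: data.frame with epoch, loss, optional valid_dice and
#'   valid_acc, and wall-clock time stamps).
#' @export
train_model <- function(model, samples, config = train_config(),
                        valid = NULL) {
  stopifnot(inherits(model, "model_graph"), length(samples) >= 1L,
            inherits(config, "train_config"))
  if (config$epochs == 0L) {
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       elapsed = numeric())
    class(hist) <- c("train_history", class(hist))
    return(list(model = model, history = hist))
  }
  run <- function() {
    state <- list(
      t = 0L,
      m = lapply(model$params, function(p) array(0, dim(p) %||% length(p))),
      v = lapply(model$params, function(p) array(0, dim(p) %||% length(p)))
    )
    n <- length(samples)
    bs <- min(config$batch_size, n)
    hist <- vector("list", config$epochs)
    t0 <- proc.time()[["elapsed"]]
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        batch <- lapply(samples[idx], augment_pair,
                        ratio = config$augmentation_ratio)
        xy <- batch_from_samples(batch)
        fw <- model_forward(model, xy$x, training = TRUE, keep_cache = TRUE)
        model <- fw$model
        dl <- batch_dice(fw$out, xy$y, config$dice_eps)
        if (!is.finite(dl$loss)) {
          stop_prunet(
            sprintf("training diverged: non-finite loss at epoch %d", ep),
            "prunet_divergence"
          )
        }
        grads <- model_backward(model, fw, dl$grad)
        upd <- adam_step(model$params, grads, state,
                         config$learning_rate, config$weight_decay)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + dl$loss
        nb <- nb + 1L
      }
      row <- data.frame(epoch = ep, loss = ep_loss / nb,
                        elapsed = proc.time()[["elapsed"]] - t0)
      if (!is.null(valid)) {
        vm <- evaluate_model(model, valid, config$threshold)
        row$valid_dice <- vm$aggregate$DC[vm$aggregate$scope == "per_image_mean"]
        row$valid_acc <- vm$aggregate$ACC[vm$aggregate$scope == "per_image_mean"]
      }
      hist[[ep]] <- row
    }
    list(model = model, history = do.call(rbind, hist))
  }
  out <- if (config$deterministic) {
    with_seed(derive_seed(config$seed, 23L), run())
  } else {
    run()
  }
  class(out$history) <- c("train_history", class(out$history))
  out
}

#' Evaluate a model on labelled samples
#'
#' Forward pass, binarization at `threshold`, per-image metrics, and both
#' aggregation scopes (per-image mean and pooled global counts).
#' @param model a trained [assemble_model()] result.
#' @param samples non-empty list of `seg_sample`s.
#' @param threshold binarization threshold.
#' @param batch_size evaluation batch size.
#' @return list with `per_image` (one [metric_record()] row per sample)
#'   and `aggregate` (see [aggregate_metrics()]).
#' @export
evaluate_model <- function(model, samples, threshold = 0.5, batch_size = 8L) {
  stopifnot(length(samples) >= 1L)
  rows <- list()
  for (start in seq(1L, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(samples))
    xy <- batch_from_samples(samples[idx])
    prob <- model_forward(model, xy$x, training = FALSE)$out
    for (j in seq_along(idx)) {
      sr <- binarize(prob[, , j, 1L], threshold)
      rows[[length(rows) + 1L]] <- metric_record(sr, xy$y[, , j])
    }
  }
  per_image <- do.call(rbind, rows)
  list(per_image = per_image, aggregate = aggregate_metrics(per_image))
}

#' k-fold cross-validation of one architecture
#'
#' Runs one train/evaluate cycle per fold with disjoint validation data
#' (folds are shared across variants given the same `n`, `k` and seed)
#' and reports the conventional fold table: one row per fold plus an
#' `Average` row equal to the arithmetic mean of the fold rows.
#'
#' @param arch an [arch_config()].
#' @param dataset list of `seg_sample`s (length >= k).
#' @param k number of folds.
#' @param config a [train_config()].
#' @return list of class `cv_result`: `table` (fold rows + Average, using
#'   per-image-mean metrics), `global_table` (same, pooled-count scope),
#'   `folds` (index sets), `histories` (per-fold `train_history`).
#' @export
cross_validate <- function(arch, dataset, k = 5L, config = train_config()) {
  stopifnot(inherits(arch, "arch_config"), length(dataset) >= k)
  folds <- kfold_split(length(dataset), k, config$seed)
  rows <- list()
  grows <- list()
  histories <- list()
  for (f in seq_len(k)) {
    vidx <- folds[[f]]
    tidx <- setdiff(seq_along(dataset), vidx)
    model <- assemble_model(arch, seed = derive_seed(config$seed, 100L + f))
    fit_cfg <- config
    fit_cfg$seed <- as.integer(derive_seed(config$seed, 200L + f))
    fit <- train_model(model, dataset[tidx], fit_cfg)
    ev <- evaluate_model(fit$model, dataset[vidx], config$threshold)
    agg <- ev$aggregate
    mrow <- agg[agg$scope == "per_image_mean",
                c("ACC", "PRE", "SE", "F1", "JS", "DC")]
    growvals <- agg[agg$scope == "global",
                    c("ACC", "PRE", "SE", "F1", "JS", "DC")]
    rows[[f]] <- cbind(data.frame(fold = sprintf("%d-fold", f)), mrow)
    grows[[f]] <- cbind(data.frame(fold = sprintf("%d-fold", f)), growvals)
    histories[[f]] <- fit$history
  }
  finish <- function(rws) {
    tab <- do.call(rbind, rws)
    avg <- cbind(
      data.frame(fold = "Average"),
      as.data.frame(as.list(colMeans(tab[, -1L])))
    )
    rownames(tab) <- NULL
    rbind(tab, avg)
  }
  structure(
    list(table = finish(rows), global_table = finish(grows), folds = folds,
         histories = histories, arch = arch, config = config),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s%s, %d folds (per-image-mean scope)\n",
              x$arch$variant, if (x$arch$attention) "+cbam" else "",
              length(x$folds)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a run manifest
#'
#' Records the command, resolved configuration, seeds, convention set,
#' timestamps, a content hash of the dataset and the output paths of a
#' run as JSON, so every artifact on disk is reachable from a manifest.
#' @param path output JSON path.
#' @param command character label of the command that produced the run.
#' @param arch optional [arch_config()].
#' @param config optional [train_config()].
#' @param dataset optional dataset (hashed).
#' @param outputs named list/character vector of artifact paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, arch = NULL, config = NULL,
                               dataset = NULL, outputs = list()) {
  manifest <- list(
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    arch = if (!is.null(arch)) {
      x <- unclass(arch)
      x$conventions <- unclass(x$conventions)
      x
    },
    train_config = if (!is.null(config)) unclass(config),
    dataset_hash = if (!is.null(dataset)) dataset_hash(dataset),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# Cheap content hash (sum-based) of a dataset, stable across sessions.
dataset_hash <- function(dataset) {
  acc <- 0
  for (s in dataset) {
    acc <- (acc + sum(s$image) * 1e3 + sum(s$mask)) %% 1e9
  }
  sprintf("%s-n%d-%.6f", "sum", length(dataset), acc)
}
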