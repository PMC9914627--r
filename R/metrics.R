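#' Soft Dice loss
#'
#' Training objective for binary segmentation: `1 - (2 * sum(p * g) +
#' eps) / (sum(p) + sum(g) + eps)`, computed on predicted probabilities
#' (not binarized maps) so that it stays differentiable. The smoothing
#' term `eps` guards the empty-mask case.
#'
#' @param probabilities numeric array of predicted foreground
#'   probabilities in (0, 1).
#' @param gt binary ground-truth mask of the same shape.
#' @param eps smoothing constant (default 1).
#' @return a scalar in `[0, 1)` with attribute `eps`.
#' @export
soft_dice_loss <- function(probabilities, gt, eps = 1) {
  if (!identical(dim(probabilities) %||% length(probabilities),
                 dim(gt) %||% length(gt))) {
    stop_prunet("probability map and ground truth differ in shape",
                "prunet_shape_mismatch")
  }
  if (!all(gt %in% c(0, 1))) {
    stop_prunet("ground truth must be binary", "prunet_not_binary")
  }
  inter <- sum(probabilities * gt)
  loss <- 1 - (2 * inter + eps) / (sum(probabilities) + sum(gt) + eps)
  structure(loss, eps = eps)
}

# Gradient of the per-image soft Dice loss wrt the probabilities.
soft_dice_grad <- function(probabilities, gt, eps = 1) {
  inter <- sum(probabilities * gt)
  denom <- sum(probabilities) + sum(gt) + eps
  -(2 * gt * denom - (2 * inter + eps)) / denom^2
}

#' Binarize a probability map
#'
#' A pixel is foreground iff its probability is greater than or equal to
#' the threshold (the boundary case `p == threshold` maps to 1).
#' Raising the threshold never adds foreground pixels.
#'
#' @param prob_map numeric array of probabilities.
#' @param threshold scalar in (0, 1), default 0.5.
#' @return an integer 0/1 array of the same shape.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  stopifnot(length(threshold) == 1L, threshold > 0, threshold < 1)
  out <- (prob_map >= threshold) * 1L
  dim(out) <- dim(prob_map)
  out
}

#' Pixel confusion counts
#'
#' Exact TP/FP/TN/FN pixel tallies between a predicted binary mask `SR`
#' and the ground truth `GT`.
#' @param sr,gt binary arrays of the same shape.
#' @return a list of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(sr, gt) {
  if (!identical(dim(sr) %||% length(sr), dim(gt) %||% length(gt))) {
    stop_prunet("masks differ in shape", "prunet_shape_mismatch")
  }
  if (!all(sr %in% c(0, 1)) || !all(gt %in% c(0, 1))) {
    stop_prunet("confusion counts need binary masks", "prunet_not_binary")
  }
  tp <- sum(sr == 1 & gt == 1)
  fp <- sum(sr == 1 & gt == 0)
  fn <- sum(sr == 0 & gt == 1)
  tn <- sum(sr == 0 & gt == 0)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
            class = "confusion_counts")
}

ratio0 <- function(num, den, what) {
  if (den == 0) {
    log_msg(sprintf("%s undefined (0/0); returning 0", what))
    return(0)
  }
  num / den
}

#' Pixel-level classification metrics
#'
#' Accuracy, sensitivity (recall), precision and F1 score from confusion
#' counts. Undefined 0/0 ratios return 0 with a logged note.
#' @param counts a [confusion_counts()] result.
#' @return named numeric vector `ACC`, `SE`, `PRE`, `F1`.
#' @export
pixel_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  stopifnot(total > 0)
  acc <- (counts$TP + counts$TN) / total
  se <- ratio0(counts$TP, counts$TP + counts$FN, "sensitivity")
  pre <- ratio0(counts$TP, counts$TP + counts$FP, "precision")
  f1 <- if (pre + se > 0) 2 * pre * se / (pre + se) else {
    log_msg("F1 undefined (PRE+SE = 0); returning 0")
    0
  }
  c(ACC = acc, SE = se, PRE = pre, F1 = f1)
}

#' Overlap metrics
#'
#' Jaccard similarity `|GT n SR| / |GT u SR|` and Dice coefficient
#' `2 |GT n SR| / (|GT| + |SR|)`. Two empty masks are in perfect
#' agreement: both metrics return 1 in that case.
#' @param sr,gt binary arrays of the same shape.
#' @return named numeric vector `JS`, `DC`.
#' @export
overlap_metrics <- function(sr, gt) {
  cc <- confusion_counts(sr, gt)
  inter <- cc$TP
  union <- cc$TP + cc$FP + cc$FN
  size_sum <- 2 * cc$TP + cc$FP + cc$FN
  if (union == 0) return(c(JS = 1, DC = 1))
  c(JS = inter / union, DC = 2 * inter / size_sum)
}

#' Per-image metric record
#'
#' All six indicators for one predicted/true mask pair.
#' @param sr,gt binary arrays of the same shape.
#' @return a one-row data.frame `ACC`, `PRE`, `SE`, `F1`, `JS`, `DC` plus
#'   the confusion counts.
#' @export
metric_record <- function(sr, gt) {
  cc <- confusion_counts(sr, gt)
  pm <- pixel_metrics(cc)
  om <- overlap_metrics(sr, gt)
  data.frame(
    ACC = pm[["ACC"]], PRE = pm[["PRE"]], SE = pm[["SE"]], F1 = pm[["F1"]],
    JS = om[["JS"]], DC = om[["DC"]],
    TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN
  )
}

#' Aggregate per-image metrics
#'
#' Two aggregation scopes are always computed: `per_image_mean` (the
#' arithmetic mean of the per-image metrics) and `global` (metrics
#' recomputed from the pooled confusion counts of all images). The two
#' differ whenever image sizes or prevalence differ, so both are
#' reported.
#' @param records a data.frame of [metric_record()] rows.
#' @return a data.frame with one row per scope.
#' @export
aggregate_metrics <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_prunet("need a non-empty data.frame of metric records",
                "prunet_empty_records")
  }
  cols <- c("ACC", "PRE", "SE", "F1", "JS", "DC")
  mean_row <- as.data.frame(as.list(colMeans(records[cols])))
  pooled <- structure(
    list(TP = sum(records$TP), FP = sum(records$FP),
         TN = sum(records$TN), FN = sum(records$FN)),
    class = "confusion_counts"
  )
  pm <- pixel_metrics(pooled)
  union <- pooled$TP + pooled$FP + pooled$FN
  js <- if (union == 0) 1 else pooled$TP / union
  dc <- if (union == 0) 1 else 2 * pooled$TP / (2 * pooled$TP + pooled$FP + pooled$FN)
  global_row <- data.frame(
    ACC = pm[["ACC"]], PRE = pm[["PRE"]], SE = pm[["SE"]], F1 = pm[["F1"]],
    JS = js, DC = dc
  )
  out <- rbind(mean_row, global_row)
  out$scope <- c("per_image_mean", "global")
  out[c("scope", cols)]
}

#' Write a metric table
#'
#' Writes a fold-by-fold metric table as CSV and/or JSON using the
#' conventional column order ACC, PRE, SE, F1-Score, JS, DC.
#' @param table a data.frame with a `fold` column and the six metrics.
#' @param csv,json optional output paths.
#' @return the table with columns reordered, invisibly.
#' @export
write_metric_table <- function(table, csv = NULL, json = NULL) {
  cols <- c("fold", "ACC", "PRE", "SE", "F1", "JS", "DC")
  extra <- setdiff(names(table), cols)
  out <- table[c(intersect(cols, names(table)), extra)]
  names(out)[names(out) == "F1"] <- "F1-Score"
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(out, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(out)
}
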