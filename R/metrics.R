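# Segmentation metrics: pixel confusion counts, overall/average accuracy,
# Dice, Jaccard, the Dice<->Jaccard single-trial identity, the 95th-percentile
# Hausdorff boundary distance, and fold-level aggregation.

check_binary_pair <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("masks must share a shape")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary {0,1}")
}

#' Pixel confusion counts
#'
#' @param pred,truth binary H x W masks (1 = tumor)
#' @return list with `TP`, `TN`, `FP`, `FN`
#' @export
confusion_counts <- function(pred, truth) {
  check_binary_pair(pred, truth)
  list(TP = sum(pred == 1 & truth == 1),
       TN = sum(pred == 0 & truth == 0),
       FP = sum(pred == 1 & truth == 0),
       FN = sum(pred == 0 & truth == 1))
}

as_counts <- function(pred, truth) {
  if (is.list(pred) && all(c("TP", "TN", "FP", "FN") %in% names(pred))) pred
  else confusion_counts(pred, truth)
}

#' Overall accuracy
#' @param pred binary mask or a confusion-counts list
#' @param truth binary mask (ignored when `pred` is a counts list)
#' @return fraction in `[0, 1]`
#' @export
metric_oa <- function(pred, truth = NULL) {
  k <- as_counts(pred, truth)
  (k$TP + k$TN) / (k$TP + k$TN + k$FP + k$FN)
}

#' Average (class-balanced) accuracy
#'
#' Mean of tumor recall and background recall; `NA` with a warning when a
#' class is absent from the ground truth.
#' @inheritParams metric_oa
#' @export
metric_aa <- function(pred, truth = NULL) {
  k <- as_counts(pred, truth)
  if (k$TP + k$FN == 0 || k$FP + k$TN == 0) {
    warning("average accuracy undefined: a class is absent from the truth")
    return(NA_real_)
  }
  0.5 * (k$TP / (k$TP + k$FN) + k$TN / (k$FP + k$TN))
}

#' Dice similarity coefficient
#' @inheritParams metric_oa
#' @export
metric_dsc <- function(pred, truth = NULL) {
  k <- as_counts(pred, truth)
  den <- 2 * k$TP + k$FP + k$FN
  if (den == 0) {
    warning("DSC undefined: both masks are empty")
    return(NA_real_)
  }
  2 * k$TP / den
}

#' Jaccard index
#' @inheritParams metric_oa
#' @export
metric_jaccard <- function(pred, truth = NULL) {
  k <- as_counts(pred, truth)
  den <- k$TP + k$FP + k$FN
  if (den == 0) {
    warning("Jaccard undefined: both masks are empty")
    return(NA_real_)
  }
  k$TP / den
}

#' Dice from Jaccard (single-trial identity)
#'
#' `DSC = 2 J / (1 + J)`. Holds per image; does not commute with averaging
#' across folds.
#'
#' @param j Jaccard index value(s)
#' @return Dice value(s)
#' @export
dsc_from_jaccard <- function(j) 2 * j / (1 + j)

# boundary pixels: mask minus its 4-connectivity erosion (zero-padded)
boundary_pixels <- function(mask) {
  m <- mask == 1
  H <- nrow(m); W <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-H, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -W, drop = FALSE])
  interior <- m & up & dn & lf & rt
  which(m & !interior, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance
#'
#' Boundary pixels are extracted by 4-connectivity erosion; the directed
#' nearest-boundary distances of both directions are pooled and the 95th
#' percentile reported, in Euclidean pixel units. Symmetric by construction.
#' An empty mask makes the distance undefined (`NA` with a warning).
#'
#' @param pred,truth binary H x W masks
#' @return distance in pixels, or `NA`
#' @export
metric_hd95 <- function(pred, truth) {
  check_binary_pair(pred, truth)
  if (sum(pred) == 0 || sum(truth) == 0) {
    warning("HD95 undefined for an empty mask")
    return(NA_real_)
  }
  a <- boundary_pixels(pred)
  b <- boundary_pixels(truth)
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  d_ab <- sqrt(apply(d2, 1, min))
  d_ba <- sqrt(apply(d2, 2, min))
  unname(stats::quantile(c(d_ab, d_ba), 0.95))
}

#' Per-image metrics report
#'
#' @param pred,truth binary masks
#' @return one-row data frame with OA, AA, DSC, Jaccard, HD95
#' @export
metrics_report <- function(pred, truth) {
  k <- confusion_counts(pred, truth)
  data.frame(OA = metric_oa(k), AA = suppressWarnings(metric_aa(k)),
             DSC = suppressWarnings(metric_dsc(k)),
             Jaccard = suppressWarnings(metric_jaccard(k)),
             HD95 = suppressWarnings(metric_hd95(pred, truth)))
}

#' Evaluate a model on a sample list
#'
#' @param model a `semiseg_model`
#' @param samples list of `image_sample` with masks
#' @param params optional parameter override (e.g. best checkpoint values)
#' @return data frame of per-image metrics with an `id` column
#' @export
evaluate_samples <- function(model, samples, params = model$params) {
  do.call(rbind, lapply(samples, function(s) {
    pred <- predict_mask(model, s$image, params = params)
    cbind(data.frame(id = s$id), metrics_report(pred, s$mask))
  }))
}

#' Aggregate per-fold (or per-image) metric reports
#'
#' Means and standard deviations per metric column, excluding undefined
#' (`NA`) entries. Note that because Dice is a concave function of Jaccard,
#' the mean DSC across folds is generally not `dsc_from_jaccard(mean J)`.
#'
#' @param reports data frame with metric columns (and optionally `id`/`fold`)
#' @return data frame with `metric`, `mean`, `sd`, `n`
#' @export
aggregate_reports <- function(reports) {
  cols <- intersect(c("OA", "AA", "DSC", "Jaccard", "HD95"), names(reports))
  if (length(cols) == 0L) stop("no metric columns found")
  do.call(rbind, lapply(cols, function(cl) {
    v <- reports[[cl]]
    v <- v[!is.na(v)]
    data.frame(metric = cl, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  }))
}
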