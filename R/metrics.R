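# Segmentation evaluation.
#
# Pixel-overlap metrics (Dice, IoU) and the region-tolerant scores
# (aRec, aPrec, aF1) designed for weakly annotated lesions: a ground
# truth region counts as detected (TPC) as soon as the prediction
# touches it with at least one pixel, while precision stays pixel-exact
# (true-positive area over total predicted-positive area). Metrics that
# would divide by zero return NA and are excluded from aggregates.

.as_binary <- function(x, what = "mask") {
  if (is.logical(x)) x <- x * 1L
  ux <- unique(as.vector(x))
  if (!all(ux %in% c(0, 1))) {
    stop(sprintf("%s must be binary (0/1); found other values", what))
  }
  x
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}

#' Dice coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks score 1 by
#' convention (perfect agreement on "nothing to segment").
#'
#' @param a,b 0/1 matrices of identical shape.
#' @return Dice in `[0, 1]`.
#' @export
dice_coef <- function(a, b) {
  a <- .as_binary(a); b <- .as_binary(b)
  .check_same_shape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Intersection over union (Jaccard) of two binary masks
#'
#' `|A intersect B| / |A union B|`; two empty masks score 1.
#'
#' @inheritParams dice_coef
#' @return IoU in `[0, 1]`.
#' @export
iou_coef <- function(a, b) {
  a <- .as_binary(a); b <- .as_binary(b)
  .check_same_shape(a, b)
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Harmonic mean of region recall and pixel precision
#'
#' `aF1 = 2 * aRec * aPrec / (aRec + aPrec)`; returns 0 when both are 0
#' and NA when either input is NA.
#'
#' @param aprec pixel precision in `[0, 1]`.
#' @param arec region recall in `[0, 1]`.
#' @return aF1 in `[0, 1]`, or NA.
#' @export
adapted_f1 <- function(aprec, arec) {
  if (is.na(aprec) || is.na(arec)) return(NA_real_)
  if (aprec == 0 && arec == 0) return(0)
  2 * arec * aprec / (arec + aprec)
}

#' Connected annotated regions of a ground-truth mask
#'
#' Decomposes the foreground into connected components under 4- or
#' 8-connectivity. Labeling is deterministic: components are numbered by
#' their smallest linear (column-major) pixel index.
#'
#' @param gt 0/1 matrix.
#' @param connectivity 4 or 8 (default 8: lesions annotated as loose
#'   strokes often touch only diagonally).
#' @return object of class `lesion_regions`: list with `regions` (list
#'   of integer vectors of linear pixel indices), `n`, `dim` and
#'   `connectivity`.
#' @export
extract_regions <- function(gt, connectivity = 8) {
  gt <- .as_binary(gt, "ground truth")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- label_components(gt, connectivity)
  n <- max(lab)
  regions <- if (n > 0) split(which(lab > 0), lab[lab > 0]) else list()
  regions <- unname(regions)
  structure(list(regions = regions, n = n, dim = dim(gt),
                 connectivity = connectivity),
            class = "lesion_regions")
}

#' Label connected components of a binary matrix
#'
#' Iterative frontier-expansion flood fill; component ids are assigned
#' in increasing order of each component's smallest column-major pixel
#' index, which makes the labeling deterministic.
#'
#' @inheritParams extract_regions
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(gt, connectivity = 8) {
  gt <- .as_binary(gt, "mask")
  h <- nrow(gt); w <- ncol(gt)
  lab <- matrix(0L, h, w)
  fg <- which(gt == 1)
  if (!length(fg)) return(lab)
  # neighbor offsets in linear (column-major) indexing, with row guards
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1L, -1L), c(1L, -1L), c(-1L, 1L), c(1L, 1L)))
  }
  nextid <- 0L
  unvisited <- logical(h * w)
  unvisited[fg] <- TRUE
  for (s in fg) {
    if (!unvisited[s]) next
    nextid <- nextid + 1L
    frontier <- s
    unvisited[s] <- FALSE
    while (length(frontier)) {
      lab[frontier] <- nextid
      rows <- ((frontier - 1L) %% h) + 1L
      nbrs <- integer(0)
      for (o in offs) {
        ok <- rows + o[1] >= 1L & rows + o[1] <= h
        cand <- frontier[ok] + o[1] + o[2] * h
        cand <- cand[cand >= 1L & cand <= h * w]
        nbrs <- c(nbrs, cand)
      }
      nbrs <- unique(nbrs[unvisited[nbrs]])
      unvisited[nbrs] <- FALSE
      frontier <- nbrs
    }
  }
  lab
}

#' Region-tolerant scores of a prediction against annotated regions
#'
#' For ground-truth regions AK_1..AK_N, `TPC_i = 1` iff the prediction
#' intersects AK_i in at least one pixel; `TPC = sum TPC_i`;
#' `aRec = TPC / N`; `aPrec = |AK_area intersect AK_pred| / |AK_pred|`
#' (true-positive area over total predicted-positive area); aF1 is their
#' harmonic mean. `aRec` is NA when N = 0, `aPrec` is NA when the
#' prediction is empty, and aF1 is NA when either is.
#'
#' @param gt_regions a `lesion_regions` from [extract_regions()] on `gt`.
#' @param pred 0/1 predicted mask.
#' @param gt 0/1 ground-truth mask the regions were extracted from.
#' @return object of class `metrics_report`: list with `dice`, `iou`,
#'   `aprec`, `arec`, `af1`, pixel counts `tp`, `fp`, `fn`, region
#'   counts `tpc`, `n_regions`.
#' @export
adapted_scores <- function(gt_regions, pred, gt) {
  stopifnot(inherits(gt_regions, "lesion_regions"))
  pred <- .as_binary(pred, "prediction")
  gt <- .as_binary(gt, "ground truth")
  .check_same_shape(pred, gt)
  if (!identical(dim(gt), gt_regions$dim)) {
    stop("gt_regions were extracted from a mask of a different shape")
  }
  reg_px <- unlist(gt_regions$regions)
  if (length(reg_px) && !all(gt[reg_px] == 1)) {
    stop("gt_regions are inconsistent with the ground-truth mask")
  }
  tp <- sum(pred * gt)
  fp <- sum(pred * (1 - gt))
  fn <- sum((1 - pred) * gt)
  pred_area <- tp + fp
  n <- gt_regions$n
  tpc <- if (n > 0) sum(vapply(gt_regions$regions,
                               function(px) any(pred[px] == 1), logical(1))) else 0L
  arec <- if (n > 0) tpc / n else NA_real_
  aprec <- if (pred_area > 0) tp / pred_area else NA_real_
  structure(list(dice = dice_coef(pred, gt), iou = iou_coef(pred, gt),
                 aprec = aprec, arec = arec, af1 = adapted_f1(aprec, arec),
                 tp = tp, fp = fp, fn = fn,
                 tpc = as.integer(tpc), n_regions = as.integer(n)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("Dice %s | IoU %s | aPrec %s | aRec %s | aF1 %s (TPC %d/%d)\n",
              fmt(x$dice), fmt(x$iou), fmt(x$aprec), fmt(x$arec), fmt(x$af1),
              x$tpc, x$n_regions))
  invisible(x)
}

#' Binarize a probability map and compute all metrics
#'
#' @param pred_prob numeric probability matrix in `[0, 1]`.
#' @param gt 0/1 ground-truth matrix of the same shape.
#' @param threshold binarization cut in `[0, 1]`.
#' @param connectivity region connectivity for the adapted scores.
#' @return a `metrics_report` (see [adapted_scores()]).
#' @export
evaluate_pair <- function(pred_prob, gt, threshold = 0.5, connectivity = 8) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  .check_same_shape(pred_prob, gt)
  pred <- binarize_prob(pred_prob, threshold)
  adapted_scores(extract_regions(gt, connectivity), pred, gt)
}

#' Aggregate per-crop metric reports
#'
#' Unweighted mean of each metric over the reports where it is defined;
#' the number of excluded (undefined) entries is reported per metric so
#' batch averaging never divides by zero silently.
#'
#' @param reports list of `metrics_report` objects.
#' @return data.frame with one row per metric: `metric`, `mean`, `n`,
#'   `n_excluded`.
#' @export
aggregate_metrics <- function(reports) {
  mets <- c("dice", "iou", "aprec", "arec", "af1")
  do.call(rbind, lapply(mets, function(m) {
    v <- vapply(reports, function(r) r[[m]] %||% NA_real_, numeric(1))
    data.frame(metric = m,
               mean = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
               n = sum(!is.na(v)), n_excluded = sum(is.na(v)))
  }))
}
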