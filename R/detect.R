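#' Frame-level detection series from a mask stack
#'
#' A frame counts as a detection when its mask area reaches `min_area_px`;
#' runs of consecutive detections shorter than `min_run` are cleared (they
#' typically come from the structure clipping the imaging plane for too few
#' frames to be reliable). Cleared and absent frames report area 0 and an
#' undefined depth centroid.
#'
#' @param mask_stack list of logical matrices, ordered along one sweep.
#' @param min_area_px minimum mask area in pixels (default 30 at 128x128).
#' @param min_run minimum run length of consecutive detections (default 3).
#' @return A `detection_series`: list(present, area, depth_centroid,
#'   n_frames); `depth_centroid` is the mean mask row position normalized
#'   to `[0,1]` (0 = near field / anterior).
#' @export
detect_series <- function(mask_stack, min_area_px = 30, min_run = 3) {
  n <- length(mask_stack)
  area <- vapply(mask_stack, sum, numeric(1))
  present <- area >= max(min_area_px, 1)
  if (min_run > 1 && any(present)) {
    r <- rle(present)
    r$values[r$values & r$lengths < min_run] <- FALSE
    present <- inverse.rle(r)
  }
  area[!present] <- 0
  centroid <- rep(NA_real_, n)
  for (i in which(present)) {
    m <- mask_stack[[i]]
    rows <- row(m)[m]
    centroid[i] <- (mean(rows) - 0.5) / nrow(m)
  }
  structure(list(present = present, area = area, depth_centroid = centroid,
                 n_frames = n),
            class = "detection_series")
}

#' Detection and segmentation metrics for aligned mask stacks
#'
#' Frame-level presence is cross-tabulated into sensitivity, specificity,
#' accuracy, PPV and NPV; pixel-level Jaccard and Dice are averaged over
#' the frames where the reference contains the structure, and the area
#' error is the mean over those frames of |predicted - true| / true areas,
#' in percent.
#'
#' @param pred_masks,truth_masks equal-length lists of logical matrices.
#' @return list with detection counts and rates, `jaccard`, `dice`,
#'   `pixel_accuracy`, `area_error_pct`, and `pixel_metrics_defined`
#'   (FALSE when the reference has no structure-present frame).
#' @export
segmentation_metrics <- function(pred_masks, truth_masks) {
  if (length(pred_masks) != length(truth_masks))
    stop("mask stacks must be aligned", call. = FALSE)
  pa <- vapply(pred_masks, sum, numeric(1))
  ta <- vapply(truth_masks, sum, numeric(1))
  pp <- pa > 0; tp_frames <- ta > 0
  TP <- sum(pp & tp_frames); FN <- sum(!pp & tp_frames)
  FP <- sum(pp & !tp_frames); TN <- sum(!pp & !tp_frames)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  pix_acc <- mean(vapply(seq_along(pred_masks), function(i)
    mean((pred_masks[[i]] != 0) == (truth_masks[[i]] != 0)), numeric(1)))
  roi <- which(tp_frames)
  if (length(roi)) {
    jd <- vapply(roi, function(i) {
      p <- pred_masks[[i]] != 0; t <- truth_masks[[i]] != 0
      inter <- sum(p & t); uni <- sum(p | t)
      if (uni == 0) 1 else inter / uni
    }, numeric(1))
    jac <- mean(jd)
    dice <- mean(2 * jd / (1 + jd))
    aerr <- mean(abs(pa[roi] - ta[roi]) / ta[roi]) * 100
    defined <- TRUE
  } else {
    jac <- dice <- aerr <- NA_real_
    defined <- FALSE
  }
  list(tp = TP, fn = FN, fp = FP, tn = TN,
       sensitivity = rate(TP, TP + FN), specificity = rate(TN, TN + FP),
       accuracy = rate(TP + TN, TP + TN + FP + FN),
       ppv = rate(TP, TP + FP), npv = rate(TN, TN + FN),
       jaccard = jac, dice = dice, pixel_accuracy = pix_acc,
       area_error_pct = aerr, pixel_metrics_defined = defined)
}
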