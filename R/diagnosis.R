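#' Classifier parameters for the score-based diagnosis
#'
#' All decision thresholds of the diagnosis stage in one place, so the
#' rule set can be substituted without touching code.
#'
#' @param presentation_threshold axial centroid below which the head map is
#'   called cephalic (head toward the pelvis).
#' @param fundal_axial_threshold placenta-map axial centroid at or above
#'   which the placenta is called fundal, before any depth reasoning
#'   (fundal implantation straddles both walls).
#' @param depth_anterior_max maximum within-frame depth centroid for an
#'   anterior call.
#' @param depth_posterior_min minimum depth centroid for a posterior call.
#' @param low_axial_threshold axial centroid at or below which the
#'   low-placenta (previa-suspect) referral flag is raised.
#' @param min_total_mass map mass below which the result is indeterminate.
#' @return A `classifier_params`.
#' @export
classifier_params <- function(presentation_threshold = 0.5,
                              fundal_axial_threshold = 0.75,
                              depth_anterior_max = 0.45,
                              depth_posterior_min = 0.55,
                              low_axial_threshold = 0.10,
                              min_total_mass = 1e-8) {
  thr <- c(presentation_threshold, fundal_axial_threshold,
           depth_anterior_max, depth_posterior_min, low_axial_threshold)
  if (any(thr <= 0) || any(thr >= 1))
    stop_field("classifier_params", "thresholds must lie strictly in (0,1)")
  if (depth_anterior_max > depth_posterior_min)
    stop_field("depth_anterior_max", "must not exceed depth_posterior_min")
  if (min_total_mass <= 0)
    stop_field("min_total_mass", "must be strictly positive")
  structure(list(presentation_threshold = presentation_threshold,
                 fundal_axial_threshold = fundal_axial_threshold,
                 depth_anterior_max = depth_anterior_max,
                 depth_posterior_min = depth_posterior_min,
                 low_axial_threshold = low_axial_threshold,
                 min_total_mass = min_total_mass),
            class = "classifier_params")
}

#' Classify fetal presentation from the head likelihood map
#'
#' The score is the mass-weighted axial centroid of the map (0 = pelvis);
#' below the threshold the head sits toward the pelvis and the
#' presentation is cephalic. A map with (near-)zero mass is indeterminate.
#'
#' @param head_map a `likelihood_map`.
#' @param params a [classifier_params()].
#' @return list(label, score).
#' @export
classify_presentation <- function(head_map, params = classifier_params()) {
  if (sum(head_map$values) < params$min_total_mass)
    return(list(label = "indeterminate", score = NA_real_))
  score <- map_centroid(head_map)$axial
  list(label = if (score < params$presentation_threshold) "cephalic" else "non-cephalic",
       score = score)
}

#' Area-weighted depth centroid over detected frames
#'
#' The axial x lateral likelihood map carries no depth information, so the
#' anterior/posterior decision uses the within-frame depth centroid of the
#' detections (0 = near field = anterior wall), averaged over all detected
#' frames weighted by mask area.
#'
#' @param detections_by_sweep named list of `detection_series`.
#' @return Scalar in `[0,1]`, or NA when nothing was detected.
#' @export
depth_stat <- function(detections_by_sweep) {
  num <- 0; den <- 0
  for (s in detections_by_sweep) {
    i <- which(s$present)
    if (!length(i)) next
    num <- num + sum(s$area[i] * s$depth_centroid[i])
    den <- den + sum(s$area[i])
  }
  if (den == 0) NA_real_ else num / den
}

#' Classify placental location
#'
#' Rule order: indeterminate on an empty map; fundal when the map's axial
#' centroid reaches the fundal threshold (fundal implantation straddles
#' the anterior and posterior walls, so it is decided before depth);
#' anterior when the depth centroid is in the near-field half; posterior
#' when in the far-field half; otherwise fundal (straddling). A placenta
#' mapped to the lowest part of the matrix raises the previa-suspect
#' low-placenta flag.
#'
#' @param placenta_map a `likelihood_map`.
#' @param depth depth centroid from [depth_stat()].
#' @param params a [classifier_params()].
#' @return list(label, axial_score, depth_score, low_placenta_flag).
#' @export
classify_placenta <- function(placenta_map, depth, params = classifier_params()) {
  if (sum(placenta_map$values) < params$min_total_mass)
    return(list(label = "indeterminate", axial_score = NA_real_,
                depth_score = NA_real_, low_placenta_flag = FALSE))
  axial <- map_centroid(placenta_map)$axial
  label <- if (axial >= params$fundal_axial_threshold) "fundal"
  else if (!is.na(depth) && depth <= params$depth_anterior_max) "anterior"
  else if (!is.na(depth) && depth >= params$depth_posterior_min) "posterior"
  else "fundal"
  list(label = label, axial_score = axial, depth_score = depth,
       low_placenta_flag = axial <= params$low_axial_threshold)
}

# Run a segmenter over every frame of the exam and build per-sweep
# detection series plus the per-frame masks (with their spacing).
segment_exam <- function(exam, segmenter, threshold = 0.5,
                         min_area_px = 30, min_run = 3) {
  needs_resize <- inherits(segmenter, "unet_model")
  isz <- if (needs_resize) segmenter$config$input_size
  detections <- list()
  masks <- list()
  spacing <- list()
  for (sid in names(exam$sweeps)) {
    sw <- exam$sweeps[[sid]]
    stack <- vector("list", length(sw$frames))
    sp <- vector("list", length(sw$frames))
    for (i in seq_along(sw$frames)) {
      fr <- sw$frames[[i]]
      if (needs_resize) {
        pre <- crop_and_resize(fr, crop_box = NULL, out_size = isz)
        pr <- predict_mask(segmenter, pre, threshold = threshold)
        sp[[i]] <- pre$pixel_spacing_mm
      } else {
        pr <- predict_mask(segmenter, fr, threshold = threshold)
        sp[[i]] <- rep_len(fr$pixel_spacing_mm %||% 1, 2L)
      }
      stack[[i]] <- pr$mask
    }
    detections[[sid]] <- detect_series(stack, min_area_px, min_run)
    masks[[sid]] <- stack
    spacing[[sid]] <- sp
  }
  list(detections = detections, masks = masks, spacing = spacing)
}

#' Diagnose a VSI examination end to end
#'
#' Runs preprocessing, segmentation, per-sweep detection, likelihood-map
#' construction and the score-based classifiers for both structures, plus
#' head biometry from the largest predicted head mask. Deterministic given
#' the exam and the segmenters.
#'
#' @param exam a `vsi_exam` covering all sweeps in `registry`.
#' @param head_segmenter,placenta_segmenter objects satisfying the
#'   [predict_mask()] contract (trained models or oracle segmenters).
#' @param registry sweep-geometry registry.
#' @param params a [classifier_params()].
#' @param sigma likelihood-map smoothing (default `0.03 * max(dim)`).
#' @param threshold mask binarization threshold.
#' @param min_area_px,min_run detection filters, see [detect_series()].
#' @param biometry also measure BPD/HC from the head masks (default TRUE).
#' @return A `vsi_diagnosis`: presentation and placenta labels with scores,
#'   the two likelihood maps, detections, and (optionally) a
#'   `biometry_result`.
#' @export
diagnose_exam <- function(exam, head_segmenter, placenta_segmenter,
                          registry = default_registry(),
                          params = classifier_params(), sigma = NULL,
                          threshold = 0.5, min_area_px = 30, min_run = 3,
                          biometry = TRUE) {
  stopifnot(inherits(exam, "vsi_exam"))
  missing <- setdiff(names(registry), names(exam$sweeps))
  if (length(missing))
    stop(sprintf("exam is missing sweeps: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  seg_h <- segment_exam(exam, head_segmenter, threshold, min_area_px, min_run)
  seg_p <- segment_exam(exam, placenta_segmenter, threshold, min_area_px, min_run)
  head_map <- build_likelihood_map(exam, seg_h$detections, registry, sigma,
                                   structure = "head")
  plac_map <- build_likelihood_map(exam, seg_p$detections, registry, sigma,
                                   structure = "placenta")
  pres <- classify_presentation(head_map, params)
  plac <- classify_placenta(plac_map, depth_stat(seg_p$detections), params)
  bio <- NULL
  if (biometry) {
    bio <- tryCatch(
      biometry_from_masks(seg_h$masks, seg_h$spacing),
      error = function(e) NULL)
  }
  structure(list(
    presentation = pres$label, presentation_score = pres$score,
    placenta_location = plac$label,
    placenta_axial_score = plac$axial_score,
    placenta_depth_score = plac$depth_score,
    low_placenta_flag = plac$low_placenta_flag,
    head_map = head_map, placenta_map = plac_map,
    head_detections = seg_h$detections,
    placenta_detections = seg_p$detections,
    biometry = bio
  ), class = "vsi_diagnosis")
}

#' @export
print.vsi_diagnosis <- function(x, ...) {
  cat("VSI automatic diagnosis\n")
  cat(sprintf("  presentation     : %s (axial score %.3f)\n",
              x$presentation, x$presentation_score))
  cat(sprintf("  placenta location: %s (axial %.3f, depth %s)\n",
              x$placenta_location, x$placenta_axial_score,
              ifelse(is.na(x$placenta_depth_score), "NA",
                     sprintf("%.3f", x$placenta_depth_score))))
  if (isTRUE(x$low_placenta_flag))
    cat("  low placenta flag: RAISED (refer for previa work-up)\n")
  if (!is.null(x$biometry))
    cat(sprintf("  biometry         : BPD %.1f mm, HC %.1f mm\n",
                x$biometry$bpd_mm, x$biometry$hc_mm))
  invisible(x)
}
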