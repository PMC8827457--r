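#' Select the largest mask across an examination
#'
#' Scans all sweeps in order and returns the mask with maximal pixel area;
#' ties break toward the earliest sweep, then the earliest frame.
#'
#' @param mask_stacks named list (by sweep, in sweep order) of lists of
#'   logical matrices.
#' @return list(sweep_id, frame_index (0-based), mask).
#' @export
select_largest_mask <- function(mask_stacks) {
  best <- NULL; best_area <- 0
  for (sid in names(mask_stacks)) {
    stack <- mask_stacks[[sid]]
    for (i in seq_along(stack)) {
      a <- sum(stack[[i]])
      if (a > best_area) {
        best_area <- a
        best <- list(sweep_id = sid, frame_index = i - 1L, mask = stack[[i]])
      }
    }
  }
  if (is.null(best)) stop("no non-empty head mask in the examination", call. = FALSE)
  best
}

#' Moment-based ellipse fit of a binary mask
#'
#' Fits the equivalent ellipse from the second central moments of the
#' filled mask: a uniform ellipse with semi-axes (a, b) has eigenvalues
#' (a^2/4, b^2/4) of its covariance, so the semi-axes are twice the square
#' roots of the covariance eigenvalues.
#'
#' @param mask logical matrix with at least 5 foreground pixels.
#' @return An `ellipse_fit`: list(center (row, col), semi_major_px,
#'   semi_minor_px, angle) — `angle` in radians of the major axis against
#'   the column (x) axis, in `[0, pi)`.
#' @export
fit_ellipse <- function(mask) {
  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) < 5)
    stop("ellipse fit needs at least 5 foreground pixels", call. = FALSE)
  # x = columns, y = rows, in pixel units
  x <- px[, 2]; y <- px[, 1]
  cx <- mean(x); cy <- mean(y)
  cxx <- mean((x - cx)^2); cyy <- mean((y - cy)^2); cxy <- mean((x - cx) * (y - cy))
  cov <- matrix(c(cxx, cxy, cxy, cyy), 2, 2)
  e <- eigen(cov, symmetric = TRUE)
  if (e$values[2] <= 1e-9)
    stop("degenerate (collinear) mask: ellipse fit undefined", call. = FALSE)
  a <- 2 * sqrt(e$values[1]); b <- 2 * sqrt(e$values[2])
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) %% pi
  structure(list(center = c(row = cy, col = cx),
                 semi_major_px = a, semi_minor_px = b, angle = ang),
            class = "ellipse_fit")
}

#' Biparietal diameter from an ellipse fit
#'
#' BPD is the full minor axis of the fitted head ellipse in physical
#' units: two times the semi-minor axis length times the pixel spacing.
#'
#' @param fit an [fit_ellipse()] result.
#' @param spacing mm per pixel (scalar; for anisotropic frames use
#'   [measure_biometry()], which works in physical coordinates).
#' @return BPD in mm.
#' @export
bpd_from_fit <- function(fit, spacing) {
  2 * fit$semi_minor_px * spacing
}

#' Head circumference from a mask contour
#'
#' Perimeter of the mask's outer border, measured as the arc length of the
#' sub-pixel 0.5-level contour of the lightly blurred mask (marching
#' squares via [grDevices::contourLines]). If the mask has several
#' connected components the largest is measured and the result is flagged.
#' The fitted-ellipse perimeter (Ramanujan) is available as an alternative
#' for sensitivity analysis.
#'
#' @param mask logical matrix.
#' @param spacing mm per pixel, scalar or `c(row, col)`.
#' @param method `"contour"` (default) or `"ellipse"`.
#' @return HC in mm, with attribute `multiple_components` when flagged.
#' @export
hc_from_mask <- function(mask, spacing, method = c("contour", "ellipse")) {
  method <- match.arg(method)
  spacing <- rep_len(as.numeric(spacing), 2L)
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp == 0) stop("empty mask", call. = FALSE)
  flagged <- ncomp > 1
  if (flagged) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    mask <- lab == which.max(sizes)
  }
  if (method == "ellipse") {
    hc <- ellipse_perimeter_physical(mask, spacing)
  } else {
    hc <- contour_perimeter(mask, spacing)
  }
  attr(hc, "multiple_components") <- flagged
  hc
}

# Ellipse perimeter from moments computed in mm coordinates.
ellipse_perimeter_physical <- function(mask, spacing) {
  px <- which(mask != 0, arr.ind = TRUE)
  y <- px[, 1] * spacing[1]; x <- px[, 2] * spacing[2]
  cxx <- mean((x - mean(x))^2); cyy <- mean((y - mean(y))^2)
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
  ellipse_perimeter(2 * sqrt(e[1]), 2 * sqrt(max(e[2], 0)))
}

# Sub-pixel contour length: blur the indicator slightly and take the
# 0.5-level marching-squares contour in physical coordinates.
contour_perimeter <- function(mask, spacing) {
  m <- gaussian_blur(mask * 1, 1)
  # pad so the contour closes even when the mask touches the border
  H <- nrow(m); W <- ncol(m)
  mp <- matrix(0, H + 2, W + 2)
  mp[2:(H + 1), 2:(W + 1)] <- m
  cl <- grDevices::contourLines(x = (seq_len(H + 2) - 1) * spacing[1],
                                y = (seq_len(W + 2) - 1) * spacing[2],
                                z = mp, levels = 0.5)
  if (!length(cl)) stop("no contour found", call. = FALSE)
  lens <- vapply(cl, function(cc) {
    dx <- diff(c(cc$x, cc$x[1])); dy <- diff(c(cc$y, cc$y[1]))
    sum(sqrt(dx^2 + dy^2))
  }, numeric(1))
  max(lens)
}

#' Measure head biometry from a mask in physical coordinates
#'
#' Handles anisotropic spacing (as produced by [crop_and_resize()]) by
#' computing the ellipse moments and the contour directly in mm
#' coordinates, which is equivalent to mapping the mask back through the
#' crop/resize transform.
#'
#' @param mask logical matrix.
#' @param spacing mm per pixel, scalar or `c(row, col)`.
#' @param hc_method `"contour"` or `"ellipse"`.
#' @return list(bpd_mm, hc_mm, fit (pixel-unit [fit_ellipse()]),
#'   multiple_components).
#' @export
measure_biometry <- function(mask, spacing, hc_method = "contour") {
  spacing <- rep_len(as.numeric(spacing), 2L)
  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) < 5)
    stop("ellipse fit needs at least 5 foreground pixels", call. = FALSE)
  y <- px[, 1] * spacing[1]; x <- px[, 2] * spacing[2]
  cxx <- mean((x - mean(x))^2); cyy <- mean((y - mean(y))^2)
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
  if (e[2] <= 1e-9)
    stop("degenerate (collinear) mask: ellipse fit undefined", call. = FALSE)
  bpd <- 2 * (2 * sqrt(e[2]))   # full minor axis in mm
  hc <- hc_from_mask(mask, spacing, method = hc_method)
  list(bpd_mm = bpd, hc_mm = as.numeric(hc),
       fit = fit_ellipse(mask),
       multiple_components = isTRUE(attr(hc, "multiple_components")))
}

#' Head biometry for a segmented examination
#'
#' Selects the largest head mask over all sweeps and measures BPD
#' (full minor axis of the fitted ellipse) and HC (border length of the
#' same mask).
#'
#' @param mask_stacks named list of per-sweep mask lists.
#' @param spacing_stacks matching per-frame `c(row, col)` spacings in mm.
#' @param hc_method `"contour"` or `"ellipse"`.
#' @return A `biometry_result`: list(bpd_mm, hc_mm, sweep_id, frame_index,
#'   ellipse, pixel_spacing_mm, multiple_components).
#' @export
biometry_from_masks <- function(mask_stacks, spacing_stacks,
                                hc_method = "contour") {
  sel <- select_largest_mask(mask_stacks)
  sp <- spacing_stacks[[sel$sweep_id]][[sel$frame_index + 1L]]
  meas <- measure_biometry(sel$mask, sp, hc_method)
  structure(list(bpd_mm = meas$bpd_mm, hc_mm = meas$hc_mm,
                 sweep_id = sel$sweep_id, frame_index = sel$frame_index,
                 ellipse = meas$fit, pixel_spacing_mm = sp,
                 multiple_components = meas$multiple_components),
            class = "biometry_result")
}

#' Default gestational-age formula table
#'
#' Polynomial regressions of gestational age (weeks) on a measurement in
#' cm, shipped as editable data (`inst/extdata/ga_formulas.csv`): GA =
#' c0 + c1 x + c2 x^2 + c3 x^3, converted to days. The defaults are the
#' classical Hadlock-type curves for BPD and HC.
#'
#' @return data.frame with columns formula_id, measure, c0..c3,
#'   min_mm, max_mm.
#' @export
default_ga_formulas <- function() {
  read.csv(system.file("extdata", "ga_formulas.csv", package = "vsidiag"),
           stringsAsFactors = FALSE)
}

eval_ga_formula <- function(row, value_mm) {
  if (value_mm < row$min_mm || value_mm > row$max_mm)
    warning(sprintf("%s = %.1f mm outside the validity range [%g, %g] of %s",
                    row$measure, value_mm, row$min_mm, row$max_mm,
                    row$formula_id))
  x <- value_mm / 10  # cm
  7 * (row$c0 + row$c1 * x + row$c2 * x^2 + row$c3 * x^3)
}

#' Gestational age from head biometry
#'
#' Evaluates the configured regression for each measurement; estimates are
#' returned (with a warning) even outside the stated validity range.
#'
#' @param bpd_mm,hc_mm measurements in mm (either may be NA).
#' @param formula_table see [default_ga_formulas()].
#' @return A `ga_estimate`: list(ga_days_bpd, ga_days_hc, formula_id).
#' @export
ga_from_biometry <- function(bpd_mm, hc_mm = NA, formula_table = default_ga_formulas()) {
  get_row <- function(measure) {
    r <- formula_table[formula_table$measure == measure, , drop = FALSE]
    if (!nrow(r)) NULL else r[1, , drop = FALSE]
  }
  rb <- get_row("bpd"); rh <- get_row("hc")
  ga_bpd <- if (!is.na(bpd_mm) && !is.null(rb)) eval_ga_formula(rb, bpd_mm) else NA_real_
  ga_hc <- if (!is.na(hc_mm) && !is.null(rh)) eval_ga_formula(rh, hc_mm) else NA_real_
  structure(list(ga_days_bpd = ga_bpd, ga_days_hc = ga_hc,
                 formula_id = c(bpd = if (!is.null(rb)) rb$formula_id,
                                hc = if (!is.null(rh)) rh$formula_id)),
            class = "ga_estimate")
}

#' Proportion of gestational-age differences within a window
#'
#' @param deltas_days signed day differences between two GA estimates.
#' @param window_days window half-width in days (e.g. 7 or 14).
#' @return Fraction of `|delta| <= window`; NA (with a warning) for empty
#'   input.
#' @export
ga_within <- function(deltas_days, window_days) {
  if (!length(deltas_days)) {
    warning("no gestational-age differences supplied; proportion undefined")
    return(NA_real_)
  }
  mean(abs(deltas_days) <= window_days)
}
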