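#' Sweep geometry
#'
#' Describes how one sweep of the protocol maps onto the normalized
#' abdomen: vertical sweeps index their frames along the axial (pelvis to
#' fundus) axis and cover a lateral `band`; horizontal sweeps index frames
#' along the lateral (right to left) axis and cover an axial `band`.
#'
#' @param sweep_id character identifier.
#' @param orientation `"vertical"` or `"horizontal"`.
#' @param band numeric(2), normalized interval on the orthogonal axis.
#' @param direction free-text start/end landmarks.
#' @return A `sweep_geometry`.
#' @export
sweep_geometry <- function(sweep_id, orientation = c("vertical", "horizontal"),
                           band, direction = "") {
  orientation <- match.arg(orientation)
  band <- as.numeric(band)
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0 || band[2] > 1)
    stop_field("band", "must be a non-empty interval inside [0,1]")
  structure(list(sweep_id = as.character(sweep_id), orientation = orientation,
                 band = band, direction = direction),
            class = "sweep_geometry")
}

#' Default eight-sweep geometry registry
#'
#' Four vertical sweeps (pelvis to fundus) at lateral band centres
#' 0.2/0.4/0.6/0.8 and four horizontal sweeps (maternal right to left) at
#' axial band centres 0.2/0.4/0.6/0.8, each band 0.25 wide. The registry is
#' plain data so the exact acquisition protocol of a site can be
#' substituted (see [write_registry()]).
#'
#' @return Named list of eight [sweep_geometry()] objects.
#' @export
default_registry <- function() {
  centres <- c(0.2, 0.4, 0.6, 0.8)
  half <- 0.125
  reg <- list()
  for (i in seq_along(centres)) {
    id <- sprintf("sweep%d", i)
    reg[[id]] <- sweep_geometry(id, "vertical",
                                c(centres[i] - half, centres[i] + half),
                                "pelvis->fundus")
  }
  for (i in seq_along(centres)) {
    id <- sprintf("sweep%d", i + 4L)
    reg[[id]] <- sweep_geometry(id, "horizontal",
                                c(centres[i] - half, centres[i] + half),
                                "right->left")
  }
  reg
}

validate_registry <- function(registry) {
  if (!length(registry)) stop("empty sweep registry", call. = FALSE)
  ok <- vapply(registry, inherits, logical(1), "sweep_geometry")
  if (!all(ok)) stop("registry entries must be sweep_geometry objects", call. = FALSE)
  invisible(registry)
}

sweep_lengths <- function(exam) {
  if (inherits(exam, "vsi_exam"))
    vapply(exam$sweeps, function(s) length(s$frames), integer(1))
  else if (is.numeric(exam) && !is.null(names(exam)))
    setNames(as.integer(exam), names(exam))
  else stop("exam must be a vsi_exam or a named vector of sweep lengths",
            call. = FALSE)
}

#' Initialize the spatial likelihood matrix
#'
#' The zero matrix stands for the pregnant abdomen; its number of rows is
#' the largest vertical sweep's frame count (axial samples) and its number
#' of columns the largest horizontal sweep's frame count (lateral samples).
#'
#' @param exam a `vsi_exam` or a named vector `sweep_id -> n_frames`.
#' @param registry geometry registry covering all sweeps of the exam.
#' @return A `likelihood_map` with zero `counts`/`values` and normalized
#'   axis coordinates.
#' @export
init_map <- function(exam, registry = default_registry()) {
  lens <- sweep_lengths(exam)
  missing <- setdiff(names(lens), names(registry))
  if (length(missing))
    stop(sprintf("registry does not cover sweeps: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  orient <- vapply(registry[names(lens)], function(g) g$orientation, character(1))
  if (!any(orient == "vertical") || !any(orient == "horizontal"))
    stop("need at least one vertical and one horizontal sweep", call. = FALSE)
  R <- max(lens[orient == "vertical"])
  C <- max(lens[orient == "horizontal"])
  structure(list(counts = matrix(0, R, C), values = matrix(0, R, C),
                 axial_axis = (seq_len(R) - 0.5) / R,
                 lateral_axis = (seq_len(C) - 0.5) / C,
                 structure = NULL, smoothed = FALSE),
            class = "likelihood_map")
}

#' Rescale a detection vector to the map dimension
#'
#' Nearest-index (floor) resampling of the present/absent vector so that a
#' sweep with fewer frames than the matrix dimension still fills it; the
#' identity when the lengths match. Down-scaling is not supported.
#'
#' @param series logical vector or a `detection_series`.
#' @param target_len target length, at least the series length.
#' @return Logical vector of length `target_len`.
#' @export
rescale_detections <- function(series, target_len) {
  v <- if (inherits(series, "detection_series")) series$present else as.logical(series)
  n <- length(v)
  if (n < 1) stop("empty detection series", call. = FALSE)
  if (target_len < n)
    stop("down-scaling detections is not supported", call. = FALSE)
  if (target_len == n) return(v)
  v[floor((seq_len(target_len) - 1L) * n / target_len) + 1L]
}

#' Accumulate one sweep's detections into the likelihood matrix
#'
#' Vertical sweeps increment the rows at detected frame positions within
#' the sweep's lateral band; horizontal sweeps increment the columns at
#' detected positions within their axial band. Votes from different sweeps
#' add, so overlap raises the likelihood.
#'
#' @param map a `likelihood_map`.
#' @param geometry the sweep's [sweep_geometry()].
#' @param detections logical vector already rescaled to the matching map
#'   dimension.
#' @return The updated map (counts only; smoothing is a separate stage).
#' @export
accumulate_sweep <- function(map, geometry, detections) {
  stopifnot(inherits(map, "likelihood_map"), inherits(geometry, "sweep_geometry"))
  b <- geometry$band
  if (geometry$orientation == "vertical") {
    if (length(detections) != nrow(map$counts))
      stop("detections must be rescaled to the map's row count", call. = FALSE)
    cols <- which(map$lateral_axis >= b[1] & map$lateral_axis <= b[2])
    map$counts[which(detections), cols] <- map$counts[which(detections), cols] + 1
  } else {
    if (length(detections) != ncol(map$counts))
      stop("detections must be rescaled to the map's column count", call. = FALSE)
    rows <- which(map$axial_axis >= b[1] & map$axial_axis <= b[2])
    map$counts[rows, which(detections)] <- map$counts[rows, which(detections)] + 1
  }
  map$values <- map$counts
  map
}

#' Gaussian-smooth a likelihood map
#'
#' Separable Gaussian with reflective boundary; `sigma = 0` is the
#' identity. Total mass is preserved (relative error below 1e-6).
#'
#' @param map a `likelihood_map`.
#' @param sigma standard deviation in cells.
#' @return The map with smoothed `values` (raw `counts` kept).
#' @export
smooth_map <- function(map, sigma) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  map$values <- gaussian_blur(map$counts, sigma)
  map$smoothed <- sigma > 0
  map
}

#' Build the spatial location likelihood map for one structure
#'
#' Composition of the three stages: zero-matrix initialization from the
#' largest vertical/horizontal sweep sizes, nearest-index rescaling of
#' each sweep's detection series, additive accumulation over all sweeps,
#' and Gaussian smoothing. Axes are normalized to `[0,1]`.
#'
#' @param exam a `vsi_exam` or named vector of sweep lengths.
#' @param detections_by_sweep named list (by sweep_id) of
#'   `detection_series` or logical vectors.
#' @param registry geometry registry.
#' @param sigma Gaussian sigma in cells; default `0.03 * max(dim)`; 0
#'   disables smoothing.
#' @param structure optional structure label stored on the map.
#' @return A `likelihood_map` with `counts` (integer votes, before
#'   smoothing) and `values` (after smoothing).
#' @export
build_likelihood_map <- function(exam, detections_by_sweep,
                                 registry = default_registry(), sigma = NULL,
                                 structure = NULL) {
  map <- init_map(exam, registry)
  sigma <- sigma %||% (0.03 * max(dim(map$counts)))
  for (sid in names(detections_by_sweep)) {
    geom <- registry[[sid]]
    if (is.null(geom)) stop(sprintf("sweep %s not in registry", sid), call. = FALSE)
    target <- if (geom$orientation == "vertical") nrow(map$counts) else ncol(map$counts)
    det <- rescale_detections(detections_by_sweep[[sid]], target)
    map <- accumulate_sweep(map, geom, det)
  }
  map <- smooth_map(map, sigma)
  map$structure <- structure
  map
}

#' Mass centroid of a likelihood map
#' @param map a `likelihood_map`.
#' @param use_counts use the raw counts instead of the smoothed values.
#' @return list(axial, lateral) in `[0,1]`, or NAs for an empty map.
#' @export
map_centroid <- function(map, use_counts = FALSE) {
  v <- if (use_counts) map$counts else map$values
  tot <- sum(v)
  if (tot <= 0) return(list(axial = NA_real_, lateral = NA_real_))
  list(axial = sum(rowSums(v) * map$axial_axis) / tot,
       lateral = sum(colSums(v) * map$lateral_axis) / tot)
}
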