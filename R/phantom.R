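#' Configuration for a synthetic sweep phantom
#'
#' Describes a 3D pregnant-abdomen scene: a homogeneous mid-gray abdomen
#' containing an ellipsoidal fetal head (bright rim, dark interior) and a
#' placental slab on the anterior wall, posterior wall, or fundus. All
#' positions use the normalized abdomen frame (axial 0 = pelvis, 1 = fundus;
#' depth 0 = anterior/probe side, 1 = posterior; lateral 0 = maternal right,
#' 1 = left).
#'
#' The head is oriented with its shortest semi-axis along the maternal axial
#' direction, so the transverse sweep plane through the head centre is the
#' standard biometry plane: its cross-section ellipse carries the two largest
#' semi-axes, exactly as the clinical BPD/HC plane does.
#'
#' @param abdomen_size_mm numeric(3), axial/lateral/depth extents in mm.
#' @param head_center numeric(3), normalized (axial, lateral, depth) centre.
#' @param head_axes_mm numeric(3), semi-axes in mm along (axial, lateral,
#'   depth).
#' @param presentation_label `"cephalic"` or `"non-cephalic"`; must be
#'   consistent with the head's axial centre (cephalic iff axial < 0.5).
#' @param placenta_location_label `"anterior"`, `"posterior"` or `"fundal"`.
#' @param placenta_thickness_mm slab thickness in mm.
#' @param pixel_spacing_mm rendered pixel size in mm.
#' @param frames_per_sweep integer, frames per sweep (scalar or length 8,
#'   each at least 8).
#' @param noise_level speckle variance of the unit-mean multiplicative
#'   gamma noise; 0 disables noise.
#' @param seed integer seed; the phantom is a pure function of
#'   (config, seed).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(abdomen_size_mm = c(300, 260, 150),
                           head_center = c(0.25, 0.5, 0.5),
                           head_axes_mm = c(42, 55, 44),
                           presentation_label = c("cephalic", "non-cephalic"),
                           placenta_location_label = c("anterior", "posterior", "fundal"),
                           placenta_thickness_mm = 30,
                           pixel_spacing_mm = 1,
                           frames_per_sweep = 24,
                           noise_level = 0.1,
                           seed = 1L) {
  cfg <- list(
    abdomen_size_mm = as.numeric(abdomen_size_mm),
    head_center = as.numeric(head_center),
    head_axes_mm = as.numeric(head_axes_mm),
    presentation_label = match.arg(presentation_label),
    placenta_location_label = match.arg(placenta_location_label),
    placenta_thickness_mm = as.numeric(placenta_thickness_mm),
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    frames_per_sweep = as.integer(frames_per_sweep),
    noise_level = as.numeric(noise_level),
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$abdomen_size_mm) != 3 || any(cfg$abdomen_size_mm <= 0))
    stop_field("abdomen_size_mm", "three strictly positive extents required")
  if (length(cfg$head_axes_mm) != 3 || any(cfg$head_axes_mm <= 0))
    stop_field("head_axes_mm", "three strictly positive semi-axes required")
  if (length(cfg$head_center) != 3 || any(cfg$head_center < 0) || any(cfg$head_center > 1))
    stop_field("head_center", "normalized coordinates in [0,1]^3 required")
  axes_norm <- cfg$head_axes_mm / cfg$abdomen_size_mm
  if (any(cfg$head_center - axes_norm < 0) || any(cfg$head_center + axes_norm > 1))
    stop_field("head_center", "head ellipsoid must lie fully inside the abdomen")
  cephalic <- cfg$head_center[1] < 0.5
  if (cephalic != (cfg$presentation_label == "cephalic"))
    stop_field("presentation_label",
               "inconsistent with head axial centre (cephalic iff axial < 0.5)")
  if (cfg$placenta_thickness_mm <= 0)
    stop_field("placenta_thickness_mm", "must be strictly positive")
  if (cfg$pixel_spacing_mm <= 0)
    stop_field("pixel_spacing_mm", "must be strictly positive")
  if (any(cfg$frames_per_sweep < 8))
    stop_field("frames_per_sweep", "at least 8 frames per sweep required")
  if (!length(cfg$frames_per_sweep) %in% c(1L, 8L))
    stop_field("frames_per_sweep", "scalar or one value per sweep (8) required")
  if (cfg$noise_level < 0)
    stop_field("noise_level", "speckle variance must be non-negative")
  invisible(cfg)
}

# Normalized slab bounds (axial, lateral, depth intervals) of the placenta.
placenta_slab <- function(cfg) {
  td <- cfg$placenta_thickness_mm / cfg$abdomen_size_mm[3]
  ta <- cfg$placenta_thickness_mm / cfg$abdomen_size_mm[1]
  switch(cfg$placenta_location_label,
    anterior  = list(axial = c(0.15, 0.85), lateral = c(0.10, 0.90),
                     depth = c(0.04, min(0.96, 0.04 + td))),
    posterior = list(axial = c(0.15, 0.85), lateral = c(0.10, 0.90),
                     depth = c(max(0.04, 0.96 - td), 0.96)),
    fundal    = list(axial = c(max(0.04, 0.96 - ta), 0.96),
                     lateral = c(0.10, 0.90), depth = c(0.10, 0.90))
  )
}

# Intensities of the noiseless scene.
.phantom_shades <- list(background = 0.45, rim = 0.90, interior = 0.15,
                        placenta = 0.70, rim_frac = 0.85)

# Rasterize one planar section of the scene, without noise.
# orientation "vertical": plane at fixed axial; rows = depth, cols = lateral.
# orientation "horizontal": plane at fixed lateral; rows = depth, cols = axial.
# `window` is the normalized interval imaged along the column axis.
render_section <- function(cfg, orientation, position, window = c(0, 1)) {
  sz <- cfg$abdomen_size_mm
  sp <- cfg$pixel_spacing_mm
  H <- max(1L, round(sz[3] / sp))
  col_axis_len <- if (orientation == "vertical") sz[2] else sz[1]
  w0 <- window[1] * col_axis_len
  w1 <- window[2] * col_axis_len
  W <- max(1L, round((w1 - w0) / sp))
  depth_mm <- (seq_len(H) - 0.5) * sp
  col_mm <- w0 + (seq_len(W) - 0.5) * sp
  cx <- cfg$head_center * sz          # head centre in mm (axial, lateral, depth)
  ax <- cfg$head_axes_mm
  if (orientation == "vertical") {
    axial_mm <- position * sz[1]
    t_fix <- (axial_mm - cx[1]) / ax[1]
    t_col <- (col_mm - cx[2]) / ax[2]
    t_row <- (depth_mm - cx[3]) / ax[3]
  } else {
    lateral_mm <- position * sz[2]
    t_fix <- (lateral_mm - cx[2]) / ax[2]
    t_col <- (col_mm - cx[1]) / ax[1]
    t_row <- (depth_mm - cx[3]) / ax[3]
  }
  r2 <- outer(t_row^2, t_col^2, `+`) + t_fix^2
  head_mask <- r2 <= 1
  rim <- head_mask & r2 > .phantom_shades$rim_frac^2

  slab <- placenta_slab(cfg)
  row_in <- depth_mm / sz[3] >= slab$depth[1] & depth_mm / sz[3] <= slab$depth[2]
  if (orientation == "vertical") {
    fix_in <- position >= slab$axial[1] && position <= slab$axial[2]
    col_in <- col_mm / sz[2] >= slab$lateral[1] & col_mm / sz[2] <= slab$lateral[2]
  } else {
    fix_in <- position >= slab$lateral[1] && position <= slab$lateral[2]
    col_in <- col_mm / sz[1] >= slab$axial[1] & col_mm / sz[1] <= slab$axial[2]
  }
  placenta_mask <- if (fix_in) outer(row_in, col_in, `&`) else
    matrix(FALSE, H, W)
  placenta_mask <- placenta_mask & !head_mask

  img <- matrix(.phantom_shades$background, H, W)
  img[placenta_mask] <- .phantom_shades$placenta
  img[head_mask] <- .phantom_shades$interior
  img[rim] <- .phantom_shades$rim
  list(pixels = img, head_mask = head_mask, placenta_mask = placenta_mask)
}

apply_speckle <- function(img, noise_level, seed) {
  if (noise_level == 0) return(img)
  with_seed(seed, {
    mult <- rgamma(length(img), shape = 1 / noise_level, rate = 1 / noise_level)
    pmin(pmax(img * mult, 0), 1)   # first argument keeps the matrix dims
  })
}

#' Render one frame of a sweep phantom
#'
#' Rasterizes a planar cross-section of the phantom scene and applies
#' unit-mean multiplicative gamma speckle. With `noise_level = 0` the
#' noiseless rasterization is returned exactly.
#'
#' @param scene a [phantom_config()].
#' @param plane list with `orientation` (`"vertical"` = plane at fixed axial
#'   position, `"horizontal"` = fixed lateral position), `position`
#'   (normalized, in `[0,1]`) and optional `window` (normalized interval
#'   imaged along the frame's column axis; default the full extent).
#' @param noise_level speckle variance; defaults to the config's.
#' @param seed_offset integer stream offset so each frame gets independent
#'   speckle while the whole exam stays reproducible.
#' @return A frame: list with `pixels` (matrix in `[0,1]`),
#'   `pixel_spacing_mm`, `head_mask`, `placenta_mask`.
#' @export
render_frame <- function(scene, plane, noise_level = NULL, seed_offset = 0L) {
  stopifnot(inherits(scene, "phantom_config"))
  if (is.null(plane$position) || plane$position < 0 || plane$position > 1)
    stop("plane does not intersect the abdomen volume", call. = FALSE)
  orientation <- match.arg(plane$orientation, c("vertical", "horizontal"))
  window <- plane$window %||% c(0, 1)
  nl <- noise_level %||% scene$noise_level
  sec <- render_section(scene, orientation, plane$position, window)
  sec$pixels <- apply_speckle(sec$pixels, nl, derive_seed(scene$seed, seed_offset))
  sec$pixel_spacing_mm <- c(scene$pixel_spacing_mm, scene$pixel_spacing_mm)
  sec
}

#' Generate a synthetic VSI examination with ground truth
#'
#' Renders the eight sweeps of the VSI protocol over the configured scene.
#' Vertical sweeps (probe moving pelvis to fundus) produce transverse
#' sections imaging the full lateral extent; horizontal sweeps (right to
#' left) produce sagittal sections imaging only the sweep's axial band, so
#' a detection along a horizontal sweep localizes the structure laterally
#' while the band localizes it axially.
#'
#' @param config a [phantom_config()].
#' @param registry sweep-geometry registry, see [default_registry()].
#' @return list with `exam` (class `vsi_exam`) and `truth`
#'   (class `phantom_truth`): per-sweep binary masks for head and placenta,
#'   the true labels, and the analytic `true_bpd_mm` / `true_hc_mm`
#'   (2 x second-largest semi-axis; perimeter of the maximal cross-section
#'   ellipse).
#' @export
make_phantom <- function(config, registry = default_registry()) {
  stopifnot(inherits(config, "phantom_config"))
  validate_phantom_config(config)
  validate_registry(registry)
  nfr <- rep_len(config$frames_per_sweep, length(registry))
  sweeps <- list()
  head_masks <- list()
  placenta_masks <- list()
  counter <- 0L
  for (k in seq_along(registry)) {
    geom <- registry[[k]]
    n <- nfr[k]
    window <- if (geom$orientation == "vertical") c(0, 1) else geom$band
    frames <- vector("list", n)
    hm <- vector("list", n)
    pm <- vector("list", n)
    for (i in seq_len(n)) {
      counter <- counter + 1L
      fr <- render_frame(config,
                         plane = list(orientation = geom$orientation,
                                      position = (i - 0.5) / n,
                                      window = window),
                         seed_offset = counter)
      frames[[i]] <- list(pixels = fr$pixels,
                          pixel_spacing_mm = fr$pixel_spacing_mm,
                          sweep_id = geom$sweep_id,
                          frame_index = i - 1L)
      hm[[i]] <- fr$head_mask
      pm[[i]] <- fr$placenta_mask
    }
    sweeps[[geom$sweep_id]] <- list(geometry = geom, frames = frames)
    head_masks[[geom$sweep_id]] <- hm
    placenta_masks[[geom$sweep_id]] <- pm
  }
  exam <- structure(list(sweeps = sweeps,
                         pixel_spacing_mm = config$pixel_spacing_mm,
                         labels = list(presentation = config$presentation_label,
                                       placenta_location = config$placenta_location_label)),
                    class = "vsi_exam")
  ax_sorted <- sort(config$head_axes_mm, decreasing = TRUE)
  truth <- structure(list(
    masks = list(head = head_masks, placenta = placenta_masks),
    true_presentation = config$presentation_label,
    true_placenta_location = config$placenta_location_label,
    true_bpd_mm = 2 * ax_sorted[2],
    true_hc_mm = ellipse_perimeter(ax_sorted[1], ax_sorted[2]),
    config = config
  ), class = "phantom_truth")
  list(exam = exam, truth = truth)
}

#' Ramanujan approximation to the perimeter of an ellipse
#'
#' @param a,b semi-axes (same unit as the returned perimeter).
#' @return The perimeter, accurate to well below 0.1% for head-like
#'   aspect ratios.
#' @export
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Default random phantom sampler
#'
#' Draws scene configurations emulating third-trimester variation:
#' presentation balanced cephalic/non-cephalic (axial centre uniform in
#' `[0.16, 0.4]` resp. `[0.6, 0.84]`), placental location uniform over
#' anterior/posterior/fundal, and head size scaled by +/- 10% around
#' semi-axes (42, 55, 44) mm. Call inside a seeded RNG context.
#'
#' @param frames_per_sweep,noise_level,pixel_spacing_mm passed through to
#'   [phantom_config()].
#' @return A `phantom_config`.
#' @export
sample_phantom_config <- function(frames_per_sweep = 24, noise_level = 0.1,
                                  pixel_spacing_mm = 1) {
  cephalic <- runif(1) < 0.5
  axial <- if (cephalic) runif(1, 0.16, 0.40) else runif(1, 0.60, 0.84)
  u <- runif(1, 0.85, 1.1)
  axes <- c(42, 55, 44) * u * runif(3, 0.98, 1.02)
  axes[1] <- min(axes) * 0.99  # keep the axial semi-axis strictly smallest
  phantom_config(
    head_center = c(axial, runif(1, 0.45, 0.55), runif(1, 0.45, 0.55)),
    head_axes_mm = axes,
    presentation_label = if (cephalic) "cephalic" else "non-cephalic",
    placenta_location_label = sample(c("anterior", "posterior", "fundal"), 1),
    frames_per_sweep = frames_per_sweep,
    noise_level = noise_level,
    pixel_spacing_mm = pixel_spacing_mm,
    seed = sample.int(2^30, 1)
  )
}

#' Generate a network-ready training set from random phantoms
#'
#' Renders `n_patients` random phantoms and preprocesses every frame to the
#' network input size (full-frame crop, bilinear resize; nearest-neighbour
#' for masks). Structure-present flags and the head/placenta class ratios
#' are attached.
#'
#' @param n_patients number of phantoms (at least 1).
#' @param config_sampler function() returning a `phantom_config`; defaults
#'   to [sample_phantom_config()].
#' @param seed master seed; the whole dataset is reproducible from it.
#' @param out_size network input size (rows, cols).
#' @return A `vsi_dataset`: parallel lists `frames`, `head_masks`,
#'   `placenta_masks`, `spacing`, and vectors `head_present`,
#'   `placenta_present`, `patient`, `sweep_id`, `frame_index`, with
#'   attribute `class_ratio`.
#' @export
gen_training_set <- function(n_patients, config_sampler = NULL, seed = 1L,
                             out_size = c(128, 128)) {
  if (n_patients < 1) stop("n_patients must be at least 1", call. = FALSE)
  sampler <- config_sampler %||% sample_phantom_config
  frames <- list(); hmasks <- list(); pmasks <- list(); spacing <- list()
  hp <- logical(0); pp <- logical(0)
  patient <- integer(0); sweep_id <- character(0); frame_index <- integer(0)
  for (p in seq_len(n_patients)) {
    cfg <- with_seed(derive_seed(seed, p), sampler())
    ph <- make_phantom(cfg)
    for (sid in names(ph$exam$sweeps)) {
      sw <- ph$exam$sweeps[[sid]]
      for (i in seq_along(sw$frames)) {
        fr <- sw$frames[[i]]
        pre <- crop_and_resize(fr, crop_box = NULL, out_size = out_size)
        hm <- resize_mask(ph$truth$masks$head[[sid]][[i]], out_size)
        pm <- resize_mask(ph$truth$masks$placenta[[sid]][[i]], out_size)
        frames[[length(frames) + 1L]] <- pre$pixels
        spacing[[length(spacing) + 1L]] <- pre$pixel_spacing_mm
        hmasks[[length(hmasks) + 1L]] <- hm
        pmasks[[length(pmasks) + 1L]] <- pm
        hp <- c(hp, any(hm)); pp <- c(pp, any(pm))
        patient <- c(patient, p)
        sweep_id <- c(sweep_id, sid)
        frame_index <- c(frame_index, i - 1L)
      }
    }
  }
  structure(list(frames = frames, head_masks = hmasks, placenta_masks = pmasks,
                 spacing = spacing, head_present = hp, placenta_present = pp,
                 patient = patient, sweep_id = sweep_id,
                 frame_index = frame_index),
            class = "vsi_dataset",
            class_ratio = c(head = mean(hp), placenta = mean(pp)))
}

#' Subset a `vsi_dataset` by frame index
#' @param dataset a `vsi_dataset`.
#' @param idx integer or logical index over frames.
#' @return The subset, still a `vsi_dataset` with updated class ratios.
#' @export
dataset_subset <- function(dataset, idx) {
  out <- dataset
  for (f in c("frames", "head_masks", "placenta_masks", "spacing"))
    out[[f]] <- dataset[[f]][idx]
  for (f in c("head_present", "placenta_present", "patient", "sweep_id", "frame_index"))
    out[[f]] <- dataset[[f]][idx]
  attr(out, "class_ratio") <- c(head = mean(out$head_present),
                                placenta = mean(out$placenta_present))
  out
}

#' @export
length.vsi_dataset <- function(x) length(x$frames)
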