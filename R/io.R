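#' Write / read a VSI examination on disk
#'
#' One multipage TIFF per sweep (frames), one PNG per mask, and a JSON
#' sidecar describing sweep identity, orientation, frame order, pixel
#' spacing and labels.
#'
#' @param exam a `vsi_exam`.
#' @param dir output directory (created if needed).
#' @param truth optional `phantom_truth`; when given, masks are written too.
#' @return `write_exam`: `dir`, invisibly. `read_exam`: a `vsi_exam` (with
#'   `masks` attached when present on disk).
#' @export
write_exam <- function(exam, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sidecar <- list()
  for (sid in names(exam$sweeps)) {
    sw <- exam$sweeps[[sid]]
    pages <- lapply(sw$frames, function(f) f$pixels)
    tiff::writeTIFF(pages, file.path(dir, paste0(sid, ".tiff")),
                    bits.per.sample = 16L)
    sidecar[[sid]] <- list(
      sweep_id = sid, orientation = sw$geometry$orientation,
      band = sw$geometry$band, direction = sw$geometry$direction,
      n_frames = length(sw$frames),
      pixel_spacing_mm = sw$frames[[1]]$pixel_spacing_mm)
    if (!is.null(truth)) {
      mdir <- file.path(dir, "masks", sid)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(sw$frames)) {
        for (st in c("head", "placenta")) {
          png::writePNG(truth$masks[[st]][[sid]][[i]] * 1,
                        file.path(mdir, sprintf("%s_%03d.png", st, i - 1L)))
        }
      }
    }
  }
  meta <- list(sweeps = sidecar, labels = exam$labels,
               pixel_spacing_mm = exam$pixel_spacing_mm)
  jsonlite::write_json(meta, file.path(dir, "exam.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_exam
#' @export
read_exam <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "exam.json"), simplifyVector = TRUE)
  sweeps <- list()
  masks <- list(head = list(), placenta = list())
  have_masks <- dir.exists(file.path(dir, "masks"))
  for (sid in names(meta$sweeps)) {
    info <- meta$sweeps[[sid]]
    pages <- tiff::readTIFF(file.path(dir, paste0(sid, ".tiff")), all = TRUE)
    geom <- sweep_geometry(sid, info$orientation, unlist(info$band),
                           info$direction %||% "")
    frames <- lapply(seq_along(pages), function(i)
      list(pixels = pages[[i]],
           pixel_spacing_mm = unlist(info$pixel_spacing_mm),
           sweep_id = sid, frame_index = i - 1L))
    sweeps[[sid]] <- list(geometry = geom, frames = frames)
    if (have_masks) {
      mdir <- file.path(dir, "masks", sid)
      for (st in c("head", "placenta")) {
        masks[[st]][[sid]] <- lapply(seq_along(pages), function(i)
          png::readPNG(file.path(mdir, sprintf("%s_%03d.png", st, i - 1L))) > 0.5)
      }
    }
  }
  exam <- structure(list(sweeps = sweeps,
                         pixel_spacing_mm = meta$pixel_spacing_mm,
                         labels = meta$labels),
                    class = "vsi_exam")
  if (have_masks) attr(exam, "masks") <- masks
  exam
}

#' Write / read a sweep-geometry registry as JSON
#'
#' @param registry named list of [sweep_geometry()].
#' @param path JSON file path.
#' @return `write_registry`: path, invisibly; `read_registry`: the registry.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(lapply(registry, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- lapply(names(raw), function(id)
    sweep_geometry(id, raw[[id]]$orientation, unlist(raw[[id]]$band),
                   raw[[id]]$direction %||% ""))
  setNames(reg, names(raw))
}
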