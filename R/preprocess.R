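#' Convert an RGB frame to grayscale
#'
#' Applies the ITU-R 601 luminance weights (0.299, 0.587, 0.114). A
#' single-channel input passes through unchanged.
#'
#' @param frame_rgb `H x W x 3` array, `H x W` matrix, or a frame list whose
#'   `pixels` field is one of those.
#' @return The same structure with single-channel `pixels`.
#' @export
to_grayscale <- function(frame_rgb) {
  if (is.list(frame_rgb) && !is.null(frame_rgb$pixels)) {
    frame_rgb$pixels <- to_grayscale(frame_rgb$pixels)
    return(frame_rgb)
  }
  x <- frame_rgb
  if (is.matrix(x)) return(x)
  if (!is.array(x) || length(dim(x)) != 3 || !dim(x)[3] %in% c(1, 3))
    stop("expected 1 or 3 channels", call. = FALSE)
  if (dim(x)[3] == 1) return(x[, , 1])
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

#' Crop box constructor
#'
#' 0-based, half-open pixel box, e.g. the region of the scan that excludes
#' the device's burned-in setup parameters.
#'
#' @param top,left 0-based offsets of the first row/column kept.
#' @param height,width box extents in pixels (strictly positive).
#' @return A `crop_box` list.
#' @export
crop_box <- function(top, left, height, width) {
  if (height <= 0 || width <= 0)
    stop_field("crop_box", "height and width must be strictly positive")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "crop_box")
}

# Bilinear resize with half-pixel centre alignment; exact identity when the
# sizes are equal and exact constant preservation everywhere.
bilinear_resize <- function(m, out_h, out_w) {
  H <- nrow(m); W <- ncol(m)
  if (H == out_h && W == out_w) return(m)
  y <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  x <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  y <- pmin(pmax(y, 1), H); x <- pmin(pmax(x, 1), W)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  fy <- y - y0; fx <- x - x0
  A <- m[y0, x0, drop = FALSE]; B <- m[y0, x1, drop = FALSE]
  C <- m[y1, x0, drop = FALSE]; D <- m[y1, x1, drop = FALSE]
  top <- A + (B - A) * rep(fx, each = out_h)
  bot <- C + (D - C) * rep(fx, each = out_h)
  top + (bot - top) * fy
}

nearest_resize <- function(m, out_h, out_w) {
  H <- nrow(m); W <- ncol(m)
  if (H == out_h && W == out_w) return(m)
  y <- pmin(pmax(round((seq_len(out_h) - 0.5) * H / out_h + 0.5), 1), H)
  x <- pmin(pmax(round((seq_len(out_w) - 0.5) * W / out_w + 0.5), 1), W)
  m[y, x, drop = FALSE]
}

#' Resize a binary mask (nearest neighbour)
#' @param mask logical matrix.
#' @param out_size c(rows, cols).
#' @return Logical matrix of size `out_size`.
#' @export
resize_mask <- function(mask, out_size) {
  nearest_resize(mask, out_size[1], out_size[2]) != 0
}

#' Crop and resize a frame to the network input size
#'
#' The physical extent is preserved exactly: per axis,
#' `out_size * new_spacing == crop_extent * old_spacing`. The per-axis
#' (possibly anisotropic) spacing is recorded on the returned frame, and
#' the crop/scale transform is attached as attribute `transform`.
#'
#' @param frame matrix or frame list with `pixels` and `pixel_spacing_mm`
#'   (scalar or `c(row, col)` mm/px).
#' @param crop_box a [crop_box()] within the frame, or `NULL` for the full
#'   frame.
#' @param out_size target size `c(rows, cols)`, default `c(128, 128)`.
#' @return Frame list with `pixels` of size `out_size`, per-axis
#'   `pixel_spacing_mm`, and the originating `sweep_id`/`frame_index` if
#'   present.
#' @export
crop_and_resize <- function(frame, crop_box = NULL, out_size = c(128, 128)) {
  if (any(out_size <= 0)) stop_field("out_size", "must be strictly positive")
  px <- if (is.list(frame)) frame$pixels else frame
  sp <- if (is.list(frame)) frame$pixel_spacing_mm %||% 1 else 1
  sp <- rep_len(as.numeric(sp), 2L)
  H <- nrow(px); W <- ncol(px)
  if (is.null(crop_box)) crop_box <- crop_box(0L, 0L, H, W)
  if (crop_box$top < 0 || crop_box$left < 0 ||
      crop_box$top + crop_box$height > H || crop_box$left + crop_box$width > W)
    stop("crop box outside frame bounds", call. = FALSE)
  cropped <- px[crop_box$top + seq_len(crop_box$height),
                crop_box$left + seq_len(crop_box$width), drop = FALSE]
  out <- bilinear_resize(cropped, out_size[1], out_size[2])
  new_sp <- c(sp[1] * crop_box$height / out_size[1],
              sp[2] * crop_box$width / out_size[2])
  res <- list(pixels = out, pixel_spacing_mm = new_sp,
              sweep_id = if (is.list(frame)) frame$sweep_id else NULL,
              frame_index = if (is.list(frame)) frame$frame_index else NULL)
  attr(res, "transform") <- list(crop = crop_box, in_size = c(H, W),
                                 out_size = out_size, in_spacing = sp)
  res
}

#' Rebalance structure-present vs structure-absent frames
#'
#' Keeps every structure-present frame and randomly subsamples the absent
#' frames to the closest achievable positive:negative ratio, the deletion
#' strategy used to counter class imbalance (head 1:2 from 1:10, placenta
#' 1:1 from 1:4). If the target requires more negatives than exist, all are
#' kept and the result is flagged.
#'
#' @param dataset a `vsi_dataset`.
#' @param structure `"head"` or `"placenta"`.
#' @param target_ratio `c(positive, negative)` ratio, e.g. `c(1, 2)`.
#' @param seed seed for the negative subsample.
#' @return The rebalanced `vsi_dataset`, with attributes `achieved_ratio`
#'   and `ratio_warning` (TRUE when the target was infeasible).
#' @export
rebalance_frames <- function(dataset, structure = c("head", "placenta"),
                             target_ratio = c(1, 2), seed = 1L) {
  structure <- match.arg(structure)
  if (any(target_ratio <= 0)) stop_field("target_ratio", "must be positive")
  present <- dataset[[paste0(structure, "_present")]]
  pos <- which(present); neg <- which(!present)
  want <- round(length(pos) * target_ratio[2] / target_ratio[1])
  warn <- want > length(neg)
  keep_neg <- if (warn) {
    warning("target ratio infeasible: keeping all structure-absent frames")
    neg
  } else {
    with_seed(seed, sample(neg, want))
  }
  out <- dataset_subset(dataset, sort(c(pos, keep_neg)))
  attr(out, "achieved_ratio") <- length(keep_neg) / max(1L, length(pos))
  attr(out, "ratio_warning") <- warn
  out
}

#' Augment a frame/mask pair
#'
#' Intensity operations (brightness, contrast, blur) leave the mask
#' untouched; only the left-right reflection transforms the mask. Rotation
#' is deliberately not offered: frames from a convex probe with a
#' standardized region of interest must keep their orientation.
#'
#' @param frame matrix in `[0,1]`.
#' @param mask logical matrix of the same size.
#' @param ops character vector, subset of
#'   `c("brightness", "reflect_lr", "blur", "contrast")`, applied in order.
#' @param brightness_delta additive offset (clamped to `[0,1]`).
#' @param contrast_factor multiplicative contrast about 0.5.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @return list(frame, mask).
#' @export
augment <- function(frame, mask, ops, brightness_delta = 0.1,
                    contrast_factor = 1.2, blur_sigma = 1) {
  allowed <- c("brightness", "reflect_lr", "blur", "contrast")
  bad <- setdiff(ops, allowed)
  if (length(bad))
    stop_field("ops", paste("unknown augmentation:", paste(bad, collapse = ", ")))
  for (op in ops) {
    if (op == "brightness") {
      frame <- pmin(pmax(frame + brightness_delta, 0), 1)
    } else if (op == "contrast") {
      frame <- pmin(pmax(0.5 + (frame - 0.5) * contrast_factor, 0), 1)
    } else if (op == "blur") {
      frame <- gaussian_blur(frame, blur_sigma)
    } else if (op == "reflect_lr") {
      frame <- frame[, rev(seq_len(ncol(frame))), drop = FALSE]
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }
  }
  list(frame = frame, mask = mask)
}
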