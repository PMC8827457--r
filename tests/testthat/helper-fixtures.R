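# Shared fixture builders. Everything is generated in code at test time.

# A coarse phantom (2 mm pixels, 8 frames per sweep) keeps unit tests fast;
# geometry and labels are unchanged from the defaults.
tiny_phantom_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(pixel_spacing_mm = 2, frames_per_sweep = 12, seed = seed)
  do.call(phantom_config, utils::modifyList(defaults, args))
}

# Rasterized ellipse mask: semi-axes (a, b) in px, rotation theta (radians),
# on a square grid with margin.
raster_ellipse <- function(a, b, theta = 0, pad = 6) {
  n <- ceiling(2 * max(a, b)) + 2 * pad
  cx <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n) - cx, each = n), n, n)   # column offsets
  ys <- matrix(rep(seq_len(n) - cx, times = n), n, n)  # row offsets
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Independent per-pixel moment computation (kept separate from the package
# implementation on purpose): returns semi-axes of the equivalent ellipse.
moment_axes <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  x <- px[, 2]; y <- px[, 1]
  cov <- stats::cov(cbind(x, y)) * (nrow(px) - 1) / nrow(px)
  ev <- sort(eigen(cov, symmetric = TRUE)$values, decreasing = TRUE)
  2 * sqrt(ev)
}

ramanujan <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# A tiny dataset of synthetic frames where the mask is a pure function of
# the frame (bright disc on dark ground), for fast segmenter tests.
disc_dataset <- function(n_frames, size = 32L, n_patients = 1L, seed = 1L) {
  set.seed(seed)
  frames <- list(); masks <- list(); present <- logical(0)
  patient <- integer(0)
  for (i in seq_len(n_frames)) {
    has <- i %% 3 != 0
    m <- matrix(0.2 + 0.05 * matrix(rnorm(size * size), size), size, size)
    msk <- matrix(FALSE, size, size)
    if (has) {
      cx <- sample(10:(size - 10), 1); cy <- sample(10:(size - 10), 1)
      r <- sample(4:7, 1)
      d <- outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, `+`)
      msk <- d <= r^2
      m[msk] <- m[msk] + 0.6
    }
    m <- pmin(pmax(m, 0), 1)
    frames[[i]] <- m; masks[[i]] <- msk; present <- c(present, has)
    patient <- c(patient, ((i - 1L) %% n_patients) + 1L)
  }
  structure(list(frames = frames, head_masks = masks, placenta_masks = masks,
                 spacing = rep(list(c(1, 1)), n_frames),
                 head_present = present, placenta_present = present,
                 patient = patient,
                 sweep_id = rep("sweep1", n_frames),
                 frame_index = seq_len(n_frames) - 1L),
            class = "vsi_dataset")
}
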