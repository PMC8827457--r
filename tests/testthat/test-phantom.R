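test_that("config validation names the offending field", {
  expect_error(phantom_config(head_axes_mm = c(-1, 40, 40)), "head_axes_mm")
  expect_error(phantom_config(head_center = c(0.05, 0.5, 0.5)), "head_center")
  expect_error(phantom_config(head_center = c(0.8, 0.5, 0.5),
                              presentation_label = "cephalic"),
               "presentation_label")
  expect_error(phantom_config(frames_per_sweep = 4), "frames_per_sweep")
  expect_error(phantom_config(noise_level = -0.1), "noise_level")
  expect_error(phantom_config(pixel_spacing_mm = 0), "pixel_spacing_mm")
})

test_that("phantom generation is a pure function of (config, seed)", {
  cfg <- tiny_phantom_config(seed = 9)
  a <- make_phantom(cfg)
  b <- make_phantom(cfg)
  expect_identical(a$exam$sweeps$sweep1$frames[[3]]$pixels,
                   b$exam$sweeps$sweep1$frames[[3]]$pixels)
  expect_identical(a$truth$masks, b$truth$masks)
  c2 <- make_phantom(tiny_phantom_config(seed = 10))
  expect_false(identical(a$exam$sweeps$sweep1$frames[[3]]$pixels,
                         c2$exam$sweeps$sweep1$frames[[3]]$pixels))
})

test_that("a pelvic head intersects only pelvic-third vertical frames", {
  cfg <- tiny_phantom_config(seed = 2, head_center = c(0.2, 0.5, 0.5),
                             head_axes_mm = c(30, 45, 38))
  ph <- make_phantom(cfg)
  n <- cfg$frames_per_sweep
  for (sid in paste0("sweep", 1:4)) {
    areas <- vapply(ph$truth$masks$head[[sid]], sum, numeric(1))
    pos <- (seq_len(n) - 0.5) / n
    lo <- 0.2 - 30 / 300; hi <- 0.2 + 30 / 300
    expect_true(all(areas[pos < lo - 1e-9 | pos > hi + 1e-9] == 0))
    expect_true(any(areas[pos >= lo & pos <= hi] > 0))
  }
})

test_that("anterior placenta sits in the near-field half of every frame", {
  ph <- make_phantom(tiny_phantom_config(seed = 3,
                                         placenta_location_label = "anterior"))
  for (sid in names(ph$truth$masks$placenta)) {
    for (m in ph$truth$masks$placenta[[sid]]) {
      if (!any(m)) next
      centroid <- mean(row(m)[m]) / nrow(m)
      expect_lt(centroid, 0.5)
    }
  }
})

test_that("zero noise returns the exact rasterization; speckle is unit-mean", {
  cfg <- tiny_phantom_config(seed = 5)
  f0 <- render_frame(cfg, list(orientation = "vertical", position = 0.25),
                     noise_level = 0, seed_offset = 1)
  sec <- vsidiag:::render_section(cfg, "vertical", 0.25, c(0, 1))
  expect_identical(f0$pixels, sec$pixels)
  expect_true(all(f0$pixels >= 0 & f0$pixels <= 1))
  # Monte-Carlo: speckled frame mean approximately preserves the clean mean
  means <- vapply(1:20, function(k)
    mean(render_frame(cfg, list(orientation = "vertical", position = 0.25),
                      noise_level = 0.1, seed_offset = k)$pixels), numeric(1))
  expect_lt(abs(mean(means) - mean(sec$pixels)) / mean(sec$pixels), 0.02)
  expect_error(render_frame(cfg, list(orientation = "vertical", position = 1.4)),
               "intersect")
})

test_that("the plane through the head centre gives the maximal mask", {
  cfg <- tiny_phantom_config(seed = 6)
  ph <- make_phantom(cfg)
  areas <- vapply(ph$truth$masks$head$sweep1, sum, numeric(1))
  n <- cfg$frames_per_sweep
  centre_frame <- which.min(abs((seq_len(n) - 0.5) / n - cfg$head_center[1]))
  expect_equal(which.max(areas), centre_frame)
})

test_that("analytic BPD/HC agree with brute-force mask measurement", {
  cfg <- phantom_config(seed = 7, frames_per_sweep = 24)  # 1 mm pixels
  ph <- make_phantom(cfg)
  stacks <- ph$truth$masks$head
  areas <- lapply(stacks, vapply, sum, numeric(1))
  sid <- names(which.max(vapply(areas, max, numeric(1))))
  mask <- stacks[[sid]][[which.max(areas[[sid]])]]
  ax <- moment_axes(mask)                       # independent moments
  expect_equal(2 * ax[2], ph$truth$true_bpd_mm, tolerance = 0.015)
  expect_equal(ramanujan(ax[1], ax[2]), ph$truth$true_hc_mm,
               tolerance = 0.015)
  expect_equal(ph$truth$true_bpd_mm, 2 * sort(cfg$head_axes_mm, TRUE)[2])
})

test_that("head mask union is non-empty iff the ellipsoid meets a slice plane", {
  cfg <- tiny_phantom_config(seed = 8)
  ph <- make_phantom(cfg)
  any_mask <- any(vapply(ph$truth$masks$head,
                         function(s) any(vapply(s, any, logical(1))),
                         logical(1)))
  # analytic check: some vertical slice position falls within the head's
  # axial footprint
  n <- cfg$frames_per_sweep
  pos <- (seq_len(n) - 0.5) / n
  foot <- abs(pos - cfg$head_center[1]) < cfg$head_axes_mm[1] / 300
  expect_equal(any_mask, any(foot))
})

test_that("training set generation is deterministic with sane class ratios", {
  sampler <- function() sample_phantom_config(frames_per_sweep = 8,
                                              pixel_spacing_mm = 2)
  d1 <- gen_training_set(2, sampler, seed = 31, out_size = c(64, 64))
  d2 <- gen_training_set(2, sampler, seed = 31, out_size = c(64, 64))
  expect_identical(d1$frames, d2$frames)
  expect_identical(d1$head_present, d2$head_present)
  ratio <- attr(d1, "class_ratio")["head"]
  expect_gte(ratio, 0.05); expect_lte(ratio, 0.5)
  expect_equal(dim(d1$frames[[1]]), c(64L, 64L))
  # forcing the head into view everywhere drives the ratio to 1
  forced <- gen_training_set(1, function()
    phantom_config(head_center = c(0.499, 0.5, 0.5),
                   head_axes_mm = c(147, 128, 73),
                   abdomen_size_mm = c(300, 260, 150),
                   presentation_label = "cephalic",
                   frames_per_sweep = 8, pixel_spacing_mm = 2, seed = 1),
    seed = 32, out_size = c(32, 32))
  expect_equal(attr(forced, "class_ratio")[["head"]], 1)
})
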