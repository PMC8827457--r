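test_that("the network has 23 convolutional layers at the default depth", {
  layers <- unet_layers(unet_config())
  expect_equal(nrow(layers), 23L)
  # enumeration oracle: 2 convs per contracting scale incl. bottleneck,
  # (1 up-conv + 2 convs) per decoder level, 1 output conv = 5d + 3
  for (d in 2:4) {
    cfg <- unet_config(input_size = c(2^(d + 3), 2^(d + 3)), depth = d,
                       base_filters = 8)
    expect_equal(nrow(unet_layers(cfg)), 5L * d + 3L)
  }
  # filters double down the contracting path, halve up the expansive path
  enc <- layers[grepl("^e|^b", layers$name) & layers$kind == "conv3x3", ]
  expect_true(all(diff(enc$c_out) >= 0))
  expect_error(unet_config(input_size = c(100, 100), depth = 4), "divisible")
})

test_that("an untrained network emits probabilities strictly inside (0,1)", {
  cfg <- unet_config(input_size = c(32, 32), depth = 2, base_filters = 4,
                     seed = 5)
  model <- build_unet(cfg)
  set.seed(1)
  pr <- predict_mask(model, matrix(runif(32 * 32), 32))
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  expect_equal(dim(pr$prob), c(32L, 32L))
  expect_error(predict_mask(model, matrix(0, 16, 16)), "input size")
})

test_that("thresholding is a pure comparison on the probability map", {
  cfg <- unet_config(input_size = c(32, 32), depth = 2, base_filters = 4)
  model <- build_unet(cfg)
  f <- matrix(runif(32 * 32), 32)
  pr0 <- predict_mask(model, f, threshold = 0)
  expect_true(all(pr0$mask))
  pr1 <- predict_mask(model, f, threshold = 1)
  expect_equal(pr1$mask, pr1$prob >= 1)
})

test_that("the oracle segmenter returns ground truth exactly", {
  ph <- make_phantom(tiny_phantom_config(seed = 12))
  seg <- oracle_segmenter(ph$truth, "head")
  fr <- ph$exam$sweeps$sweep2$frames[[5]]
  pr <- predict_mask(seg, fr)
  expect_identical(pr$mask, ph$truth$masks$head$sweep2[[5]])
})

test_that("training on all-empty masks learns the empty prediction", {
  ds <- disc_dataset(24, size = 32, seed = 3)
  for (i in seq_along(ds$head_masks)) ds$head_masks[[i]][] <- FALSE
  ds$head_present[] <- FALSE
  cfg <- unet_config(input_size = c(32, 32), depth = 2, base_filters = 4,
                     epochs = 10, learning_rate = 0.02, seed = 2)
  model <- train_segmenter(ds, cfg, "head")
  pr <- predict_mask(model, ds$frames[[1]])
  expect_true(all(!pr$mask))
})

test_that("training is deterministic and its history is well-formed", {
  ds <- disc_dataset(30, size = 32, seed = 6)
  cfg <- unet_config(input_size = c(32, 32), depth = 2, base_filters = 4,
                     epochs = 3, seed = 11)
  m1 <- train_segmenter(ds, cfg, "head")
  m2 <- train_segmenter(ds, cfg, "head")
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 3L)
  expect_true(all(c("train_loss", "val_dice", "val_jaccard") %in%
                    names(m1$history)))
  # the 80/20 split covers the data without overlap
  expect_length(intersect(m1$split$train, m1$split$val), 0)
  expect_setequal(c(m1$split$train, m1$split$val), seq_along(ds$frames))
})

test_that("training loss trends downward at a reduced learning rate", {
  ds <- disc_dataset(30, size = 32, seed = 8)
  cfg <- unet_config(input_size = c(32, 32), depth = 2, base_filters = 4,
                     epochs = 5, learning_rate = 1e-4, seed = 3)
  m <- train_segmenter(ds, cfg, "head")
  l <- m$history$train_loss
  expect_true(all(diff(l) <= 0.05 * l[-length(l)]))
  expect_lt(l[length(l)], l[1])
})

test_that("detection series reproduce the frame-interval example", {
  blob <- matrix(FALSE, 20, 20); blob[5:12, 5:12] <- TRUE
  stack <- rep(list(matrix(FALSE, 20, 20)), 137)
  for (i in 77:92) stack[[i]] <- blob           # 1-based frames 77..92
  s <- detect_series(stack, min_area_px = 30, min_run = 3)
  expect_equal(which(s$present), 77:92)
  expect_true(all(s$area[77:92] == 64))
  expect_true(all(s$area[-(77:92)] == 0))
  empty <- detect_series(rep(list(matrix(FALSE, 4, 4)), 10))
  expect_true(all(!empty$present))
  single <- rep(list(matrix(FALSE, 20, 20)), 10); single[[5]] <- blob
  s2 <- detect_series(single, min_area_px = 30, min_run = 2)
  expect_true(all(!s2$present))                 # brute-force run scan: cleared
  expect_true(all(s2$area == 0))
})

test_that("depth centroid reflects the mask's row position", {
  m <- matrix(FALSE, 100, 50); m[10:20, 10:40] <- TRUE
  s <- detect_series(list(m), min_area_px = 10, min_run = 1)
  expect_equal(s$depth_centroid[1], (15 - 0.5) / 100, tolerance = 1e-12)
})

test_that("segmentation metrics: perfect, inverted and area-error cases", {
  blob <- matrix(FALSE, 16, 16); blob[4:9, 4:9] <- TRUE
  perf <- segmentation_metrics(list(blob, blob), list(blob, blob))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$jaccard, 1)
  expect_equal(perf$dice, 1)
  expect_equal(perf$area_error_pct, 0)
  inv <- segmentation_metrics(list(!blob), list(blob))
  expect_equal(inv$jaccard, 0)
  p1 <- matrix(FALSE, 20, 20); p1[1:9, 1:10] <- TRUE    # 90 px
  p2 <- matrix(FALSE, 20, 20); p2[1:10, 1:11] <- TRUE   # 110 px
  t1 <- matrix(FALSE, 20, 20); t1[1:10, 1:10] <- TRUE   # 100 px
  m <- segmentation_metrics(list(p1, p2), list(t1, t1))
  expect_equal(m$area_error_pct, 10)
  und <- segmentation_metrics(list(blob), list(blob & FALSE))
  expect_false(und$pixel_metrics_defined)
})

test_that("Dice and Jaccard satisfy D = 2J/(1+J) on random masks", {
  set.seed(17)
  for (i in 1:25) {
    a <- matrix(runif(400) < 0.4, 20)
    b <- matrix(runif(400) < 0.4, 20)
    inter <- sum(a & b)
    dice <- 2 * inter / (sum(a) + sum(b))
    jac <- inter / sum(a | b)
    expect_equal(dice, 2 * jac / (1 + jac), tolerance = 1e-12)
  }
})

test_that("models survive a save/load round trip", {
  ds <- disc_dataset(12, size = 32, seed = 4)
  cfg <- unet_config(input_size = c(32, 32), depth = 2, base_filters = 4,
                     epochs = 1, seed = 7)
  m <- train_segmenter(ds, cfg, "head")
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  f <- ds$frames[[1]]
  expect_equal(predict_mask(m, f)$prob, predict_mask(m2, f)$prob)
})
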