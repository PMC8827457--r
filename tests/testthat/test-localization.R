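test_that("map dimensions follow the largest-sweep rule", {
  reg <- default_registry()
  lens <- c(sweep1 = 137L, sweep2 = 120L, sweep3 = 100L, sweep4 = 90L,
            sweep5 = 144L, sweep6 = 130L, sweep7 = 101L, sweep8 = 99L)
  m <- init_map(lens, reg)
  expect_equal(dim(m$counts), c(137L, 144L))
  expect_true(all(m$counts == 0))

  lens10 <- setNames(rep(10L, 8), names(reg))
  expect_equal(dim(init_map(lens10, reg)$counts), c(10L, 10L))

  reg2 <- list(
    v = sweep_geometry("v", "vertical", c(0.4, 0.6)),
    h = sweep_geometry("h", "horizontal", c(0.4, 0.6)))
  expect_equal(dim(init_map(c(v = 5L, h = 7L), reg2)$counts), c(5L, 7L))

  regv <- list(v = sweep_geometry("v", "vertical", c(0.4, 0.6)))
  expect_error(init_map(c(v = 5L), regv), "horizontal")
})

test_that("rescale_detections is nearest-index resampling", {
  v <- rep(FALSE, 10); v[4:6] <- TRUE         # 0-based frames 3..5
  out <- rescale_detections(v, 20)
  expect_equal(which(out), 7:12)              # 0-based cells 6..11
  # brute-force oracle over every target index
  oracle <- vapply(seq_len(20), function(j) v[floor((j - 1) * 10 / 20) + 1],
                   logical(1))
  expect_equal(out, oracle)
  expect_identical(rescale_detections(v, 10), v)
  expect_true(all(rescale_detections(rep(TRUE, 4), 11)))
  expect_error(rescale_detections(v, 5), "not supported")
})

test_that("a run of k detections maps to a run of about k * target/len cells", {
  set.seed(11)
  for (i in 1:25) {
    len <- sample(5:20, 1); target <- len + sample(0:30, 1)
    k <- sample(1:len, 1); s <- sample(seq_len(len - k + 1), 1)
    v <- rep(FALSE, len); v[s:(s + k - 1)] <- TRUE
    out <- rescale_detections(v, target)
    expect_lte(abs(sum(out) - round(k * target / len)), 1)
  }
})

test_that("accumulate_sweep places votes in band and overlap adds", {
  reg <- list(v = sweep_geometry("v", "vertical", c(0.375, 0.625)),
              h = sweep_geometry("h", "horizontal", c(0.375, 0.625)))
  lens <- c(v = 137L, h = 144L)
  m <- init_map(lens, reg)
  det <- rep(FALSE, 137); det[77:92] <- TRUE   # 1-based frames 77..92
  m1 <- accumulate_sweep(m, reg$v, det)
  hit_rows <- which(rowSums(m1$counts) > 0)
  expect_equal(hit_rows, 77:92)
  expect_true(all(m1$counts %in% c(0, 1)))
  deth <- rep(FALSE, 144); deth[40:60] <- TRUE
  m2 <- accumulate_sweep(m1, reg$h, deth)
  expect_equal(max(m2$counts), 2)              # crossing blocks overlap
  expect_equal(sort(unique(as.vector(m2$counts))), c(0, 1, 2))
  m3 <- accumulate_sweep(m, reg$v, rep(FALSE, 137))
  expect_true(all(m3$counts == 0))
})

test_that("smoothing preserves mass, symmetry and the argmax", {
  reg <- list(v = sweep_geometry("v", "vertical", c(0.3, 0.7)),
              h = sweep_geometry("h", "horizontal", c(0.3, 0.7)))
  m <- init_map(c(v = 21L, h = 21L), reg)
  m$counts[11, 11] <- 1
  sm <- smooth_map(m, 2)
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)
  expect_equal(which(sm$values == max(sm$values), arr.ind = TRUE)[1, ],
               c(row = 11L, col = 11L))
  expect_equal(sm$values, t(sm$values), tolerance = 1e-12)  # symmetric bump
  id <- smooth_map(m, 0)
  expect_identical(id$values, m$counts)
})

test_that("pre-smoothing maps equal brute-force indicator summation", {
  set.seed(21)
  for (rep_i in 1:30) {
    nv <- sample(1:2, 1); nh <- sample(1:2, 1)
    reg <- list(); lens <- integer(0)
    for (i in seq_len(nv)) {
      id <- sprintf("v%d", i)
      b <- sort(runif(2)); if (diff(b) < 0.05) b[2] <- min(1, b[1] + 0.1)
      reg[[id]] <- sweep_geometry(id, "vertical", b)
      lens[id] <- sample(4:12, 1)
    }
    for (i in seq_len(nh)) {
      id <- sprintf("h%d", i)
      b <- sort(runif(2)); if (diff(b) < 0.05) b[2] <- min(1, b[1] + 0.1)
      reg[[id]] <- sweep_geometry(id, "horizontal", b)
      lens[id] <- sample(4:12, 1)
    }
    dets <- lapply(lens, function(n) runif(n) < 0.4)
    map <- build_likelihood_map(lens, dets, reg, sigma = 0)
    # brute force: sum of outer indicator products per sweep
    R <- nrow(map$counts); C <- ncol(map$counts)
    ref <- matrix(0, R, C)
    for (id in names(dets)) {
      g <- reg[[id]]
      if (g$orientation == "vertical") {
        d <- rescale_detections(dets[[id]], R)
        colsin <- (seq_len(C) - 0.5) / C >= g$band[1] &
                  (seq_len(C) - 0.5) / C <= g$band[2]
        ref <- ref + outer(as.numeric(d), as.numeric(colsin))
      } else {
        d <- rescale_detections(dets[[id]], C)
        rowsin <- (seq_len(R) - 0.5) / R >= g$band[1] &
                  (seq_len(R) - 0.5) / R <= g$band[2]
        ref <- ref + outer(as.numeric(rowsin), as.numeric(d))
      }
    }
    expect_equal(map$counts, ref)
    expect_true(all(map$counts == round(map$counts)))
    expect_lte(max(map$counts), length(dets))
  }
})

test_that("map construction is order-invariant and monotone", {
  reg <- default_registry()
  lens <- setNames(rep(12L, 8), names(reg))
  set.seed(3)
  dets <- lapply(lens, function(n) runif(n) < 0.5)
  m1 <- build_likelihood_map(lens, dets, reg, sigma = 0)
  m2 <- build_likelihood_map(lens, dets[sample(names(dets))], reg, sigma = 0)
  expect_equal(m1$counts, m2$counts)
  # adding a detection never decreases any cell
  id <- "sweep2"
  if (any(!dets[[id]])) {
    dets2 <- dets
    dets2[[id]][which(!dets2[[id]])[1]] <- TRUE
    m3 <- build_likelihood_map(lens, dets2, reg, sigma = 0)
    expect_true(all(m3$counts >= m1$counts))
  }
  # no detections anywhere -> all-zero map
  m0 <- build_likelihood_map(lens, lapply(lens, function(n) rep(FALSE, n)), reg)
  expect_true(all(m0$values == 0))
})

test_that("centroid sits where the mass is", {
  reg <- default_registry()
  lens <- setNames(rep(20L, 8), names(reg))
  dets <- lapply(lens, function(n) rep(FALSE, n))
  for (id in paste0("sweep", 1:4)) dets[[id]][2:5] <- TRUE  # pelvic end
  m <- build_likelihood_map(lens, dets, reg, sigma = 0)
  expect_lt(map_centroid(m)$axial, 0.5)
})
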