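# Quadrant split, correction factor, threshold rules and mask assembly.

test_that("quadrant split partitions the image, extra row/col going top/left", {
  px <- array(sample(0:255, 100 * 100 * 3, TRUE), c(100, 100, 3))
  qs <- split_quadrants(px)
  expect_length(qs, 4)
  expect_true(all(vapply(qs, function(q) all(dim(q$pixels)[1:2] == c(50, 50)), TRUE)))

  px2 <- array(0L, c(101, 100, 3))
  qs2 <- split_quadrants(px2)
  expect_identical(dim(qs2[[1]]$pixels)[1], 51L)
  expect_identical(dim(qs2[[3]]$pixels)[1], 50L)

  # reassembly reproduces the image bit-exactly
  recon <- array(0L, dim(px))
  for (q in qs)
    recon[(q$r0 + 1):q$r1, (q$c0 + 1):q$c1, ] <- q$pixels
  expect_identical(recon, px)
})

test_that("correction factor follows cf = 85 / mean over ROI pixels", {
  q <- split_quadrants(uniform_image(100, 100, c(85, 85, 85)))[[1]]
  expect_equal(correction_factor(q), 1.0)
  q2 <- split_quadrants(uniform_image(100, 100, c(170, 170, 170)))[[1]]
  expect_equal(correction_factor(q2), 0.5)

  # zeroed non-ROI pixels are excluded from the mean
  px <- uniform_image(100, 100, c(85, 85, 85))
  roi <- structure(list(pixels = px, roi_mask = matrix(FALSE, 100, 100)),
                   class = "roi_image")
  roi$roi_mask[1:50, ] <- TRUE
  px[51:100, , ] <- 0
  roi$pixels <- px
  q3 <- split_quadrants(roi)[[1]]
  expect_equal(correction_factor(q3), 1.0)

  q4 <- split_quadrants(uniform_image(100, 100, c(0, 0, 0)))[[1]]
  expect_error(correction_factor(q4), "undefined")
})

test_that("fixed thresholds scale with cf and respect their caps", {
  expect_equal(fixed_thresholds(1), c(C = 40, M = 30, custom = 120))
  expect_equal(fixed_thresholds(5), c(C = 100, M = 30, custom = 150))
  expect_equal(fixed_thresholds(0.5), c(C = 20, M = 30, custom = 60))
  # monotone nondecreasing in cf
  cfs <- seq(0.1, 6, by = 0.1)
  th <- t(vapply(cfs, fixed_thresholds, numeric(3)))
  expect_true(all(diff(th[, 1]) >= 0))
  expect_true(all(diff(th[, 3]) >= 0))
  expect_true(all(th[, 1] <= 100) && all(th[, 3] <= 150))
  expect_error(fixed_thresholds(-1), "positive")
})

test_that("very dark quadrants get threshold 10 and unimodal ones are discarded", {
  set.seed(1)
  dark <- c(sample(0:9, 60000, TRUE), sample(100:255, 40000, TRUE))
  res <- y_quadrant_threshold(dark)
  expect_identical(res$status, "dark")
  expect_identical(res$threshold, 10L)

  uni <- pmin(pmax(round(stats::rnorm(50000, 140, 20)), 0), 255)
  res2 <- y_quadrant_threshold(uni)
  expect_identical(res2$status, "discarded")
  expect_true(is.na(res2$threshold))

  expect_error(y_quadrant_threshold(integer(0)), "empty")
})

test_that("bimodal histograms yield the valley chosen by the brute-force rules", {
  set.seed(2)
  vals <- c(round(stats::rnorm(6000, 60, 8)), round(stats::rnorm(24000, 180, 10)))
  vals <- pmin(pmax(vals, 0), 255)
  res <- y_quadrant_threshold(vals)
  ref <- oracle_y_threshold(vals)
  expect_identical(res$status, "valid")
  expect_identical(res$threshold, ref$threshold)
  expect_gt(res$threshold, 60)
  expect_lt(res$threshold, 180)
})

test_that("y threshold chain equals the bin-by-bin oracle across branches", {
  for (s in c(1:40, 101:140)) {
    v <- random_hist_values(s)
    a <- y_quadrant_threshold(v)
    b <- oracle_y_threshold(v)
    expect_identical(a$status, b$status)
    expect_identical(as.integer(a$threshold), b$threshold)
  }
})

test_that("quadrants below the active-pixel floor contribute all-black masks", {
  # bottom-right quadrant gets only 49,999 pixels with Y > 0: one short of
  # the floor, so the whole quadrant is discarded
  H <- 640; W <- 640
  px <- uniform_image(H, W, c(95, 140, 70))        # Y > 0 everywhere
  idx <- which(matrix(TRUE, 320, 320))[1:(320 * 320 - 49999)]
  sub <- px[321:640, 321:640, ]
  for (ch in c(1, 2)) { s <- sub[, , ch]; s[idx] <- 0; sub[, , ch] <- s }
  s <- sub[, , 3]; s[idx] <- 200; sub[, , 3] <- s   # B max => Y = 0
  px[321:640, 321:640, ] <- sub
  ms <- build_mask_set(px)
  qi <- ms$quadrants[[4]]
  expect_false(qi$active)
  expect_identical(qi$n_active_y, 49999L)
  for (nm in c("mask_C", "mask_M", "mask_Y_T", "mask_Y_T2", "mask_Y_T4", "mask_custom"))
    expect_false(any(ms[[nm]][321:640, 321:640]))
  # one more active pixel and the quadrant participates again
  s <- sub[, , 3]; s[idx[1]] <- 60; sub[, , 3] <- s
  s <- sub[, , 2]; s[idx[1]] <- 140; sub[, , 2] <- s
  s <- sub[, , 1]; s[idx[1]] <- 95; sub[, , 1] <- s
  px[321:640, 321:640, ] <- sub
  ms2 <- build_mask_set(px)
  expect_identical(ms2$quadrants[[4]]$n_active_y, 50000L)
  expect_true(ms2$quadrants[[4]]$active)
})

test_that("mask sets honour the ROI, the nesting and the global threshold", {
  sc <- generate_scene(scene_spec(n_animals = 3,
                                  cluster_size_distribution = c(1, rep(0, 7))), 5)
  grid <- tile_image(sc$image, 224)
  roi <- build_roi(sc$image, grid, classifier_truth(sc$truth, 640, 640))
  ms <- build_mask_set(roi)

  # no white pixel outside the ROI
  for (nm in c("mask_C", "mask_M", "mask_Y_T", "mask_Y_T2", "mask_Y_T4", "mask_custom"))
    expect_false(any(ms[[nm]] & !roi$roi_mask))
  # threshold monotonicity: quarter threshold is the most restrictive
  expect_true(all(ms$mask_Y_T4 <= ms$mask_Y_T2))
  expect_true(all(ms$mask_Y_T2 <= ms$mask_Y_T))
  # global threshold is the smallest valid quadrant threshold
  thr <- vapply(ms$quadrants, function(q)
    if (q$active && q$y_status %in% c("valid", "dark")) as.numeric(q$y_threshold)
    else NA_real_, 0)
  expect_identical(ms$global_Y_threshold, as.integer(min(thr, na.rm = TRUE)))
  # every truth animal pixel is white in the most permissive Y mask
  fp <- truth_mask(sc$truth, 640, 640)
  expect_gt(mean(ms$mask_Y_T[fp]), 0.98)
})

test_that("scenes without usable content flag the Y masks as invalid", {
  px <- uniform_image(640, 640, c(95, 140, 70))   # no animals: unimodal Y
  ms <- build_mask_set(px)
  expect_false(ms$y_valid)
  expect_false(any(ms$mask_Y_T) || any(ms$mask_Y_T2) || any(ms$mask_Y_T4))
})
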