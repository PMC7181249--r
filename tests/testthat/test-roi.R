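# Grid tiling and region-of-interest extraction.

test_that("tiling partitions the image with truncated edge tiles", {
  g <- tile_image(uniform_image(448, 448, c(1, 2, 3)), 224)
  expect_identical(nrow(g$tiles), 4L)

  g1 <- tile_image(uniform_image(224, 224, c(0, 0, 0)), 224)
  expect_identical(nrow(g1$tiles), 1L)
  expect_identical(unname(unlist(g1$tiles[1, c("r0", "r1", "c0", "c1")])),
                   c(0L, 224L, 0L, 224L))

  g2 <- tile_image(uniform_image(500, 300, c(0, 0, 0)), 224)
  expect_identical(nrow(g2$tiles), 6L)
  # last row/col tiles truncated to the remainders
  expect_identical(max(g2$tiles$r1 - g2$tiles$r0), 224L)
  expect_identical(min(g2$tiles$r1 - g2$tiles$r0), 500L - 2L * 224L)
  expect_identical(min(g2$tiles$c1 - g2$tiles$c0), 300L - 224L)

  # every pixel belongs to exactly one tile
  cover <- matrix(0L, 500, 300)
  for (i in seq_len(nrow(g2$tiles)))
    cover[(g2$tiles$r0[i] + 1):g2$tiles$r1[i],
          (g2$tiles$c0[i] + 1):g2$tiles$c1[i]] <-
      cover[(g2$tiles$r0[i] + 1):g2$tiles$r1[i],
            (g2$tiles$c0[i] + 1):g2$tiles$c1[i]] + 1L
  expect_true(all(cover == 1L))

  expect_error(tile_image(uniform_image(100, 448, c(0, 0, 0)), 224), "smaller")
})

test_that("constant classifiers keep or zero the whole image", {
  px <- uniform_image(448, 448, c(10, 20, 30))
  g <- tile_image(px, 224)
  roi_all <- build_roi(px, g, classifier_constant("cattle"))
  expect_identical(roi_all$pixels, array(px, dim(px)))
  expect_true(all(roi_all$roi_mask))

  roi_none <- build_roi(px, g, classifier_constant("non_cattle"))
  expect_true(all(roi_none$pixels == 0L))
  expect_false(any(roi_none$roi_mask))
})

test_that("truth-oracle classifier keeps every animal pixel in the ROI", {
  sc <- generate_scene(scene_spec(n_animals = 3,
                                  cluster_size_distribution = c(1, rep(0, 7))), 3)
  g <- tile_image(sc$image, 224)
  clf <- classifier_truth(sc$truth, 640, 640)
  roi <- build_roi(sc$image, g, clf)
  fp <- truth_mask(sc$truth, 640, 640)
  expect_true(all(roi$roi_mask[fp]))
  # pixels outside the ROI are exactly zero, and the mask is a tile union
  expect_true(all(roi$pixels[!array(roi$roi_mask, dim(roi$pixels))] == 0L))
  labs <- roi$grid$tiles$label
  expect_true(all(labs %in% c("cattle", "non_cattle")))
  expect_gt(sum(labs == "non_cattle"), 0)
})

test_that("building the ROI twice with the same labels is a no-op", {
  sc <- generate_scene(scene_spec(n_animals = 3,
                                  cluster_size_distribution = c(1, rep(0, 7))), 4)
  g <- classify_tiles(sc$image, tile_image(sc$image, 224),
                      classifier_truth(sc$truth, 640, 640))
  roi1 <- build_roi(sc$image, g)
  roi2 <- build_roi(roi1$pixels, g)
  expect_identical(roi1$pixels, roi2$pixels)
  expect_identical(roi1$roi_mask, roi2$roi_mask)
})

test_that("classifier contract violations are reported", {
  px <- uniform_image(448, 448, c(1, 1, 1))
  g <- tile_image(px, 224)
  expect_error(build_roi(px, g, function(tile, window) "bovine"),
               "contract violation")
  expect_error(build_roi(px, g, function(tile, window) 1L),
               "contract violation")
})

test_that("the brightness heuristic separates coat tiles from pasture", {
  sc <- generate_scene(scene_spec(n_animals = 3,
                                  cluster_size_distribution = c(1, rep(0, 7))), 6)
  g <- classify_tiles(sc$image, tile_image(sc$image, 224),
                      classifier_brightness())
  fp <- truth_mask(sc$truth, 640, 640)
  for (i in seq_len(nrow(g$tiles))) {
    t <- g$tiles[i, ]
    n_animal <- sum(fp[(t$r0 + 1):t$r1, (t$c0 + 1):t$c1])
    n_tile <- (t$r1 - t$r0) * (t$c1 - t$c0)
    # tiles with a substantial animal presence must be accepted, empty
    # pasture tiles rejected (slivers below the fraction cutoff may go
    # either way by design)
    if (n_animal >= 0.05 * n_tile) expect_identical(t$label, "cattle")
    if (n_animal == 0) expect_identical(t$label, "non_cattle")
  }
})
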