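# Scene and survey generation: determinism, truth consistency, geometry.

test_that("scene generation is deterministic and honours the empty case", {
  sp <- scene_spec()
  a <- generate_scene(sp, 7)
  b <- generate_scene(sp, 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$animals, b$truth$animals)
  c <- generate_scene(sp, 8)
  expect_false(identical(a$image$pixels, c$image$pixels))

  empty <- generate_scene(scene_spec(n_animals = 0), 1)
  expect_identical(empty$truth$n, 0L)
  expect_identical(nrow(empty$truth$animals), 0L)
})

test_that("singleton scenes render disjoint ellipses matching their truth", {
  sp <- scene_spec(n_animals = 4, cluster_size_distribution = c(1, rep(0, 7)))
  sc <- generate_scene(sp, 7)
  an <- sc$truth$animals
  expect_identical(nrow(an), 4L)
  expect_true(all(table(an$cluster) == 1))
  # footprints pairwise disjoint
  fps <- lapply(seq_len(4), function(i) truth_mask(an[i, ], 640, 640))
  for (i in 1:3) for (j in (i + 1):4)
    expect_identical(sum(fps[[i]] & fps[[j]]), 0L)
  # rendered coat pixels are bright where the truth says an animal is
  px <- sc$image$pixels
  inside <- truth_mask(sc$truth, 640, 640)
  expect_gt(mean(px[, , 1][inside]), 150)
})

test_that("clusters are connected unions of touching members", {
  sp <- scene_spec(n_animals = 3, cluster_size_distribution = c(0, 0, 1, rep(0, 5)))
  sc <- generate_scene(sp, 11)
  an <- sc$truth$animals
  expect_identical(unique(an$cluster), 1L)
  u <- truth_mask(sc$truth, 640, 640)
  expect_identical(max(label_components(u)), 1L)
})

test_that("rendered animal areas match the configured size model", {
  areas <- numeric(0)
  for (s in 1:15) {
    sc <- generate_scene(scene_spec(n_animals = 4,
                                    cluster_size_distribution = c(1, rep(0, 7))), s)
    an <- sc$truth$animals
    areas <- c(areas, vapply(seq_len(nrow(an)), function(i)
      sum(truth_mask(an[i, ], 640, 640)), 0))
  }
  expect_gt(mean(areas), 13000 * 0.85)
  expect_lt(mean(areas), 13000 * 1.15)
})

test_that("capacity errors are raised for impossible requests", {
  expect_error(generate_scene(scene_spec(n_animals = 60,
                                         cluster_size_distribution = c(1, rep(0, 7))), 1),
               "capacity")
  expect_error(scene_spec(width = 300), "448")
  expect_error(scene_spec(cluster_size_distribution = rep(0.2, 8)), "summing to 1")
  expect_error(scene_spec(major_axis_px = c(-5, 10)), "positive")
})

test_that("surveys crop one world mosaic with exact transforms", {
  spv <- survey_spec(n_frames = 5, overlap = 0.7, n_animals = 20)
  sv <- generate_survey(spv, 3)
  expect_length(sv$frames, 5)
  expect_equal(sv$overlap, 0.7, tolerance = 0.02)
  ts <- vapply(sv$frames, function(f) as.numeric(f$timestamp), 0)
  expect_true(all(diff(ts) > 0))

  # an animal visible in two frames sits at positions differing by the
  # true translation
  common <- intersect(sv$truths[[1]]$animals$id, sv$truths[[2]]$animals$id)
  expect_gt(length(common), 0)
  a1 <- sv$truths[[1]]$animals
  a2 <- sv$truths[[2]]$animals
  k <- common[1]
  expect_equal(a2$center_c[a2$id == k] - a1$center_c[a1$id == k], -sv$step)
  expect_equal(a2$center_r[a2$id == k], a1$center_r[a1$id == k])

  # registry equals the union of per-frame truths under the true offsets
  seen <- unique(unlist(lapply(sv$truths, function(t) t$animals$id)))
  expect_setequal(seen, sv$registry$id)
  expect_identical(nrow(sv$registry), 20L)
})

test_that("single-frame surveys degenerate to the frame truth", {
  sv <- generate_survey(survey_spec(n_frames = 1, n_animals = 5), 9)
  expect_identical(sort(sv$truths[[1]]$animals$id), sort(sv$registry$id))
})

test_that("overlap outside the feasible range is rejected", {
  expect_error(survey_spec(overlap = 0.95), "overlap")
  expect_error(survey_spec(overlap = 0.999), "overlap")
})

test_that("frames round-trip through PNG plus JSON metadata", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(scene_spec(n_animals = 2,
                                  cluster_size_distribution = c(1, rep(0, 7))), 5)
  p <- file.path(dir, "frame.png")
  write_frame(sc$image, p)
  back <- read_frame(p)
  expect_identical(back$pixels, sc$image$pixels)
  expect_equal(as.numeric(back$timestamp), as.numeric(sc$image$timestamp))
  expect_equal(back$lat, sc$image$lat)
})
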