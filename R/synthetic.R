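#' Specification of a synthetic pasture scene
#'
#' Describes the statistical structure of a generated survey frame: a
#' textured pasture background, light-coated elliptical animals of roughly
#' 13,000 px each at a 1 cm/px ground sample distance (calves at a quarter
#' of the adult area), clusters of touching animals, optional distractor
#' structures (white-roofed shed, light-blue feeder, tree), and a global
#' exposure bias. These defaults are the study conditions every downstream
#' stage is exercised against.
#'
#' @param width,height frame dimensions in pixels (>= 448, so the ROI grid
#'   has at least four tiles).
#' @param background_kind one of `"green_pasture"`, `"dry_pasture"`,
#'   `"bare_soil"`, `"mixed"`.
#' @param background_mean_rgb mean background color; `NULL` picks a
#'   kind-specific default.
#' @param noise_sd per-channel Gaussian pixel noise, intensity units.
#' @param n_animals total number of animals in the scene.
#' @param cluster_size_distribution probability vector over cluster sizes
#'   1..8; must sum to 1 within 1e-9.
#' @param calf_fraction probability that an animal is a calf (0.25x adult
#'   area, placed touching an adult of its cluster when one exists).
#' @param major_axis_px,minor_axis_px ranges (length-2) of the adult ellipse
#'   semi-axes in pixels. The defaults give a mean area of about 12,700 px.
#' @param coat_mean_rgb mean coat color (white to light beige).
#' @param coat_shading maximum relative darkening of the shaded flank.
#' @param distractors character subset of `c("shed", "feeder", "tree")`.
#' @param exposure_bias multiplicative exposure factor (<1 under-, >1
#'   over-exposure).
#' @param edge_margin_px minimum clearance between any animal footprint and
#'   the image edge (kept a little wider than the de-duplication border
#'   band so that a static survey conserves its animal registry).
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(width = 640, height = 640,
                       background_kind = "green_pasture",
                       background_mean_rgb = NULL,
                       noise_sd = 6,
                       n_animals = 4,
                       cluster_size_distribution = c(0.7, 0.2, 0.1, 0, 0, 0, 0, 0),
                       calf_fraction = 0,
                       major_axis_px = c(80, 100),
                       minor_axis_px = c(40, 50),
                       coat_mean_rgb = c(228, 220, 200),
                       coat_shading = 0.25,
                       distractors = character(0),
                       exposure_bias = 1,
                       edge_margin_px = 16) {
  if (width < 448 || height < 448)
    stopf("scene dimensions must be at least 448 px")
  p <- cluster_size_distribution
  if (length(p) != 8 || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stopf("cluster_size_distribution must be 8 probabilities summing to 1")
  if (any(major_axis_px <= 0) || any(minor_axis_px <= 0))
    stopf("animal axes must be positive")
  if (calf_fraction < 0 || calf_fraction > 1)
    stopf("calf_fraction must be in [0,1]")
  if (!background_kind %in% c("green_pasture", "dry_pasture", "bare_soil", "mixed"))
    stopf("unknown background_kind '%s'", background_kind)
  bad <- setdiff(distractors, c("shed", "feeder", "tree"))
  if (length(bad) > 0) stopf("unknown distractors: %s", paste(bad, collapse = ","))
  structure(list(
    width = as.integer(width), height = as.integer(height),
    background_kind = background_kind,
    background_mean_rgb = background_mean_rgb,
    noise_sd = noise_sd, n_animals = as.integer(n_animals),
    cluster_size_distribution = p, calf_fraction = calf_fraction,
    major_axis_px = major_axis_px, minor_axis_px = minor_axis_px,
    coat_mean_rgb = coat_mean_rgb, coat_shading = coat_shading,
    distractors = distractors, exposure_bias = exposure_bias,
    edge_margin_px = edge_margin_px), class = "scene_spec")
}

background_base_rgb <- function(kind) {
  switch(kind,
         green_pasture = c(95, 140, 70),
         dry_pasture   = c(205, 190, 120),
         bare_soil     = c(150, 100, 70),
         mixed         = c(150, 165, 95))
}

# Ellipse support radius along world direction phi for an ellipse with
# semi-axes (a, b) and major-axis orientation theta.
ellipse_radius <- function(a, b, theta, phi) {
  psi <- phi - theta
  (a * b) / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# Support function: half-width of the ellipse projected onto direction phi.
# If two ellipses' center distance along phi exceeds the sum of their
# supports, a separating line perpendicular to phi exists and they are
# disjoint.
ellipse_support <- function(a, b, theta, phi) {
  psi <- phi - theta
  sqrt((a * cos(psi))^2 + (b * sin(psi))^2)
}

# Axis-aligned bounding half-extents (rows, cols) of an ellipse.
ellipse_extents <- function(a, b, theta) {
  c(r = sqrt((a * sin(theta))^2 + (b * cos(theta))^2),
    c = sqrt((a * cos(theta))^2 + (b * sin(theta))^2))
}

# Anti-aliased coverage of one ellipse inside an H x W frame; returns a list
# with the integer bbox (1-based, clipped) and the coverage matrix, or NULL
# if the ellipse misses the frame.
ellipse_coverage <- function(cr, cc, a, b, theta, H, W) {
  ext <- ellipse_extents(a, b, theta)
  r0 <- max(1L, floor(cr - ext["r"]) + 1L - 1L); r1 <- min(H, ceiling(cr + ext["r"]) + 2L)
  c0 <- max(1L, floor(cc - ext["c"]) + 1L - 1L); c1 <- min(W, ceiling(cc + ext["c"]) + 2L)
  r0 <- max(1L, r0); c0 <- max(1L, c0)
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dr <- (rows - 1) - cr            # pixel centers at 0-based integer coords
  dc <- (cols - 1) - cc
  DR <- matrix(dr, length(rows), length(cols))
  DC <- matrix(dc, length(rows), length(cols), byrow = TRUE)
  u <- (DC * cos(theta) + DR * sin(theta)) / a
  v <- (-DC * sin(theta) + DR * cos(theta)) / b
  q <- sqrt(u^2 + v^2)
  cov <- clip01((1 - q) * min(a, b) + 0.5)   # ~1 px anti-aliased edge
  if (all(cov == 0)) return(NULL)
  list(rows = rows, cols = cols, cov = cov, v = v)
}

# Low-frequency multiplicative blotch field emulating pasture heterogeneity.
blotch_field <- function(H, W, n_waves = 4, amp = 0.10) {
  f <- matrix(0, H, W)
  r <- matrix(0:(H - 1), H, W)
  c <- matrix(0:(W - 1), H, W, byrow = TRUE)
  for (k in seq_len(n_waves)) {
    fr <- stats::runif(1, 0.5, 2.5) / H
    fc <- stats::runif(1, 0.5, 2.5) / W
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::runif(1, 0.3, 1) * cos(2 * pi * (fr * r + fc * c) + ph)
  }
  1 + amp * f / max(abs(f))
}

sample_cluster_sizes <- function(n, p) {
  sizes <- integer(0)
  left <- n
  while (left > 0) {
    s <- sample.int(8, 1, prob = p)
    s <- min(s, left)
    sizes <- c(sizes, s)
    left <- left - s
  }
  sizes
}

# Relative member geometry of one cluster: growth by attachment, each new
# ellipse overlapping the support radius of an existing member so
# footprints touch. Animals in a group tend to stand side by side, so the
# attachment direction is biased perpendicular to the reference member's
# major axis and orientations are roughly parallel, keeping clusters
# compact.
place_cluster_members <- function(sizes_axes) {
  n <- nrow(sizes_axes)
  out <- cbind(sizes_axes, dr = 0, dc = 0, angle = 0)
  out$angle[1] <- stats::runif(1, 0, pi)
  for (k in seq_len(n)[-1]) {
    for (try in 1:50) {
      m <- sample.int(k - 1, 1)
      side <- sample(c(-1, 1), 1)
      phi <- out$angle[m] + side * pi / 2 + stats::rnorm(1, 0, 0.35)
      out$angle[k] <- out$angle[m] + stats::rnorm(1, 0, 0.3)
      rm <- ellipse_radius(out$a[m], out$b[m], out$angle[m], phi)
      rk <- ellipse_radius(out$a[k], out$b[k], out$angle[k], phi + pi)
      d <- 0.9 * (rm + rk)
      dr <- out$dr[m] + d * sin(phi)
      dc <- out$dc[m] + d * cos(phi)
      others <- setdiff(seq_len(k - 1), m)
      ok <- TRUE
      for (o in others) {
        dist <- sqrt((dr - out$dr[o])^2 + (dc - out$dc[o])^2)
        if (dist < 0.6 * (out$b[o] + out$b[k])) { ok <- FALSE; break }
      }
      if (ok || try == 50) {
        out$dr[k] <- dr; out$dc[k] <- dc
        break
      }
    }
  }
  out
}

#' Generate a ground-truthed synthetic scene
#'
#' Renders one frame according to a [scene_spec()]: background base color
#' with low-frequency blotches and Gaussian noise, anti-aliased shaded
#' elliptical animals arranged in touching clusters, optional distractors,
#' and a final multiplicative exposure bias. Identical `(spec, seed)` input
#' produces bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @param seed integer RNG seed.
#' @return A list with elements `image` (an [rgb_image()]) and `truth`
#'   (a `scene_truth`: data frame of per-animal ellipse parameters with
#'   0-based centers, calf flags and cluster ids, plus distractor records).
#' @export
generate_scene <- function(spec, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sc <- render_scene_impl(spec)
  img <- rgb_image(sc$pixels,
                   timestamp = as.POSIXct("2018-05-17 09:00:00", tz = "UTC"),
                   lat = -21.9744, lon = -47.8497, altitude_m = 30,
                   id = sprintf("scene_%d", seed))
  list(image = img, truth = sc$truth)
}

render_scene_impl <- function(spec, world_animals = NULL) {
  H <- spec$height; W <- spec$width
  base <- spec$background_mean_rgb %||% background_base_rgb(spec$background_kind)
  blotch <- blotch_field(H, W)
  px <- array(0, c(H, W, 3))
  if (spec$background_kind == "mixed") {
    mixf <- (blotch_field(H, W, n_waves = 3, amp = 0.5) - 0.5) # in [0,1]
    g <- background_base_rgb("green_pasture"); d <- background_base_rgb("dry_pasture")
    for (ch in 1:3) px[, , ch] <- (g[ch] * mixf + d[ch] * (1 - mixf)) * blotch
  } else {
    for (ch in 1:3) px[, , ch] <- base[ch] * blotch
  }

  distr <- render_distractors(px, spec)
  px <- distr$pixels

  if (is.null(world_animals)) {
    animals <- sample_scene_animals(spec)
  } else {
    animals <- world_animals
  }

  if (nrow(animals) > 0) {
    for (i in seq_len(nrow(animals))) {
      an <- animals[i, ]
      cv <- ellipse_coverage(an$center_r, an$center_c, an$a, an$b, an$angle, H, W)
      if (is.null(cv)) next
      shade <- 1 - spec$coat_shading * clip01((cv$v + 1) / 2)
      for (ch in 1:3) {
        col <- spec$coat_mean_rgb[ch] * an$coat_scale * shade
        px[cv$rows, cv$cols, ch] <-
          cv$cov * col + (1 - cv$cov) * px[cv$rows, cv$cols, ch]
      }
    }
  }

  if (spec$noise_sd > 0)
    px <- px + array(stats::rnorm(length(px), 0, spec$noise_sd), dim(px))
  px <- clip255(round_half_up(px * spec$exposure_bias))

  truth <- structure(list(animals = animals, distractors = distr$truth,
                          n = nrow(animals)), class = "scene_truth")
  list(pixels = px, truth = truth)
}

sample_scene_animals <- function(spec) {
  H <- spec$height; W <- spec$width
  empty <- data.frame(id = integer(0), center_r = numeric(0), center_c = numeric(0),
                      a = numeric(0), b = numeric(0), angle = numeric(0),
                      calf = logical(0), cluster = integer(0), coat_scale = numeric(0))
  if (spec$n_animals == 0) return(empty)
  sizes <- sample_cluster_sizes(spec$n_animals, spec$cluster_size_distribution)
  sizes <- sort(sizes, decreasing = TRUE)   # big clusters claim space first
  placed <- list()
  margin <- spec$edge_margin_px
  next_id <- 1L
  prev <- NULL   # all already placed animals (absolute positions)
  for (ci in seq_along(sizes)) {
    n <- sizes[ci]
    calf <- stats::runif(n) < spec$calf_fraction
    if (n > 1 && any(!calf)) {
      # adults first so every calf can attach to an adult chain
      calf <- sort(calf)
    }
    ax <- stats::runif(n, spec$major_axis_px[1], spec$major_axis_px[2])
    bx <- stats::runif(n, spec$minor_axis_px[1], spec$minor_axis_px[2])
    ax[calf] <- ax[calf] * 0.5; bx[calf] <- bx[calf] * 0.5
    mem <- place_cluster_members(data.frame(a = ax, b = bx, calf = calf))
    ext <- t(vapply(seq_len(n), function(k)
      ellipse_extents(mem$a[k], mem$b[k], mem$angle[k]), numeric(2)))
    lo_r <- margin - min(mem$dr - ext[, 1]); hi_r <- H - 1 - margin - max(mem$dr + ext[, 1])
    lo_c <- margin - min(mem$dc - ext[, 2]); hi_c <- W - 1 - margin - max(mem$dc + ext[, 2])
    if (hi_r <= lo_r || hi_c <= lo_c)
      stopf("scene capacity error: cluster of %d animals does not fit in %d x %d", n, H, W)
    ok <- FALSE
    for (try in 1:2000) {
      cr <- stats::runif(1, lo_r, hi_r); cc <- stats::runif(1, lo_c, hi_c)
      if (is.null(prev)) { ok <- TRUE; break }
      clear <- TRUE
      for (k in seq_len(n)) {
        kr <- cr + mem$dr[k]; kc <- cc + mem$dc[k]
        dd <- sqrt((prev$center_r - kr)^2 + (prev$center_c - kc)^2)
        phi <- atan2(kr - prev$center_r, kc - prev$center_c)
        req <- vapply(seq_len(nrow(prev)), function(o)
          ellipse_support(prev$a[o], prev$b[o], prev$angle[o], phi[o]),
          numeric(1)) +
          ellipse_support(mem$a[k], mem$b[k], mem$angle[k], phi) + 4
        if (any(dd <= req)) { clear <- FALSE; break }
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok)
      stopf("scene capacity error: could not place %d animals in %d x %d", spec$n_animals, H, W)
    placed[[ci]] <- data.frame(
      id = next_id:(next_id + n - 1L),
      center_r = cr + mem$dr, center_c = cc + mem$dc,
      a = mem$a, b = mem$b, angle = mem$angle,
      calf = mem$calf, cluster = ci,
      coat_scale = stats::runif(n, 0.95, 1.05))
    prev <- rbind(prev, placed[[ci]])
    next_id <- next_id + n
  }
  do.call(rbind, placed)
}

render_distractors <- function(px, spec) {
  H <- nrow(px); W <- ncol(px)
  recs <- data.frame(kind = character(0), r0 = numeric(0), c0 = numeric(0),
                     r1 = numeric(0), c1 = numeric(0))
  for (kind in spec$distractors) {
    dims <- switch(kind, shed = c(120, 180), feeder = c(50, 240), tree = c(220, 220))
    col <- switch(kind, shed = c(248, 246, 240), feeder = c(150, 190, 215),
                  tree = c(45, 75, 40))
    for (try in 1:100) {
      r0 <- floor(stats::runif(1, 4, H - dims[1] - 4))
      c0 <- floor(stats::runif(1, 4, W - dims[2] - 4))
      break
    }
    rows <- (r0 + 1):(r0 + dims[1]); cols <- (c0 + 1):(c0 + dims[2])
    if (kind == "tree") {
      # irregular blob: radius modulated by random harmonics
      cr <- r0 + dims[1] / 2; cc <- c0 + dims[2] / 2
      DR <- matrix(rows - 1 - cr, length(rows), length(cols))
      DC <- matrix(cols - 1 - cc, length(rows), length(cols), byrow = TRUE)
      ang <- atan2(DR, DC)
      rad <- dims[1] / 2 * (0.72 + 0.18 * cos(3 * ang + stats::runif(1, 0, 2 * pi)) +
                              0.10 * cos(7 * ang + stats::runif(1, 0, 2 * pi)))
      inside <- sqrt(DR^2 + DC^2) <= rad
      for (ch in 1:3) {
        sl <- px[rows, cols, ch]
        sl[inside] <- col[ch] * (0.85 + 0.3 * stats::runif(sum(inside)))
        px[rows, cols, ch] <- sl
      }
    } else {
      for (ch in 1:3) px[rows, cols, ch] <- col[ch]
    }
    recs <- rbind(recs, data.frame(kind = kind, r0 = r0, c0 = c0,
                                   r1 = r0 + dims[1], c1 = c0 + dims[2]))
  }
  list(pixels = px, truth = recs)
}

#' Rasterize truth footprints
#'
#' `animal_footprint()` renders the binary footprint of one truth record;
#' `truth_mask()` renders the union over all animals of a scene truth.
#' Footprints use the same >0.5 anti-aliased coverage rule as the renderer,
#' so they match the generated image pixel for pixel.
#'
#' @param truth a `scene_truth` (or its `animals` data frame).
#' @param H,W frame dimensions.
#' @return A logical H×W matrix.
#' @export
truth_mask <- function(truth, H, W) {
  an <- if (is.data.frame(truth)) truth else truth$animals
  m <- matrix(FALSE, H, W)
  if (nrow(an) == 0) return(m)
  for (i in seq_len(nrow(an))) {
    cv <- ellipse_coverage(an$center_r[i], an$center_c[i], an$a[i], an$b[i],
                           an$angle[i], H, W)
    if (is.null(cv)) next
    m[cv$rows, cv$cols] <- m[cv$rows, cv$cols] | (cv$cov > 0.5)
  }
  m
}

#' @rdname truth_mask
#' @param rec one-row animal record.
#' @export
animal_footprint <- function(rec, H, W) {
  truth_mask(rec, H, W)
}

#' Specification of a synthetic overlapping survey
#'
#' A survey is a strip of frames cropped from a single rendered world
#' mosaic, so exact ground-truth inter-frame translations are available for
#' registration and de-duplication tests. Consecutive frames overlap by the
#' configured fraction; the flight direction is along image columns.
#'
#' @param n_frames number of frames.
#' @param overlap fractional overlap between consecutive frames, in
#'   `[0, 0.9]`.
#' @param n_animals number of animals in the whole surveyed world.
#' @param frame_width,frame_height frame size in pixels.
#' @param jitter_px per-frame random animal displacement (standard
#'   deviation, pixels); 0 keeps the world static, the default, in which
#'   case frames are exact crops of one mosaic.
#' @param ... further arguments passed to [scene_spec()] (background,
#'   cluster distribution, calf fraction, ...).
#' @return A `survey_spec` object.
#' @export
survey_spec <- function(n_frames = 5, overlap = 0.7, n_animals = 20,
                        frame_width = 640, frame_height = 640,
                        jitter_px = 0, ...) {
  if (overlap < 0 || overlap > 0.9) stopf("overlap must be in [0, 0.9]")
  step <- round(frame_width * (1 - overlap))
  if (step < 1) stopf("overlap too high: frame step below 1 px")
  structure(list(n_frames = as.integer(n_frames), overlap = overlap,
                 n_animals = as.integer(n_animals),
                 frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 jitter_px = jitter_px, step = as.integer(step),
                 scene_args = list(...)), class = "survey_spec")
}

#' Generate a ground-truthed overlapping survey
#'
#' Renders the world mosaic once and crops `n_frames` windows stepping
#' `round(frame_width * (1 - overlap))` px along the columns. Returns the
#' frames, per-frame truths (in frame coordinates), the true inter-frame
#' translations as 3×3 transforms mapping frame i coordinates into frame
#' i+1, and the global animal registry in world coordinates. Timestamps
#' increase strictly with frame order.
#'
#' @param spec a [survey_spec()].
#' @param seed integer RNG seed.
#' @return A `survey_truth` list: `frames`, `truths`, `transforms`,
#'   `registry`, `offsets`, `overlap`, `step`.
#' @export
generate_survey <- function(spec, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n <- spec$n_frames; step <- spec$step
  world_w <- spec$frame_width + (n - 1L) * step
  world_args <- c(list(width = world_w, height = spec$frame_height,
                       n_animals = spec$n_animals), spec$scene_args)
  wspec <- do.call(scene_spec, world_args)
  world <- render_scene_impl(wspec)
  registry <- world$truth$animals
  offsets <- (seq_len(n) - 1L) * step

  frames <- vector("list", n)
  truths <- vector("list", n)
  t0 <- as.POSIXct("2018-05-17 09:00:00", tz = "UTC")
  fspec <- do.call(scene_spec, c(list(width = spec$frame_width,
                                      height = spec$frame_height,
                                      n_animals = 0), spec$scene_args))
  for (i in seq_len(n)) {
    off <- offsets[i]
    if (spec$jitter_px > 0 && nrow(registry) > 0) {
      an <- registry
      an$center_r <- an$center_r + stats::rnorm(nrow(an), 0, spec$jitter_px)
      an$center_c <- an$center_c + stats::rnorm(nrow(an), 0, spec$jitter_px)
      an$center_c <- an$center_c - off
      rendered <- render_scene_impl(fspec, world_animals = an)
      px <- rendered$pixels
      frame_animals <- an
    } else {
      px <- world$pixels[, (off + 1):(off + spec$frame_width), , drop = FALSE]
      frame_animals <- registry
      frame_animals$center_c <- frame_animals$center_c - off
    }
    keep <- logical(nrow(frame_animals))
    for (k in seq_len(nrow(frame_animals))) {
      e <- ellipse_extents(frame_animals$a[k], frame_animals$b[k], frame_animals$angle[k])
      keep[k] <- frame_animals$center_c[k] + e["c"] >= 0 &&
        frame_animals$center_c[k] - e["c"] <= spec$frame_width - 1
    }
    truths[[i]] <- structure(list(animals = frame_animals[keep, , drop = FALSE],
                                  distractors = world$truth$distractors,
                                  n = sum(keep)), class = "scene_truth")
    frames[[i]] <- rgb_image(px,
                             timestamp = t0 + (i - 1) * 2,
                             lat = -21.9744, lon = -47.8497 + off * 1e-7,
                             altitude_m = 30,
                             id = sprintf("frame_%03d", i))
  }
  transforms <- lapply(seq_len(max(0, n - 1)), function(i)
    translation_transform(dx = -step, dy = 0, src = i, dst = i + 1,
                          detector = "truth"))
  structure(list(frames = frames, truths = truths, transforms = transforms,
                 registry = registry, offsets = offsets,
                 overlap = (spec$frame_width - step) / spec$frame_width,
                 step = step), class = "survey_truth")
}

#' Write a survey to a directory
#'
#' Writes one PNG plus one metadata JSON per frame and a `truth.json`
#' sidecar holding the registry, per-frame truths, frame offsets and the
#' overlap fraction.
#'
#' @param survey a `survey_truth` from [generate_survey()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(survey$frames))
    write_frame(survey$frames[[i]], file.path(dir, sprintf("frame_%03d.png", i)))
  truth <- list(registry = survey$registry,
                offsets = survey$offsets,
                overlap = survey$overlap,
                step = survey$step,
                frames = lapply(survey$truths, function(t) t$animals))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
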