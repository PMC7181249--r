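#' Tile an image on a regular grid
#'
#' Divides the image into `tile_size` × `tile_size` squares anchored at
#' pixel (0,0), row-major. Edge tiles are truncated, not padded, so every
#' pixel belongs to exactly one tile.
#'
#' @param img an [rgb_image()] or H×W×3 array.
#' @param tile_size tile side in pixels (default 224).
#' @return A `tile_grid`: list with `tile_size`, `H`, `W` and a data frame
#'   `tiles` with 0-based half-open pixel windows
#'   `(row, col, r0, r1, c0, c1)` and a `label` column initialised to
#'   `"unknown"`.
#' @export
tile_image <- function(img, tile_size = 224) {
  px <- if (inherits(img, "rgb_image")) img$pixels else img
  H <- dim(px)[1]; W <- dim(px)[2]
  ts <- as.integer(tile_size)
  if (ts <= 0) stopf("tile_size must be positive")
  if (H < ts || W < ts)
    stopf("image (%d x %d) smaller than one %d px tile", H, W, ts)
  nr <- ceiling(H / ts); nc <- ceiling(W / ts)
  tiles <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)[, 2:1]
  tiles$r0 <- tiles$row * ts
  tiles$r1 <- pmin(H, tiles$r0 + ts)
  tiles$c0 <- tiles$col * ts
  tiles$c1 <- pmin(W, tiles$c0 + ts)
  tiles$label <- "unknown"
  structure(list(tile_size = ts, H = H, W = W, tiles = tiles),
            class = "tile_grid")
}

#' Tile classifiers
#'
#' A tile classifier is a function `(tile_pixels, window) -> label` with
#' label one of `"cattle"`, `"non_cattle"`; it must be stateless across
#' tiles. The trained network that fills this role on real imagery is a
#' drop-in; these built-ins cover testing and baseline use:
#' `classifier_constant()` labels every tile the same,
#' `classifier_brightness()` accepts tiles whose fraction of near-coat-color
#' pixels exceeds a cutoff, and `classifier_truth()` consults a scene truth
#' footprint mask.
#'
#' @param label constant label to return.
#' @return A classifier function.
#' @export
classifier_constant <- function(label = "cattle") {
  force(label)
  function(tile, window) label
}

#' @rdname classifier_constant
#' @param reference_rgb coat reference color.
#' @param tolerance maximum per-channel deviation from the reference.
#' @param min_fraction minimum fraction of near-coat pixels.
#' @export
classifier_brightness <- function(reference_rgb = c(228, 220, 200),
                                  tolerance = 45, min_fraction = 0.02) {
  function(tile, window) {
    near <- abs(tile[, , 1] - reference_rgb[1]) <= tolerance &
      abs(tile[, , 2] - reference_rgb[2]) <= tolerance &
      abs(tile[, , 3] - reference_rgb[3]) <= tolerance
    if (mean(near) >= min_fraction) "cattle" else "non_cattle"
  }
}

#' @rdname classifier_constant
#' @param truth a `scene_truth` from [generate_scene()].
#' @param H,W frame dimensions.
#' @export
classifier_truth <- function(truth, H, W) {
  fp <- truth_mask(truth, H, W)
  function(tile, window) {
    sub <- fp[(window["r0"] + 1):window["r1"], (window["c0"] + 1):window["c1"]]
    if (any(sub)) "cattle" else "non_cattle"
  }
}

# Resolve a classifier selector from config: keyword or "pkg::fun".
resolve_classifier <- function(name, truth = NULL, H = NULL, W = NULL,
                               cfg = default_config()) {
  if (is.function(name)) return(name)
  switch(name,
         constant_accept = classifier_constant("cattle"),
         constant_reject = classifier_constant("non_cattle"),
         brightness = classifier_brightness(cfg$coat_reference_rgb,
                                            cfg$coat_tolerance, cfg$coat_fraction),
         truth = {
           if (is.null(truth)) stopf("truth classifier requires a scene truth")
           classifier_truth(truth, H, W)
         },
         {
           if (!grepl("::", name)) stopf("unknown classifier '%s'", name)
           parts <- strsplit(name, "::", fixed = TRUE)[[1]]
           getExportedValue(parts[1], parts[2])
         })
}

#' Classify tiles and build the region of interest
#'
#' `classify_tiles()` runs a classifier over every tile of a grid;
#' `build_roi()` copies cattle tiles verbatim and zeroes everything else,
#' discarding the non-cattle regions. Tiles labelled `"unknown"` are
#' treated as non-cattle.
#'
#' @param img an [rgb_image()] or H×W×3 array.
#' @param grid a `tile_grid` built from `img`.
#' @param clf a classifier function (see [classifier_constant()]).
#' @return `classify_tiles()` returns the grid with labels filled in;
#'   `build_roi()` returns a `roi_image`: list with `pixels` (non-cattle
#'   tiles zeroed), logical `roi_mask`, the labelled `grid` and the source
#'   metadata.
#' @export
classify_tiles <- function(img, grid, clf) {
  px <- if (inherits(img, "rgb_image")) img$pixels else img
  t <- grid$tiles
  for (i in seq_len(nrow(t))) {
    w <- c(r0 = t$r0[i], r1 = t$r1[i], c0 = t$c0[i], c1 = t$c1[i])
    tile <- px[(w["r0"] + 1):w["r1"], (w["c0"] + 1):w["c1"], , drop = FALSE]
    lab <- clf(tile, w)
    if (!is.character(lab) || length(lab) != 1 ||
        !lab %in% c("cattle", "non_cattle", "unknown"))
      stopf("classifier contract violation: got %s", deparse(lab))
    t$label[i] <- lab
  }
  grid$tiles <- t
  grid
}

#' @rdname classify_tiles
#' @export
build_roi <- function(img, grid, clf = NULL) {
  px <- if (inherits(img, "rgb_image")) img$pixels else img
  if (dim(px)[1] != grid$H || dim(px)[2] != grid$W)
    stopf("grid was not built from this image")
  if (!is.null(clf)) grid <- classify_tiles(img, grid, clf)
  t <- grid$tiles
  mask <- matrix(FALSE, grid$H, grid$W)
  for (i in seq_len(nrow(t)))
    if (t$label[i] == "cattle")
      mask[(t$r0[i] + 1):t$r1[i], (t$c0[i] + 1):t$c1[i]] <- TRUE
  out <- px
  out[!array(mask, dim(px))] <- 0L
  meta <- if (inherits(img, "rgb_image")) img[c("timestamp", "lat", "lon", "altitude_m", "id")] else NULL
  structure(list(pixels = out, roi_mask = mask, grid = grid, meta = meta),
            class = "roi_image")
}
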