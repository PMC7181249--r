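#' 8-bit RGB survey image
#'
#' Lightweight container for one aerial frame: an H×W×3 integer array of
#' 8-bit intensities plus capture metadata. Pixel coordinates are 0-based
#' with half-open windows throughout the package; `pixels[r, c, ]` is the
#' pixel at 0-based (row r-1, col c-1).
#'
#' @param pixels H×W×3 numeric array with values in 0..255.
#' @param timestamp capture time (`POSIXct` or seconds since epoch).
#' @param lat,lon optional geotag in decimal degrees.
#' @param altitude_m optional altitude above ground in metres.
#' @param id optional frame identifier (e.g. filename stem).
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, timestamp = NA, lat = NA_real_, lon = NA_real_,
                      altitude_m = NA_real_, id = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stopf("pixels must be an H x W x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stopf("pixel values must lie in 0..255")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, timestamp = timestamp, lat = lat, lon = lon,
         altitude_m = altitude_m, id = id),
    class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %s: %d x %d px, timestamp %s>\n",
              x$id %||% "?", d[1], d[2], format(x$timestamp)))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Read and write frames as PNG
#'
#' Frames are stored as ordinary PNGs; capture metadata travels in a JSON
#' sidecar (`<stem>.json`) with fields `timestamp`, `lat`, `lon`,
#' `altitude_m`, rather than binary EXIF.
#'
#' @param path PNG file path.
#' @return [read_frame()] returns an `rgb_image`.
#' @export
read_frame <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  arr <- arr[, , 1:3, drop = FALSE]
  px <- round_half_up(arr * 255)
  meta_path <- sub("\\.png$", ".json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  ts <- meta$timestamp
  if (!is.null(ts)) ts <- as.POSIXct(ts, tz = "UTC", origin = "1970-01-01")
  rgb_image(px,
            timestamp = ts %||% NA,
            lat = meta$lat %||% NA_real_, lon = meta$lon %||% NA_real_,
            altitude_m = meta$altitude_m %||% NA_real_,
            id = sub("\\.png$", "", basename(path)))
}

#' @rdname read_frame
#' @param img an `rgb_image`.
#' @export
write_frame <- function(img, path) {
  png::writePNG(img$pixels / 255, path)
  meta <- list(timestamp = as.numeric(img$timestamp), lat = img$lat,
               lon = img$lon, altitude_m = img$altitude_m, id = img$id)
  jsonlite::write_json(meta, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Grayscale intensity (mean of channels), used by registration.
gray_of <- function(img) {
  px <- if (inherits(img, "rgb_image")) img$pixels else img
  (px[, , 1] + px[, , 2] + px[, , 3]) / 3
}
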