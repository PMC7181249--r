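#' Split a region-of-interest image into four quadrants
#'
#' Each quadrant is processed separately so that illumination differences
#' within a frame do not skew a single global brightness correction. For
#' odd dimensions the top/left quadrants take the extra row/column. The
#' four half-open windows partition the image exactly.
#'
#' @param roi a `roi_image` from [build_roi()] (or an H×W×3 array, in which
#'   case the ROI mask is taken as all-true).
#' @return A list of four `quadrant` objects, row-major (top-left,
#'   top-right, bottom-left, bottom-right), each with 0-based half-open
#'   window `(r0, r1, c0, c1)`, the pixel sub-array, and the ROI sub-mask.
#' @export
split_quadrants <- function(roi) {
  px <- if (inherits(roi, "roi_image")) roi$pixels else roi
  mask <- if (inherits(roi, "roi_image")) roi$roi_mask else
    matrix(TRUE, dim(px)[1], dim(px)[2])
  H <- dim(px)[1]; W <- dim(px)[2]
  if (H < 2 || W < 2) stopf("image too small to split into quadrants")
  hr <- ceiling(H / 2); hc <- ceiling(W / 2)
  wins <- list(c(0, hr, 0, hc), c(0, hr, hc, W),
               c(hr, H, 0, hc), c(hr, H, hc, W))
  lapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    structure(list(
      index = i - 1L, r0 = w[1], r1 = w[2], c0 = w[3], c1 = w[4],
      pixels = px[(w[1] + 1):w[2], (w[3] + 1):w[4], , drop = FALSE],
      roi_mask = mask[(w[1] + 1):w[2], (w[3] + 1):w[4], drop = FALSE]),
      class = "quadrant")
  })
}

#' Quadrant brightness correction factor
#'
#' `cf = target / mean(Pi)` where the `Pi` are the values of all pixels in
#' all three color channels of the quadrant. The mean is taken over pixels
#' inside the ROI mask only: zeroed non-cattle tiles carry no brightness
#' information and would deflate it meaninglessly.
#'
#' @param q a `quadrant` from [split_quadrants()].
#' @param cfg pipeline configuration (uses `cf_target`, default 85).
#' @return The correction factor, a positive scalar.
#' @export
correction_factor <- function(q, cfg = default_config()) {
  sel <- array(q$roi_mask, dim(q$pixels))
  vals <- q$pixels[sel]
  if (length(vals) == 0 || mean(vals) == 0)
    stopf("correction factor undefined: quadrant has no usable pixels")
  cfg$cf_target / mean(vals)
}

#' Fixed per-channel binarization thresholds
#'
#' The C-channel threshold is `min(100, 40 cf)`, the M-channel threshold is
#' the constant 30, and the custom-channel threshold is `min(150, 120 cf)`.
#' All are monotone nondecreasing in `cf` and capped.
#'
#' @param cf quadrant correction factor (> 0).
#' @param cfg pipeline configuration.
#' @return Named numeric vector `c(C = , M = , custom = )`.
#' @export
fixed_thresholds <- function(cf, cfg = default_config()) {
  if (cf <= 0) stopf("cf must be positive")
  c(C = min(cfg$c_thresh_cap, cfg$c_thresh_scale * cf),
    M = cfg$m_thresh,
    custom = min(cfg$custom_thresh_cap, cfg$custom_thresh_scale * cf))
}

# 256-bin histogram of 8-bit values (bins 0..255).
hist256 <- function(vals) {
  tabulate(as.integer(vals) + 1L, nbins = 256L)
}

#' Smooth a 256-bin histogram
#'
#' Centered moving average with symmetric (mirrored) boundary padding so
#' that the edge bins are defined; window length 25 by default.
#'
#' @param h numeric vector of 256 bin counts.
#' @param window odd window length.
#' @return Numeric vector of 256 smoothed values.
#' @export
smooth_histogram <- function(h, window = 25) {
  n <- length(h)
  half <- (window - 1) %/% 2
  padded <- c(rev(h[seq_len(half)]), h, h[n - seq_len(half) + 1])
  cs <- cumsum(c(0, padded))
  (cs[(1:n) + 2 * half + 1] - cs[1:n]) / window
}

# Strict local maxima of a smoothed curve; plateaus take their leftmost
# bin; the outside of the curve counts as -Inf so endpoints can be peaks.
find_peaks <- function(s) {
  n <- length(s)
  ext <- c(-Inf, s, -Inf)
  peaks <- integer(0)
  i <- 2
  while (i <= n + 1) {
    j <- i
    while (j < n + 1 && ext[j + 1] == ext[i]) j <- j + 1
    if (ext[i - 1] < ext[i] && ext[j + 1] < ext[i])
      peaks <- c(peaks, i - 2L)   # 0-based bin index of plateau start
    i <- j + 1
  }
  peaks
}

# Greedy left-to-right merge of peaks closer than min_sep bins, keeping the
# larger (ties keep the lower index).
merge_close_peaks <- function(peaks, s, min_sep) {
  if (length(peaks) < 2) return(peaks)
  kept <- peaks[1]
  for (p in peaks[-1]) {
    last <- kept[length(kept)]
    if (p - last < min_sep) {
      if (s[p + 1] > s[last + 1]) kept[length(kept)] <- p
    } else {
      kept <- c(kept, p)
    }
  }
  kept
}

#' Y-channel threshold for one quadrant
#'
#' Implements the full histogram rule chain on the Y channel of an active
#' quadrant: build the 256-bin histogram of the ROI pixels, smooth it with
#' a length-25 moving average, and then (i) if the mass of the 10 lowest
#' bins exceeds the mass of the 156 highest bins (bins 100..255), the
#' quadrant is deemed very dark and the threshold is 10; (ii) otherwise
#' locate the peaks of the smoothed curve, merge peaks separated by fewer
#' than 30 bins keeping the larger, and require at least two peaks, else
#' the quadrant's threshold is discarded; (iii) keep the two lowest-index
#' peaks and, among the bins strictly between them with amplitude below 10%
#' of the second peak's amplitude, return the bin closest to the second
#' peak; if no bin qualifies, return the bin of smallest amplitude between
#' the peaks.
#'
#' @param y integer matrix (or vector) of Y-channel values 0..255; for a
#'   ROI quadrant pass the ROI pixels only.
#' @param cfg pipeline configuration.
#' @return A `y_threshold` list: `status` (`"dark"`, `"valid"` or
#'   `"discarded"`) and integer `threshold` (NA when discarded).
#' @export
y_quadrant_threshold <- function(y, cfg = default_config()) {
  vals <- as.vector(y)
  if (length(vals) == 0) stopf("empty histogram: no pixels in quadrant")
  h <- hist256(vals)
  s <- smooth_histogram(h, cfg$hist_smooth_window)
  low <- sum(s[seq_len(cfg$dark_low_bins)])
  high <- sum(s[(256 - cfg$dark_high_bins + 1):256])
  if (low > high)
    return(structure(list(status = "dark",
                          threshold = as.integer(cfg$dark_threshold)),
                     class = "y_threshold"))
  peaks <- find_peaks(s)
  peaks <- merge_close_peaks(peaks, s, cfg$peak_min_separation)
  if (length(peaks) < 2)
    return(structure(list(status = "discarded", threshold = NA_integer_),
                     class = "y_threshold"))
  p1 <- peaks[1]; p2 <- peaks[2]
  between <- if (p2 - p1 >= 2) (p1 + 1):(p2 - 1) else integer(0)
  if (length(between) == 0)          # adjacent peaks: no valley to pick
    return(structure(list(status = "valid", threshold = as.integer(p1)),
                     class = "y_threshold"))
  qual <- between[s[between + 1] < cfg$valley_fraction * s[p2 + 1]]
  thr <- if (length(qual) > 0) {
    max(qual)                                  # closest to the second peak
  } else {
    between[which.min(s[between + 1])]         # ties take the lowest index
  }
  structure(list(status = "valid", threshold = as.integer(thr)),
            class = "y_threshold")
}

#' Build the six binary masks of one frame
#'
#' Runs the whole quadrant stage: quadrant split, per-quadrant activity
#' check (a quadrant is inactive when it has no ROI content or fewer than
#' `min_active_pixels` Y-channel pixels above zero), brightness correction
#' factor, CMY + custom channel decomposition, per-quadrant thresholds for
#' C, M and the custom channel, the Y histogram-valley threshold per
#' quadrant, and reassembly. A single global Y threshold — the smallest
#' among the quadrants' valid thresholds (dark quadrants participate with
#' threshold 10) — is applied across the frame at T, floor(T/2) and
#' floor(T/4), giving three Y masks. In every mask, white (TRUE) marks
#' candidate-animal pixels: channel value strictly below the threshold,
#' inside the ROI mask, and in an active quadrant.
#'
#' @param roi a `roi_image` (or H×W×3 array).
#' @param cfg pipeline configuration.
#' @return A `mask_set`: logical matrices `mask_C`, `mask_M`, `mask_Y_T`,
#'   `mask_Y_T2`, `mask_Y_T4`, `mask_custom`; `global_Y_threshold`
#'   (NA when no quadrant yielded one, in which case the Y masks are empty
#'   and `y_valid` is FALSE); per-quadrant diagnostics in `quadrants`.
#' @export
build_mask_set <- function(roi, cfg = default_config()) {
  px <- if (inherits(roi, "roi_image")) roi$pixels else roi
  H <- dim(px)[1]; W <- dim(px)[2]
  quads <- split_quadrants(roi)

  empty <- matrix(FALSE, H, W)
  masks <- list(mask_C = empty, mask_M = empty, mask_Y_T = empty,
                mask_Y_T2 = empty, mask_Y_T4 = empty, mask_custom = empty)
  qinfo <- vector("list", 4)
  chans <- vector("list", 4)

  for (i in seq_along(quads)) {
    q <- quads[[i]]
    ch <- rgb_to_cmy(q$pixels)
    ch$custom <- pseudo_lab_channel(q$pixels)
    chans[[i]] <- ch
    n_active_y <- sum(ch$Y[q$roi_mask] > 0)
    active <- any(q$roi_mask) && n_active_y >= cfg$min_active_pixels
    cf <- NA_real_
    ythr <- list(status = "inactive", threshold = NA_integer_)
    if (active) {
      cf <- tryCatch(correction_factor(q, cfg), error = function(e) NA_real_)
      if (is.na(cf)) {
        active <- FALSE
      } else {
        ythr <- y_quadrant_threshold(ch$Y[q$roi_mask], cfg)
      }
    }
    qinfo[[i]] <- list(index = q$index, active = active, cf = cf,
                       n_active_y = n_active_y,
                       y_status = ythr$status, y_threshold = ythr$threshold)
  }

  thr_all <- vapply(qinfo, function(x)
    if (x$active && x$y_status %in% c("valid", "dark")) as.numeric(x$y_threshold)
    else NA_real_, numeric(1))
  y_valid <- any(!is.na(thr_all))
  Tg <- if (y_valid) as.integer(min(thr_all, na.rm = TRUE)) else NA_integer_

  for (i in seq_along(quads)) {
    q <- quads[[i]]; info <- qinfo[[i]]
    if (!info$active) next
    ch <- chans[[i]]
    th <- fixed_thresholds(info$cf, cfg)
    rows <- (q$r0 + 1):q$r1; cols <- (q$c0 + 1):q$c1
    rm <- q$roi_mask
    masks$mask_C[rows, cols] <- (ch$C < th["C"]) & rm
    masks$mask_M[rows, cols] <- (ch$M < th["M"]) & rm
    masks$mask_custom[rows, cols] <- (ch$custom < th["custom"]) & rm
    if (y_valid) {
      masks$mask_Y_T[rows, cols] <- (ch$Y < Tg) & rm
      masks$mask_Y_T2[rows, cols] <- (ch$Y < Tg %/% 2L) & rm
      masks$mask_Y_T4[rows, cols] <- (ch$Y < Tg %/% 4L) & rm
    }
  }

  structure(c(masks, list(global_Y_threshold = Tg, y_valid = y_valid,
                          all_inactive = !any(vapply(qinfo, `[[`, TRUE, "active")),
                          quadrants = qinfo)),
            class = "mask_set")
}
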