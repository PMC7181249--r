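# Pairwise frame registration. The synthetic surveys are pure camera
# translations, so the estimators recover a translation; it is stored as a
# normalized 3x3 planar transform so the de-duplication code is agnostic to
# the transform family.

#' Build a translation transform
#'
#' @param dx,dy translation in columns (x) and rows (y): a point at
#'   `(x, y)` in the source frame appears at `(x + dx, y + dy)` in the
#'   target frame.
#' @param src,dst source and target image ids.
#' @param n_matched_points number of agreeing feature matches.
#' @param detector one of `"primary"`, `"fallback"`, `"truth"`.
#' @return A `pair_transform`: list with the 3×3 matrix `M` (last row
#'   `c(0,0,1)`), ids and provenance.
#' @export
translation_transform <- function(dx, dy, src = NA, dst = NA,
                                  n_matched_points = NA_integer_,
                                  detector = "truth") {
  M <- diag(3)
  M[1, 3] <- dx
  M[2, 3] <- dy
  structure(list(M = M, src = src, dst = dst,
                 n_matched_points = n_matched_points, detector_used = detector),
            class = "pair_transform")
}

apply_transform <- function(tf, xy) {
  M <- if (inherits(tf, "pair_transform")) tf$M else tf
  p <- M %*% c(xy[1], xy[2], 1)
  c(p[1] / p[3], p[2] / p[3])
}

invert_transform <- function(tf) {
  out <- tf
  out$M <- solve(tf$M)
  s <- out$src; out$src <- out$dst; out$dst <- s
  out
}

# Phase correlation (whitened cross-power spectrum) between two matrices;
# returns the circular displacement (dr, dc) of b relative to a and a peak
# z-score against the correlation surface.
phase_corr_peak <- function(a, b) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  Fa <- stats::fft(a0); Fb <- stats::fft(b0)
  R <- Fb * Conj(Fa)
  R <- R / pmax(Mod(R), 1e-12)
  cc <- Re(stats::fft(R, inverse = TRUE))
  peak <- which.max(cc)
  z <- (max(cc) - mean(cc)) / stats::sd(cc)
  H <- nrow(a)
  dr <- (peak - 1) %% H
  dc <- (peak - 1) %/% H
  if (dr > H / 2) dr <- dr - H
  if (dc > ncol(a) / 2) dc <- dc - ncol(a)
  list(dr = dr, dc = dc, z = z)
}

#' Register a pair of overlapping frames
#'
#' Estimates the planar transform mapping coordinates of `a` into `b`.
#' The primary detector correlates a grid of texture patches from `a`
#' against `b` and takes the consensus displacement; the number of patches
#' agreeing with the consensus within 2 px is the match count. When fewer
#' than `min_matches` patches agree, the fallback detector — global phase
#' correlation — is used instead. If the fallback peak is not significant
#' either the registration fails with an error. A `truth` backend serves
#' synthetic surveys (see [generate_survey()]), whose transforms are exact.
#'
#' @param a,b two [rgb_image()]s of identical size.
#' @param cfg pipeline configuration (uses `min_matches`).
#' @param n_patches number of primary-detector patches.
#' @param patch_size patch side in pixels.
#' @return A `pair_transform` mapping `a` coordinates into `b`.
#' @export
register_pair <- function(a, b, cfg = default_config(),
                          n_patches = 10, patch_size = 56) {
  ga <- gray_of(a); gb <- gray_of(b)
  if (!all(dim(ga) == dim(gb))) stopf("frames must have identical size")
  H <- nrow(ga); W <- ncol(ga)
  ps <- patch_size
  # patch centers on a coarse grid, ranked by local variance (texture)
  grid_r <- round(seq(ps, H - ps, length.out = 5))
  grid_c <- round(seq(ps, W - ps, length.out = 5))
  cand <- expand.grid(r = grid_r, c = grid_c)
  v <- vapply(seq_len(nrow(cand)), function(i) {
    stats::var(as.vector(ga[(cand$r[i] - ps / 2):(cand$r[i] + ps / 2),
                            (cand$c[i] - ps / 2):(cand$c[i] + ps / 2)]))
  }, numeric(1))
  cand <- cand[order(-v)[seq_len(min(n_patches, nrow(cand)))], ]

  disp <- matrix(NA_real_, nrow(cand), 2)
  for (i in seq_len(nrow(cand))) {
    r0 <- cand$r[i] - ps / 2; c0 <- cand$c[i] - ps / 2
    patch <- matrix(0, H, W)
    pr <- r0:(r0 + ps - 1); pc <- c0:(c0 + ps - 1)
    patch[pr, pc] <- ga[pr, pc] - mean(ga[pr, pc])
    pk <- phase_corr_peak(patch, gb)
    disp[i, ] <- c(pk$dr, pk$dc)
  }
  med <- c(stats::median(disp[, 1]), stats::median(disp[, 2]))
  agree <- abs(disp[, 1] - med[1]) <= 2 & abs(disp[, 2] - med[2]) <= 2
  n_ok <- sum(agree)
  if (n_ok >= cfg$min_matches) {
    d <- colMeans(disp[agree, , drop = FALSE])
    return(translation_transform(dx = round(d[2]), dy = round(d[1]),
                                 src = a$id, dst = b$id,
                                 n_matched_points = n_ok,
                                 detector = "primary"))
  }
  pk <- phase_corr_peak(ga, gb)
  if (pk$z >= 8)
    return(translation_transform(dx = pk$dc, dy = pk$dr,
                                 src = a$id, dst = b$id,
                                 n_matched_points = n_ok,
                                 detector = "fallback"))
  stopf("registration failure: %d/%d patches agreed and phase correlation peak z=%.1f is not significant",
        n_ok, nrow(cand), pk$z)
}
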