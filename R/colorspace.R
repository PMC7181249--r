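#' Color-space decompositions used by the masks
#'
#' `rgb_to_cmy()` converts an 8-bit RGB array to the C, M and Y channels of
#' the standard CMYK conversion with black extraction, each rescaled to
#' 0..255 (the K channel is not used downstream). `pseudo_lab_channel()`
#' computes the contrast-enhancing custom channel: the CIELAB-to-sRGB
#' formulas are applied to the RGB channels as if they were L, a and b, and
#' the third output channel (the blue one) is kept. The transform has no
#' perceptual meaning but strongly darkens the light warm coat colors.
#'
#' Scaling convention for the pseudo-CIELAB transform: R in 0..255 maps to
#' L in 0..100 (factor 100/255); G and B map to a and b by subtracting 128;
#' D65 white point and sRGB companding; the companded output is rescaled to
#' 0..255 and clipped. In all four channels the animals come out darker
#' than their surroundings.
#'
#' @param px H×W×3 numeric array of 8-bit RGB values.
#' @return `rgb_to_cmy()`: list of integer matrices `C`, `M`, `Y` in
#'   0..255. `pseudo_lab_channel()`: one integer matrix in 0..255.
#' @export
rgb_to_cmy <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]
  r <- matrix(px[, , 1], H, W) / 255
  g <- matrix(px[, , 2], H, W) / 255
  b <- matrix(px[, , 3], H, W) / 255
  k <- 1 - pmax(r, g, b)
  denom <- 1 - k
  safe <- denom > 0
  cm <- ym <- cy <- matrix(0, H, W)
  cy[safe] <- (1 - r[safe] - k[safe]) / denom[safe]
  cm[safe] <- (1 - g[safe] - k[safe]) / denom[safe]
  ym[safe] <- (1 - b[safe] - k[safe]) / denom[safe]
  list(C = matrix(as.integer(round_half_up(cy * 255)), H),
       M = matrix(as.integer(round_half_up(cm * 255)), H),
       Y = matrix(as.integer(round_half_up(ym * 255)), H))
}

#' @rdname rgb_to_cmy
#' @export
pseudo_lab_channel <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]
  L <- matrix(px[, , 1], H, W) * (100 / 255)
  a <- matrix(px[, , 2], H, W) - 128
  b <- matrix(px[, , 3], H, W) - 128
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  finv <- function(t) ifelse(t^3 > 0.008856, t^3, (t - 16 / 116) / 7.787)
  # D65 reference white
  X <- 0.95047 * finv(fx)
  Y <- 1.00000 * finv(fy)
  Z <- 1.08883 * finv(fz)
  blin <- 0.0557 * X - 0.2040 * Y + 1.0570 * Z
  v <- ifelse(blin <= 0.0031308, 12.92 * blin,
              1.055 * pmax(blin, 0)^(1 / 2.4) - 0.055)
  matrix(as.integer(round_half_up(clip255(v * 255))), nrow(L))
}
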