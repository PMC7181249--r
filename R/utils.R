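# Internal matrix helpers shared by the morphology and mask code.

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(src_r) < 1 || length(src_c) < 1) return(out)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c, drop = FALSE]
  out
}

# pmin/pmax take attributes (dim) from their first argument
clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Round half away from zero; base round() is banker's rounding.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_mask <- function(m, name = "mask") {
  if (!is.matrix(m) || !(is.logical(m) || all(m %in% c(0, 1))))
    stopf("%s must be a logical matrix", name)
  invisible(TRUE)
}
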