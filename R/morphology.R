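# Binary morphology primitives: 8-connected labeling, zero-padded erosion
# and topology-preserving (Zhang-Suen) thinning. These are the operations
# the cluster-splitting stage is built from; boundaries outside the image
# are background throughout.

#' Label 8-connected components
#'
#' Connected-component labeling with 8-connectivity (diagonal neighbours
#' belong to the same object, so diagonally touching animal fragments count
#' as one).
#'
#' @param mask logical matrix.
#' @return Integer matrix of the same shape; 0 is background, components
#'   are numbered 1..k.
#' @export
label_components <- function(mask) {
  assert_mask(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab4 <- EBImage::bwlabel(m)           # 4-connectivity
  k <- max(lab4)
  if (k <= 1) return(matrix(as.integer(lab4), nrow(mask)))
  # merge labels that touch diagonally
  pairs <- rbind(
    diag_pairs(lab4, 1, 1),
    diag_pairs(lab4, 1, -1))
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs) > 0)
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  root <- vapply(seq_len(k), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- matrix(0L, nrow(mask), ncol(mask))
  nz <- lab4 > 0
  out[nz] <- relab[lab4[nz]]
  out
}

diag_pairs <- function(lab, dr, dc) {
  a <- lab
  b <- shift_mat(lab, dr, dc)
  sel <- a > 0 & b > 0 & a != b
  if (!any(sel)) return(matrix(integer(0), 0, 2))
  cbind(as.integer(a[sel]), as.integer(b[sel]))
}

#' Erode with a 3x3 square
#'
#' One-pixel binary erosion with a 3×3 structuring element; pixels outside
#' the image count as background, so objects shrink at the frame edge too.
#' Used after thinning to sever the one-pixel necks left between cluster
#' members.
#'
#' @param mask logical matrix.
#' @param iterations number of erosion passes.
#' @return Logical matrix.
#' @export
erode3 <- function(mask, iterations = 1) {
  assert_mask(mask)
  m <- mask
  for (it in seq_len(iterations)) {
    acc <- m
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0)
        acc <- acc & shift_mat(m, dr, dc, fill = FALSE)
    m <- acc
    if (!any(m)) break
  }
  m
}

# Number of 0->1 transitions around the 8-neighbourhood, and neighbour sum,
# for the whole matrix at once (Zhang-Suen bookkeeping).
zs_neighbours <- function(m) {
  p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
  p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
  p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
  p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
  ring <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  A <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) A <- A + (ring[[i]] == 0 & ring[[i + 1]] == 1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  list(A = A, B = B, p2 = p2, p4 = p4, p6 = p6, p8 = p8)
}

#' Topology-preserving thinning
#'
#' Zhang–Suen iterative thinning: each iteration runs the two standard
#' sub-passes, peeling at most one boundary layer while preserving
#' connectivity, so an n-iteration thinning reduces necks narrower than
#' about 2n px to a one-pixel line while thicker cores survive. Stops early
#' when stable.
#'
#' @param mask logical matrix.
#' @param iterations number of thinning iterations (layers to peel).
#' @return Logical matrix.
#' @export
thin_mask <- function(mask, iterations) {
  assert_mask(mask)
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  for (it in seq_len(iterations)) {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- zs_neighbours(m)
      cond <- m == 1 & nb$B >= 2 & nb$B <= 6 & nb$A == 1
      if (pass == 1) {
        cond <- cond & (nb$p2 * nb$p4 * nb$p6 == 0) & (nb$p4 * nb$p6 * nb$p8 == 0)
      } else {
        cond <- cond & (nb$p2 * nb$p4 * nb$p8 == 0) & (nb$p2 * nb$p6 * nb$p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}
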