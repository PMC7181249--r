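#' AND two masks, restoring partially surviving objects
#'
#' Combines a Y mask with the M mask by a pixelwise AND, then reverts the
#' blackened pixels of every Y object that lost area but was not completely
#' removed: a connected component of `y` that intersects `m` anywhere is
#' kept verbatim, and components disjoint from `m` disappear. Objects are
#' 8-connected. The operation is idempotent in its first argument.
#'
#' @param y,m logical matrices of the same shape.
#' @return Logical matrix: the union of the `y` components that meet `m`.
#' @export
and_with_restore <- function(y, m) {
  if (!all(dim(y) == dim(m))) stopf("mask shapes differ")
  if (!any(y) || !any(m)) return(y & m)
  lab <- label_components(y)
  hit <- sort(unique(lab[y & m]))
  hit <- hit[hit > 0]
  out <- matrix(FALSE, nrow(y), ncol(y))
  if (length(hit) > 0) out[lab %in% hit] <- TRUE
  out
}

#' Fuse the six channel masks into three final masks
#'
#' For each Y-threshold variant: the Y mask is ANDed with the M mask under
#' the object-restore rule, the result is merged with the C mask by OR, and
#' the custom-channel mask is incorporated by a final OR. The three final
#' masks inherit the Y masks' nesting (the quarter-threshold mask is the
#' most restrictive).
#'
#' @param masks a `mask_set` from [build_mask_set()].
#' @return A `fused_masks` list: logical `final_T`, `final_T2`, `final_T4`.
#' @export
fuse_masks <- function(masks) {
  stopifnot(inherits(masks, "mask_set"))
  fuse_one <- function(ym)
    and_with_restore(ym, masks$mask_M) | masks$mask_C | masks$mask_custom
  structure(list(final_T = fuse_one(masks$mask_Y_T),
                 final_T2 = fuse_one(masks$mask_Y_T2),
                 final_T4 = fuse_one(masks$mask_Y_T4)),
            class = "fused_masks")
}
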