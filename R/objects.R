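# Object-level stage: shape measurement, size/solidity filtering, and the
# rule-based estimation of how many animals a connected object contains.

# Number of lattice points (pixel centers) inside or on the convex hull of
# the given pixel coordinates. This is the convex-hull area used for
# solidity, so a convex object has solidity exactly 1.
convex_hull_lattice_area <- function(rs, cs) {
  n <- length(rs)
  if (n <= 2) return(segment_lattice_count(rs, cs))
  hull <- grDevices::chull(cs, rs)
  if (length(hull) <= 2) return(segment_lattice_count(rs, cs))
  hx <- cs[hull]; hy <- rs[hull]
  # candidate lattice points: the hull's bounding box
  r0 <- min(rs); r1 <- max(rs); c0 <- min(cs); c1 <- max(cs)
  pr <- rep(r0:r1, times = c1 - c0 + 1)
  pc <- rep(c0:c1, each = r1 - r0 + 1)
  k <- length(hull)
  eps <- 1e-9
  # polygon orientation (chull gives clockwise in plotting coords)
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  sgn <- if (area2 >= 0) 1 else -1
  inside <- rep(TRUE, length(pr))
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (pr - hy[i]) - (hy[j] - hy[i]) * (pc - hx[i])
    inside <- inside & (sgn * cr >= -eps)
    if (!any(inside)) break
  }
  sum(inside)
}

# Lattice points on the segment spanned by a (possibly degenerate or
# collinear) pixel set.
segment_lattice_count <- function(rs, cs) {
  pts <- unique(cbind(rs, cs))
  if (nrow(pts) == 1) return(1L)
  o <- order(pts[, 1], pts[, 2])
  p0 <- pts[o[1], ]; p1 <- pts[o[nrow(pts)], ]
  v <- p1 - p0
  if (all(v == 0)) return(nrow(pts))
  g <- gcd2(abs(v[1]), abs(v[2]))
  g + 1L
}

gcd2 <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  as.integer(max(a, 1L))
}

#' Identify and measure the objects of a binary mask
#'
#' Labels the 8-connected components of a mask and computes, for each, its
#' area, solidity (area over the number of pixels covered by its convex
#' hull), centroid, bounding box, and whether it touches the image border.
#'
#' @param mask logical matrix (white = candidate animal).
#' @return A list of `seg_object`s: `label`, `area`, `solidity`, `centroid`
#'   (0-based `(row, col)`), `bbox` (0-based half-open `(r0, r1, c0, c1)`),
#'   `touches_border`, and `pixels` (linear indices into the mask).
#' @export
label_objects <- function(mask) {
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0) return(list())
  H <- nrow(mask); W <- ncol(mask)
  idx_all <- which(lab > 0)
  by_lab <- split(idx_all, lab[idx_all])
  lapply(seq_len(k), function(i) {
    idx <- by_lab[[as.character(i)]]
    rs <- ((idx - 1) %% H)          # 0-based rows
    cs <- ((idx - 1) %/% H)         # 0-based cols
    area <- length(idx)
    hull_area <- convex_hull_lattice_area(rs, cs)
    structure(list(
      label = i, area = area,
      solidity = area / max(hull_area, area),
      centroid = c(row = mean(rs), col = mean(cs)),
      bbox = c(r0 = min(rs), r1 = max(rs) + 1L, c0 = min(cs), c1 = max(cs) + 1L),
      touches_border = any(rs == 0 | rs == H - 1 | cs == 0 | cs == W - 1),
      pixels = idx, mask_dim = c(H, W)), class = "seg_object")
  })
}

#' Remove small and small-ragged objects
#'
#' Drops objects with area below 2000 px, and objects with area below
#' 5000 px whose solidity is below 0.7 ("smaller than" read strictly, so
#' objects exactly at a boundary survive).
#'
#' @param objs list of `seg_object`s.
#' @param cfg pipeline configuration.
#' @return The surviving objects.
#' @export
filter_objects <- function(objs, cfg = default_config()) {
  keep <- vapply(objs, function(o)
    o$area >= cfg$min_area &&
      !(o$area < cfg$small_area && o$solidity < cfg$small_solidity),
    logical(1))
  objs[keep]
}

#' Elevation correction factor
#'
#' Compensates ground-sample-distance drift caused by terrain elevation:
#' with a mean object area `Ao` the factor is 1 when `Ao < 8000`, 1.25 when
#' `8000 <= Ao < 15000`, and 1.5 when `Ao >= 15000`. With no objects there
#' is no basis for rescaling and the factor is 1.
#'
#' @param objs list of `seg_object`s (post-filtering), or a numeric vector
#'   of areas.
#' @param cfg pipeline configuration.
#' @return The elevation factor `ev`.
#' @export
elevation_factor <- function(objs, cfg = default_config()) {
  areas <- if (is.numeric(objs)) objs else vapply(objs, `[[`, 0, "area")
  if (length(areas) == 0) return(cfg$ev_values[1])
  ao <- mean(areas)
  if (ao < cfg$ev_breaks[1]) cfg$ev_values[1]
  else if (ao < cfg$ev_breaks[2]) cfg$ev_values[2]
  else cfg$ev_values[3]
}

# The cluster predicate of the counting rules.
is_cluster_candidate <- function(area, solidity, ev, cfg) {
  area > ev * cfg$cluster_area ||
    solidity < cfg$cluster_solidity ||
    (area > ev * cfg$cluster_area2 && solidity < cfg$cluster_solidity2)
}

# Extract an object's footprint as a small padded logical matrix.
object_footprint <- function(obj, pad = 2L) {
  H <- obj$mask_dim[1]
  rs <- ((obj$pixels - 1) %% H)
  cs <- ((obj$pixels - 1) %/% H)
  r0 <- min(rs); c0 <- min(cs)
  m <- matrix(FALSE, max(rs) - r0 + 1 + 2 * pad, max(cs) - c0 + 1 + 2 * pad)
  m[cbind(rs - r0 + 1 + pad, cs - c0 + 1 + pad)] <- TRUE
  m
}

#' Number of animals in one object
#'
#' Applies the cluster rules to a filtered object. Objects are potential
#' clusters when their area exceeds `ev * 15000`, their solidity is below
#' 0.65, or their area exceeds `ev * 12000` with solidity below 0.7; other
#' objects count as one animal. A candidate cluster is thinned for
#' `round(20 ev)` iterations and eroded by one pixel on its own footprint;
#' the fragments are censused as `Ah` (area above 100 px) and `Sl`
#' (solidity below 0.5, fragments may count in both), and the object's
#' count is `N = Ah + Sl - 1`. In the default `"pooled"` mode the object
#' contributes `max(1, N)`; in `"additive"` mode it contributes
#' `1 + max(0, N)`. An object whose footprint is completely removed by the
#' morphology contributes 1, or 0 when `strict_empty` is set.
#'
#' @param obj a `seg_object` that survived [filter_objects()].
#' @param ev elevation factor of the image.
#' @param cfg pipeline configuration.
#' @return Integer animal count for this object.
#' @export
cluster_count <- function(obj, ev, cfg = default_config()) {
  if (!is_cluster_candidate(obj$area, obj$solidity, ev, cfg)) return(1L)
  fp <- object_footprint(obj)
  thinned <- thin_mask(fp, round(cfg$thinning_base * ev))
  core <- erode3(thinned, 1)
  frags <- label_objects(core)
  if (length(frags) == 0)
    return(if (isTRUE(cfg$strict_empty)) 0L else 1L)
  ah <- sum(vapply(frags, `[[`, 0, "area") > cfg$fragment_area)
  sl <- sum(vapply(frags, `[[`, 0, "solidity") < cfg$fragment_solidity)
  n <- ah + sl - 1L
  if (cfg$n_mode == "additive") 1L + max(0L, n) else max(1L, n)
}

#' Per-image animal count
#'
#' Runs the object stage on each of the three fused masks: label, filter,
#' elevation factor, and the sum of per-object cluster counts; then
#' arbitrates the final estimate across the three masks.
#'
#' @param fused a `fused_masks` from [fuse_masks()].
#' @param cfg pipeline configuration.
#' @return An `image_estimate`: integer `estimates` (named `T`, `T2`,
#'   `T4`), `final`, per-mask `ev`, and `objects` — for each mask a data
#'   frame of retained objects (area, solidity, centroid, border flag,
#'   contribution) plus the object list of the arbitrated mask in
#'   `final_objects`.
#' @export
count_image <- function(fused, cfg = default_config()) {
  stopifnot(inherits(fused, "fused_masks"))
  variants <- c("T", "T2", "T4")
  ests <- setNames(integer(3), variants)
  evs <- setNames(numeric(3), variants)
  obj_lists <- setNames(vector("list", 3), variants)
  for (i in seq_along(variants)) {
    mask <- fused[[c("final_T", "final_T2", "final_T4")[i]]]
    objs <- filter_objects(label_objects(mask), cfg)
    ev <- elevation_factor(objs, cfg)
    counts <- vapply(objs, cluster_count, integer(1), ev = ev, cfg = cfg)
    ests[i] <- sum(counts)
    evs[i] <- ev
    obj_lists[[i]] <- list(objects = objs, counts = counts)
  }
  fin <- final_estimate(ests, cfg)
  pick <- names(which(ests == fin))[1] %||% "T"
  if (is.na(pick)) pick <- "T"
  structure(list(estimates = ests, final = fin, ev = evs,
                 objects = obj_lists, final_variant = pick,
                 final_objects = obj_lists[[pick]]),
            class = "image_estimate")
}

#' Arbitrate the final per-image estimate
#'
#' The final count is the highest of the per-mask estimates, unless it is
#' more than three animals above the second highest, in which case the
#' second highest is taken (a guard against one mask fragmenting badly).
#'
#' @param estimates integer vector of per-mask estimates (NAs are dropped).
#' @param cfg pipeline configuration (uses `final_gap`).
#' @return Integer final estimate.
#' @export
final_estimate <- function(estimates, cfg = default_config()) {
  e <- estimates[!is.na(estimates)]
  if (length(e) == 0) stopf("no estimates to arbitrate")
  if (length(e) == 1) return(as.integer(e))
  s <- sort(e, decreasing = TRUE)
  if (s[1] - s[2] <= cfg$final_gap) as.integer(s[1]) else as.integer(s[2])
}
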