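#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters of the counting pipeline with
#' their published defaults. Every constant used anywhere in the pipeline is
#' routed through this list so that a run is fully described by its
#' configuration. Values were tuned for light-coated (Canchim/Nelore type)
#' cattle imaged at a ground sample distance of about 1 cm/pixel; size rules
#' must be rescaled for other GSDs.
#'
#' @return A named list of class `herd_config`:
#' \describe{
#'   \item{tile_size}{Grid tile side in pixels for region-of-interest
#'     classification (default 224).}
#'   \item{classifier}{Tile classifier selector: `"constant_accept"`,
#'     `"constant_reject"`, `"brightness"`, `"truth"`, or a dotted
#'     `"pkg::fun"` name resolving to a classifier factory.}
#'   \item{cf_target}{Numerator of the quadrant brightness correction factor
#'     `cf = cf_target / mean(Pi)` (default 85).}
#'   \item{min_active_pixels}{Minimum number of Y-channel pixels with value
#'     > 0 for a quadrant to be processed at all (default 50000).}
#'   \item{c_thresh_scale, c_thresh_cap}{C-channel threshold
#'     `min(c_thresh_cap, c_thresh_scale * cf)` (defaults 40, 100).}
#'   \item{m_thresh}{Fixed M-channel threshold (default 30).}
#'   \item{custom_thresh_scale, custom_thresh_cap}{Custom-channel threshold
#'     `min(cap, scale * cf)` (defaults 120, 150).}
#'   \item{hist_smooth_window}{Moving-average window for the Y histogram
#'     (default 25).}
#'   \item{dark_low_bins}{Number of lowest histogram bins summed in the
#'     dark-quadrant test (default 10).}
#'   \item{dark_high_bins}{Number of highest histogram bins summed in the
#'     dark-quadrant test (default 156, i.e. bins 100..255).}
#'   \item{dark_threshold}{Y threshold assigned to a very dark quadrant
#'     (default 10).}
#'   \item{peak_min_separation}{Peaks closer than this many bins are merged,
#'     keeping the larger (default 30).}
#'   \item{valley_fraction}{A valley bin qualifies when its amplitude is
#'     below this fraction of the second peak's amplitude (default 0.10).}
#'   \item{min_area}{Objects below this area are dropped (default 2000).}
#'   \item{small_area, small_solidity}{Objects with area below `small_area`
#'     and solidity below `small_solidity` are dropped (defaults 5000, 0.7).}
#'   \item{ev_breaks, ev_values}{Elevation factor: mean object area below
#'     `ev_breaks[1]` gives `ev_values[1]`, below `ev_breaks[2]` gives
#'     `ev_values[2]`, else `ev_values[3]` (defaults 8000/15000 and
#'     1/1.25/1.5).}
#'   \item{cluster_area, cluster_solidity, cluster_area2, cluster_solidity2}{
#'     An object is a candidate cluster when area > ev*cluster_area, or
#'     solidity < cluster_solidity, or (area > ev*cluster_area2 and
#'     solidity < cluster_solidity2) (defaults 15000, 0.65, 12000, 0.7).}
#'   \item{thinning_base}{Thinning iterations = round(thinning_base * ev)
#'     (default 20), followed by a 1-pixel erosion.}
#'   \item{fragment_area, fragment_solidity}{Fragment census cutoffs: Ah =
#'     fragments with area > `fragment_area` (default 100), Sl = fragments
#'     with solidity < `fragment_solidity` (default 0.5).}
#'   \item{n_mode}{Cluster count interpretation of N = Ah + Sl - 1:
#'     `"pooled"` (object contributes max(1, N)) or `"additive"`
#'     (object contributes 1 + max(0, N)).}
#'   \item{strict_empty}{If TRUE an object whose footprint is completely
#'     removed by the morphology contributes 0 instead of 1, reproducing the
#'     undercount failure mode of complete removal.}
#'   \item{final_gap}{Final-estimate rule: take the highest per-mask estimate
#'     unless it exceeds the second highest by more than this many animals,
#'     in which case take the second (default 3).}
#'   \item{border_band}{De-duplication border band width in pixels
#'     (default 10).}
#'   \item{match_tolerance}{Stored border-object matching tolerance in
#'     pixels, about 1.5 m at 1 cm/pixel (default 150).}
#'   \item{min_matches}{Minimum matched points before the fallback
#'     registration detector is invoked (default 6).}
#'   \item{coat_reference_rgb, coat_tolerance, coat_fraction}{Brightness
#'     heuristic classifier: a tile is cattle when at least `coat_fraction`
#'     of its pixels are within `coat_tolerance` (per channel) of
#'     `coat_reference_rgb`.}
#' }
#' @seealso [read_config()], [write_config()]
#' @export
default_config <- function() {
  cfg <- list(
    tile_size            = 224L,
    classifier           = "constant_accept",
    cf_target            = 85,
    min_active_pixels    = 50000L,
    c_thresh_scale       = 40,
    c_thresh_cap         = 100,
    m_thresh             = 30,
    custom_thresh_scale  = 120,
    custom_thresh_cap    = 150,
    hist_smooth_window   = 25L,
    dark_low_bins        = 10L,
    dark_high_bins       = 156L,
    dark_threshold       = 10L,
    peak_min_separation  = 30L,
    valley_fraction      = 0.10,
    min_area             = 2000,
    small_area           = 5000,
    small_solidity       = 0.7,
    ev_breaks            = c(8000, 15000),
    ev_values            = c(1, 1.25, 1.5),
    cluster_area         = 15000,
    cluster_solidity     = 0.65,
    cluster_area2        = 12000,
    cluster_solidity2    = 0.7,
    thinning_base        = 20,
    fragment_area        = 100,
    fragment_solidity    = 0.5,
    n_mode               = "pooled",
    strict_empty         = FALSE,
    final_gap            = 3,
    border_band          = 10,
    match_tolerance      = 150,
    min_matches          = 6L,
    coat_reference_rgb   = c(228, 220, 200),
    coat_tolerance       = 45,
    coat_fraction        = 0.02
  )
  class(cfg) <- "herd_config"
  cfg
}

#' Validate a configuration list
#'
#' Checks types, ranges and key names. Unknown keys are rejected so that a
#' typo in a config file cannot silently fall back to a default.
#'
#' @param cfg a list as returned by [default_config()], possibly modified.
#' @return The validated config (invisibly classed `herd_config`).
#' @export
validate_config <- function(cfg) {
  ref <- unclass(default_config())
  if (!is.list(cfg)) stopf("config must be a list")
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0)
    stopf("unknown config keys: %s", paste(extra, collapse = ", "))
  merged <- ref
  merged[names(cfg)] <- cfg
  num_pos <- c("tile_size", "cf_target", "c_thresh_scale", "c_thresh_cap",
               "m_thresh", "custom_thresh_scale", "custom_thresh_cap",
               "hist_smooth_window", "dark_low_bins", "dark_high_bins",
               "dark_threshold", "peak_min_separation", "min_area",
               "small_area", "thinning_base", "fragment_area", "final_gap",
               "border_band", "match_tolerance", "min_matches")
  for (k in num_pos) {
    v <- merged[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stopf("config key '%s' must be a positive number", k)
  }
  if (merged$min_active_pixels < 0) stopf("min_active_pixels must be >= 0")
  if (merged$valley_fraction <= 0 || merged$valley_fraction >= 1)
    stopf("valley_fraction must be in (0,1)")
  if (!merged$n_mode %in% c("pooled", "additive"))
    stopf("n_mode must be 'pooled' or 'additive'")
  if (length(merged$ev_breaks) != 2 || length(merged$ev_values) != 3)
    stopf("ev_breaks must have length 2 and ev_values length 3")
  class(merged) <- "herd_config"
  invisible(merged)
}

#' Read / write a configuration as YAML
#'
#' The YAML file is the single source of all pipeline constants; reading a
#' file written by [write_config()] round-trips to an identical config.
#'
#' @param path path to a YAML file.
#' @return [read_config()] returns a validated `herd_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a configuration list.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
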