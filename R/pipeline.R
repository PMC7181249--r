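#' Count the animals in one frame
#'
#' Runs the full single-image pipeline: grid tiling, tile classification,
#' region-of-interest extraction, quadrant mask generation, mask fusion,
#' and object counting.
#'
#' @param img an [rgb_image()] (or H×W×3 array).
#' @param cfg pipeline configuration; `cfg$classifier` selects the tile
#'   classifier.
#' @param truth optional `scene_truth`, required when
#'   `cfg$classifier == "truth"`.
#' @param keep_masks if TRUE the returned object also carries the mask set
#'   and fused masks (for debugging / mask dumps).
#' @return An `image_estimate` (see [count_image()]); the threshold chosen
#'   for each quadrant is available in `attr(, "masks")$quadrants` when
#'   `keep_masks` is set.
#' @export
detect_image <- function(img, cfg = default_config(), truth = NULL,
                         keep_masks = FALSE) {
  px <- if (inherits(img, "rgb_image")) img$pixels else img
  grid <- tile_image(px, cfg$tile_size)
  clf <- resolve_classifier(cfg$classifier, truth = truth,
                            H = dim(px)[1], W = dim(px)[2], cfg = cfg)
  roi <- build_roi(img, grid, clf)
  masks <- build_mask_set(roi, cfg)
  fused <- fuse_masks(masks)
  est <- count_image(fused, cfg)
  if (keep_masks) {
    attr(est, "masks") <- masks
    attr(est, "fused") <- fused
    attr(est, "roi") <- roi
  }
  est
}

#' Batch detection over images
#'
#' Runs [detect_image()] over a set of frames and collects one CSV row per
#' image: the three per-threshold estimates, the elevation factor of the
#' arbitrated mask and the final count. Unreadable files are reported and
#' skipped; the run continues. Reruns with the same configuration and
#' inputs are bit-identical.
#'
#' @param inputs character vector of PNG paths, or a list of
#'   [rgb_image()]s.
#' @param cfg pipeline configuration.
#' @param out_csv optional path; when given the table is written there.
#' @return A data frame with columns `image`, `estimate_T`, `estimate_T2`,
#'   `estimate_T4`, `ev`, `final` (and an `error` column when a file could
#'   not be processed).
#' @export
run_detect <- function(inputs, cfg = default_config(), out_csv = NULL) {
  cfg <- validate_config(cfg)
  rows <- lapply(inputs, function(inp) {
    res <- tryCatch({
      img <- if (is.character(inp)) read_frame(inp) else inp
      est <- detect_image(img, cfg)
      data.frame(image = if (is.character(inp)) basename(inp) else (img$id %||% "image"),
                 estimate_T = est$estimates["T"],
                 estimate_T2 = est$estimates["T2"],
                 estimate_T4 = est$estimates["T4"],
                 ev = est$ev[est$final_variant],
                 final = est$final, error = NA_character_)
    }, error = function(e) {
      data.frame(image = if (is.character(inp)) basename(inp) else "image",
                 estimate_T = NA_integer_, estimate_T2 = NA_integer_,
                 estimate_T4 = NA_integer_, ev = NA_real_,
                 final = NA_integer_, error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Detect and de-duplicate a whole survey
#'
#' Chains per-frame detection, pairwise registration of consecutive frames
#' and the sequential overlap de-duplication into the survey total.
#'
#' @param survey either a `survey_truth` from [generate_survey()] or a
#'   directory of `frame_*.png` files with metadata sidecars.
#' @param cfg pipeline configuration.
#' @param registration `"estimate"` registers consecutive frames with
#'   [register_pair()]; `"truth"` uses the survey's exact transforms
#'   (synthetic surveys only).
#' @param out_json optional path for the survey tally JSON.
#' @return A `survey_tally` (see [dedup_survey()]) with the per-image
#'   estimates attached as attribute `"detections"`.
#' @export
run_survey <- function(survey, cfg = default_config(),
                       registration = c("estimate", "truth"),
                       out_json = NULL) {
  cfg <- validate_config(cfg)
  registration <- match.arg(registration)
  if (is.character(survey)) {
    paths <- sort(list.files(survey, pattern = "\\.png$", full.names = TRUE))
    if (length(paths) == 0) stopf("no frames found in %s", survey)
    frames <- lapply(paths, read_frame)
    truths <- NULL
  } else {
    frames <- survey$frames
    truths <- survey$truths
  }
  if (any(vapply(frames, function(f) is.na(as.numeric(f$timestamp)), TRUE)))
    stopf("frames are missing timestamps")
  ord <- order(vapply(frames, function(f) as.numeric(f$timestamp), 0),
               vapply(frames, function(f) f$id %||% "", ""))
  frames <- frames[ord]

  records <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    truth_i <- if (!is.null(truths)) truths[[ord[i]]] else NULL
    est <- detect_image(frames[[i]], cfg, truth = truth_i)
    records[[i]] <- estimate_records(frames[[i]], est)
  }
  transforms <- if (registration == "truth") {
    if (is.character(survey)) stopf("truth registration needs a synthetic survey object")
    survey$transforms
  } else {
    lapply(seq_len(max(0, length(frames) - 1)), function(i)
      register_pair(frames[[i]], frames[[i + 1]], cfg))
  }
  tally <- dedup_survey(records, transforms, cfg)
  if (!is.null(out_json)) {
    payload <- list(config = unclass(cfg), total = tally$total,
                    images = tally$images)
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  attr(tally, "detections") <- records
  tally
}
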