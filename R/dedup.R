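# Sequential overlap de-duplication across a survey.
#
# Frames are processed in chronological order. Objects in the border band
# are excluded from their frame's tally; the first time such an object is
# seen in fresh (uncovered) ground its world position is stored. Interior
# objects falling in ground covered by earlier frames are excluded, unless
# they match a stored border object, in which case they are counted and
# the entry consumed. Interior objects on fresh ground are counted (and
# consume a matching stored entry, so a deferred object is never credited
# twice). Objects carry their multi-animal cluster count through every
# exclusion and credit.

# World position = centroid mapped through the chained transforms into the
# first frame's coordinate system.
compose_to_world <- function(transforms, n) {
  mats <- vector("list", n)
  mats[[1]] <- diag(3)
  if (n >= 2) {
    for (i in 2:n) {
      Tprev <- transforms[[i - 1]]
      Mprev <- if (inherits(Tprev, "pair_transform")) Tprev$M else Tprev
      mats[[i]] <- mats[[i - 1]] %*% solve(Mprev)
    }
  }
  mats
}

point_in_rects <- function(x, y, rects) {
  if (length(rects) == 0) return(FALSE)
  for (rc in rects)
    if (x >= rc[1] && x <= rc[2] && y >= rc[3] && y <= rc[4]) return(TRUE)
  FALSE
}

#' Build de-duplication records from ground truth
#'
#' Converts a synthetic survey's per-frame truths into the per-object
#' records [dedup_survey()] consumes, one record per visible animal with a
#' count of one, centroid and bounding box in frame coordinates. Running
#' the de-duplication on these records isolates its bookkeeping from any
#' counting-stage error.
#'
#' @param survey a `survey_truth` from [generate_survey()].
#' @return A list of per-frame records.
#' @export
truth_records <- function(survey) {
  lapply(seq_along(survey$frames), function(i) {
    fr <- survey$frames[[i]]
    an <- survey$truths[[i]]$animals
    H <- dim(fr$pixels)[1]; W <- dim(fr$pixels)[2]
    if (nrow(an) > 0) {
      ext <- t(vapply(seq_len(nrow(an)), function(k)
        ellipse_extents(an$a[k], an$b[k], an$angle[k]), numeric(2)))
      objs <- data.frame(
        row = an$center_r, col = an$center_c, count = 1L,
        r0 = pmax(0, an$center_r - ext[, 1]), r1 = pmin(H, an$center_r + ext[, 1]),
        c0 = pmax(0, an$center_c - ext[, 2]), c1 = pmin(W, an$center_c + ext[, 2]))
    } else {
      objs <- data.frame(row = numeric(0), col = numeric(0), count = integer(0),
                         r0 = numeric(0), r1 = numeric(0),
                         c0 = numeric(0), c1 = numeric(0))
    }
    list(id = fr$id, timestamp = fr$timestamp, H = H, W = W, objects = objs)
  })
}

# Records from a pipeline image estimate: the retained objects of the
# arbitrated mask with their cluster contributions.
estimate_records <- function(img, est) {
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  objs <- est$final_objects$objects
  counts <- est$final_objects$counts
  if (length(objs) > 0) {
    df <- data.frame(
      row = vapply(objs, function(o) o$centroid["row"], 0),
      col = vapply(objs, function(o) o$centroid["col"], 0),
      count = as.integer(counts),
      r0 = vapply(objs, function(o) o$bbox["r0"], 0),
      r1 = vapply(objs, function(o) o$bbox["r1"], 0),
      c0 = vapply(objs, function(o) o$bbox["c0"], 0),
      c1 = vapply(objs, function(o) o$bbox["c1"], 0))
  } else {
    df <- data.frame(row = numeric(0), col = numeric(0), count = integer(0),
                     r0 = numeric(0), r1 = numeric(0),
                     c0 = numeric(0), c1 = numeric(0))
  }
  list(id = img$id, timestamp = img$timestamp, H = H, W = W, objects = df)
}

#' Sequential overlap de-duplication
#'
#' Tallies a survey so that each animal (or cluster object) is counted
#' exactly once across overlapping frames, following the border-band /
#' covered-region bookkeeping described above. The per-image identity
#' `adjusted = raw - removed_border - removed_overlap` holds on every run
#' (credited carryovers are part of `adjusted` and reported separately).
#'
#' @param records list of per-frame records: `id`, `timestamp`, `H`, `W`
#'   and an `objects` data frame with columns `row`, `col` (0-based
#'   centroid), `count` (animals in the object) and bounding box
#'   `r0, r1, c0, c1`. Must be sorted by strictly increasing timestamp.
#' @param transforms list of `pair_transform`s mapping frame i into frame
#'   i+1, length `length(records) - 1`.
#' @param cfg pipeline configuration (uses `border_band`,
#'   `match_tolerance`).
#' @return A `survey_tally`: per-image data frame (`id`, `raw`,
#'   `removed_border`, `removed_overlap`, `credited`, `adjusted`), the
#'   survey `total`, and the number of stored entries never consumed.
#' @export
dedup_survey <- function(records, transforms, cfg = default_config()) {
  n <- length(records)
  if (n == 0) stopf("empty survey")
  ts <- vapply(records, function(r) as.numeric(r$timestamp), numeric(1))
  if (n > 1 && any(diff(ts) <= 0)) stopf("timestamps must be strictly increasing")
  if (n > 1 && length(transforms) < n - 1)
    stopf("missing transform between overlapping images")
  world <- compose_to_world(transforms, n)
  band <- cfg$border_band
  tol <- cfg$match_tolerance

  stored <- data.frame(x = numeric(0), y = numeric(0), count = integer(0),
                       frame = integer(0))
  covered <- list()
  out <- data.frame(id = character(n), raw = integer(n),
                    removed_border = integer(n), removed_overlap = integer(n),
                    credited = integer(n), adjusted = integer(n),
                    stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    rec <- records[[i]]
    obj <- rec$objects
    M <- world[[i]]
    raw <- sum(obj$count)
    removed_border <- removed_overlap <- credited <- 0L

    if (nrow(obj) > 0) {
      wpos <- t(apply(cbind(obj$col, obj$row), 1, function(p) apply_transform(M, p)))
      is_border <- obj$r0 < band | obj$c0 < band |
        obj$r1 > rec$H - band | obj$c1 > rec$W - band
      is_covered <- vapply(seq_len(nrow(obj)), function(k)
        point_in_rects(wpos[k, 1], wpos[k, 2], covered), logical(1))

      # Match this frame's objects against the stored border entries of
      # earlier frames (entries stored in the current frame are not yet
      # eligible): greedy assignment by increasing distance, each entry and
      # each object used at most once, so an object standing exactly on
      # its own deferred position always claims it first.
      elig <- which(stored$frame < i)
      match_of <- rep(NA_integer_, nrow(obj))
      if (length(elig) > 0) {
        dmat <- outer(seq_len(nrow(obj)), elig, function(k, j)
          sqrt((wpos[k, 1] - stored$x[j])^2 + (wpos[k, 2] - stored$y[j])^2))
        cand <- which(dmat <= tol, arr.ind = TRUE)
        if (nrow(cand) > 0) {
          cand <- cand[order(dmat[cand]), , drop = FALSE]
          used_entry <- logical(length(elig))
          for (r in seq_len(nrow(cand))) {
            k <- cand[r, 1]; e <- cand[r, 2]
            if (is.na(match_of[k]) && !used_entry[e]) {
              match_of[k] <- elig[e]
              used_entry[e] <- TRUE
            }
          }
        }
      }

      consumed <- integer(0)
      # pass 1: border objects are excluded; first appearances on fresh
      # ground are deferred (a matched entry stays deferred, not re-stored)
      for (k in which(is_border)) {
        removed_border <- removed_border + obj$count[k]
        if (is.na(match_of[k]) && !is_covered[k])
          stored[nrow(stored) + 1, ] <- list(wpos[k, 1], wpos[k, 2],
                                             obj$count[k], i)
      }
      # pass 2: interior objects on covered ground — credit deferred ones
      for (k in which(!is_border & is_covered)) {
        if (!is.na(match_of[k])) {
          credited <- credited + obj$count[k]
          consumed <- c(consumed, match_of[k])
        } else {
          removed_overlap <- removed_overlap + obj$count[k]
        }
      }
      # pass 3: interior objects on fresh ground are counted; a matching
      # deferred entry is consumed so it cannot be credited again later
      for (k in which(!is_border & !is_covered)) {
        if (!is.na(match_of[k])) consumed <- c(consumed, match_of[k])
      }
      if (length(consumed) > 0)
        stored <- stored[-consumed, , drop = FALSE]
    }

    corner <- apply_transform(M, c(0, 0))
    covered[[i]] <- c(corner[1], corner[1] + rec$W - 1,
                      corner[2], corner[2] + rec$H - 1)
    out$id[i] <- as.character(rec$id)
    out$raw[i] <- raw
    out$removed_border[i] <- removed_border
    out$removed_overlap[i] <- removed_overlap
    out$credited[i] <- credited
    out$adjusted[i] <- raw - removed_border - removed_overlap
  }
  structure(list(images = out, total = sum(out$adjusted),
                 unconsumed = nrow(stored)),
            class = "survey_tally")
}

#' @export
print.survey_tally <- function(x, ...) {
  cat(sprintf("<survey_tally: %d frames, total %d animals>\n",
              nrow(x$images), x$total))
  print(x$images)
  invisible(x)
}
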