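#' Count-based evaluation metrics
#'
#' Scores estimated against actual counts, per object, image or survey.
#' From each (estimate, truth) pair the tally takes `TP = min(Ce, Ct)`,
#' `FP = max(0, Ce - Ct)` and `FN = max(0, Ct - Ce)`, pooled over pairs:
#' precision `= 100 ΣTP / (ΣTP + ΣFP)`, recall `= 100 ΣTP / (ΣTP + ΣFN)`,
#' `F1 = 2PR / (P + R)`. The mean deviation is `Σ(Ce - Ct) / N` and the
#' dispersion figure reported alongside it is the mean absolute deviation
#' `Σ|Ce - Ct| / N`; the largest negative and positive deviations complete
#' the report. When the totals balance (`ΣCe = ΣCt`), precision equals
#' recall by construction. A confusion matrix crossing actual and
#' estimated counts is included, and an optional stratification label
#' yields the same metrics per stratum.
#'
#' @param pairs data frame (or 2-column matrix) with columns `estimate`
#'   and `truth`, one row per scored unit.
#' @param strata optional vector of stratum labels, same length as
#'   `nrow(pairs)`.
#' @return A `metrics_report` list: `precision`, `recall`, `f1` (percent),
#'   `mean_deviation`, `mean_abs_deviation`, `min_deviation`,
#'   `max_deviation`, `n`, `confusion` (actual × estimated table), and
#'   `by_stratum` when `strata` is given.
#' @export
count_metrics <- function(pairs, strata = NULL) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) stopf("count_metrics needs at least one pair")
  ce <- pairs$estimate; ct <- pairs$truth
  if (is.null(ce) || is.null(ct)) stopf("pairs must have columns estimate and truth")
  tp <- sum(pmin(ce, ct)); fp <- sum(pmax(0, ce - ct)); fn <- sum(pmax(0, ct - ce))
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  dev <- ce - ct
  rep <- list(precision = prec, recall = rec, f1 = f1,
              mean_deviation = mean(dev),
              mean_abs_deviation = mean(abs(dev)),
              min_deviation = min(dev), max_deviation = max(dev),
              n = nrow(pairs),
              confusion = table(actual = ct, estimated = ce))
  if (!is.null(strata)) {
    rep$by_stratum <- lapply(split(seq_len(nrow(pairs)), strata),
                             function(ix) count_metrics(pairs[ix, , drop = FALSE]))
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.1f%%  recall %.1f%%  F1 %.1f%%  (n = %d)\n",
              x$precision, x$recall, x$f1, x$n))
  cat(sprintf("mean dev %+.2f  mean |dev| %.2f  range [%+d, %+d]\n",
              x$mean_deviation, x$mean_abs_deviation,
              x$min_deviation, x$max_deviation))
  invisible(x)
}
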