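#' Window-level classification accuracy
#'
#' Fraction of windows whose hard label under the prediction matches the
#' hard label of the ground truth (see [hard_label()] for the collapsing
#' rule).
#'
#' @param pred,truth K x 4 soft-label matrices (or character label
#'   vectors) of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
window_accuracy <- function(pred, truth) {
  p <- if (is.matrix(pred)) hard_label(pred) else pred
  t <- if (is.matrix(truth)) hard_label(truth) else truth
  if (length(p) != length(t)) stop("prediction and truth lengths differ")
  mean(p == t)
}

#' Per-activity sample-level accuracy
#'
#' Per-sample recall of a predicted segmentation against the ground
#' truth: for each activity class, the fraction of ground-truth samples
#' of that class that the prediction labels identically; plus the total
#' fraction over all samples. Classes absent from the truth are omitted
#' (never reported as 1).
#'
#' @param pred_segs A `segment_list` covering the same range as `truth`.
#' @param truth A [protocol()].
#' @return A list: `per_activity` (named vector over the classes present)
#'   and `total`.
#' @export
activity_sample_accuracy <- function(pred_segs, truth) {
  pl <- protocol_sample_labels(pred_segs)
  tl <- protocol_sample_labels(truth)
  if (length(pl) != length(tl)) stop("segmentations cover different ranges")
  tally <- sample_accuracy_tally(pl, tl)
  list(per_activity = tally$correct[tally$total > 0] / tally$total[tally$total > 0],
       total = sum(tally$correct) / sum(tally$total))
}

# correct / total per class, over one pair of per-sample label vectors
sample_accuracy_tally <- function(pred_labels, truth_labels) {
  lv <- activity_levels()
  total <- vapply(lv, function(a) sum(truth_labels == a), numeric(1))
  correct <- vapply(lv, function(a) {
    sum(truth_labels == a & pred_labels == a)
  }, numeric(1))
  list(correct = correct, total = total)
}

#' Scenario-recognition accuracy
#'
#' Fraction of protocols whose extracted scenario (the ordered sequence
#' of non-break activities) is exactly equal to the ground-truth
#' scenario; order matters and no partial credit is given.
#'
#' @param pred,truth Lists of character vectors (scenarios), equal
#'   length.
#' @return Fraction in `[0, 1]`.
#' @export
scenario_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("scenario list lengths differ")
  mean(mapply(identical, lapply(pred, as.character),
              lapply(truth, as.character)))
}

#' Repetition-counting accuracy
#'
#' Fraction of exercise segments whose predicted count is within
#' `tolerance` of the true count, per activity and overall, together with
#' the total miscount `sum(|predicted - truth|)` and the miscount rate
#' (total miscount over total true repetitions).
#'
#' @param report A `repetition_report` (or data.frame with `label`,
#'   `predicted`, `truth`) carrying truth counts.
#' @param tolerance Allowed absolute error (0 = exact, 1, 2, ...).
#' @return A list: `per_activity` (named vector over activities present),
#'   `total`, `miscount`, `miscount_rate`, `n_segments`.
#' @export
#' @examples
#' r <- data.frame(label = "squat", predicted = c(5, 5, 7), truth = c(5, 6, 5))
#' repetition_accuracy(r, 1)$total  # 2/3
repetition_accuracy <- function(report, tolerance = 0) {
  if (anyNA(report$truth)) stop("report lacks ground-truth counts")
  err <- abs(report$predicted - report$truth)
  ok <- err <= tolerance
  acts <- intersect(exercise_levels(), unique(report$label))
  per <- vapply(acts, function(a) mean(ok[report$label == a]), numeric(1))
  list(per_activity = per,
       total = if (nrow(report) > 0) mean(ok) else NA_real_,
       miscount = sum(err),
       miscount_rate = sum(err) / sum(report$truth),
       n_segments = nrow(report))
}

#' Match predicted segments to ground-truth exercise segments
#'
#' Pairs every ground-truth exercise segment with the same-label
#' predicted segment of maximal overlap. Unmatched truth segments (no
#' overlapping prediction of that label) are kept with the truth bounds
#' and flagged, so a downstream count of 0 can be charged against them.
#'
#' @param pred_segs A `segment_list`.
#' @param truth A [protocol()].
#' @return A data.frame with one row per truth exercise segment: `label`,
#'   truth bounds and count, matched predicted bounds (`pred_start`,
#'   `pred_end`) and `matched` flag.
#' @export
match_segments <- function(pred_segs, truth) {
  tx <- truth[truth$label != "break", , drop = FALSE]
  out <- data.frame(label = tx$label, start = tx$start, end = tx$end,
                    truth = tx$repetitions,
                    pred_start = tx$start, pred_end = tx$end,
                    matched = FALSE)
  px <- pred_segs[pred_segs$label != "break", , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    same <- px[px$label == out$label[i], , drop = FALSE]
    if (nrow(same) == 0L) next
    ov <- pmin(same$end, out$end[i]) - pmax(same$start, out$start[i])
    j <- which.max(ov)
    if (ov[j] > 0L) {
      out$pred_start[i] <- same$start[j]
      out$pred_end[i] <- same$end[j]
      out$matched[i] <- TRUE
    }
  }
  out
}
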