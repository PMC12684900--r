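#' Base-pair-level interval confusion between truth and test ROH
#'
#' Clips both segment sets to the assayable regions, then computes by exact
#' interval arithmetic (no discretization): tp = |truth and test|,
#' fp = |test \\ truth|, fn = |truth \\ test|, tn = remaining assayable
#' length. tp + fp + tn + fn equals the assayable genome length exactly.
#'
#' @param truth,test Segment data.frames (chrom, start, end; 0-based
#'   half-open).
#' @param assayable Segment data.frame of assayable regions.
#' @return List of class `interval_confusion` with integer bp fields
#'   `tp`, `fp`, `fn`, `tn` and `basis = "length"`.
#' @export
interval_confusion_bp <- function(truth, test, assayable) {
  if (nrow(assayable) == 0L) stop_canroh("assayable regions are empty")
  a <- GenomicRanges::reduce(segments_to_granges(assayable))
  t_gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(segments_to_granges(truth)), a
  )
  s_gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(segments_to_granges(test)), a
  )
  tp <- sum(GenomicRanges::width(GenomicRanges::intersect(t_gr, s_gr)))
  fp <- sum(GenomicRanges::width(s_gr)) - tp
  fn <- sum(GenomicRanges::width(t_gr)) - tp
  tn <- sum(GenomicRanges::width(a)) - tp - fp - fn
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, basis = "length"),
    class = "interval_confusion"
  )
}

#' Segment-level confusion between truth and test ROH
#'
#' A truth segment overlapped by >= 1 bp of any test segment (or by at
#' least `min_overlap_frac` of its own length) is a true positive,
#' otherwise a false negative; a test segment with no truth overlap is a
#' false positive. True negatives are undefined on the segment basis and
#' reported as `NA` by default; optionally (`tn_from_gaps = TRUE`) tn is
#' taken as the number of gaps between truth segments with no test overlap
#' — an artifact convention enabling a segment-basis normalized MCC, off by
#' default.
#'
#' @param truth,test Segment data.frames.
#' @param min_overlap_frac Minimum fraction of the truth segment covered by
#'   test segments to count as recovered (0 = any overlap).
#' @param tn_from_gaps Substitute truth gaps without test overlap for tn.
#' @return List of class `interval_confusion`, `basis = "segments"`.
#' @export
segment_confusion <- function(truth, test, min_overlap_frac = 0,
                              tn_from_gaps = FALSE) {
  t_gr <- segments_to_granges(truth)
  s_gr <- segments_to_granges(test)
  if (min_overlap_frac <= 0) {
    tp <- sum(IRanges::overlapsAny(t_gr, s_gr))
    fp <- sum(!IRanges::overlapsAny(s_gr, t_gr))
  } else {
    cov <- GenomicRanges::intersect(
      t_gr, GenomicRanges::reduce(s_gr)
    )
    hits <- GenomicRanges::findOverlaps(t_gr, cov)
    covered <- tapply(
      GenomicRanges::width(cov)[S4Vectors::subjectHits(hits)],
      factor(S4Vectors::queryHits(hits), levels = seq_along(t_gr)),
      sum
    )
    covered[is.na(covered)] <- 0
    tp <- sum(covered / GenomicRanges::width(t_gr) >= min_overlap_frac)
    fp <- sum(!IRanges::overlapsAny(s_gr, t_gr))
  }
  fn <- length(t_gr) - tp
  tn <- NA_real_
  if (tn_from_gaps && length(t_gr) > 1L) {
    gaps <- GenomicRanges::gaps(GenomicRanges::reduce(t_gr))
    gaps <- gaps[GenomicRanges::start(gaps) > 1]
    tn <- sum(!IRanges::overlapsAny(gaps, s_gr))
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, basis = "segments"),
    class = "interval_confusion"
  )
}

#' Overlap scores from an interval confusion
#'
#' Computes F1 = 2tp/(2tp+fp+fn), Matthews correlation coefficient,
#' normalized MCC = (MCC+1)/2, sensitivity = tp/(tp+fn), specificity =
#' tn/(tn+fp) and FDR = fp/(tp+fp). Any statistic whose denominator is zero
#' (or whose inputs are undefined, e.g. tn on the segment basis) is `NA`.
#'
#' @param confusion An `interval_confusion`.
#' @return Named numeric vector `(f1, mcc, nmcc, sensitivity, specificity,
#'   fdr)`.
#' @export
overlap_scores <- function(confusion) {
  tp <- as.numeric(confusion$tp)
  fp <- as.numeric(confusion$fp)
  fn <- as.numeric(confusion$fn)
  tn <- as.numeric(confusion$tn)
  safe_div <- function(num, den) {
    if (is.na(den) || den == 0) NA_real_ else num / den
  }
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (is.na(mcc_den) || mcc_den == 0) {
    NA_real_
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  c(
    f1 = f1,
    mcc = mcc,
    nmcc = if (is.na(mcc)) NA_real_ else (mcc + 1) / 2,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    fdr = safe_div(fp, tp + fp)
  )
}
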