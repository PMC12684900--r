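#' Mann-Whitney rank-sum statistic W and two-sided p-value
#'
#' W is the rank-sum-minus-offset convention: the sum of the ranks of `x`
#' in the pooled sample (midranks for ties) minus \eqn{n_x(n_x+1)/2}, so
#' \eqn{W \in [0, n_x n_y]} and \eqn{W(x, y) + W(y, x) = n_x n_y}. This is
#' the convention under which published W values from the same statistical
#' environment are directly comparable. The p-value is exact (by
#' enumeration of the null rank distribution) when \eqn{n_x n_y \le 400}
#' and there are no ties, and otherwise uses the normal approximation with
#' tie correction; no continuity correction by default.
#'
#' @param x,y Numeric samples (e.g. per-sample F_ROH of two cohorts).
#' @param continuity Apply the continuity correction in the normal
#'   approximation.
#' @return List: `W`, `p_value`, `n_x`, `n_y`, `exact` (logical).
#' @export
rank_sum_W <- function(x, y, continuity = FALSE) {
  if (length(x) < 1L || length(y) < 1L) {
    stop_canroh("both groups must be non-empty")
  }
  n_x <- length(x)
  n_y <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  ties <- any(duplicated(c(x, y)))
  use_exact <- (n_x * n_y <= 400) && !ties
  wt <- suppressWarnings(wilcox.test(
    x, y,
    exact = use_exact, correct = continuity
  ))
  stopifnot(isTRUE(all.equal(unname(wt$statistic), W)))
  list(W = W, p_value = wt$p.value, n_x = n_x, n_y = n_y, exact = use_exact)
}

#' Pairwise cohort comparisons of F_ROH
#'
#' Runs [rank_sum_W()] for each requested pair of groups. No multiplicity
#' adjustment is applied (pairwise tests are reported raw).
#'
#' @param froh_table data.frame with columns `sample`, `group` and a value
#'   column (default `froh_all`).
#' @param pairs List of length-2 character vectors of group labels.
#' @param value Name of the value column to compare.
#' @return data.frame: group_x, group_y, n_x, n_y, W, p_value.
#' @export
compare_groups <- function(froh_table, pairs, value = "froh_all") {
  stopifnot(all(c("sample", "group", value) %in% names(froh_table)))
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% froh_table$group)) {
      stop_canroh("unknown group in pair: ", paste(pr, collapse = ":"))
    }
    x <- froh_table[[value]][froh_table$group == pr[1]]
    y <- froh_table[[value]][froh_table$group == pr[2]]
    res <- rank_sum_W(x, y)
    data.frame(
      group_x = pr[1], group_y = pr[2],
      n_x = res$n_x, n_y = res$n_y,
      W = res$W, p_value = res$p_value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Build a per-sample F_ROH table from segment sets
#'
#' @param roh_sets Named list of per-sample segment data.frames.
#' @param labels data.frame with `sample` and `group`.
#' @param autosome_length Total autosome length in bp.
#' @param long_threshold Short/long boundary in bp (default 1.6 Mb).
#' @return data.frame: sample, group, froh_all, froh_short, froh_long,
#'   n_segments, total_bp, max_bp.
#' @export
froh_table <- function(roh_sets, labels, autosome_length,
                       long_threshold = 1.6e6) {
  rows <- lapply(names(roh_sets), function(s) {
    segs <- roh_sets[[s]]
    data.frame(
      sample = s,
      group = labels$group[match(s, labels$sample)],
      froh_all = froh(segs, autosome_length, "all", long_threshold),
      froh_short = froh(segs, autosome_length, "short", long_threshold),
      froh_long = froh(segs, autosome_length, "long", long_threshold),
      n_segments = nrow(segs),
      total_bp = if (nrow(segs)) sum(segs$end - segs$start) else 0,
      max_bp = if (nrow(segs)) max(segs$end - segs$start) else 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
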