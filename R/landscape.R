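#' Tile the genome into fixed-width windows
#'
#' Each chromosome is tiled with `width`-bp windows (default 500 kb); the
#' last window of a chromosome is truncated, so total window length equals
#' total genome length.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param width Window width in bp.
#' @return data.frame (window, chrom, start, end; 0-based half-open) with
#'   the chromosome lengths attached as attribute `chrom_lengths`.
#' @export
make_windows <- function(chrom_lengths, width = 5e5) {
  assert_pos(width, "width")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  tiles <- GenomicRanges::tileGenome(
    chrom_lengths,
    tilewidth = width, cut.last.tile.in.chrom = TRUE
  )
  out <- granges_to_segments(tiles)
  out <- data.frame(window = seq_len(nrow(out)), out,
    stringsAsFactors = FALSE
  )
  attr(out, "chrom_lengths") <- chrom_lengths
  out
}

#' Depth and CNV window quality filter
#'
#' Marks a window as included when its mean depth lies within
#' mean +/- `k_sd` * SD of the genome-wide per-window depths (sample SD,
#' n - 1) and it is not excluded by the CNV mask. A window overlapping the
#' mask by at least `cnv_overlap_frac` of its own length is excluded
#' regardless of depth.
#'
#' @param windows Window grid from [make_windows()].
#' @param depths Per-window mean depth vector, aligned to `windows`.
#' @param cnv_mask Optional segment data.frame of CNV-rich regions.
#' @param k_sd SD multiplier (default 2).
#' @param cnv_overlap_frac Overlap fraction triggering exclusion.
#' @return The window grid with columns `depth` and `included` added.
#' @export
filter_windows <- function(windows, depths, cnv_mask = NULL, k_sd = 2,
                           cnv_overlap_frac = 0.5) {
  if (length(depths) != nrow(windows)) {
    stop_canroh("depths must align with the window grid")
  }
  mu <- mean(depths)
  s <- sd(depths)
  included <- depths >= mu - k_sd * s & depths <= mu + k_sd * s
  if (!is.null(cnv_mask) && nrow(cnv_mask) > 0L) {
    win_gr <- segments_to_granges(windows)
    mask_gr <- GenomicRanges::reduce(segments_to_granges(cnv_mask))
    cov <- GenomicRanges::intersect(win_gr, mask_gr)
    hits <- GenomicRanges::findOverlaps(win_gr, cov)
    overlap <- rep(0, nrow(windows))
    if (length(hits) > 0) {
      agg <- tapply(
        GenomicRanges::width(cov)[S4Vectors::subjectHits(hits)],
        S4Vectors::queryHits(hits), sum
      )
      overlap[as.integer(names(agg))] <- agg
    }
    frac <- overlap / (windows$end - windows$start)
    included <- included & frac < cnv_overlap_frac
  }
  if (!any(included)) stop_canroh("all windows were excluded by the filter")
  windows$depth <- depths
  windows$included <- included
  windows
}

#' Per-sample window ROH indicators
#'
#' Indicator is `TRUE` when the sample has at least 1 bp of ROH overlapping
#' the window.
#'
#' @param roh_sets Named list of per-sample segment data.frames.
#' @param windows Window grid from [make_windows()].
#' @return Logical matrix, windows x samples.
#' @export
window_indicators <- function(roh_sets, windows) {
  win_gr <- segments_to_granges(windows)
  ind <- vapply(roh_sets, function(segs) {
    IRanges::overlapsAny(win_gr, segments_to_granges(segs))
  }, logical(nrow(windows)))
  matrix(ind,
    nrow = nrow(windows),
    dimnames = list(NULL, names(roh_sets))
  )
}

#' Cohort ROH frequencies per window
#'
#' @param indicators Logical windows x samples matrix.
#' @param labels data.frame with `sample` and `group` columns; groups index
#'   into the indicator columns.
#' @return data.frame of per-window frequencies, one column per group.
#' @export
cohort_frequencies <- function(indicators, labels) {
  missing <- setdiff(labels$sample, colnames(indicators))
  if (length(missing) > 0) {
    stop_canroh("unknown sample label(s): ", paste(missing, collapse = ", "))
  }
  groups <- split(labels$sample, labels$group)
  out <- lapply(groups, function(s) {
    rowMeans(indicators[, s, drop = FALSE])
  })
  as.data.frame(out)
}

#' Find ROH deserts
#'
#' A desert is an included window where strictly less than `cutoff` of the
#' ancient and strictly less than `cutoff` of the modern samples carry an
#' ROH. Excluded windows are never deserts.
#'
#' @param windows Filtered window grid (with `included`).
#' @param freq_ancient,freq_modern Per-window cohort frequencies.
#' @param cutoff Frequency cutoff (default 0.05).
#' @return List: `deserts` (window indices), `n_deserts`, `n_included`,
#'   `fraction` (of included windows).
#' @export
find_deserts <- function(windows, freq_ancient, freq_modern, cutoff = 0.05) {
  if (is.null(windows$included)) {
    stop_canroh("windows must carry an `included` flag (run filter_windows)")
  }
  desert <- windows$included & freq_ancient < cutoff & freq_modern < cutoff
  list(
    deserts = windows$window[desert],
    n_deserts = sum(desert),
    n_included = sum(windows$included),
    fraction = sum(desert) / sum(windows$included)
  )
}

count_deserts <- function(counts_a, counts_b, n_a, n_b, cutoff) {
  sum(counts_a / n_a < cutoff & counts_b / n_b < cutoff)
}

#' Randomization test for ROH desert sharing
#'
#' Tests whether the observed number of shared desert windows exceeds what
#' is expected when ROH windows are randomly placed along the genome and
#' independently distributed among ancient and present-day samples. Each
#' permutation reassigns every sample's ROH-window indicators to a uniform
#' random subset of the included windows of the same size (preserving the
#' per-sample count, independently across samples and cohorts), then
#' recomputes the desert count. The one-sided p-value for an excess of
#' deserts uses the standard +1 correction:
#' p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' An alternative contiguity-preserving null (`null = "shift"`) circularly
#' rotates each sample's indicator vector over the included windows, for
#' sensitivity analysis.
#'
#' @param indicators_ancient,indicators_modern Logical windows x samples
#'   matrices (full grid; rows are subset by `included`).
#' @param included Logical vector over windows.
#' @param cutoff Desert frequency cutoff.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; fixed seed gives an identical p-value.
#' @param null "uniform" (independent random placement) or "shift"
#'   (circular rotation).
#' @return List of class `desert_test`: `observed`, `null_counts`,
#'   `p_value`, `n_perm`.
#' @export
desert_randomization_test <- function(indicators_ancient, indicators_modern,
                                      included, cutoff = 0.05,
                                      n_perm = 999L, seed = 1L,
                                      null = c("uniform", "shift")) {
  null <- match.arg(null)
  if (n_perm < 1L) stop_canroh("`n_perm` must be at least 1")
  ia <- indicators_ancient[included, , drop = FALSE]
  im <- indicators_modern[included, , drop = FALSE]
  n_inc <- nrow(ia)
  n_a <- ncol(ia)
  n_m <- ncol(im)
  k_a <- colSums(ia)
  k_m <- colSums(im)
  if (any(c(k_a, k_m) > n_inc)) {
    stop_canroh("per-sample ROH window count exceeds the included windows")
  }
  observed <- count_deserts(rowSums(ia), rowSums(im), n_a, n_m, cutoff)
  null_counts <- integer(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      ca <- integer(n_inc)
      cm <- integer(n_inc)
      if (null == "uniform") {
        for (j in seq_len(n_a)) {
          if (k_a[j] > 0) {
            idx <- sample.int(n_inc, k_a[j])
            ca[idx] <- ca[idx] + 1L
          }
        }
        for (j in seq_len(n_m)) {
          if (k_m[j] > 0) {
            idx <- sample.int(n_inc, k_m[j])
            cm[idx] <- cm[idx] + 1L
          }
        }
      } else {
        for (j in seq_len(n_a)) {
          r <- sample.int(n_inc, 1L) - 1L
          v <- ia[(seq_len(n_inc) - 1L + r) %% n_inc + 1L, j]
          ca <- ca + v
        }
        for (j in seq_len(n_m)) {
          r <- sample.int(n_inc, 1L) - 1L
          v <- im[(seq_len(n_inc) - 1L + r) %% n_inc + 1L, j]
          cm <- cm + v
        }
      }
      null_counts[b] <- count_deserts(ca, cm, n_a, n_m, cutoff)
    }
  })
  p <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  structure(
    list(
      observed = observed, null_counts = null_counts,
      p_value = p, n_perm = n_perm
    ),
    class = "desert_test"
  )
}

#' @export
print.desert_test <- function(x, ...) {
  cat(sprintf(
    "<desert_test> observed = %d deserts; null mean = %.1f; p = %.4g (%d permutations)\n",
    x$observed, mean(x$null_counts), x$p_value, x$n_perm
  ))
  invisible(x)
}
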