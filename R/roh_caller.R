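#' ROH scan parameters
#'
#' Parameters of the sliding-window homozygosity scan, following the
#' published defaults of the widely used PLINK `--homozyg` scan: 50-SNP
#' windows allowing 1 heterozygote and 5 missing calls, a 5% window-hit
#' threshold, and segment thresholds of 100 SNPs, 1 Mb minimum length,
#' 1 SNP per 50 kb density and a 1 Mb maximum gap. All values are
#' overridable; the algorithm, not the constants, is the contract.
#'
#' @param window_snp SNPs per sliding window.
#' @param window_het Maximum heterozygous calls for a window to be a hit.
#' @param window_missing Maximum missing calls for a window to be a hit.
#' @param hit_threshold Minimum fraction of hit windows covering a SNP for
#'   it to be homozygous-eligible, in (0, 1\].
#' @param min_snp Minimum SNPs per emitted segment.
#' @param min_kb Minimum segment length in bp.
#' @param min_density Maximum bp per SNP within a segment (1 SNP / 50 kb).
#' @param max_gap Maximum bp between consecutive SNPs within a segment.
#' @return Object of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50L, window_het = 1L,
                       window_missing = 5L, hit_threshold = 0.05,
                       min_snp = 100L, min_kb = 1e6,
                       min_density = 5e4, max_gap = 1e6) {
  for (nm in c("window_snp", "min_snp", "min_kb", "min_density", "max_gap")) {
    assert_pos(get(nm), nm)
  }
  if (window_het < 0 || window_missing < 0) {
    stop_canroh("window_het and window_missing must be non-negative")
  }
  if (hit_threshold <= 0 || hit_threshold > 1) {
    stop_canroh("`hit_threshold` must be in (0, 1]")
  }
  structure(
    list(
      window_snp = as.integer(window_snp),
      window_het = as.integer(window_het),
      window_missing = as.integer(window_missing),
      hit_threshold = hit_threshold,
      min_snp = as.integer(min_snp),
      min_kb = min_kb,
      min_density = min_density,
      max_gap = max_gap
    ),
    class = "roh_params"
  )
}

# Scan one chromosome; positions must be sorted 1-based bp.
scan_chromosome <- function(geno, pos, params) {
  n <- length(geno)
  W <- params$window_snp
  if (n < W) {
    return(empty_segments())
  }
  if (is.unsorted(pos, strictly = FALSE)) {
    stop_canroh("sites must be sorted by position within chromosome")
  }
  het <- as.integer(!is.na(geno) & geno == 1L)
  mis <- as.integer(is.na(geno))
  # rolling window counts via cumulative sums; window j covers SNPs
  # j .. j + W - 1, j = 1 .. n - W + 1
  ch <- cumsum(het)
  cm <- cumsum(mis)
  nw <- n - W + 1L
  j <- seq_len(nw)
  het_w <- ch[j + W - 1L] - c(0L, ch)[j]
  mis_w <- cm[j + W - 1L] - c(0L, cm)[j]
  hit <- as.integer(het_w <= params$window_het &
    mis_w <= params$window_missing)
  chit <- c(0L, cumsum(hit))
  i <- seq_len(n)
  lo <- pmax(1L, i - W + 1L)
  hi <- pmin(i, nw)
  n_cov <- hi - lo + 1L
  n_hit <- chit[hi + 1L] - chit[lo]
  eligible <- n_hit / n_cov >= params$hit_threshold
  if (!any(eligible)) {
    return(empty_segments())
  }
  # maximal runs of eligible SNPs, split where the bp gap exceeds max_gap
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    gaps <- diff(pos[idx])
    brk <- which(gaps > params$max_gap)
    piece_start <- c(1L, brk + 1L)
    piece_end <- c(brk, length(idx))
    for (pz in seq_along(piece_start)) {
      sub <- idx[piece_start[pz]:piece_end[pz]]
      n_snps <- length(sub)
      span <- pos[sub[n_snps]] - pos[sub[1]] + 1L
      if (n_snps >= params$min_snp &&
        span >= params$min_kb &&
        span / n_snps <= params$min_density) {
        segs[[length(segs) + 1L]] <- c(
          start = pos[sub[1]] - 1L, end = pos[sub[n_snps]], n_snps = n_snps
        )
      }
    }
  }
  if (length(segs) == 0L) {
    return(empty_segments())
  }
  m <- do.call(rbind, segs)
  data.frame(
    chrom = NA_character_, start = m[, "start"], end = m[, "end"],
    n_snps = as.integer(m[, "n_snps"]), stringsAsFactors = FALSE
  )
}

#' Call runs of homozygosity
#'
#' Sliding-window homozygosity scan in the style of PLINK `--homozyg`: a
#' window of `window_snp` consecutive SNPs is a "hit" when it contains at
#' most `window_het` heterozygous and `window_missing` missing calls; each
#' SNP's hit proportion is the fraction of hits among the windows covering
#' it; SNPs with proportion >= `hit_threshold` are homozygous-eligible; and
#' maximal runs of eligible SNPs are emitted as segments when they satisfy
#' the `min_snp`, `min_kb` and `min_density` thresholds, splitting runs at
#' inter-SNP gaps larger than `max_gap`. Segment coordinates run from the
#' first to the last SNP of the run (0-based half-open). Chromosomes are
#' scanned independently, so processing order cannot matter.
#'
#' @param geno Genotype vector (0/1/2/NA) aligned to `sites`.
#' @param sites Sites data.frame with `chrom` and `pos` (1-based), sorted
#'   by chromosome and position.
#' @param params A [roh_params()].
#' @return data.frame (chrom, start, end, n_snps), sorted, non-overlapping.
#' @export
call_roh <- function(geno, sites, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"), length(geno) == nrow(sites))
  out <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
    segs <- scan_chromosome(geno[idx], sites$pos[idx], params)
    if (nrow(segs) > 0) segs$chrom <- sites$chrom[idx[1]]
    segs
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) {
    return(empty_segments())
  }
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "n_snps")]
}

#' Genomic inbreeding coefficient from ROH
#'
#' \eqn{F_{ROH}} = total length of ROH segments in a length class divided by
#' the total autosome length. The class boundary follows the short/long
#' split at 1.6 Mb: short ROH (< 1.6 Mb) reflect older shared ancestry,
#' long ROH (>= 1.6 Mb) recent inbreeding. The denominator is the full
#' autosome length (configurable via `autosome_length`).
#'
#' @param roh Segment data.frame (chrom, start, end).
#' @param autosome_length Total autosome length in bp.
#' @param length_class One of "all", "short", "long".
#' @param long_threshold Boundary in bp (default 1.6 Mb); short is strictly
#'   below, long at or above.
#' @return Coefficient in \[0, 1\].
#' @export
froh <- function(roh, autosome_length, length_class = c("all", "short", "long"),
                 long_threshold = 1.6e6) {
  assert_pos(autosome_length, "autosome_length")
  length_class <- match.arg(length_class)
  if (nrow(roh) == 0L) {
    return(0)
  }
  len <- roh$end - roh$start
  keep <- switch(length_class,
    all = rep(TRUE, length(len)),
    short = len < long_threshold,
    long = len >= long_threshold
  )
  sum(len[keep]) / autosome_length
}

#' Summary statistics of an ROH segment set
#'
#' @param roh Segment data.frame.
#' @param autosome_length Optional total autosome length; when given, the
#'   sample is flagged highly inbred if F_ROH exceeds `inbred_threshold`.
#' @param inbred_threshold F_ROH flag threshold (default 0.1).
#' @return List: `n_segments`, `total_bp`, `max_bp`, and (when
#'   `autosome_length` is given) `froh` and `inbred`.
#' @export
summarize_roh <- function(roh, autosome_length = NULL,
                          inbred_threshold = 0.1) {
  len <- if (nrow(roh) > 0) roh$end - roh$start else numeric(0)
  out <- list(
    n_segments = nrow(roh),
    total_bp = sum(len),
    max_bp = if (length(len)) max(len) else 0
  )
  if (!is.null(autosome_length)) {
    out$froh <- froh(roh, autosome_length)
    out$inbred <- out$froh > inbred_threshold
  }
  out
}
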