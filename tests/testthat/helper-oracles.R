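# Independent brute-force oracles. These deliberately share no code with the
# package implementation: loops and boolean vectors instead of cumulative
# sums and interval trees.

# Naive reimplementation of the sliding-window homozygosity scan.
naive_roh_scan <- function(geno, pos, params) {
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    n_snps = integer(), stringsAsFactors = FALSE
  )
  n <- length(geno)
  W <- params$window_snp
  if (n < W) return(empty)
  nw <- n - W + 1
  hit <- logical(nw)
  for (j in seq_len(nw)) {
    win <- geno[j:(j + W - 1)]
    hit[j] <- sum(win == 1, na.rm = TRUE) <= params$window_het &&
      sum(is.na(win)) <= params$window_missing
  }
  elig <- logical(n)
  for (i in seq_len(n)) {
    js <- max(1, i - W + 1):min(i, nw)
    elig[i] <- mean(hit[js]) >= params$hit_threshold
  }
  segs <- list()
  cur <- integer(0)
  flush <- function(cur, segs) {
    if (length(cur) == 0) return(segs)
    span <- pos[cur[length(cur)]] - pos[cur[1]] + 1
    if (length(cur) >= params$min_snp && span >= params$min_kb &&
      span / length(cur) <= params$min_density) {
      segs[[length(segs) + 1]] <- cur
    }
    segs
  }
  for (i in seq_len(n)) {
    if (elig[i]) {
      if (length(cur) > 0 && pos[i] - pos[cur[length(cur)]] > params$max_gap) {
        segs <- flush(cur, segs)
        cur <- integer(0)
      }
      cur <- c(cur, i)
    } else {
      segs <- flush(cur, segs)
      cur <- integer(0)
    }
  }
  segs <- flush(cur, segs)
  if (length(segs) == 0) return(empty)
  do.call(rbind, lapply(segs, function(idx) {
    data.frame(
      chrom = NA_character_,
      start = pos[idx[1]] - 1,
      end = pos[idx[length(idx)]],
      n_snps = length(idx),
      stringsAsFactors = FALSE
    )
  }))
}

# Per-bp boolean recount of the interval confusion on a single toy
# chromosome of length L (segments 0-based half-open).
bp_confusion_oracle <- function(truth, test, assayable, L) {
  mark <- function(segs) {
    v <- logical(L)
    for (i in seq_len(nrow(segs))) {
      v[(segs$start[i] + 1):segs$end[i]] <- TRUE
    }
    v
  }
  t <- mark(truth)
  s <- mark(test)
  a <- mark(assayable)
  t <- t & a
  s <- s & a
  list(
    tp = sum(t & s), fp = sum(!t & s), fn = sum(t & !s),
    tn = sum(a & !t & !s)
  )
}

# Score formulas recomputed from scratch.
scores_oracle <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp)
  fp <- as.numeric(fp)
  fn <- as.numeric(fn)
  tn <- as.numeric(tn)
  c(
    f1 = 2 * tp / (2 * tp + fp + fn),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn)) / sqrt((tn + fp) * (tn + fn)),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    fdr = fp / (tp + fp)
  )
}

# Exhaustive enumeration of the desert-count null on the toy case:
# `n_windows` windows, each of `n_samples` samples (cohorts of equal size
# concatenated) carrying exactly one ROH window placed uniformly.
desert_null_enumeration <- function(n_windows, n_ancient, n_modern, cutoff) {
  n_samples <- n_ancient + n_modern
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_windows)), n_samples)))
  counts <- apply(grid, 1, function(placement) {
    ca <- tabulate(placement[seq_len(n_ancient)], n_windows)
    cm <- tabulate(placement[n_ancient + seq_len(n_modern)], n_windows)
    sum(ca / n_ancient < cutoff & cm / n_modern < cutoff)
  })
  counts
}

# Exact two-sided rank-sum p by enumeration of all group assignments
# (no ties assumed).
rank_sum_p_enumeration <- function(x, y) {
  n_x <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  combs <- utils::combn(n, n_x)
  W_null <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n_x * (n_x + 1) / 2
  })
  min(1, 2 * min(mean(W_null <= W_obs), mean(W_null >= W_obs)))
}

# Random sorted, non-overlapping segments on one chromosome of length L,
# built by alternating gaps and widths (base R only).
random_segments <- function(L, k, min_w, max_w, chrom = "chr1") {
  widths <- sample(min_w:max_w, k, replace = TRUE)
  slack <- L - sum(widths)
  stopifnot(slack > k)
  cuts <- sort(sample.int(slack, k))
  gaps <- diff(c(0, cuts))
  starts <- cumsum(gaps) + c(0, cumsum(widths))[seq_len(k)]
  data.frame(
    chrom = chrom, start = starts, end = starts + widths,
    n_snps = NA_integer_, stringsAsFactors = FALSE
  )
}

# Small genotype fixture builder: sorted sites on one chromosome.
toy_sites <- function(pos, maf = 0.2, chrom = "chr1") {
  n <- length(pos)
  data.frame(
    chrom = chrom, pos = as.integer(pos),
    ref = rep("A", n), alt = rep("C", n),
    maf = rep(maf, length.out = n),
    transversion = TRUE,
    stringsAsFactors = FALSE
  )
}
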