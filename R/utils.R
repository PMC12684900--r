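# Internal helpers shared across modules.

# One user-facing seed expands to per-operation substreams via a counter, so
# adding a sample or an operation never perturbs draws made by earlier ones.
# Result stays below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (abs(as.integer(seed)) %% 1000000L) * 2048L + (as.integer(stream) %% 2048L)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_canroh <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_canroh(sprintf("`%s` must be a probability in [0, 1]", name))
  }
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_canroh(sprintf("`%s` must be a positive number", name))
  }
}

# Convert a segment data.frame (chrom, start, end; 0-based half-open) to
# GRanges (1-based closed) for interval arithmetic.
segments_to_granges <- function(segments, seqlengths = NULL) {
  if (nrow(segments) == 0L) {
    return(GenomicRanges::GRanges(seqlengths = seqlengths))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start + 1L, end = segments$end)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

granges_to_segments <- function(gr) {
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

empty_segments <- function() {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    n_snps = integer(), stringsAsFactors = FALSE
  )
}
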