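test_that("window tiling truncates the last window and conserves length", {
  w <- make_windows(c(chrA = 1.2e6), width = 5e5)
  expect_equal(nrow(w), 3L)
  expect_equal(w$end[3] - w$start[3], 2e5)
  w1 <- make_windows(c(chrA = 5e5), width = 5e5)
  expect_equal(nrow(w1), 1L)
  cl <- c(chr1 = 3.7e6, chr2 = 1.1e6)
  wg <- make_windows(cl, width = 5e5)
  expect_equal(sum(wg$end - wg$start), sum(cl))
  # windows tile without overlap
  for (ch in names(cl)) {
    sub <- wg[wg$chrom == ch, ]
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])
  }
})

test_that("depth filter applies the mean +/- 2 SD rule and the CNV mask", {
  w <- make_windows(c(chr1 = 5e6), width = 5e5)
  depths <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 30)
  f <- filter_windows(w, depths)
  expect_identical(f$included, c(rep(TRUE, 9), FALSE))
  # hand check of the bounds: mean 3.9, sd ~9.17
  expect_equal(mean(depths), 3.9)
  expect_equal(sd(depths), sqrt(84.1), tolerance = 1e-9)
  # constant depths: everything kept
  f2 <- filter_windows(w, rep(5, 10))
  expect_true(all(f2$included))
  # CNV mask overrides depth
  mask <- data.frame(chrom = "chr1", start = 0, end = 4e5)
  f3 <- filter_windows(w, rep(5, 10), cnv_mask = mask)
  expect_false(f3$included[1]) # 80% overlap
  mask_small <- data.frame(chrom = "chr1", start = 0, end = 2e5)
  f4 <- filter_windows(w, rep(5, 10), cnv_mask = mask_small)
  expect_true(f4$included[1]) # 40% < 50% threshold
  expect_error(filter_windows(w, rep(5, 9)), "align")
  expect_error(
    filter_windows(w[1:2, ], c(1, 1e6), k_sd = 0.001),
    "excluded"
  )
})

test_that("spiked windows are flagged in nearly all replicates", {
  w <- make_windows(c(chr1 = 5e7), width = 5e5)
  mu <- 5
  flagged <- vapply(1:100, function(s) {
    depth <- withr::with_seed(s, rnorm(nrow(w), mu, 0.2 * mu))
    depth[c(10, 50)] <- 8 * mu
    f <- filter_windows(w, depth)
    all(!f$included[c(10, 50)])
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
})

test_that("window indicators use the >= 1 bp overlap rule", {
  w <- make_windows(c(chr1 = 2e6), width = 5e5)
  roh <- list(
    s1 = data.frame(chrom = "chr1", start = 5e5, end = 1e6, n_snps = 1L),
    s2 = data.frame(chrom = "chr1", start = 9e5, end = 1.1e6, n_snps = 1L),
    s3 = data.frame(chrom = "chr1", start = 0, end = 0, n_snps = 0L)[0, ]
  )
  ind <- window_indicators(roh, w)
  expect_identical(ind[, "s1"], c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(ind[, "s2"], c(FALSE, TRUE, TRUE, FALSE)) # boundary spanner
  expect_identical(ind[, "s3"], rep(FALSE, 4))
  labels <- data.frame(
    sample = c("s1", "s2", "s3"),
    group = c("ancient", "ancient", "modern")
  )
  fr <- cohort_frequencies(ind, labels)
  expect_equal(fr$ancient, c(0, 1, 0.5, 0))
  expect_equal(fr$modern, c(0, 0, 0, 0))
  bad <- data.frame(sample = "nope", group = "ancient")
  expect_error(cohort_frequencies(ind, bad), "unknown sample")
})

test_that("desert detection is strict and ignores excluded windows", {
  w <- make_windows(c(chr1 = 2e6), width = 5e5)
  w$included <- c(TRUE, TRUE, TRUE, FALSE)
  fa <- c(0.04, 0.05, 0.049, 0.0)
  fm <- c(0.049, 0.01, 0.01, 0.0)
  d <- find_deserts(w, fa, fm, cutoff = 0.05)
  expect_equal(d$deserts, c(1L, 3L)) # window 2 fails the strict <, 4 excluded
  expect_equal(d$n_included, 3L)
  expect_equal(d$fraction, 2 / 3)
  expect_error(find_deserts(w[, 1:4], fa, fm), "included")
})

test_that("randomization test is deterministic with the +1 p floor", {
  set.seed(5)
  n_win <- 50L
  ia <- matrix(runif(n_win * 6) < 0.3, n_win, 6,
    dimnames = list(NULL, paste0("a", 1:6))
  )
  im <- matrix(runif(n_win * 6) < 0.3, n_win, 6,
    dimnames = list(NULL, paste0("m", 1:6))
  )
  inc <- rep(TRUE, n_win)
  t1 <- desert_randomization_test(ia, im, inc, n_perm = 199L, seed = 9L)
  t2 <- desert_randomization_test(ia, im, inc, n_perm = 199L, seed = 9L)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$null_counts, t2$null_counts)
  # column order must not matter
  t3 <- desert_randomization_test(
    ia[, 6:1], im[, c(3, 1, 2, 6, 5, 4)], inc,
    n_perm = 199L, seed = 9L
  )
  expect_identical(t1$p_value, t3$p_value)
  # p floor: all samples pile onto one window, so the observed desert count
  # (9) exceeds every realistic null draw
  ia0 <- matrix(FALSE, 10, 5, dimnames = list(NULL, paste0("a", 1:5)))
  im0 <- matrix(FALSE, 10, 5, dimnames = list(NULL, paste0("m", 1:5)))
  ia0[1, ] <- TRUE
  im0[1, ] <- TRUE
  t4 <- desert_randomization_test(
    ia0, im0, rep(TRUE, 10),
    n_perm = 999L, seed = 1L
  )
  expect_equal(t4$observed, 9L)
  expect_equal(t4$p_value, 1 / 1000)
  expect_error(
    desert_randomization_test(ia, im, inc, n_perm = 0L),
    "n_perm"
  )
})

test_that("protected shared deserts are detected with high power", {
  cl <- c(chr1 = 50e6, chr2 = 50e6)
  sim <- simulate_cohorts(
    n_ancient = 20L, n_modern = 20L,
    froh_ancient = 0.08, froh_modern = 0.25,
    chrom_lengths = cl, desert_windows = c(10:24, 110:124),
    seed = 77L
  )
  ind <- window_indicators(sim$roh, sim$windows)
  anc <- sim$labels$sample[sim$labels$group == "ancient"]
  mod <- sim$labels$sample[sim$labels$group == "modern"]
  fr <- cohort_frequencies(ind, sim$labels)
  w <- sim$windows
  w$included <- rep(TRUE, nrow(w))
  d <- find_deserts(w, fr$ancient, fr$modern)
  expect_true(all(c(10:24, 110:124) %in% d$deserts))
  tst <- desert_randomization_test(
    ind[, anc], ind[, mod], w$included,
    n_perm = 999L, seed = 3L
  )
  expect_lt(tst$p_value, 0.01)
})

test_that("circular-shift null preserves per-sample counts", {
  set.seed(8)
  ia <- matrix(runif(40 * 4) < 0.25, 40, 4,
    dimnames = list(NULL, paste0("a", 1:4))
  )
  im <- matrix(runif(40 * 4) < 0.25, 40, 4,
    dimnames = list(NULL, paste0("m", 1:4))
  )
  t_shift <- desert_randomization_test(
    ia, im, rep(TRUE, 40),
    n_perm = 99L, seed = 2L, null = "shift"
  )
  expect_true(t_shift$p_value > 0 && t_shift$p_value <= 1)
  expect_length(t_shift$null_counts, 99L)
})
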