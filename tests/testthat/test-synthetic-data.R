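test_that("panel simulation is deterministic and respects its contracts", {
  cfg <- sim_config(n_sites = 1000L, n_ref = 20L, seed = 11L)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$sites), 1000L)
  expect_true(all(p1$sites$maf > 0 & p1$sites$maf <= 0.5))
  expect_true(all(p1$sites$ref != p1$sites$alt))
  # sorted by chromosome then position
  ord <- order(p1$sites$chrom, p1$sites$pos)
  expect_identical(ord, seq_len(nrow(p1$sites)))
  expect_true(all(p1$genotypes %in% 0:2))
})

test_that("transversion fraction matches the 2/3-transition sampler", {
  cfg <- sim_config(n_sites = 1e5L, n_ref = 2L, seed = 5L)
  panel <- simulate_panel(cfg)
  expect_lt(abs(mean(panel$sites$transversion) - 1 / 3), 0.01)
  # flags agree with the ref/alt pairs
  expect_identical(
    panel$sites$transversion,
    mapply(is_transversion, panel$sites$ref, panel$sites$alt,
      USE.NAMES = FALSE
    )
  )
})

test_that("truth individuals hit the target autozygous fraction", {
  cfg <- sim_config(
    n_chromosomes = 2L, chromosome_length = 50e6,
    n_sites = 20000L, n_ref = 2L, seed = 2L
  )
  panel <- simulate_panel(cfg)
  tr <- simulate_truth_individual(panel$sites, 0.14, seed = 3L)
  total <- sum(tr$truth_roh$end - tr$truth_roh$start)
  expect_lt(abs(total - 0.14 * 100e6), 1.4 * 14e6 / 14) # 14 Mb +/- 1.4 Mb
  # tracts sorted, non-overlapping, within bounds
  for (ch in unique(tr$truth_roh$chrom)) {
    seg <- tr$truth_roh[tr$truth_roh$chrom == ch, ]
    expect_true(all(diff(seg$start) > 0))
    expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
    expect_true(all(seg$start >= 0 & seg$end <= 50e6))
  }
  # zero heterozygous calls inside tracts
  in_tract <- rep(FALSE, nrow(panel$sites))
  for (i in seq_len(nrow(tr$truth_roh))) {
    in_tract <- in_tract | (
      panel$sites$chrom == tr$truth_roh$chrom[i] &
        panel$sites$pos - 1 >= tr$truth_roh$start[i] &
        panel$sites$pos - 1 < tr$truth_roh$end[i]
    )
  }
  expect_true(all(tr$genotypes[in_tract] != 1L))
})

test_that("f = 0 gives no tracts and panel-level heterozygosity", {
  cfg <- sim_config(n_sites = 50000L, n_ref = 2L, seed = 7L)
  panel <- simulate_panel(cfg)
  tr <- simulate_truth_individual(panel$sites, 0, seed = 1L)
  expect_equal(nrow(tr$truth_roh), 0L)
  expected_het <- mean(2 * panel$sites$maf * (1 - panel$sites$maf))
  expect_lt(abs(mean(tr$genotypes == 1L) - expected_het), 0.01)
  expect_error(simulate_truth_individual(panel$sites, 1), "\\[0, 1\\)")
})

test_that("imputed calls degrade with low coverage and rare alleles", {
  cfg <- sim_config(n_sites = 1e5L, n_ref = 2L, seed = 9L)
  panel <- simulate_panel(cfg)
  tr <- simulate_truth_individual(panel$sites, 0.1, seed = 4L)

  # zero error: calls identical to truth, all INFO = 1
  cfg0 <- cfg
  cfg0$error_base <- 0
  imp0 <- simulate_imputed_calls(tr, panel$sites, cfg0)
  expect_identical(imp0$gt[, 1], tr$genotypes)
  expect_true(all(imp0$info == 1))

  cfg_err <- cfg
  cfg_err$error_base <- 0.1
  cfg_err$coverage_scale <- 0.5
  cfg_err$rare_penalty <- 1
  cfg_hi <- cfg_err
  cfg_hi$coverage <- 2
  cfg_lo <- cfg_err
  cfg_lo$coverage <- 0.1
  imp_hi <- simulate_imputed_calls(tr, panel$sites, cfg_hi)
  imp_lo <- simulate_imputed_calls(tr, panel$sites, cfg_lo)
  err_hi <- mean(imp_hi$gt[, 1] != tr$genotypes)
  err_lo <- mean(imp_lo$gt[, 1] != tr$genotypes)
  expect_lt(err_hi, err_lo)

  # rare sites err more under the rare-allele penalty
  err_site <- imp_lo$gt[, 1] != tr$genotypes
  rare <- panel$sites$maf < 0.05
  expect_gt(mean(err_site[rare]), mean(err_site[!rare]))

  # GP rows sum to one, DS consistent
  sums <- imp_hi$gp[, 1, 1] + imp_hi$gp[, 1, 2] + imp_hi$gp[, 1, 3]
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(imp_hi$ds >= 0 & imp_hi$ds <= 2))
})

test_that("pseudohaploid sampling follows the two-step draw", {
  sites <- toy_sites(seq(1000, 1000 * 1e5, by = 1000))
  truth_het <- structure(
    list(genotypes = rep(1L, 1e5)),
    class = "truth_individual"
  )
  ps <- simulate_pseudohaploid(truth_het, coverage = 1, seed = 21L)
  calls <- ps$gt[, 1]
  p_obs <- (1 - exp(-1)) / 2
  expect_lt(abs(mean(is.na(calls)) - exp(-1)), 0.01)
  expect_lt(abs(mean(calls == 0, na.rm = TRUE) - 0.5), 0.01)
  expect_true(all(calls %in% c(0L, 2L, NA)))
  expect_lt(abs(mean(!is.na(calls) & calls == 0) - p_obs), 0.01)

  # low coverage: missing fraction ~ exp(-0.05)
  truth_hom <- structure(
    list(genotypes = rep(2L, 1e5)),
    class = "truth_individual"
  )
  ps2 <- simulate_pseudohaploid(truth_hom, coverage = 0.05, seed = 22L)
  expect_lt(abs(mean(is.na(ps2$gt)) - exp(-0.05)), 0.01)
  # effectively infinite coverage on a hom site reproduces the truth
  ps3 <- simulate_pseudohaploid(truth_hom, coverage = 50, seed = 23L)
  expect_true(all(ps3$gt == 2L))
})

test_that("cohort simulation respects deserts, targets and occupancy", {
  cl <- c(chr1 = 60e6, chr2 = 60e6)
  sim <- simulate_cohorts(
    n_ancient = 10L, n_modern = 10L,
    froh_ancient = 0.05, froh_modern = 0.3,
    chrom_lengths = cl, desert_windows = 5:15, seed = 31L
  )
  ind <- window_indicators(sim$roh, sim$windows)
  expect_true(all(!ind[5:15, ]))
  ft <- froh_table(sim$roh, sim$labels, sum(cl))
  expect_gt(
    mean(ft$froh_all[ft$group == "modern"]),
    mean(ft$froh_all[ft$group == "ancient"])
  )
  expect_error(
    simulate_cohorts(2, 2, 0.4, 0.4, cl,
      desert_windows = seq_len(200), seed = 1
    ),
    "desert windows"
  )
  expect_error(
    simulate_cohorts(2, 2, 0.1, 0.1, cl,
      hotspot_windows = 1:3, desert_windows = 3:5, seed = 1
    ),
    "disjoint"
  )
})

test_that("uniform tract placement matches closed-form window occupancy", {
  cl <- c(chr1 = 60e6, chr2 = 60e6)
  len <- 2e6
  froh <- 0.1
  sim <- simulate_cohorts(
    n_ancient = 100L, n_modern = 100L,
    froh_ancient = froh, froh_modern = froh,
    chrom_lengths = cl,
    tract_length_dist = function(n) rep(len, n),
    sd_log = 0,
    seed = 41L
  )
  w <- sim$windows
  ind <- window_indicators(sim$roh, w)
  # interior windows only (ends see truncated placement ranges)
  interior <- w$start > len & w$end < 60e6 - len
  m <- froh * sum(cl) / len # tracts per sample
  p_tract <- 0.5 * (5e5 + len) / (60e6 - len) # chrom pick x start range
  expected <- 1 - (1 - p_tract)^m
  expect_lt(abs(mean(ind[interior, ]) - expected), 0.02)
})

test_that("window depth simulation is deterministic with stated outliers", {
  d1 <- simulate_window_depths(500L, outlier_fraction = 0.05, seed = 3L)
  d2 <- simulate_window_depths(500L, outlier_fraction = 0.05, seed = 3L)
  expect_identical(d1, d2)
  expect_equal(sum(d1$outlier), 25L)
  expect_true(all(d1$depth[d1$outlier] >= 5 * 5))
  d0 <- simulate_window_depths(10000L, outlier_fraction = 0, seed = 4L)
  within <- abs(d0$depth - 5) <= 2 * 1
  expect_lt(abs(mean(within) - 0.954), 0.01)
})
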