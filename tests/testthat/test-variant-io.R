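test_that("transversion classification is exhaustive over ordered pairs", {
  nt <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = nt, alt = nt, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  flags <- mapply(is_transversion, pairs$ref, pairs$alt)
  expect_equal(sum(!flags), 4L) # A>G, G>A, C>T, T>C
  expect_equal(sum(flags), 8L)
  expect_false(is_transversion("C", "T"))
  expect_true(is_transversion("A", "C"))
  expect_error(is_transversion("N", "A"), "nucleotide")
  expect_error(is_transversion("A", "A"), "differ")
})

test_that("MAF binning is half-open with a closed right end", {
  expect_equal(as.integer(assign_maf_bin(0.005)), 1L)
  expect_equal(as.integer(assign_maf_bin(0.05)), 4L) # [0.05, 0.1)
  expect_equal(as.integer(assign_maf_bin(0.5)), 6L)
  expect_equal(as.integer(assign_maf_bin(0)), 1L)
  expect_error(assign_maf_bin(0.6), "\\[0, 0.5\\]")
  expect_error(assign_maf_bin(0.2, edges = c(0, 0.3, 0.2, 0.5)), "increase")
})

test_that("INFO score matches hand-evaluated cases and degenerate rules", {
  expect_equal(compute_info(rbind(c(0, 1, 0), c(0, 0, 1))), 1)
  expect_equal(
    compute_info(rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0))), 1 / 3
  )
  expect_equal(compute_info(rbind(c(1, 0, 0), c(1, 0, 0))), 1)
  expect_error(compute_info(rbind(c(0.5, 0.2, 0.2))), "sum to 1")
})

test_that("INFO decreases with posterior entropy (brute-force grid)", {
  # single polymorphic configuration, second sample increasingly uncertain
  infos <- vapply(seq(0, 0.5, by = 0.05), function(u) {
    compute_info(rbind(c(0, 0, 1), c(1 - u, u, 0)))
  }, numeric(1))
  expect_true(all(diff(infos) <= 1e-12))
  # one-hot call sets are fully informative
  expect_equal(compute_info(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))), 1)
  # vectorized array route agrees with the per-site formula
  set.seed(1)
  gp <- array(0, dim = c(20, 4, 3))
  for (i in 1:20) for (j in 1:4) {
    x <- runif(3)
    gp[i, j, ] <- x / sum(x)
  }
  by_site <- vapply(1:20, function(i) {
    compute_info(matrix(gp[i, , ], ncol = 3))
  }, numeric(1))
  expect_equal(canroh:::info_from_gp_array(gp), by_site, tolerance = 1e-12)
})

test_that("site filtering counts removals, is idempotent, and commutes", {
  sites <- toy_sites(seq(1e4, 1e6, length.out = 10))
  sites$maf <- rep(0.1, 10)
  sites$transversion <- rep(c(TRUE, FALSE), 5)
  info <- c(0.7, 0.7, 0.7, rep(0.95, 7))
  cs <- callset(sites, matrix(0L, 10, 1), samples = "s", info = info)
  f <- filter_sites(cs, info_min = 0.8)
  expect_equal(nrow(f$sites), 7L)
  expect_equal(attr(f, "removed")[["info"]], 3L)
  # identity filter
  f0 <- filter_sites(cs, 0, 0, FALSE)
  expect_equal(f0$sites, cs$sites)
  # idempotence and commutation
  f1 <- filter_sites(filter_sites(cs, info_min = 0.8), info_min = 0.8)
  expect_equal(f1$sites, f$sites)
  a <- filter_sites(filter_sites(cs, info_min = 0.8), transversions_only = TRUE)
  b <- filter_sites(filter_sites(cs, transversions_only = TRUE), info_min = 0.8)
  expect_equal(a$sites, b$sites)
})

test_that("transversions-only filtering keeps about a third of sites", {
  cfg <- sim_config(n_sites = 2e4L, n_ref = 4L, seed = 13L)
  panel <- simulate_panel(cfg)
  cs <- callset(panel$sites, matrix(0L, nrow(panel$sites), 1), samples = "s")
  f <- filter_sites(cs, transversions_only = TRUE)
  expect_lt(abs(nrow(f$sites) / nrow(cs$sites) - 1 / 3), 0.02)
})

test_that("VCF round trip preserves genotypes, posteriors and INFO", {
  cfg <- sim_config(n_sites = 100L, n_ref = 4L, seed = 17L, missing_base = 0.05)
  panel <- simulate_panel(cfg)
  truth <- list(
    a = simulate_truth_individual(panel$sites, 0.1, seed = 1L),
    b = simulate_truth_individual(panel$sites, 0, seed = 2L)
  )
  cs <- simulate_imputed_calls(truth, panel$sites, cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(cs, path)
  back <- read_vcf(path)
  expect_identical(unname(back$gt), unname(cs$gt))
  expect_equal(back$sites$pos, cs$sites$pos)
  expect_equal(back$sites$maf, cs$sites$maf, tolerance = 1e-5)
  expect_equal(back$info, cs$info, tolerance = 1e-5)
  expect_equal(back$gp, cs$gp, tolerance = 1e-3)
  # serialization reaches a fixed point after one read-write cycle (the
  # first cycle may renormalize 4-decimal GP rounding drift)
  path2 <- withr::local_tempfile(fileext = ".vcf")
  path3 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(back, path2)
  write_vcf(read_vcf(path2), path3)
  body <- function(p) grep("^[^#]", readLines(p), value = TRUE)
  expect_identical(body(path3), body(path2))
})

test_that("multiallelic and non-SNP records are skipped with a count", {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "s1",
      sep = "\t"
    ),
    "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/1",
    "chr1\t200\t.\tA\tC,G\t.\tPASS\t.\tGT\t0/1",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0",
    "chr1\t400\t.\tG\tT\t.\tPASS\t.\tGT\t./."
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  expect_warning(cs <- read_vcf(path), "skipped 2")
  expect_equal(attr(cs, "skipped"), 2L)
  expect_equal(nrow(cs$sites), 2L)
  expect_identical(unname(cs$gt[, 1]), c(1L, NA))
})

test_that("call set validation rejects inconsistent containers", {
  sites <- toy_sites(c(100, 200))
  expect_error(callset(sites, matrix(3L, 2, 1)), "0, 1, 2")
  gp <- array(c(0.5, 0.2, 0.5, 0.3, 0.5, 0.2), dim = c(2, 1, 3))
  expect_error(callset(sites, matrix(0L, 2, 1), gp = gp), "sum to 1")
  gp_ok <- array(c(0, 1, 1, 0, 0, 0), dim = c(2, 1, 3))
  expect_error(
    callset(sites, matrix(c(2L, 0L), 2, 1), gp = gp_ok),
    "argmax"
  )
  expect_error(
    callset(sites, matrix(0L, 2, 1), ds = matrix(c(2.5, 0), 2, 1)),
    "\\[0, 2\\]"
  )
})

test_that("recalibration recomputes INFO over a merged cohort", {
  cfg <- sim_config(n_sites = 200L, n_ref = 4L, seed = 19L, coverage = 0.5)
  panel <- simulate_panel(cfg)
  t1 <- simulate_truth_individual(panel$sites, 0, seed = 1L)
  t2 <- simulate_truth_individual(panel$sites, 0, seed = 2L)
  both <- simulate_imputed_calls(list(a = t1, b = t2), panel$sites, cfg)
  merged <- recalibrate_info(both)
  expect_equal(merged$info, both$info) # emitted INFO is already cohort-wide
  # recalibrating a subset changes the score where samples disagree
  solo <- both
  solo$gp <- both$gp[, 1, , drop = FALSE]
  solo$gt <- both$gt[, 1, drop = FALSE]
  solo$ds <- both$ds[, 1, drop = FALSE]
  solo$samples <- "a"
  solo <- recalibrate_info(solo)
  expect_false(isTRUE(all.equal(solo$info, both$info)))
})
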