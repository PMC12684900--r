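#' Simulation configuration
#'
#' Bundles the parameters of the synthetic benchmark: genome geometry, the
#' size of the emulated reference panel, the coverage of the downsampled
#' sample, and the imputation error model
#' \deqn{\varepsilon(c, p) = \varepsilon_0 \, e^{-c/c_0} \,
#'       (1 + \kappa \cdot 1[p < 0.05])}
#' where \eqn{c} is fold-coverage and \eqn{p} the panel minor allele
#' frequency. Low coverage and rare alleles both inflate the miscall rate,
#' emulating the behaviour of haplotype-based imputation of low-coverage
#' ancient genomes.
#'
#' @param n_chromosomes Number of autosomes to simulate.
#' @param chromosome_length Length of each chromosome in bp.
#' @param n_sites Total number of biallelic SNPs across the genome.
#' @param n_ref Number of diploid reference-panel individuals.
#' @param coverage Fold-coverage of the downsampled sample (dimensionless).
#'   The study's downsampling grid was 0.05, 0.1, 0.2, 0.5, 1 and 2 fold.
#' @param error_base Baseline miscall probability \eqn{\varepsilon_0}.
#' @param coverage_scale Coverage scale \eqn{c_0} of the exponential decay.
#' @param rare_penalty Multiplicative penalty \eqn{\kappa} for rare sites
#'   (panel MAF < 0.05).
#' @param missing_base Per-call missingness probability of the emulated
#'   imputation output.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chromosome_length = 50e6,
                       n_sites = 20000L,
                       n_ref = 100L,
                       coverage = 1,
                       error_base = 0.1,
                       coverage_scale = 0.5,
                       rare_penalty = 2,
                       missing_base = 0,
                       seed = 1L) {
  assert_pos(n_chromosomes, "n_chromosomes")
  assert_pos(chromosome_length, "chromosome_length")
  assert_pos(n_sites, "n_sites")
  assert_pos(n_ref, "n_ref")
  if (!is.numeric(coverage) || coverage < 0) {
    stop_canroh("`coverage` must be a non-negative fold-coverage")
  }
  assert_prob(error_base, "error_base")
  assert_pos(coverage_scale, "coverage_scale")
  if (!is.numeric(rare_penalty) || rare_penalty < 0) {
    stop_canroh("`rare_penalty` must be non-negative")
  }
  assert_prob(missing_base, "missing_base")
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      chromosome_length = as.numeric(chromosome_length),
      n_sites = as.integer(n_sites),
      n_ref = as.integer(n_ref),
      coverage = as.numeric(coverage),
      error_base = as.numeric(error_base),
      coverage_scale = as.numeric(coverage_scale),
      rare_penalty = as.numeric(rare_penalty),
      missing_base = as.numeric(missing_base),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate a reference panel
#'
#' Draws per-site minor allele frequencies from a folded Beta distribution
#' (default Beta(0.3, 0.7) folded to \eqn{\le 0.5}, giving a rare-allele-heavy
#' site-frequency spectrum), assigns ref/alt nucleotides so that roughly 2/3
#' of sites are transitions (matching genome-wide SNP composition), and draws
#' Hardy-Weinberg panel genotypes at those frequencies. The alternative
#' allele is the minor allele.
#'
#' @param config A [sim_config()].
#' @param maf_sampler Function of `n` returning minor allele frequencies in
#'   (0, 0.5].
#' @param transition_fraction Expected fraction of transition sites.
#' @return A list with `sites` (data.frame: chrom, pos (1-based), ref, alt,
#'   maf, transversion) carrying a `chrom_lengths` attribute, and `genotypes`
#'   (sites x n_ref matrix of alt-allele counts 0/1/2).
#' @export
simulate_panel <- function(config,
                           maf_sampler = function(n) {
                             x <- rbeta(n, 0.3, 0.7)
                             pmax(pmin(x, 1 - x), 1e-4)
                           },
                           transition_fraction = 2 / 3) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_sites < 2L || config$n_ref < 2L) {
    stop_canroh("panel needs at least 2 sites and 2 reference individuals")
  }
  chrom_lengths <- setNames(
    rep(config$chromosome_length, config$n_chromosomes),
    paste0("chr", seq_len(config$n_chromosomes))
  )
  with_seed(substream_seed(config$seed, 1L), {
    per_chrom <- table(factor(
      sample.int(config$n_chromosomes, config$n_sites, replace = TRUE),
      levels = seq_len(config$n_chromosomes)
    ))
    sites <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(k) {
      n_k <- as.integer(per_chrom[[k]])
      pos <- sort(sample.int(as.integer(config$chromosome_length), n_k))
      data.frame(
        chrom = names(chrom_lengths)[k], pos = pos,
        stringsAsFactors = FALSE
      )
    }))
    n <- nrow(sites)
    sites$ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    is_ts <- runif(n) < transition_fraction
    alt <- character(n)
    alt[is_ts] <- transition_partner[sites$ref[is_ts]]
    # transversion partners: the two bases of the other purine/pyrimidine class
    tv_alts <- list(
      A = c("C", "T"), G = c("C", "T"),
      C = c("A", "G"), T = c("A", "G")
    )
    if (any(!is_ts)) {
      pick <- 1L + (runif(sum(!is_ts)) < 0.5)
      alt[!is_ts] <- mapply(
        function(r, i) tv_alts[[r]][i],
        sites$ref[!is_ts], pick
      )
    }
    sites$alt <- alt
    sites$maf <- maf_sampler(n)
    if (any(sites$maf <= 0 | sites$maf > 0.5)) {
      stop_canroh("maf_sampler must return values in (0, 0.5]")
    }
    sites$transversion <- mapply(is_transversion, sites$ref, sites$alt,
      USE.NAMES = FALSE
    )
    geno <- matrix(
      rbinom(n * config$n_ref, 2L, rep(sites$maf, config$n_ref)),
      nrow = n, ncol = config$n_ref
    )
    attr(sites, "chrom_lengths") <- chrom_lengths
    list(sites = sites, genotypes = geno)
  })
}

#' Simulate a truth individual with planted autozygous tracts
#'
#' Places non-overlapping autozygous tracts uniformly along the genome until
#' a target fraction `f` of the genome is covered. Inside tracts one founder
#' haplotype is duplicated: the individual is homozygous, with the allele
#' drawn by panel frequency. Outside tracts genotypes are Hardy-Weinberg
#' draws from the panel MAF.
#'
#' @param site_table Sites data.frame from [simulate_panel()] (must carry the
#'   `chrom_lengths` attribute, or pass `chrom_lengths` explicitly).
#' @param f Target autozygous fraction of the genome, in \[0, 1).
#' @param tract_length_dist Function of `n` returning tract lengths in bp.
#'   Default: uniform on 1-5 Mb, comfortably above typical minimum-ROH-length
#'   calling thresholds.
#' @param seed Integer seed.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return List of class `truth_individual`: `genotypes` (0/1/2 per site),
#'   `truth_roh` (chrom/start/end/n_snps, 0-based half-open), `f_target`,
#'   and `f_realized`.
#' @export
simulate_truth_individual <- function(site_table, f,
                                      tract_length_dist = function(n) {
                                        runif(n, 1e6, 5e6)
                                      },
                                      seed = 1L,
                                      chrom_lengths = attr(site_table, "chrom_lengths")) {
  if (!is.numeric(f) || f < 0 || f >= 1) {
    stop_canroh("`f` must be in [0, 1)")
  }
  if (is.null(chrom_lengths)) {
    stop_canroh("chromosome lengths are required (attribute or argument)")
  }
  genome_len <- sum(chrom_lengths)
  target <- f * genome_len
  with_seed(seed, {
    tracts <- empty_segments()
    total <- 0
    tries <- 0L
    min_tract <- 1e6
    while (total < target && tries < 10000L) {
      tries <- tries + 1L
      len <- tract_length_dist(1L)
      remaining <- target - total
      # trim the last tract toward the target, but never below 1 Mb
      if (len > remaining) len <- max(remaining, min_tract)
      k <- sample.int(length(chrom_lengths), 1L,
        prob = chrom_lengths / genome_len
      )
      L <- chrom_lengths[[k]]
      if (len >= L) next
      start <- floor(runif(1, 0, L - len))
      end <- start + round(len)
      ch <- names(chrom_lengths)[k]
      same <- tracts[tracts$chrom == ch, , drop = FALSE]
      if (nrow(same) > 0 && any(same$start < end & start < same$end)) next
      tracts <- rbind(tracts, data.frame(
        chrom = ch, start = start, end = end, n_snps = NA_integer_,
        stringsAsFactors = FALSE
      ))
      total <- total + (end - start)
      # stop early if the residual shortfall is negligible
      if (target - total < min_tract / 2) break
    }
    tracts <- tracts[order(tracts$chrom, tracts$start), , drop = FALSE]
    rownames(tracts) <- NULL

    p <- site_table$maf
    n <- nrow(site_table)
    geno <- rbinom(n, 2L, p)
    in_tract <- rep(FALSE, n)
    for (i in seq_len(nrow(tracts))) {
      idx <- which(site_table$chrom == tracts$chrom[i] &
        site_table$pos - 1L >= tracts$start[i] &
        site_table$pos - 1L < tracts$end[i])
      in_tract[idx] <- TRUE
      tracts$n_snps[i] <- length(idx)
    }
    # founder haplotype duplicated: homozygous by allele frequency
    geno[in_tract] <- 2L * rbinom(sum(in_tract), 1L, p[in_tract])
    structure(
      list(
        genotypes = geno,
        truth_roh = tracts,
        f_target = f,
        f_realized = sum(tracts$end - tracts$start) / genome_len
      ),
      class = "truth_individual"
    )
  })
}

# Per-site miscall probability of the imputation-error model, capped at 0.5
# so the emitted posterior's argmax always equals the called genotype.
error_rate_model <- function(config, maf) {
  eps <- config$error_base * exp(-config$coverage / config$coverage_scale) *
    (1 + config$rare_penalty * (maf < 0.05))
  pmin(eps, 0.5)
}

#' Simulate imputation-like genotype calls
#'
#' Applies the coverage- and frequency-dependent miscall model
#' \eqn{\varepsilon(c, p)} to one or more truth individuals. A miscalled
#' genotype moves to an adjacent class (0 and 2 to 1; 1 to 0 or 2 with equal
#' probability). Each emitted call carries a posterior triple placing mass
#' \eqn{1 - \varepsilon} on the called class and the remainder on its
#' adjacent class(es), so noisier sites carry lower confidence; per-site
#' INFO scores are then computed from the emitted posteriors with
#' [compute_info()]. Dosage is `GP[1] + 2 GP[2]`.
#'
#' @param truth A `truth_individual` or a list of them (the samples).
#' @param site_table Sites data.frame congruent with the truth genotypes.
#' @param config A [sim_config()]; `coverage`, `error_base`,
#'   `coverage_scale`, `rare_penalty` and `missing_base` drive the model.
#' @param stream Substream counter offsetting the RNG stream (so call sets
#'   for different coverages under one seed are independent).
#' @return A [callset()] with genotypes, posteriors, dosages and INFO.
#' @export
simulate_imputed_calls <- function(truth, site_table, config, stream = 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(truth, "truth_individual")) truth <- list(sample1 = truth)
  n <- nrow(site_table)
  for (ind in truth) {
    if (length(ind$genotypes) != n) {
      stop_canroh("truth genotypes and site table are not congruent")
    }
  }
  n_samp <- length(truth)
  samples <- names(truth) %||% paste0("sample", seq_len(n_samp))
  eps <- error_rate_model(config, site_table$maf)
  with_seed(substream_seed(config$seed, stream), {
    gt <- matrix(NA_integer_, n, n_samp)
    gp <- array(NA_real_, dim = c(n, n_samp, 3))
    for (j in seq_len(n_samp)) {
      g <- truth[[j]]$genotypes
      err <- runif(n) < eps
      called <- g
      called[err & g == 0L] <- 1L
      called[err & g == 2L] <- 1L
      het_err <- err & g == 1L
      called[het_err] <- 2L * rbinom(sum(het_err), 1L, 0.5)
      conf <- 1 - eps
      gpj <- matrix(0, n, 3)
      gpj[cbind(seq_len(n), called + 1L)] <- conf
      # residual mass on the adjacent genotype class(es)
      res <- 1 - conf
      gpj[called == 0L, 2] <- gpj[called == 0L, 2] + res[called == 0L]
      gpj[called == 2L, 2] <- gpj[called == 2L, 2] + res[called == 2L]
      gpj[called == 1L, 1] <- gpj[called == 1L, 1] + res[called == 1L] / 2
      gpj[called == 1L, 3] <- gpj[called == 1L, 3] + res[called == 1L] / 2
      if (config$missing_base > 0) {
        miss <- runif(n) < config$missing_base
        called[miss] <- NA_integer_
        gpj[miss, ] <- NA_real_
      }
      gt[, j] <- called
      gp[, j, ] <- gpj
    }
    ds <- gp[, , 2, drop = FALSE][, , 1] + 2 * gp[, , 3, drop = FALSE][, , 1]
    ds <- matrix(ds, n, n_samp)
    info <- info_from_gp_array(gp)
    callset(site_table, gt,
      samples = samples, gp = gp, ds = ds, info = info
    )
  })
}

#' Simulate pseudohaploid calls
#'
#' Emulates the standard low-coverage ancient-DNA representation: at each
#' site the call is missing with probability \eqn{e^{-c}} (Poisson
#' probability of zero reads at fold-coverage \eqn{c}); otherwise a single
#' allele is drawn uniformly from the diploid truth genotype and reported as
#' a homozygous diploid code (0 or 2).
#'
#' @param truth A `truth_individual`.
#' @param coverage Fold-coverage, > 0.
#' @param seed Integer seed.
#' @param site_table Optional sites data.frame to attach to the result.
#' @return A [callset()] with genotypes in \{0, 2, NA\} and no posteriors.
#' @export
simulate_pseudohaploid <- function(truth, coverage, seed = 1L,
                                   site_table = NULL) {
  assert_pos(coverage, "coverage")
  g <- truth$genotypes
  n <- length(g)
  with_seed(seed, {
    miss <- runif(n) < exp(-coverage)
    allele <- integer(n)
    hom <- g != 1L
    allele[hom] <- g[hom] / 2L
    allele[!hom] <- rbinom(sum(!hom), 1L, 0.5)
    call <- 2L * allele
    call[miss] <- NA_integer_
    if (is.null(site_table)) {
      structure(list(gt = matrix(call, ncol = 1)), class = "pseudohaploid")
    } else {
      callset(site_table, matrix(call, ncol = 1), samples = "pseudohaploid")
    }
  })
}

#' Simulate two cohorts of ROH segment sets
#'
#' Builds per-sample ROH segment sets for an "ancient" and a "modern" cohort
#' with differing inbreeding targets, shared hotspot windows (boosted
#' placement odds) and protected desert windows (zero placement odds).
#' Tracts are placed uniformly (rejection sampling against overlaps and
#' deserts) until each sample's total length reaches its group F_ROH target.
#'
#' @param n_ancient,n_modern Cohort sizes.
#' @param froh_ancient,froh_modern Group-level target genome fractions.
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param hotspot_windows,desert_windows Disjoint integer indices into the
#'   window grid implied by `window_width`.
#' @param window_width Width of the landscape windows the hotspot/desert
#'   indices refer to (default 500 kb).
#' @param hotspot_boost Acceptance odds multiplier inside hotspots.
#' @param tract_length_dist Function of `n` returning tract lengths (bp).
#' @param sd_log Log-normal spread of per-sample F_ROH targets around the
#'   group value (0 = every sample at exactly the group target). Real
#'   cohorts vary around their group mean; the default 0.3 gives roughly
#'   +/- 35% sample-to-sample variation.
#' @param seed Integer seed.
#' @return List with `roh` (named list of segment data.frames), `labels`
#'   (data.frame sample/group) and `windows` (the window grid used).
#' @export
simulate_cohorts <- function(n_ancient, n_modern,
                             froh_ancient, froh_modern,
                             chrom_lengths,
                             hotspot_windows = integer(),
                             desert_windows = integer(),
                             window_width = 5e5,
                             hotspot_boost = 5,
                             tract_length_dist = function(n) runif(n, 1e6, 3e6),
                             sd_log = 0.3,
                             seed = 1L) {
  if (length(intersect(hotspot_windows, desert_windows)) > 0L) {
    stop_canroh("hotspot and desert windows must be disjoint")
  }
  assert_prob(froh_ancient, "froh_ancient")
  assert_prob(froh_modern, "froh_modern")
  windows <- make_windows(chrom_lengths, window_width)
  genome_len <- sum(chrom_lengths)
  desert_len <- sum(windows$end[desert_windows] - windows$start[desert_windows])
  max_target <- max(froh_ancient, froh_modern) * genome_len
  if (genome_len - desert_len < 2.5 * max_target) {
    stop_canroh("desert windows cover too much of the genome for the F_ROH targets")
  }
  desert_by_chrom <- split(
    windows[desert_windows, , drop = FALSE],
    windows$chrom[desert_windows]
  )
  hot_by_chrom <- split(
    windows[hotspot_windows, , drop = FALSE],
    windows$chrom[hotspot_windows]
  )
  place_sample <- function(target) {
    tracts <- empty_segments()
    total <- 0
    tries <- 0L
    while (total < target && tries < 20000L) {
      tries <- tries + 1L
      len <- tract_length_dist(1L)
      if (len > target - total) len <- max(target - total, 1e6)
      k <- sample.int(length(chrom_lengths), 1L,
        prob = chrom_lengths / genome_len
      )
      L <- chrom_lengths[[k]]
      if (len >= L) next
      ch <- names(chrom_lengths)[k]
      start <- floor(runif(1, 0, L - len))
      end <- start + round(len)
      des <- desert_by_chrom[[ch]]
      if (!is.null(des) && nrow(des) > 0 &&
        any(des$start < end & start < des$end)) {
        next
      }
      same <- tracts[tracts$chrom == ch, , drop = FALSE]
      if (nrow(same) > 0 && any(same$start < end & start < same$end)) next
      hot <- hot_by_chrom[[ch]]
      in_hot <- !is.null(hot) && nrow(hot) > 0 &&
        any(hot$start < end & start < hot$end)
      # boosted odds inside hotspots: accept non-hotspot placements with
      # probability 1 / hotspot_boost
      if (!in_hot && length(hotspot_windows) > 0 &&
        runif(1) > 1 / hotspot_boost) {
        next
      }
      tracts <- rbind(tracts, data.frame(
        chrom = ch, start = start, end = end, n_snps = NA_integer_,
        stringsAsFactors = FALSE
      ))
      total <- total + (end - start)
      if (target - total < 5e5) break
    }
    tracts[order(tracts$chrom, tracts$start), , drop = FALSE]
  }
  with_seed(seed, {
    samples <- c(
      paste0("ancient", seq_len(n_ancient)),
      paste0("modern", seq_len(n_modern))
    )
    groups <- rep(c("ancient", "modern"), c(n_ancient, n_modern))
    targets <- rep(
      c(froh_ancient, froh_modern) * genome_len,
      c(n_ancient, n_modern)
    )
    if (sd_log > 0) {
      # cap the spread so the desert-feasibility guard stays valid
      targets <- targets * pmin(pmax(exp(rnorm(
        length(targets), -sd_log^2 / 2, sd_log
      )), 0.4), 2)
    }
    roh <- lapply(targets, place_sample)
    names(roh) <- samples
    list(
      roh = roh,
      labels = data.frame(
        sample = samples, group = groups,
        stringsAsFactors = FALSE
      ),
      windows = windows
    )
  })
}

#' Simulate per-window sequencing depths with outliers
#'
#' Baseline depths are Normal(mean_depth, sd_depth); a stated fraction of
#' windows is replaced by 5-10 fold spikes, emulating collapsed repeats and
#' copy-number-variable regions that the windowed depth filter must catch.
#'
#' @param n_windows Number of windows.
#' @param mean_depth,sd_depth Baseline depth model.
#' @param outlier_fraction Fraction of windows spiked, in \[0, 0.5).
#' @param seed Integer seed.
#' @return List with `depth` (numeric) and `outlier` (logical) vectors.
#' @export
simulate_window_depths <- function(n_windows, mean_depth = 5,
                                   sd_depth = 1, outlier_fraction = 0.02,
                                   seed = 1L) {
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    stop_canroh("`outlier_fraction` must be in [0, 0.5)")
  }
  with_seed(seed, {
    depth <- rnorm(n_windows, mean_depth, sd_depth)
    outlier <- rep(FALSE, n_windows)
    n_out <- floor(outlier_fraction * n_windows)
    if (n_out > 0) {
      idx <- sample.int(n_windows, n_out)
      depth[idx] <- runif(n_out, 5, 10) * mean_depth
      outlier[idx] <- TRUE
    }
    list(depth = depth, outlier = outlier)
  })
}
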