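#' Configuration for the end-to-end benchmark run
#'
#' @param coverages Coverage grid; default is the study's downsampling grid
#'   0.05, 0.1, 0.2, 0.5, 1, 2 fold.
#' @param info_cutoffs INFO cutoffs applied in the concordance report
#'   (`NA` = none).
#' @param f Planted autozygosity fraction of the benchmark individual.
#' @param n_cohort Number of co-imputed individuals; per-site INFO is
#'   computed over the whole cohort's posteriors (a per-sample INFO is
#'   degenerate, just as single-sample imputation INFO would be).
#' @param seed Master seed.
#' @param ... Overrides passed to [sim_config()] (genome geometry, error
#'   model).
#' @return List of class `benchmark_config`.
#' @export
benchmark_config <- function(coverages = c(0.05, 0.1, 0.2, 0.5, 1, 2),
                             info_cutoffs = c(NA, 0.8, 0.9, 0.95),
                             f = 0.15, n_cohort = 8L, seed = 1L, ...) {
  base <- sim_config(seed = seed, ...)
  structure(
    list(
      base = base, coverages = coverages, info_cutoffs = info_cutoffs,
      f = f, n_cohort = as.integer(n_cohort), seed = as.integer(seed)
    ),
    class = "benchmark_config"
  )
}

config_hash <- function(config) rlang::hash(config)

#' Run the simulated imputation benchmark
#'
#' End-to-end: simulate a panel and a truth individual with planted
#' autozygous tracts; for each coverage on the grid simulate imputed-like
#' and pseudohaploid call sets; score imputation concordance (binned r2,
#' error rates, NRD per INFO cutoff), call ROH on the imputed genotypes and
#' benchmark them against the truth tracts (bp basis), and compare PCA
#' placement of the imputed vs the pseudohaploid version against the truth.
#' Deterministic under a fixed seed; the config hash and seed are recorded
#' in the summary.
#'
#' @param config A [benchmark_config()].
#' @param out_dir Optional directory; when given, per-table TSVs and a JSON
#'   summary are written.
#' @param roh_pars A [roh_params()] used for ROH calling.
#' @param pca_K Number of PCs for the distance metric.
#' @return List with elements `concordance`, `r2`, `roh`, `pca`,
#'   `manifest` (invisible tables are also written if `out_dir` is set).
#' @export
run_benchmark <- function(config = benchmark_config(), out_dir = NULL,
                          roh_pars = roh_params(
                            window_snp = 50, min_snp = 50, min_kb = 5e5
                          ),
                          pca_K = 10L) {
  stopifnot(inherits(config, "benchmark_config"))
  panel <- simulate_panel(config$base)
  chrom_lengths <- attr(panel$sites, "chrom_lengths")
  genome_len <- sum(chrom_lengths)
  # sample 1 is the evaluation target; the rest make the co-imputed cohort
  # over which per-site INFO is computed
  cohort <- lapply(seq_len(config$n_cohort), function(i) {
    simulate_truth_individual(
      panel$sites, if (i == 1L) config$f else 0,
      seed = substream_seed(config$seed, 10L + i)
    )
  })
  names(cohort) <- paste0("sample", seq_along(cohort))
  truth <- cohort[[1L]]
  model <- fit_pca(t(panel$genotypes), K = pca_K)
  truth_scores <- project_pca(truth$genotypes, model)

  conc_rows <- list()
  r2_rows <- list()
  roh_rows <- list()
  pca_rows <- list()
  for (ci in seq_along(config$coverages)) {
    cov <- config$coverages[ci]
    cfg <- config$base
    cfg$coverage <- cov
    imputed <- simulate_imputed_calls(
      cohort, panel$sites, cfg,
      stream = 20L + ci
    )
    pseudo <- simulate_pseudohaploid(
      truth, cov,
      seed = substream_seed(config$seed, 40L + ci)
    )
    rep <- concordance_report(
      truth$genotypes, imputed$gt[, 1], imputed$ds[, 1],
      maf = panel$sites$maf, info = imputed$info,
      info_cutoffs = config$info_cutoffs
    )
    rep$summary$coverage <- cov
    rep$r2$coverage <- cov
    conc_rows[[ci]] <- rep$summary
    r2_rows[[ci]] <- rep$r2

    called <- call_roh(imputed$gt[, 1], panel$sites, roh_pars)
    assayable <- data.frame(
      chrom = names(chrom_lengths), start = 0,
      end = as.numeric(chrom_lengths), stringsAsFactors = FALSE
    )
    conf <- interval_confusion_bp(truth$truth_roh, called, assayable)
    sc <- overlap_scores(conf)
    roh_rows[[ci]] <- data.frame(
      coverage = cov,
      froh_true = froh(truth$truth_roh, genome_len),
      froh_called = froh(called, genome_len),
      n_segments = nrow(called),
      t(sc)
    )

    imp_scores <- project_pca(imputed$gt[, 1], model)
    ps_gt <- pseudo$gt[, 1]
    pca_rows[[ci]] <- tryCatch(
      {
        ps_scores <- project_pca(ps_gt, model)
        data.frame(
          coverage = cov,
          d_imputed = weighted_pc_distance(
            imp_scores, truth_scores, model$eigenvalues, pca_K
          ),
          d_pseudohaploid = weighted_pc_distance(
            ps_scores, truth_scores, model$eigenvalues, pca_K
          )
        )
      },
      error = function(e) {
        data.frame(coverage = cov, d_imputed = NA_real_,
          d_pseudohaploid = NA_real_)
      }
    )
  }
  out <- list(
    concordance = do.call(rbind, conc_rows),
    r2 = do.call(rbind, r2_rows),
    roh = do.call(rbind, roh_rows),
    pca = do.call(rbind, pca_rows),
    manifest = list(
      seed = config$seed,
      config_hash = config_hash(config),
      n_sites = config$base$n_sites,
      coverages = config$coverages
    )
  )
  if (!is.null(out_dir)) write_bundle(out, out_dir)
  out
}

#' Configuration for the ROH landscape run
#'
#' @param n_ancient,n_modern Cohort sizes.
#' @param froh_ancient,froh_modern Group F_ROH targets.
#' @param chrom_lengths Named chromosome lengths.
#' @param window_width Landscape window width in bp (default 500 kb).
#' @param desert_windows,hotspot_windows Designated window indices.
#' @param cutoff Desert frequency cutoff.
#' @param n_perm Permutations for the randomization test.
#' @param outlier_fraction Fraction of depth-spiked windows.
#' @param seed Master seed.
#' @return List of class `landscape_config`.
#' @export
landscape_config <- function(n_ancient = 20L, n_modern = 20L,
                             froh_ancient = 0.05, froh_modern = 0.3,
                             chrom_lengths = c(chr1 = 60e6, chr2 = 60e6),
                             window_width = 5e5,
                             desert_windows = integer(),
                             hotspot_windows = integer(),
                             cutoff = 0.05, n_perm = 999L,
                             outlier_fraction = 0.02, seed = 1L) {
  structure(
    as.list(environment()),
    class = "landscape_config"
  )
}

#' Run the simulated ROH landscape analysis
#'
#' End-to-end: simulate ancient/modern cohorts of ROH segment sets with
#' shared hotspots and protected deserts, window the genome, filter windows
#' on simulated depths (mean +/- 2 SD) , compute per-window cohort ROH
#' frequencies, detect deserts (< cutoff in both cohorts), run the
#' randomization significance test, and compare cohort F_ROH with the
#' rank-sum test.
#'
#' @param config A [landscape_config()].
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return List: `windows` (with freqs/flags), `deserts`, `test`
#'   (`desert_test`), `froh` (per-sample table), `comparison`, `manifest`.
#' @export
run_landscape <- function(config = landscape_config(), out_dir = NULL) {
  stopifnot(inherits(config, "landscape_config"))
  sim <- simulate_cohorts(
    config$n_ancient, config$n_modern,
    config$froh_ancient, config$froh_modern,
    config$chrom_lengths,
    hotspot_windows = config$hotspot_windows,
    desert_windows = config$desert_windows,
    window_width = config$window_width,
    seed = substream_seed(config$seed, 1L)
  )
  windows <- sim$windows
  depths <- simulate_window_depths(
    nrow(windows),
    outlier_fraction = config$outlier_fraction,
    seed = substream_seed(config$seed, 2L)
  )
  windows <- filter_windows(windows, depths$depth)
  ind <- window_indicators(sim$roh, windows)
  freqs <- cohort_frequencies(ind, sim$labels)
  windows$freq_ancient <- freqs$ancient
  windows$freq_modern <- freqs$modern
  deserts <- find_deserts(
    windows, windows$freq_ancient, windows$freq_modern, config$cutoff
  )
  anc <- sim$labels$sample[sim$labels$group == "ancient"]
  mod <- sim$labels$sample[sim$labels$group == "modern"]
  test <- desert_randomization_test(
    ind[, anc, drop = FALSE], ind[, mod, drop = FALSE],
    windows$included,
    cutoff = config$cutoff, n_perm = config$n_perm,
    seed = substream_seed(config$seed, 3L)
  )
  ft <- froh_table(sim$roh, sim$labels, sum(config$chrom_lengths))
  comparison <- compare_groups(ft, list(c("ancient", "modern")))
  out <- list(
    windows = windows, deserts = deserts, test = test,
    froh = ft, comparison = comparison,
    manifest = list(
      seed = config$seed,
      config_hash = config_hash(config)
    )
  )
  if (!is.null(out_dir)) write_bundle(out, out_dir)
  out
}

# Serialize a result bundle: data.frames as TSV, the rest as one JSON
# summary (scalar-unboxed so reruns are byte-comparable).
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle)) {
    if (is.data.frame(bundle[[nm]])) {
      write.table(
        bundle[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
    }
  }
  summary <- bundle[!vapply(bundle, is.data.frame, logical(1))]
  summary$test <- if (!is.null(summary$test)) {
    list(
      observed = summary$test$observed,
      p_value = summary$test$p_value,
      n_perm = summary$test$n_perm
    )
  }
  jsonlite::write_json(
    summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out_dir)
}
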