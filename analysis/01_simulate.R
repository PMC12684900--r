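#!/usr/bin/env Rscript

# Step 1 — Simulate the benchmark inputs and export them in standard formats.
#
# Builds a synthetic reference panel (per-site allele frequencies and
# Hardy-Weinberg panel genotypes), a truth individual with planted
# autozygous tracts, an imputation-like call set at 0.5x coverage, and a
# pseudohaploid call set, then writes VCF/BED/TSV artifacts so any later
# stage could be rerun on externally produced files.

suppressMessages(library(canroh))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_chromosomes = 2L, chromosome_length = 50e6, n_sites = 20000L,
  n_ref = 60L, coverage = 0.5, error_base = 0.1, coverage_scale = 0.5,
  rare_penalty = 2, seed = 1L
)
panel <- simulate_panel(cfg)
message(sprintf(
  "panel: %d sites on %d chromosomes, %d reference individuals, %.1f%% transversions",
  nrow(panel$sites), cfg$n_chromosomes, cfg$n_ref,
  100 * mean(panel$sites$transversion)
))

truth <- simulate_truth_individual(panel$sites, f = 0.15, seed = 2L)
message(sprintf(
  "truth individual: %d planted tracts, realized autozygosity %.3f (target 0.15)",
  nrow(truth$truth_roh), truth$f_realized
))

cohort <- c(list(target = truth), lapply(1:7, function(i) {
  simulate_truth_individual(panel$sites, 0, seed = 10L + i)
}))
names(cohort)[-1] <- paste0("ref", 1:7)
imputed <- simulate_imputed_calls(cohort, panel$sites, cfg)
pseudo <- simulate_pseudohaploid(truth, cfg$coverage,
  seed = 3L, site_table = panel$sites
)
message(sprintf(
  "imputed cohort at %.1fx: target genotype error %.3f, median INFO %.2f; pseudohaploid missingness %.2f",
  cfg$coverage, mean(imputed$gt[, 1] != truth$genotypes),
  median(imputed$info), mean(is.na(pseudo$gt))
))

write_vcf(imputed, file.path(out, "imputed_0.5x.vcf.gz"))
write_vcf(pseudo, file.path(out, "pseudohaploid_0.5x.vcf.gz"))
write.table(
  truth$truth_roh[, c("chrom", "start", "end")],
  file.path(out, "truth_roh.bed"),
  sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
)
write.table(
  panel$sites, file.path(out, "panel_sites.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
message("wrote imputed/pseudohaploid VCF, truth ROH BED and site TSV to ", out)
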