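#' Genotype confusion matrix between truth and imputed calls
#'
#' Tallies a 3 x 3 matrix of truth genotype class (rows: hom-ref 0, het 1,
#' hom-alt 2) against imputed class (columns) over sites non-missing in
#' both; sites missing in either vector are counted in attribute
#' `n_missing`. Sites missing in the truth are excluded rather than counted
#' as errors, since the truth represents highly confident calls only.
#'
#' @param truth,imputed Integer genotype vectors (0/1/2/NA), same length.
#' @param site_mask Optional logical vector restricting the comparison.
#' @return 3 x 3 matrix of class `genotype_confusion` with attribute
#'   `n_missing`.
#' @export
genotype_confusion <- function(truth, imputed, site_mask = NULL) {
  if (length(truth) != length(imputed)) {
    stop_canroh("truth and imputed vectors differ in length")
  }
  if (!is.null(site_mask)) {
    truth <- truth[site_mask]
    imputed <- imputed[site_mask]
  }
  ok <- !is.na(truth) & !is.na(imputed)
  m <- table(
    factor(truth[ok], levels = 0:2),
    factor(imputed[ok], levels = 0:2)
  )
  m <- matrix(as.integer(m), 3, 3,
    dimnames = list(truth = 0:2, imputed = 0:2)
  )
  structure(m, class = c("genotype_confusion", "matrix"),
    n_missing = sum(!ok)
  )
}

#' Per-genotype-class error rates
#'
#' For each truth class t, the fraction of its sites imputed as a different
#' class: \eqn{e_t = \sum_{i \ne t} n_{ti} / \sum_i n_{ti}}. A class with no
#' sites yields `NA` (undefined), never 0.
#'
#' @param confusion A [genotype_confusion()] matrix.
#' @return Named numeric vector `(error_homref, error_het, error_homalt)`.
#' @export
error_rates <- function(confusion) {
  totals <- rowSums(confusion)
  err <- (totals - diag(confusion)) / totals
  err[totals == 0] <- NA_real_
  setNames(as.numeric(err), c("error_homref", "error_het", "error_homalt"))
}

#' Non-reference discordance (NRD)
#'
#' Error rate that drops concordant homozygous-reference sites from the
#' denominator, weighting the alternative-allele calls that matter for
#' downstream inference:
#' \deqn{NRD = \frac{e_0 + e_1 + e_2}{e_0 + e_1 + e_2 + m_1 + m_2}}
#' where \eqn{e_t} are the off-diagonal (discordant) counts of truth class t
#' and \eqn{m_1, m_2} the concordant het and hom-alt counts. Adding any
#' number of concordant hom-ref sites leaves NRD unchanged.
#'
#' @param confusion A [genotype_confusion()] matrix.
#' @return NRD rate in \[0, 1\], or `NA` when undefined.
#' @export
nrd <- function(confusion) {
  errors <- sum(confusion) - sum(diag(confusion))
  matches <- confusion[2, 2] + confusion[3, 3]
  denom <- errors + matches
  if (denom == 0) {
    return(NA_real_)
  }
  errors / denom
}

#' MAF-binned squared correlation under INFO cutoffs
#'
#' The core imputation-accuracy statistic: squared Pearson correlation
#' between truth genotype codes and imputed dosages (falling back to hard
#' genotype codes when dosages are absent), computed per MAF bin after
#' applying each INFO-score cutoff. A bin with fewer than two comparable
#' sites, or zero variance in either vector, is reported as `NA`
#' (undefined), never silently 0.
#'
#' @param truth Truth genotype vector (0/1/2/NA).
#' @param dosage Imputed dosage (or genotype-code) vector.
#' @param maf Panel minor allele frequencies per site.
#' @param info Per-site INFO scores (may be `NULL` if no cutoffs > 0 used).
#' @param edges MAF bin edges (see [assign_maf_bin()]).
#' @param info_cutoffs Numeric cutoffs; `NA` means "no cutoff". Default
#'   none, 0.8, 0.9, 0.95.
#' @param transversion Optional logical per-site flag.
#' @param transversions_only Restrict to transversion sites.
#' @return data.frame with columns `bin`, `bin_label`, `info_cutoff`
#'   (`NA` = none), `r2`, `n_sites`.
#' @export
r2_by_bin <- function(truth, dosage, maf, info = NULL,
                      edges = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5),
                      info_cutoffs = c(NA, 0.8, 0.9, 0.95),
                      transversion = NULL, transversions_only = FALSE) {
  bins <- assign_maf_bin(maf, edges)
  labels <- attr(bins, "labels")
  base_ok <- !is.na(truth) & !is.na(dosage)
  if (transversions_only) {
    if (is.null(transversion)) {
      stop_canroh("transversion flags required for transversions_only")
    }
    base_ok <- base_ok & transversion
  }
  out <- expand.grid(
    bin = seq_along(labels), info_cutoff = info_cutoffs,
    KEEP.OUT.ATTRS = FALSE
  )
  out$bin_label <- labels[out$bin]
  out$r2 <- NA_real_
  out$n_sites <- 0L
  for (r in seq_len(nrow(out))) {
    ok <- base_ok & bins == out$bin[r]
    cut <- out$info_cutoff[r]
    if (!is.na(cut)) {
      if (is.null(info)) stop_canroh("INFO scores required for a cutoff")
      ok <- ok & !is.na(info) & info >= cut
    }
    out$n_sites[r] <- sum(ok)
    if (sum(ok) >= 2) {
      x <- truth[ok]
      y <- dosage[ok]
      if (sd(x) > 0 && sd(y) > 0) out$r2[r] <- cor(x, y)^2
    }
  }
  out[, c("bin", "bin_label", "info_cutoff", "r2", "n_sites")]
}

#' Full concordance report for one sample
#'
#' Combines [r2_by_bin()], [error_rates()] and [nrd()] under each INFO
#' cutoff (error rates and NRD are computed over all MAF bins jointly,
#' mirroring how they are reported alongside the binned r2 curves).
#'
#' @inheritParams r2_by_bin
#' @param imputed_gt Imputed hard genotype vector (for the confusion-based
#'   statistics).
#' @return List with `r2` (binned data.frame) and `summary` (per-cutoff
#'   data.frame: error rates, NRD, n_sites).
#' @export
concordance_report <- function(truth, imputed_gt, dosage = NULL, maf, info,
                               edges = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5),
                               info_cutoffs = c(NA, 0.8, 0.9, 0.95),
                               transversion = NULL,
                               transversions_only = FALSE) {
  if (is.null(dosage)) dosage <- as.numeric(imputed_gt)
  r2 <- r2_by_bin(truth, dosage, maf, info, edges, info_cutoffs,
    transversion, transversions_only
  )
  rows <- lapply(info_cutoffs, function(cut) {
    mask <- rep(TRUE, length(truth))
    if (transversions_only) mask <- mask & transversion
    if (!is.na(cut)) mask <- mask & !is.na(info) & info >= cut
    cm <- genotype_confusion(truth, imputed_gt, mask)
    er <- error_rates(cm)
    data.frame(
      info_cutoff = cut,
      error_homref = er[[1]], error_het = er[[2]], error_homalt = er[[3]],
      nrd = nrd(cm), n_sites = sum(cm)
    )
  })
  list(r2 = r2, summary = do.call(rbind, rows))
}
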