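#' Construct a call set
#'
#' The central per-sample x per-site container: genotype codes (alt-allele
#' counts 0/1/2, `NA` for missing), optional genotype posterior triples (GP),
#' optional dosages (DS = GP\[2\] + 2 GP\[3\]) and a per-site INFO score.
#' Consistency between genotype, posterior and dosage is validated where all
#' are present.
#'
#' @param sites Sites data.frame (chrom, pos, ref, alt, maf, transversion).
#' @param gt sites x samples integer matrix of genotype codes.
#' @param samples Character vector of sample names.
#' @param gp Optional sites x samples x 3 posterior array; rows must sum to 1.
#' @param ds Optional sites x samples dosage matrix in \[0, 2\].
#' @param info Optional per-site INFO score in \[0, 1\].
#' @return Object of class `callset`.
#' @export
callset <- function(sites, gt, samples = colnames(gt), gp = NULL, ds = NULL,
                    info = NULL) {
  gt <- as.matrix(gt)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(gt)))
  stopifnot(nrow(gt) == nrow(sites), length(samples) == ncol(gt))
  if (!all(gt %in% c(0L, 1L, 2L, NA))) {
    stop_canroh("genotype codes must be 0, 1, 2 or NA")
  }
  if (!is.null(gp)) {
    stopifnot(length(dim(gp)) == 3L, dim(gp)[3] == 3L)
    sums <- gp[, , 1] + gp[, , 2] + gp[, , 3]
    ok <- is.na(sums) | abs(sums - 1) < 1e-6
    if (!all(ok)) stop_canroh("GP rows must sum to 1")
    # argmax(GP) must equal the genotype where both are present; ties make
    # the argmax ambiguous, so only clear contradictions are flagged
    mx <- pmax(gp[, , 1], gp[, , 2], gp[, , 3])
    picked <- matrix(NA_real_, nrow(gt), ncol(gt))
    for (j in seq_len(ncol(gt))) {
      idx <- cbind(seq_len(nrow(gt)), j, gt[, j] + 1L)
      ok_row <- !is.na(gt[, j])
      picked[ok_row, j] <- gp[idx[ok_row, , drop = FALSE]]
    }
    bad <- !is.na(picked) & !is.na(mx) & (mx - picked > 1e-6)
    if (any(bad)) {
      stop_canroh("genotype does not match the posterior argmax")
    }
  }
  if (!is.null(ds)) {
    ds <- as.matrix(ds)
    if (any(ds < -1e-9 | ds > 2 + 1e-9, na.rm = TRUE)) {
      stop_canroh("dosage must lie in [0, 2]")
    }
    if (!is.null(gp)) {
      expect <- gp[, , 2] + 2 * gp[, , 3]
      if (any(abs(ds - expect) > 1e-6, na.rm = TRUE)) {
        stop_canroh("dosage inconsistent with posteriors")
      }
    }
  }
  if (!is.null(info) && any(info < -1e-9 | info > 1 + 1e-9, na.rm = TRUE)) {
    stop_canroh("INFO must lie in [0, 1]")
  }
  structure(
    list(sites = sites, gt = gt, samples = samples, gp = gp, ds = ds,
         info = info),
    class = "callset"
  )
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf(
    "<callset> %d sites x %d samples (%s%s%s)\n",
    nrow(x$sites), length(x$samples),
    "GT", if (!is.null(x$gp)) ",GP,DS" else "",
    if (!is.null(x$info)) ",INFO" else ""
  ))
  invisible(x)
}

#' Is a SNP a transversion?
#'
#' Transitions are the within-class substitutions A<->G and C<->T; every
#' other ref/alt pair is a transversion. Transitions overlap the C->T/G->A
#' pattern of post-mortem cytosine deamination, which is why ancient-DNA
#' analyses offer a transversions-only mode.
#'
#' @param ref,alt Single nucleotides in A, C, G, T; `ref != alt`.
#' @return `TRUE` for a transversion, `FALSE` for a transition.
#' @export
is_transversion <- function(ref, alt) {
  nt <- c("A", "C", "G", "T")
  if (!(ref %in% nt) || !(alt %in% nt)) {
    stop_canroh("ref and alt must be single nucleotides (A/C/G/T)")
  }
  if (ref == alt) stop_canroh("ref and alt must differ")
  purine <- c("A", "G")
  (ref %in% purine) != (alt %in% purine)
}

#' Assign minor-allele-frequency bins
#'
#' Half-open binning \[e_i, e_{i+1}) with the last bin closed at 0.5. The
#' default edges cover the cutoffs used when filtering imputed data (0.01,
#' 0.02, 0.05).
#'
#' @param maf Numeric vector of minor allele frequencies in \[0, 0.5\].
#' @param edges Strictly increasing breaks starting at 0 and ending at 0.5.
#' @return Integer bin indices with a `labels` attribute.
#' @export
assign_maf_bin <- function(maf, edges = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5)) {
  if (edges[1] != 0 || edges[length(edges)] != 0.5 ||
    any(diff(edges) <= 0)) {
    stop_canroh("`edges` must increase strictly from 0 to 0.5")
  }
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    stop_canroh("MAF values must lie in [0, 0.5]")
  }
  bin <- findInterval(maf, edges, rightmost.closed = TRUE)
  labels <- paste0(
    "[", head(edges, -1), ",", tail(edges, -1),
    c(rep(")", length(edges) - 2), "]")
  )
  structure(bin, labels = labels)
}

#' IMPUTE-style INFO score from genotype posteriors at one site
#'
#' With per-sample expected dosage \eqn{e_i = GP_{i1} + 2 GP_{i2}} and
#' second moment \eqn{f_i = GP_{i1} + 4 GP_{i2}}, and estimated allele
#' frequency \eqn{\theta = \sum_i e_i / (2N)}:
#' \deqn{INFO = 1 - \frac{\sum_i (f_i - e_i^2)}{2N\,\theta(1 - \theta)}}
#' By convention INFO = 1 when \eqn{\theta \in \{0, 1\}}. Recomputing INFO
#' over a merged cohort's posteriors is the "recalibration" applied when
#' call sets are merged. Values are clipped to \[0, 1\].
#'
#' @param gp N x 3 matrix of posterior triples, rows summing to 1.
#' @return INFO score in \[0, 1\].
#' @export
compute_info <- function(gp) {
  gp <- matrix(as.numeric(gp), ncol = 3)
  if (nrow(gp) < 1L) stop_canroh("at least one sample is required")
  sums <- rowSums(gp)
  if (any(is.na(sums)) || any(abs(sums - 1) > 1e-6)) {
    stop_canroh("malformed posterior: rows must sum to 1")
  }
  n <- nrow(gp)
  e <- gp[, 2] + 2 * gp[, 3]
  f <- gp[, 2] + 4 * gp[, 3]
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) {
    return(1)
  }
  info <- 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
  min(max(info, 0), 1)
}

# Vectorized per-site INFO over a sites x samples x 3 posterior array;
# agrees with compute_info() row by row (missing samples dropped per site).
info_from_gp_array <- function(gp) {
  e <- gp[, , 2, drop = FALSE][, , 1] + 2 * gp[, , 3, drop = FALSE][, , 1]
  f <- gp[, , 2, drop = FALSE][, , 1] + 4 * gp[, , 3, drop = FALSE][, , 1]
  e <- matrix(e, nrow = dim(gp)[1])
  f <- matrix(f, nrow = dim(gp)[1])
  n_obs <- rowSums(!is.na(e))
  theta <- rowSums(e, na.rm = TRUE) / (2 * n_obs)
  num <- rowSums(f - e^2, na.rm = TRUE)
  info <- 1 - num / (2 * n_obs * theta * (1 - theta))
  info[theta <= 0 | theta >= 1] <- 1
  info[n_obs == 0] <- NA_real_
  pmin(pmax(info, 0), 1)
}

#' Recalibrate per-site INFO over a merged call set
#'
#' Recomputes every site's INFO score from the call set's own posteriors,
#' e.g. after merging cohorts.
#'
#' @param cs A [callset()] with posteriors.
#' @return The call set with `info` replaced.
#' @export
recalibrate_info <- function(cs) {
  stopifnot(inherits(cs, "callset"))
  if (is.null(cs$gp)) stop_canroh("call set has no posteriors")
  cs$info <- info_from_gp_array(cs$gp)
  cs
}

#' Post-imputation site filtering
#'
#' Retains sites with INFO >= `info_min`, panel MAF >= `maf_min` (the "MAF
#' above 0.01" filter is implemented as inclusive) and, optionally,
#' transversions only. The number of sites removed by each criterion is
#' attached as attribute `removed`.
#'
#' @param cs A [callset()].
#' @param info_min Minimum INFO score (0 disables).
#' @param maf_min Minimum panel MAF (0 disables).
#' @param transversions_only Keep transversion sites only.
#' @return Filtered [callset()].
#' @export
filter_sites <- function(cs, info_min = 0, maf_min = 0,
                         transversions_only = FALSE) {
  stopifnot(inherits(cs, "callset"))
  n <- nrow(cs$sites)
  keep_info <- if (info_min > 0) {
    !is.na(cs$info) & cs$info >= info_min
  } else {
    rep(TRUE, n)
  }
  keep_maf <- if (maf_min > 0) cs$sites$maf >= maf_min else rep(TRUE, n)
  keep_tv <- if (transversions_only) cs$sites$transversion else rep(TRUE, n)
  keep <- keep_info & keep_maf & keep_tv
  out <- subset_callset(cs, keep)
  attr(out, "removed") <- c(
    info = sum(!keep_info), maf = sum(!keep_maf),
    transversion = sum(!keep_tv), total = sum(!keep)
  )
  out
}

subset_callset <- function(cs, keep) {
  sites <- cs$sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "chrom_lengths") <- attr(cs$sites, "chrom_lengths")
  callset(
    sites,
    cs$gt[keep, , drop = FALSE],
    samples = cs$samples,
    gp = if (!is.null(cs$gp)) cs$gp[keep, , , drop = FALSE] else NULL,
    ds = if (!is.null(cs$ds)) cs$ds[keep, , drop = FALSE] else NULL,
    info = if (!is.null(cs$info)) cs$info[keep] else NULL
  )
}

#' Write a call set as VCF 4.2
#'
#' Emits FORMAT GT (unphased), GP (4 decimals) and DS (4 decimals) where
#' present, with per-site INFO keys `INFO_SCORE` and `PANEL_MAF`.
#' Coordinates are written 1-based as VCF requires. A `.gz` suffix writes
#' through a gzip connection.
#'
#' @param cs A [callset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path) {
  stopifnot(inherits(cs, "callset"))
  sites <- cs$sites
  n <- nrow(sites)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=canroh",
    '##INFO=<ID=INFO_SCORE,Number=1,Type=Float,Description="Imputation INFO score">',
    '##INFO=<ID=PANEL_MAF,Number=1,Type=Float,Description="Reference panel minor allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  cl <- attr(sites, "chrom_lengths")
  if (!is.null(cl)) {
    header <- c(header, sprintf(
      "##contig=<ID=%s,length=%d>",
      names(cl), as.integer(cl)
    ))
  }
  has_gp <- !is.null(cs$gp)
  if (has_gp) {
    header <- c(
      header,
      '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype posterior probabilities">',
      '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alternative allele dosage">'
    )
  }
  header <- c(header, paste(
    c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      cs$samples),
    collapse = "\t"
  ))
  info_vec <- cs$info %||% rep(NA_real_, n)
  info_col <- ifelse(
    is.na(info_vec),
    sprintf("PANEL_MAF=%.6g", sites$maf),
    sprintf("INFO_SCORE=%.6g;PANEL_MAF=%.6g", info_vec, sites$maf)
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[cs$gt + 1L], nrow = n)
  gt_str[is.na(cs$gt)] <- "./."
  cells <- gt_str
  fmt <- "GT"
  if (has_gp) {
    fmt <- "GT:GP:DS"
    for (j in seq_len(ncol(cells))) {
      gpj <- matrix(cs$gp[, j, ], ncol = 3)
      dsj <- cs$ds[, j]
      cell <- sprintf(
        "%s:%.4f,%.4f,%.4f:%.4f",
        gt_str[, j], gpj[, 1], gpj[, 2], gpj[, 3], dsj
      )
      cell[is.na(gpj[, 1])] <- paste0(gt_str[is.na(gpj[, 1]), j], ":.:.")
      cells[, j] <- cell
    }
  }
  body <- paste(
    sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
    info_col, fmt,
    sep = "\t"
  )
  for (j in seq_len(ncol(cells))) body <- paste(body, cells[, j], sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a VCF into a call set
#'
#' Parses a VCF (via vcfR), keeping biallelic SNPs only; multiallelic or
#' non-SNP records are skipped and their count reported in attribute
#' `skipped` (with a warning). GT, GP, DS and the `INFO_SCORE` / `PANEL_MAF`
#' INFO keys are recovered where present; `./.` becomes a missing genotype.
#'
#' @param path VCF path (optionally gzipped).
#' @return A [callset()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop_canroh("no records in VCF")
  nt <- c("A", "C", "G", "T")
  snp <- fix$REF %in% nt & fix$ALT %in% nt & !grepl(",", fix$ALT)
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    warning(sprintf("skipped %d multiallelic/non-SNP record(s)", n_skip))
  }
  keep <- which(snp)
  fix <- fix[keep, , drop = FALSE]
  maf <- suppressWarnings(as.numeric(
    vcfR::extract.info(v, "PANEL_MAF")[keep]
  ))
  info <- suppressWarnings(as.numeric(
    vcfR::extract.info(v, "INFO_SCORE")[keep]
  ))
  sites <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    maf = maf,
    stringsAsFactors = FALSE
  )
  sites$transversion <- mapply(is_transversion, sites$ref, sites$alt,
    USE.NAMES = FALSE
  )
  gt_raw <- vcfR::extract.gt(v, "GT")[keep, , drop = FALSE]
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  gt <- apply(gt_raw, 2, code)
  gt <- matrix(gt, nrow = nrow(sites), dimnames = dimnames(gt_raw))
  gp <- NULL
  ds <- NULL
  fmt_keys <- strsplit(v@gt[1, 1], ":")[[1]]
  if ("GP" %in% fmt_keys) {
    gp_raw <- vcfR::extract.gt(v, "GP")[keep, , drop = FALSE]
    gp <- array(NA_real_, dim = c(nrow(sites), ncol(gt_raw), 3))
    for (j in seq_len(ncol(gp_raw))) {
      parts <- strsplit(gp_raw[, j], ",", fixed = TRUE)
      ok <- lengths(parts) == 3L
      m <- matrix(NA_real_, nrow(sites), 3)
      m[ok, ] <- matrix(as.numeric(unlist(parts[ok])),
        ncol = 3, byrow = TRUE
      )
      gp[, j, ] <- m
    }
    # renormalize rounding drift so rows sum to 1 exactly
    sums <- gp[, , 1] + gp[, , 2] + gp[, , 3]
    for (k in 1:3) gp[, , k] <- gp[, , k] / sums
  }
  if ("DS" %in% fmt_keys) {
    ds_raw <- vcfR::extract.gt(v, "DS")[keep, , drop = FALSE]
    ds <- matrix(suppressWarnings(as.numeric(ds_raw)), nrow = nrow(sites))
  }
  if (!is.null(gp) && !is.null(ds)) {
    ds <- gp[, , 2, drop = FALSE][, , 1] + 2 * gp[, , 3, drop = FALSE][, , 1]
    ds <- matrix(ds, nrow = nrow(sites))
  }
  out <- callset(sites, gt,
    samples = colnames(gt_raw), gp = gp, ds = ds,
    info = if (all(is.na(info))) NULL else info
  )
  attr(out, "skipped") <- n_skip
  out
}
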