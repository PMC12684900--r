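#' Fit a PCA on complete reference genotypes
#'
#' Centered, scaled singular value decomposition in the classic
#' population-genetics normalization: each site is centered by its mean
#' genotype \eqn{2p} and scaled by \eqn{\sqrt{p(1-p)}} with
#' \eqn{p = \bar g / 2}; monomorphic sites are dropped. Eigenvalues are
#' those of the sample covariance of the normalized data (\eqn{d_k^2 /
#' (n-1)}). Each loading column's sign is fixed so that its
#' largest-magnitude entry is positive, making scores reproducible.
#'
#' @param genotypes n_samples x n_sites matrix of genotype codes (0/1/2),
#'   no missing values.
#' @param K Number of components, <= min(n_samples, n_sites).
#' @return Object of class `pca_model`: `site_means`, `site_scales`,
#'   `loadings` (kept sites x K), `eigenvalues` (length K, non-increasing),
#'   `scores` (reference sample scores), `sites_kept` (indices into the
#'   input columns).
#' @export
fit_pca <- function(genotypes, K = 10L) {
  G <- as.matrix(genotypes)
  if (anyNA(G)) stop_canroh("reference genotypes must be complete")
  p <- colMeans(G) / 2
  keep <- which(p > 0 & p < 1)
  if (length(keep) == 0L) stop_canroh("all sites are monomorphic")
  if (K > min(nrow(G), length(keep))) {
    stop_canroh("K exceeds the available dimensions")
  }
  mu <- 2 * p[keep]
  sc <- sqrt(p[keep] * (1 - p[keep]))
  X <- sweep(sweep(G[, keep, drop = FALSE], 2, mu), 2, sc, "/")
  s <- svd(X, nu = K, nv = K)
  loadings <- s$v
  flip <- vapply(seq_len(K), function(k) {
    v <- loadings[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- X %*% loadings
  structure(
    list(
      site_means = mu,
      site_scales = sc,
      loadings = loadings,
      eigenvalues = s$d[seq_len(K)]^2 / (nrow(G) - 1),
      scores = scores,
      sites_kept = keep
    ),
    class = "pca_model"
  )
}

#' Least-squares projection of a partially observed sample
#'
#' Places a query genotype vector (which may contain missing values) into a
#' fitted PC space: the non-missing genotypes are centered and scaled with
#' the model's parameters and regressed onto the loadings restricted to the
#' observed sites, minimizing the squared reconstruction error. With no
#' missingness this reduces to the ordinary projection \eqn{L^\top x}.
#'
#' @param query Genotype vector over the model's input sites (0/1/2/NA).
#' @param model A [fit_pca()] model.
#' @return Numeric vector of K scores.
#' @export
project_pca <- function(query, model) {
  stopifnot(inherits(model, "pca_model"))
  g <- query[model$sites_kept]
  obs <- !is.na(g)
  K <- ncol(model$loadings)
  if (sum(obs) < K) {
    stop_canroh("fewer observed sites than components")
  }
  x <- (g[obs] - model$site_means[obs]) / model$site_scales[obs]
  L <- model$loadings[obs, , drop = FALSE]
  as.numeric(solve(crossprod(L), crossprod(L, x)))
}

#' Eigenvalue-weighted distance between two PC score vectors
#'
#' \deqn{D = \sum_{k=1}^{K} w_k |a_k - b_k|, \quad
#'       w_k = \lambda_k / \sum_{j=1}^{K} \lambda_j}
#' A weighted L1 metric over the leading K PCs (default 10), so more
#' informative components contribute proportionally to their eigenvalue.
#' Variants: squared differences (`method = "squared"`) and unweighted L1
#' (`method = "unweighted"`).
#'
#' @param a,b Score vectors.
#' @param eigenvalues Eigenvalues of the PC space.
#' @param K Number of components used (default 10).
#' @param method Distance variant.
#' @return Non-negative scalar.
#' @export
weighted_pc_distance <- function(a, b, eigenvalues, K = 10L,
                                 method = c("abs", "squared", "unweighted")) {
  method <- match.arg(method)
  if (K > length(eigenvalues) || K > length(a) || K > length(b)) {
    stop_canroh("K exceeds the available components")
  }
  idx <- seq_len(K)
  w <- eigenvalues[idx] / sum(eigenvalues[idx])
  d <- a[idx] - b[idx]
  switch(method,
    abs = sum(w * abs(d)),
    squared = sum(w * d^2),
    unweighted = sum(abs(d))
  )
}
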