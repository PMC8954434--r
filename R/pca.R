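#' Principal components analysis of genotypes
#'
#' PCA of the sample-by-locus genotype matrix. Missing calls are
#' mean-imputed per locus, loci are centred, and (by default) scaled by the
#' binomial standard deviation `sqrt(p(1-p))` of their allele frequency.
#' Scores come from the singular value decomposition; each axis's sign is
#' fixed so that its largest-magnitude locus loading is positive, making
#' results reproducible across platforms.
#'
#' @param gm A [genotype_matrix()].
#' @param n_axes Number of axes to return (default 3).
#' @param scale Apply binomial scaling (default `TRUE`).
#' @return A `pca_result`: `scores` (samples x axes),
#'   `explained_variance_fractions` (descending), `loadings`.
#' @export
pca_genotypes <- function(gm, n_axes = 3L, scale = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  x <- gm$calls
  if (nrow(x) < 2L || ncol(x) < 2L)
    ds_stop("PCA requires at least 2 samples and 2 loci", "ds_invalid")
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0L)) x[is.na(x[, j]), j] <- mu[j]
  p_hat <- mu / 2
  x <- sweep(x, 2L, mu)
  if (scale) {
    sdv <- sqrt(p_hat * (1 - p_hat))
    keep <- sdv > 0
    x <- sweep(x[, keep, drop = FALSE], 2L, sdv[keep], "/")
  } else {
    keep <- apply(x, 2L, function(v) any(v != 0))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L || all(abs(x) < 1e-12))
    ds_stop("zero-variance genotype matrix: PCA undefined", "ds_novariation")
  n_axes <- min(n_axes, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = n_axes, nv = n_axes)
  # sign convention: largest-magnitude loading positive per axis
  for (a in seq_len(n_axes)) {
    ld <- sv$v[, a]
    if (ld[which.max(abs(ld))] < 0) {
      sv$v[, a] <- -sv$v[, a]
      sv$u[, a] <- -sv$u[, a]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- gm$sample_ids
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores,
                 explained_variance_fractions = ev[seq_len(n_axes)],
                 loadings = sv$v),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d axes (%.1f%% variance on axis 1)\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$explained_variance_fractions[1L]))
  invisible(x)
}
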