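# STRUCTURE-like admixture inference.
#
# The one-hot encoded genotype matrix X (n x 3L: at each locus the three
# genotype classes 0/1/2) is factorised as Q G, where Q (n x K) holds
# per-individual ancestry coefficients on the probability simplex and G
# (K x 3L) holds per-locus genotype-class frequencies of each ancestral
# population (each K x locus block row sums to 1 over the 3 classes).
# The objective  || W * (X - Q G) ||_F^2 + alpha ||Q||_F^2  (W masks
# missing and held-out entries) is minimised by alternating projected
# gradient steps with exact Lipschitz step sizes, so each update is
# guaranteed not to increase the objective. A random fraction of observed
# entries is held out before fitting; the masked cross-entropy of those
# entries is the model-selection criterion.

one_hot_genotypes <- function(calls) {
  n <- nrow(calls); L <- ncol(calls)
  X <- matrix(0, n, 3L * L)
  idx <- which(!is.na(calls), arr.ind = TRUE)
  g <- calls[idx]
  X[cbind(idx[, 1L], (idx[, 2L] - 1L) * 3L + g + 1L)] <- 1
  X
}

# column index expansion: locus mask (n x L) -> class mask (n x 3L)
expand_mask <- function(m) m[, rep(seq_len(ncol(m)), each = 3L), drop = FALSE]

admixture_objective <- function(X, Q, G, W3, alpha) {
  R <- W3 * (Q %*% G - X)
  sum(R * R) + alpha * sum(Q * Q)
}

# project each (component, locus) triple of G onto the simplex
project_G <- function(G) {
  K <- nrow(G); L3 <- ncol(G)
  Gm <- matrix(t(G), nrow = 3L)           # 3 x (K * L)
  Gm <- t(project_rows_simplex(t(Gm)))
  t(matrix(Gm, nrow = L3))
}

#' Fit a sparse-NMF-style admixture model
#'
#' Estimates per-individual ancestry coefficients `Q` and ancestral
#' genotype-class frequencies `G` for `K` ancestral populations by
#' regularised alternating projected-gradient least squares on the one-hot
#' genotype encoding (see source comments for the objective). A random
#' `mask_fraction` of the observed genotype entries is held out before
#' fitting; the mean negative log predicted probability of the held-out
#' genotype classes (`cross_entropy`) is the model-choice criterion.
#' Missing genotypes are excluded from both the fit and the criterion.
#'
#' @param gm A [genotype_matrix()].
#' @param K Number of ancestral populations (>= 1, <= number of samples).
#' @param alpha Ridge regularisation weight on `Q` (default 10).
#' @param seed Seed controlling the initialisation (and, unless
#'   `mask_seed` is given, the hold-out mask).
#' @param mask_fraction Fraction of observed entries held out (default
#'   0.05).
#' @param mask_seed Separate seed for the hold-out mask; [select_k()]
#'   shares one mask stream across all `K` within a replicate so that
#'   cross-entropies are compared on identical held-out entries.
#' @param max_iter Maximum alternating iterations (default 200).
#' @param tol Relative objective-change convergence tolerance (default
#'   1e-5).
#' @return An `admixture_fit`: `K`, `Q` (rows sum to 1), `G` (each locus
#'   block of each component a probability distribution over the 3 genotype
#'   classes), `cross_entropy`, `objective_trace`, `converged`,
#'   `n_iterations`, `replicate_seed`.
#' @export
fit_admixture <- function(gm, K, alpha = 10, seed = 1L, mask_fraction = 0.05,
                          max_iter = 200L, tol = 1e-5, mask_seed = seed) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$calls); L <- ncol(gm$calls)
  if (K < 1L) ds_stop("K must be >= 1", "ds_invalid")
  if (K > n) ds_stop("K cannot exceed the number of samples", "ds_invalid")
  calls <- gm$calls
  obs <- !is.na(calls)
  # hold-out mask over observed entries, from its own seed so model
  # choices can share one mask stream across K
  set.seed(mask_seed)
  obs_idx <- which(obs)
  n_hold <- max(1L, round(mask_fraction * length(obs_idx)))
  hold_idx <- sample(obs_idx, n_hold)
  set.seed(seed)
  Wl <- obs
  Wl[hold_idx] <- FALSE
  X <- one_hot_genotypes(calls)
  W3 <- expand_mask(Wl * 1)

  if (K == 1L) {
    Q <- matrix(1, n, 1L, dimnames = list(gm$sample_ids, NULL))
    # optimum for K = 1 is the per-locus observed class frequency
    G <- matrix(0, 1L, 3L * L)
    for (cls in 0:2) {
      cnt <- colSums((calls == cls) & Wl, na.rm = TRUE)
      tot <- colSums(Wl)
      G[1L, seq(cls + 1L, 3L * L, by = 3L)] <- ifelse(tot > 0, cnt / tot, 1 / 3)
    }
    ce <- masked_cross_entropy(Q, G, calls, hold_idx)
    return(structure(list(K = 1L, Q = Q, G = G, cross_entropy = ce,
                          objective_trace = admixture_objective(X, Q, G, W3, alpha),
                          converged = TRUE, n_iterations = 0L,
                          replicate_seed = seed, hold_idx = hold_idx),
                     class = "admixture_fit"))
  }

  Q <- matrix(stats::rexp(n * K), n, K, dimnames = list(gm$sample_ids, NULL))
  Q <- Q / rowSums(Q)
  # initialise G from perturbed global class frequencies
  G <- matrix(stats::runif(K * 3L * L, 0.05, 1), K, 3L * L)
  G <- project_G(G)

  obj <- admixture_objective(X, Q, G, W3, alpha)
  trace <- obj
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # Q step: Lipschitz constant of the (unmasked-majorised) gradient
    GGt <- G %*% t(G)
    LQ <- 2 * (max(eigen(GGt, symmetric = TRUE, only.values = TRUE)$values) + alpha)
    R <- W3 * (Q %*% G - X)
    gradQ <- 2 * (R %*% t(G)) + 2 * alpha * Q
    Q <- project_rows_simplex(Q - gradQ / LQ)
    # G step
    QtQ <- t(Q) %*% Q
    LG <- 2 * max(eigen(QtQ, symmetric = TRUE, only.values = TRUE)$values)
    R <- W3 * (Q %*% G - X)
    gradG <- 2 * (t(Q) %*% R)
    G <- project_G(G - gradG / LG)
    new_obj <- admixture_objective(X, Q, G, W3, alpha)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) <= tol * max(1, abs(obj))) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  ce <- masked_cross_entropy(Q, G, calls, hold_idx)
  structure(list(K = as.integer(K), Q = Q, G = G, cross_entropy = ce,
                 objective_trace = trace, converged = converged,
                 n_iterations = it, replicate_seed = seed,
                 hold_idx = hold_idx),
            class = "admixture_fit")
}

# mean negative log predicted probability of the held-out genotype classes
masked_cross_entropy <- function(Q, G, calls, hold_idx) {
  if (length(hold_idx) == 0L) return(NA_real_)
  arr <- arrayInd(hold_idx, dim(calls))
  g <- calls[hold_idx]
  P <- Q %*% G
  cols <- (arr[, 2L] - 1L) * 3L + g + 1L
  p_true <- P[cbind(arr[, 1L], cols)]
  # renormalise each held-out triple (numerical safety; sums are ~1 by
  # construction)
  p_sum <- P[cbind(arr[, 1L], (arr[, 2L] - 1L) * 3L + 1L)] +
    P[cbind(arr[, 1L], (arr[, 2L] - 1L) * 3L + 2L)] +
    P[cbind(arr[, 1L], (arr[, 2L] - 1L) * 3L + 3L)]
  p <- p_true / pmax(p_sum, 1e-12)
  -mean(log(pmax(p, 1e-9)))
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, cross-entropy %.4f (%s after %d iterations)\n",
              x$K, x$cross_entropy,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' Align ancestry components between replicate fits
#'
#' Resolves label switching by greedily matching columns of `Q2` to columns
#' of `Q1` on correlation, highest first.
#'
#' @param Q1,Q2 Ancestry matrices with the same dimensions.
#' @return `Q2` with columns permuted to match `Q1`.
#' @export
align_ancestry <- function(Q1, Q2) {
  K <- ncol(Q1)
  stopifnot(ncol(Q2) == K)
  if (K == 1L) return(Q2)
  cors <- suppressWarnings(stats::cor(Q1, Q2))
  cors[is.na(cors)] <- 0
  perm <- integer(K)
  used <- logical(K)
  for (step in seq_len(K)) {
    best <- which(cors == max(cors), arr.ind = TRUE)[1L, ]
    perm[best[1L]] <- best[2L]
    cors[best[1L], ] <- -Inf
    cors[, best[2L]] <- -Inf
  }
  Q2[, perm, drop = FALSE]
}

#' Select the number of ancestral populations by cross-entropy
#'
#' Fits the admixture model over a range of `K` with several replicates per
#' `K` (fresh hold-out mask and initialisation per replicate, seeds derived
#' from `seed`), and selects the `K` minimising the mean masked
#' cross-entropy. Ties go to the smallest `K`. `K = 1` is included in the
#' default range: unstructured species are a real outcome.
#'
#' @param gm A [genotype_matrix()].
#' @param k_range Candidate values of `K` (default `1:10`).
#' @param replicates Replicates per `K` (default 10).
#' @param seed Base seed.
#' @param ... Further arguments passed to [fit_admixture()].
#' @return A `k_selection`: `K_star`, `summary` (per-K mean/sd/min
#'   cross-entropy), `best_fit` (lowest-cross-entropy replicate at
#'   `K_star`), `fits` (all fits, list indexed `[[K]][[replicate]]`).
#' @export
select_k <- function(gm, k_range = 1:10, replicates = 10, seed = 1L, ...) {
  if (length(k_range) == 0L) ds_stop("k_range must be non-empty", "ds_invalid")
  fits <- list()
  rows <- list()
  for (K in k_range) {
    kf <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      # one mask stream per replicate, shared across K: cross-entropies
      # are compared on identical held-out entries
      kf[[r]] <- fit_admixture(gm, K = K,
                               seed = derive_seed(seed, paste0("snmf_K", K), r),
                               mask_seed = derive_seed(seed, "snmf_mask", r),
                               ...)
    }
    fits[[as.character(K)]] <- kf
    ces <- vapply(kf, function(f) f$cross_entropy, numeric(1))
    rows[[as.character(K)]] <- data.frame(
      K = K, mean_cross_entropy = mean(ces), sd_cross_entropy = stats::sd(ces),
      min_cross_entropy = min(ces))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  # argmin of mean cross-entropy; ties -> smallest K (order of k_range is
  # ascending by convention, which.min takes the first)
  summary <- summary[order(summary$K), , drop = FALSE]
  K_star <- summary$K[which.min(summary$mean_cross_entropy)]
  kf <- fits[[as.character(K_star)]]
  best <- kf[[which.min(vapply(kf, function(f) f$cross_entropy, numeric(1)))]]
  structure(list(K_star = as.integer(K_star), summary = summary,
                 best_fit = best, fits = fits),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("k_selection: K* = %d\n", x$K_star))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
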