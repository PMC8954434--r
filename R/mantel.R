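#' Mantel test of isolation by distance
#'
#' Pearson Mantel test between linearised genetic distances
#' `Fst / (1 - Fst)` and natural-log geographic distances (km), with a
#' one-sided (positive association) permutation p-value computed by the
#' vegan package: `p = (#{permuted r >= observed} + 1) / (n_perm + 1)`.
#'
#' @param fst An `fst_matrix` from [pairwise_fst()].
#' @param dists Site-by-site distance matrix (km), same site order; all
#'   off-diagonal distances must be positive.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @param cap_fst Capping policy for `Fst >= 0.999`: if `FALSE` (default)
#'   such values are an error (the linearisation degenerates); if `TRUE`
#'   they are capped at 0.999 before linearising.
#' @return An object of class `mantel_result`: `r`, `p`, `n_permutations`,
#'   `n_sites`.
#' @export
mantel_ibd <- function(fst, dists, n_perm = 999, seed = 1L, cap_fst = FALSE) {
  stopifnot(inherits(fst, "fst_matrix"))
  k <- length(fst$site_codes)
  if (k < 3L)
    ds_stop("Mantel test requires at least 3 sites", "ds_toofewsites")
  if (!all(dim(dists) == c(k, k)))
    ds_stop("distance matrix dimensions must match the Fst matrix", "ds_invalid")
  off <- dists[upper.tri(dists)]
  if (any(off <= 0))
    ds_stop("all between-site distances must be positive (same-site pairs are excluded)",
            "ds_invalid")
  v <- fst$values
  if (any(v[upper.tri(v)] >= 0.999, na.rm = TRUE)) {
    if (!cap_fst)
      ds_stop("Fst >= 0.999 present: linearisation undefined; set cap_fst = TRUE to cap at 0.999",
              "ds_config")
    v[v >= 0.999] <- 0.999
  }
  if (anyNA(v[upper.tri(v)]))
    ds_stop("undefined pairwise Fst values; Mantel input must be complete",
            "ds_invalid")
  gen <- v / (1 - v)
  geo <- log(dists)
  diag(geo) <- 0
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(gen), stats::as.dist(geo),
                      method = "pearson", permutations = n_perm)
  structure(list(r = unname(mt$statistic), p = unname(mt$signif),
                 n_permutations = n_perm, n_sites = k),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel IBD: r = %.3f, p = %.4g (%d permutations, %d sites)\n",
              x$r, x$p, x$n_permutations, x$n_sites))
  invisible(x)
}

#' Signal 1: low Fst with no isolation by distance
#'
#' Flags the pattern expected from recent, rapid range-wide dispersal: low
#' overall differentiation (median pairwise Fst below `low_fst_threshold`)
#' combined with an absent isolation-by-distance relationship (Mantel
#' `r < r_threshold` or `p > 0.05`). The emphasis is on the overall pattern
#' rather than permutation significance alone, so both the correlation
#' magnitude and the p-value can veto IBD.
#'
#' @param fst An `fst_matrix`.
#' @param mantel A `mantel_result` from [mantel_ibd()], or `NULL` when the
#'   test could not be run (< 3 sites), in which case the signal is
#'   `"not_assessable"`.
#' @param low_fst_threshold Median-Fst cut-off for "low" (default 0.05).
#' @param r_threshold Mantel correlation below which IBD is considered
#'   absent (default 0.30).
#' @return A `signal_result`: `signal` (`"detected"`, `"not_detected"` or
#'   `"not_assessable"`) plus an `evidence` list recording the median Fst,
#'   Mantel r and p, and the thresholds applied.
#' @export
detect_signal1 <- function(fst, mantel, low_fst_threshold = 0.05,
                           r_threshold = 0.30) {
  stopifnot(inherits(fst, "fst_matrix"))
  med <- median_pairwise_fst(fst)
  if (is.null(mantel)) {
    return(signal_result("not_assessable",
                         list(median_fst = med, reason = "mantel unavailable (<3 sites)")))
  }
  stopifnot(inherits(mantel, "mantel_result"))
  low_fst <- !is.na(med) && med < low_fst_threshold
  no_ibd <- (mantel$r < r_threshold) || (mantel$p > 0.05)
  signal_result(if (low_fst && no_ibd) "detected" else "not_detected",
                list(median_fst = med, mantel_r = mantel$r, mantel_p = mantel$p,
                     low_fst_threshold = low_fst_threshold,
                     r_threshold = r_threshold))
}

#' Construct a signal result
#'
#' @param signal One of `"detected"`, `"not_detected"`, `"not_assessable"`.
#' @param evidence Named list of supporting numbers.
#' @return A `signal_result` object.
#' @export
signal_result <- function(signal, evidence = list()) {
  signal <- match.arg(signal, c("detected", "not_detected", "not_assessable"))
  structure(list(signal = signal, evidence = evidence),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat("signal:", x$signal, "\n")
  invisible(x)
}
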