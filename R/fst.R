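# Multilocus pairwise Fst.
#
# Two-population Weir-type variance-components estimator (theta-hat),
# combined across loci as a ratio of averages: per-locus among-population
# components (a) are summed in the numerator and total components
# (a + b + c) in the denominator. Loci monomorphic across a pair contribute
# zero to both sums; missing calls reduce the per-locus sample sizes.
#
# Per locus with r = 2 populations, n_i genotyped diploids, p_i alternate
# allele frequency and h_i observed heterozygote fraction:
#   n_bar = mean(n_i); n_c = (r n_bar - sum(n_i^2)/(r n_bar)) / (r - 1)
#   p_bar = sum(n_i p_i) / (r n_bar)
#   s2    = sum(n_i (p_i - p_bar)^2) / ((r - 1) n_bar)
#   h_bar = sum(n_i h_i) / (r n_bar)
#   a = n_bar/n_c * (s2 - (p_bar(1-p_bar) - s2 (r-1)/r - h_bar/4)/(n_bar-1))
#   b = n_bar/(n_bar-1) * (p_bar(1-p_bar) - s2 (r-1)/r
#                          - h_bar (2 n_bar - 1)/(4 n_bar))
#   c = h_bar / 2

# Vectorised per-locus components for one population pair. Returns a list
# of numeric vectors a, b, c and a logical `usable` mask.
wc_components <- function(calls1, calls2, min_per_site = 2L) {
  n1 <- colSums(!is.na(calls1))
  n2 <- colSums(!is.na(calls2))
  usable <- n1 >= min_per_site & n2 >= min_per_site
  p1 <- colSums(calls1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(calls2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(calls1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(calls2 == 1L, na.rm = TRUE) / n2
  r <- 2
  n_bar <- (n1 + n2) / 2
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- n_bar / n_c *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  a[!usable] <- 0; b[!usable] <- 0; cc[!usable] <- 0
  list(a = a, b = b, c = cc, usable = usable)
}

#' Pairwise multilocus Fst between sites
#'
#' Computes the Weir-type two-population variance-components estimator for
#' every pair of sites, combining loci as a ratio of sums (see source for
#' the per-locus formula). Negative estimates are retained untruncated.
#'
#' @param gm A [genotype_matrix()].
#' @param site_assignment Character or factor vector, one site code per
#'   sample (in `gm` sample order).
#' @param min_per_site Minimum genotyped diploids per site per locus for a
#'   locus to enter a pair's sums (default 2).
#' @return An object of class `fst_matrix`: `site_codes`, `values`
#'   (symmetric matrix, `NA` diagonal), `n_loci_used` (loci with adequate
#'   data in both sites), `n_samples` per site, and `undefined_pairs`
#'   (pairs with no usable locus).
#' @export
pairwise_fst <- function(gm, site_assignment, min_per_site = 2L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  site_assignment <- as.character(site_assignment)
  if (length(site_assignment) != nrow(gm$calls))
    ds_stop("site_assignment length must equal the number of samples",
            "ds_invalid")
  sites <- unique(site_assignment)
  if (length(sites) < 2L)
    ds_stop("at least two sites are required for pairwise Fst", "ds_invalid")
  ns <- table(factor(site_assignment, levels = sites))
  k <- length(sites)
  vals <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
  nloci <- matrix(0L, k, k, dimnames = list(sites, sites))
  undefined <- list()
  split_rows <- split(seq_len(nrow(gm$calls)), factor(site_assignment, levels = sites))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    c1 <- gm$calls[split_rows[[i]], , drop = FALSE]
    c2 <- gm$calls[split_rows[[j]], , drop = FALSE]
    comp <- wc_components(c1, c2, min_per_site)
    denom <- sum(comp$a + comp$b + comp$c)
    nloci[i, j] <- nloci[j, i] <- sum(comp$usable)
    if (!any(comp$usable) || denom == 0) {
      undefined[[length(undefined) + 1L]] <- c(sites[i], sites[j])
      next
    }
    vals[i, j] <- vals[j, i] <- sum(comp$a) / denom
  }
  structure(list(site_codes = sites, values = vals, n_loci_used = nloci,
                 n_samples = as.integer(ns), undefined_pairs = undefined),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("fst_matrix: %d sites; mean pairwise Fst %.4f\n",
              length(x$site_codes),
              mean(x$values[upper.tri(x$values)], na.rm = TRUE)))
  print(round(x$values, 4))
  invisible(x)
}

#' Mean of the off-diagonal pairwise Fst values
#'
#' @param fst An `fst_matrix`.
#' @return Scalar mean over defined site pairs.
#' @export
mean_pairwise_fst <- function(fst) {
  stopifnot(inherits(fst, "fst_matrix"))
  mean(fst$values[upper.tri(fst$values)], na.rm = TRUE)
}

#' Median of the off-diagonal pairwise Fst values
#'
#' @param fst An `fst_matrix`.
#' @return Scalar median over defined site pairs.
#' @export
median_pairwise_fst <- function(fst) {
  stopifnot(inherits(fst, "fst_matrix"))
  stats::median(fst$values[upper.tri(fst$values)], na.rm = TRUE)
}

#' Haploid pairwise Fst (Hudson-type) for haplotype data
#'
#' A simple allele-frequency estimator for haploid loci (e.g. chloroplast
#' SNPs): per pair of sites, `1 - Hw / Hb` with within- and between-site
#' heterozygosities averaged across loci. Used to compare plastid and
#' nuclear differentiation; not the primary nuclear estimator.
#'
#' @param haps Character or integer matrix (samples x loci) of haploid
#'   alleles; `NA` for missing.
#' @param site_assignment One site code per sequence.
#' @return Symmetric matrix of pairwise estimates with `NA` diagonal.
#' @export
haploid_pairwise_fst <- function(haps, site_assignment) {
  site_assignment <- as.character(site_assignment)
  sites <- unique(site_assignment)
  k <- length(sites)
  vals <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    h1 <- haps[site_assignment == sites[i], , drop = FALSE]
    h2 <- haps[site_assignment == sites[j], , drop = FALSE]
    num <- 0; den <- 0
    for (l in seq_len(ncol(haps))) {
      a1 <- h1[, l]; a1 <- a1[!is.na(a1)]
      a2 <- h2[, l]; a2 <- a2[!is.na(a2)]
      if (length(a1) < 2L || length(a2) < 2L) next
      alleles <- unique(c(a1, a2))
      if (length(alleles) < 2L) next
      f1 <- table(factor(a1, levels = alleles)) / length(a1)
      f2 <- table(factor(a2, levels = alleles)) / length(a2)
      # unbiased within-site gene diversity, mean across the two sites
      hw <- (length(a1) / (length(a1) - 1) * (1 - sum(f1^2)) +
             length(a2) / (length(a2) - 1) * (1 - sum(f2^2))) / 2
      hb <- 1 - sum(f1 * f2)
      num <- num + (hb - hw)
      den <- den + hb
    }
    if (den > 0) vals[i, j] <- vals[j, i] <- num / den
  }
  vals
}
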