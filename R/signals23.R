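# Signals 2 and 3: between-site admixture and within-site outliers,
# read off the admixture fit (verified against the PCA for signal 3).

site_modal_component <- function(Q, site_assignment) {
  dom <- max.col(Q, ties.method = "first")
  vapply(split(dom, site_assignment), function(v) {
    tb <- table(v)
    as.integer(names(tb)[which.max(tb)])
  }, integer(1))
}

#' Signal 2: admixture between sites
#'
#' Flags sites where most samples carry admixed ancestry profiles: more
#' than `site_majority` of a site's samples have a dominant ancestry
#' coefficient at or below `dominance_threshold`, and the site's two
#' largest mean ancestry components are each the dominant (modal) component
#' of at least one other site. The second condition separates genuine
#' between-site admixture from within-site noise: an admixed site must mix
#' ancestries that are "at home" elsewhere.
#'
#' @param fit An `admixture_fit` (with `K >= 2`; for `K < 2` the signal is
#'   not assessable).
#' @param site_assignment One site code per sample, in fit row order.
#' @param dominance_threshold Dominant-ancestry cut-off defining an admixed
#'   profile (default 0.75).
#' @param site_majority Fraction of a site's samples that must be admixed
#'   (default 0.5, i.e. "most samples"; strictly greater than).
#' @return A `signal_result`; evidence lists flagged sites, per-site
#'   admixed fractions, and sites excluded for having fewer than 2 samples.
#' @export
detect_signal2 <- function(fit, site_assignment, dominance_threshold = 0.75,
                           site_majority = 0.5) {
  stopifnot(inherits(fit, "admixture_fit"))
  if (fit$K < 2L)
    return(signal_result("not_assessable", list(reason = "K < 2")))
  site_assignment <- as.character(site_assignment)
  Q <- fit$Q
  sites <- unique(site_assignment)
  counts <- table(factor(site_assignment, levels = sites))
  small <- names(counts)[counts < 2L]
  eligible <- setdiff(sites, small)
  modal <- site_modal_component(Q, factor(site_assignment, levels = sites))
  dom_coef <- apply(Q, 1L, max)
  flagged <- character(0)
  admixed_frac <- stats::setNames(numeric(length(eligible)), eligible)
  for (s in eligible) {
    rows <- site_assignment == s
    frac <- mean(dom_coef[rows] <= dominance_threshold)
    admixed_frac[s] <- frac
    if (frac <= site_majority) next
    mean_anc <- colMeans(Q[rows, , drop = FALSE])
    top2 <- order(mean_anc, decreasing = TRUE)[1:2]
    others_modal <- modal[setdiff(sites, s)]
    if (all(top2 %in% others_modal)) flagged <- c(flagged, s)
  }
  signal_result(if (length(flagged)) "detected" else "not_detected",
                list(flagged_sites = flagged, admixed_fraction = admixed_frac,
                     excluded_small_sites = small,
                     dominance_threshold = dominance_threshold,
                     site_majority = site_majority))
}

#' Signal 3: within-site genomic outliers
#'
#' Flags samples whose genotype is foreign to their own site: the sample's
#' dominant ancestry component differs from its site's modal component with
#' a dominant coefficient of at least `foreign_dominance`, and its nearest
#' site centroid in PCA score space (first 3 axes, Euclidean) is not its
#' own site. Requiring agreement of both the model-based and ordination
#' views guards against assignment-algorithm artefacts on sparse sampling.
#'
#' @param fit An `admixture_fit` (`K >= 2` required to assess).
#' @param pca A `pca_result` over the same samples.
#' @param site_assignment One site code per sample.
#' @param foreign_dominance Minimum dominant coefficient of the foreign
#'   component (default 0.60; a sample at 0.55 is not flagged).
#' @return A `signal_result`; evidence lists the flagged sample ids and,
#'   per flagged sample, its dominant component, coefficient, and nearest
#'   PCA site.
#' @export
detect_signal3 <- function(fit, pca, site_assignment, foreign_dominance = 0.60) {
  stopifnot(inherits(fit, "admixture_fit"), inherits(pca, "pca_result"))
  if (fit$K < 2L)
    return(signal_result("not_assessable", list(reason = "K < 2")))
  site_assignment <- as.character(site_assignment)
  Q <- fit$Q
  sites <- unique(site_assignment)
  modal <- site_modal_component(Q, factor(site_assignment, levels = sites))
  dom <- max.col(Q, ties.method = "first")
  dom_coef <- Q[cbind(seq_len(nrow(Q)), dom)]
  n_axes <- min(3L, ncol(pca$scores))
  sc <- pca$scores[, seq_len(n_axes), drop = FALSE]
  centroids <- do.call(rbind, lapply(sites, function(s)
    colMeans(sc[site_assignment == s, , drop = FALSE])))
  rownames(centroids) <- sites
  outliers <- list()
  for (i in seq_len(nrow(Q))) {
    s <- site_assignment[i]
    admix_foreign <- dom[i] != modal[[s]] && dom_coef[i] >= foreign_dominance
    if (!admix_foreign) next
    # leave-one-out centroid for the sample's own site
    cent <- centroids
    own <- site_assignment == s & seq_len(nrow(Q)) != i
    if (any(own)) cent[s, ] <- colMeans(sc[own, , drop = FALSE])
    dists <- sqrt(rowSums(sweep(cent, 2L, sc[i, ])^2))
    nearest <- sites[which.min(dists)]
    if (nearest != s) {
      outliers[[length(outliers) + 1L]] <- data.frame(
        sample_id = (rownames(Q) %||% as.character(seq_len(nrow(Q))))[i],
        site = s, dominant_component = dom[i],
        dominant_coefficient = dom_coef[i], nearest_pca_site = nearest,
        stringsAsFactors = FALSE)[1, ]
    }
  }
  ev <- list(outliers = if (length(outliers)) do.call(rbind, outliers) else NULL,
             foreign_dominance = foreign_dominance)
  signal_result(if (length(outliers)) "detected" else "not_detected", ev)
}
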