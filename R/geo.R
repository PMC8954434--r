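#' Great-circle distances between sites
#'
#' Haversine great-circle distances (Earth radius 6371.0088 km) between site
#' centroids. Each site's coordinate is the mean of its samples'
#' coordinates.
#'
#' @param meta A [sample_metadata()] data frame.
#' @param sites Optional site ordering; defaults to order of first
#'   appearance in `meta`.
#' @return Symmetric site-by-site matrix of distances in km with zero
#'   diagonal.
#' @export
geographic_distances <- function(meta, sites = unique(meta$site_code)) {
  missing_sites <- sites[!sites %in% meta$site_code]
  if (length(missing_sites))
    ds_stop(paste0("no metadata for site(s): ",
                   paste(missing_sites, collapse = ", ")), "ds_invalid")
  cent <- do.call(rbind, lapply(sites, function(s) {
    rows <- meta[meta$site_code == s, ]
    if (any(is.na(rows$latitude)) || any(is.na(rows$longitude)))
      ds_stop(paste0("missing coordinates for site ", s), "ds_invalid")
    c(lon = mean(rows$longitude), lat = mean(rows$latitude))
  }))
  k <- length(sites)
  d <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      d[i, j] <- d[j, i] <- geosphere::distHaversine(
        cent[i, ], cent[j, ], r = 6371.0088)
    }
  }
  d
}

#' Bin pairwise Fst by geographic distance
#'
#' Averages the pairwise Fst values of site pairs falling into half-open
#' distance bins `(lower, upper]` of width `bin_width` km from 0 to
#' `max_km`; a pair at exactly a bin boundary falls in the lower bin. Pairs
#' beyond `max_km` are excluded and counted in the report. A pooled
#' `pooled_lower`-`max_km` display bin is also returned (sparse
#' long-distance classes are conventionally plotted together).
#'
#' @param fst An `fst_matrix` from [pairwise_fst()].
#' @param dists Site-by-site distance matrix (km) sharing `fst`'s site
#'   order.
#' @param bin_width Bin width in km (default 50).
#' @param max_km Maximum distance considered (default 700).
#' @param pooled_lower Lower edge of the pooled display bin (default 300).
#' @return An object of class `binned_fst`: data frame `bins` with columns
#'   `lower`, `upper`, `mean_fst`, `n_pairs`; `pooled` (one-row data frame
#'   for the pooled bin); `n_excluded` pairs beyond `max_km`.
#' @export
bin_fst_by_distance <- function(fst, dists, bin_width = 50, max_km = 700,
                                pooled_lower = 300) {
  stopifnot(inherits(fst, "fst_matrix"))
  if (!all(dim(dists) == dim(fst$values)))
    ds_stop("distance matrix dimensions must match the Fst matrix", "ds_invalid")
  pairs <- upper_pairs(length(fst$site_codes))
  pf <- fst$values[pairs]
  pd <- dists[pairs]
  ok <- !is.na(pf)
  pf <- pf[ok]; pd <- pd[ok]
  in_range <- pd <= max_km
  n_excluded <- sum(!in_range)
  pf <- pf[in_range]; pd <- pd[in_range]
  edges <- seq(0, max_km, by = bin_width)
  # (lower, upper]: exactly-on-boundary pairs fall in the lower bin
  bin_idx <- findInterval(pd, edges, left.open = TRUE, rightmost.closed = FALSE)
  bin_idx[pd <= 0] <- 1L
  bins <- data.frame(lower = edges[-length(edges)], upper = edges[-1])
  bins$mean_fst <- vapply(seq_len(nrow(bins)), function(b)
    if (any(bin_idx == b)) mean(pf[bin_idx == b]) else NA_real_, numeric(1))
  bins$n_pairs <- vapply(seq_len(nrow(bins)), function(b)
    sum(bin_idx == b), integer(1))
  pooled_mask <- pd > pooled_lower
  pooled <- data.frame(lower = pooled_lower, upper = max_km,
                       mean_fst = if (any(pooled_mask)) mean(pf[pooled_mask]) else NA_real_,
                       n_pairs = sum(pooled_mask))
  structure(list(bins = bins, pooled = pooled, n_excluded = n_excluded),
            class = "binned_fst")
}
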