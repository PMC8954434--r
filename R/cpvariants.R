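#' Chloroplast variant table
#'
#' Per-variant, per-sample calls from read mapping of whole-plastid
#' libraries against an annotated reference, with the coverage and consensus
#' metadata needed for quality filtering.
#'
#' @param variants Data frame with one row per variant and columns:
#'   `position` (1-based on the reference), `alleles` (e.g. `"A/G"`),
#'   `annotation` (one of `"non_coding"`, `"synonymous"`, `"non_synonymous"`;
#'   optional unless non-synonymous filtering is requested).
#' @param calls Character matrix (variants x samples) of called alleles,
#'   `NA` for missing.
#' @param coverage Numeric matrix (variants x samples) of read depths.
#' @param consensus Numeric matrix (variants x samples) of read consensus
#'   fractions in `[0, 1]`.
#' @return An object of class `cp_variant_table`.
#' @export
cp_variant_table <- function(variants, calls, coverage, consensus) {
  variants <- as.data.frame(variants)
  if (!all(c("position", "alleles") %in% names(variants)))
    ds_stop("variants must have 'position' and 'alleles' columns", "ds_invalid")
  n <- nrow(variants)
  for (nm in c("calls", "coverage", "consensus")) {
    m <- get(nm)
    if (nrow(m) != n)
      ds_stop(paste(nm, "row count does not match variants"), "ds_invalid")
  }
  if (any(coverage < 0, na.rm = TRUE))
    ds_stop("coverage must be non-negative", "ds_invalid")
  if (any(consensus < 0 | consensus > 1, na.rm = TRUE))
    ds_stop("consensus fractions must lie in [0, 1]", "ds_invalid")
  structure(list(variants = variants, calls = as.matrix(calls),
                 coverage = as.matrix(coverage), consensus = as.matrix(consensus)),
            class = "cp_variant_table")
}

#' @export
print.cp_variant_table <- function(x, ...) {
  cat(sprintf("cp_variant_table: %d variants x %d samples\n",
              nrow(x$variants), ncol(x$calls)))
  invisible(x)
}

#' Quality-filter chloroplast variants
#'
#' Applies the sequencing-error filters used for plastid variant tables:
#' per-sample calls with read coverage below `min_coverage` or consensus
#' below `min_consensus` are set to missing (boundary values are retained),
#' and variants annotated as non-synonymous in coding regions are removed
#' outright as likely mapping or sequencing artefacts.
#'
#' @param tbl A [cp_variant_table()].
#' @param min_coverage Minimum read depth for a call to be kept (default 8;
#'   calls with coverage `< 8` are masked).
#' @param min_consensus Minimum read consensus fraction (default 0.60).
#' @param drop_nonsynonymous Remove variants annotated `"non_synonymous"`
#'   (default `TRUE`; requires the `annotation` column).
#' @param scope `"per_call"` (default) masks individual sample calls
#'   failing the coverage/consensus thresholds; `"per_variant"` applies
#'   the thresholds to each variant's across-sample means and removes
#'   failing variants outright.
#' @return The filtered `cp_variant_table` with a `filter_report` attribute
#'   (variants removed, calls masked).
#' @export
filter_cp_variants <- function(tbl, min_coverage = 8, min_consensus = 0.60,
                               drop_nonsynonymous = TRUE,
                               scope = c("per_call", "per_variant")) {
  stopifnot(inherits(tbl, "cp_variant_table"))
  scope <- match.arg(scope)
  if (drop_nonsynonymous && !"annotation" %in% names(tbl$variants))
    ds_stop("annotation column required when drop_nonsynonymous = TRUE",
            "ds_config")
  keep <- rep(TRUE, nrow(tbl$variants))
  if (drop_nonsynonymous)
    keep <- tbl$variants$annotation != "non_synonymous"
  if (scope == "per_variant") {
    bad <- rowMeans(tbl$coverage, na.rm = TRUE) < min_coverage |
      rowMeans(tbl$consensus, na.rm = TRUE) < min_consensus
    keep <- keep & !bad
    mask <- matrix(FALSE, nrow(tbl$variants), ncol(tbl$calls))
    if (!any(keep))
      ds_stop("all variants removed by filtering", "ds_empty")
  } else {
    mask <- (tbl$coverage < min_coverage) | (tbl$consensus < min_consensus)
    mask[is.na(mask)] <- TRUE
  }
  calls <- tbl$calls
  calls[mask] <- NA
  out <- cp_variant_table(tbl$variants[keep, , drop = FALSE],
                          calls[keep, , drop = FALSE],
                          tbl$coverage[keep, , drop = FALSE],
                          tbl$consensus[keep, , drop = FALSE])
  attr(out, "filter_report") <- list(
    n_input = length(keep), n_kept = sum(keep),
    n_removed_nonsynonymous = sum(!keep),
    n_calls_masked = sum(mask[keep, , drop = FALSE] & !is.na(tbl$calls[keep, , drop = FALSE])))
  out
}
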