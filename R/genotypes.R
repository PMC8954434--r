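#' Diploid SNP genotype matrix
#'
#' Container for diploid biallelic genotype calls coded as the count of the
#' alternate (or derived) allele: 0, 1, 2, with `NA` for missing. Rows are
#' samples, columns are loci. Optional per-locus quality metadata follow the
#' conventions of reduced-representation genotyping platforms (DArTseq):
#' `reproducibility` is the fraction of technical replicate pairs with a
#' consistent score, `call_rate` the fraction of samples with a non-missing
#' call.
#'
#' @param calls Integer matrix (samples x loci) with values in `{0, 1, 2, NA}`.
#' @param sample_ids Character vector of row identifiers (defaults to
#'   `rownames(calls)`).
#' @param locus_ids Character vector of column identifiers (defaults to
#'   `colnames(calls)`).
#' @param reproducibility Optional numeric vector in `[0, 1]`, one per locus.
#' @param call_rate Optional numeric vector in `[0, 1]`, one per locus. If
#'   omitted it can be recomputed from `calls` via [locus_call_rate()].
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            locus_ids = colnames(calls),
                            reproducibility = NULL, call_rate = NULL) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(calls)))
  if (is.null(locus_ids)) locus_ids <- paste0("locus", seq_len(ncol(calls)))
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (length(sample_ids) != nrow(calls))
    ds_stop("sample_ids length does not match number of rows", "ds_invalid")
  if (length(locus_ids) != ncol(calls))
    ds_stop("locus_ids length does not match number of columns", "ds_invalid")
  if (anyDuplicated(sample_ids))
    ds_stop(paste0("duplicate sample ids: ",
                   paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
            "ds_parse")
  if (anyDuplicated(locus_ids))
    ds_stop(paste0("duplicate locus ids: ",
                   paste(utils::head(unique(locus_ids[duplicated(locus_ids)]), 5), collapse = ", ")),
            "ds_parse")
  storage.mode(calls) <- "integer"
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad))
    ds_stop("genotype calls must be 0, 1, 2 or NA", "ds_invalid")
  dimnames(calls) <- list(sample_ids, locus_ids)
  for (nm in c("reproducibility", "call_rate")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != ncol(calls))
        ds_stop(paste(nm, "length does not match number of loci"), "ds_invalid")
      if (any(!is.na(v) & (v < 0 | v > 1)))
        ds_stop(paste(nm, "values must lie in [0, 1]"), "ds_invalid")
      v <- as.numeric(v)
      names(v) <- locus_ids
      assign(nm, v)
    }
  }
  structure(list(calls = calls, sample_ids = sample_ids, locus_ids = locus_ids,
                 reproducibility = reproducibility, call_rate = call_rate),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  if (!is.null(x$reproducibility)) cat("  per-locus reproducibility present\n")
  if (!is.null(x$call_rate)) cat("  per-locus call rate present\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Observed per-locus call rate
#'
#' Fraction of samples with a non-missing call at each locus.
#'
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector, one value per locus.
#' @export
locus_call_rate <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  colMeans(!is.na(gm$calls))
}

#' Subset a genotype matrix by loci and/or samples
#'
#' @param gm A [genotype_matrix()].
#' @param loci Locus ids or indices to keep (default all).
#' @param samples Sample ids or indices to keep (default all).
#' @return A `genotype_matrix` restricted to the requested entries; metadata
#'   vectors are subset in step. Ordering of the retained entries follows the
#'   original matrix, never the request, so no operation reorders samples.
#' @export
subset_genotypes <- function(gm, loci = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  li <- seq_along(gm$locus_ids)
  si <- seq_along(gm$sample_ids)
  if (!is.null(loci)) {
    li <- if (is.character(loci)) which(gm$locus_ids %in% loci) else sort(unique(as.integer(loci)))
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) which(gm$sample_ids %in% samples) else sort(unique(as.integer(samples)))
  }
  genotype_matrix(gm$calls[si, li, drop = FALSE],
                  sample_ids = gm$sample_ids[si], locus_ids = gm$locus_ids[li],
                  reproducibility = gm$reproducibility[li],
                  call_rate = gm$call_rate[li])
}

#' Read a genotype matrix from file
#'
#' Supports two dialects: `"dart_csv"`, a CSV with samples in columns and
#' marker rows (either one row per locus scored 0/1/2, or two presence/absence
#' rows per locus that are collapsed to a 0/1/2 dosage), and `"vcf"`, a
#' VCF v4.x file with diploid `GT` fields parsed via the vcfR package.
#' Gzip-compressed files are accepted for both dialects.
#'
#' For the DArT dialect the file must contain the columns `locus_id` and
#' optionally `reproducibility`, `call_rate` and (two-row encoding)
#' `allele_row` with values `ref`/`snp`; remaining columns are samples.
#' Two-row pairs where presence/absence scores conflict (both absent) are set
#' to missing.
#'
#' @param path File path.
#' @param dialect One of `"dart_csv"`, `"vcf"`.
#' @param multiallelic For VCF input: `"reject"` (default, error on records
#'   with more than one ALT allele) or `"drop"` (silently skip them).
#' @return A [genotype_matrix()]. Sample and locus order follow the file.
#' @export
read_genotypes <- function(path, dialect = c("dart_csv", "vcf"),
                           multiallelic = c("reject", "drop")) {
  dialect <- match.arg(dialect)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) ds_stop(paste0("file not found: ", path), "ds_io")
  switch(dialect,
         dart_csv = read_dart_csv(path),
         vcf = read_vcf_genotypes(path, multiallelic))
}

read_dart_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"locus_id" %in% names(df))
    ds_stop("DArT CSV must contain a 'locus_id' column", "ds_parse")
  meta_cols <- intersect(c("locus_id", "allele_row", "reproducibility", "call_rate"),
                         names(df))
  sample_cols <- setdiff(names(df), meta_cols)
  if (length(sample_cols) == 0L)
    ds_stop("DArT CSV has no sample columns", "ds_parse")
  two_row <- "allele_row" %in% names(df)
  if (two_row) {
    loci <- unique(df$locus_id)
    calls <- matrix(NA_integer_, length(sample_cols), length(loci),
                    dimnames = list(sample_cols, loci))
    rep_v <- rep(NA_real_, length(loci))
    cr_v <- rep(NA_real_, length(loci))
    for (j in seq_along(loci)) {
      rows <- df[df$locus_id == loci[j], , drop = FALSE]
      if (nrow(rows) != 2L || !setequal(rows$allele_row, c("ref", "snp")))
        ds_stop(paste0("locus ", loci[j],
                       ": two-row encoding requires one 'ref' and one 'snp' row"),
                "ds_parse")
      ref <- as.integer(rows[rows$allele_row == "ref", sample_cols])
      snp <- as.integer(rows[rows$allele_row == "snp", sample_cols])
      # presence/absence pair -> dosage of the SNP allele; (0,0) is a
      # conflicting (failed) pair and is recorded missing.
      g <- ifelse(is.na(ref) | is.na(snp), NA_integer_,
                  ifelse(ref == 1L & snp == 0L, 0L,
                         ifelse(ref == 1L & snp == 1L, 1L,
                                ifelse(ref == 0L & snp == 1L, 2L, NA_integer_))))
      calls[, j] <- g
      if ("reproducibility" %in% names(rows)) rep_v[j] <- mean(rows$reproducibility)
      if ("call_rate" %in% names(rows)) cr_v[j] <- mean(rows$call_rate)
    }
    genotype_matrix(calls,
                    reproducibility = if (all(is.na(rep_v))) NULL else rep_v,
                    call_rate = if (all(is.na(cr_v))) NULL else cr_v)
  } else {
    vals <- as.matrix(df[, sample_cols, drop = FALSE])
    bad <- !(vals %in% c("0", "1", "2", NA, "", "NA", 0, 1, 2))
    if (any(bad)) {
      i <- which(bad)[1L]
      ds_stop(sprintf("unknown genotype code '%s' at marker row %d",
                      vals[i], (i - 1L) %% nrow(vals) + 1L), "ds_parse")
    }
    vals[vals %in% c("", "NA")] <- NA
    calls <- t(apply(vals, c(1, 2), as.integer))
    dimnames(calls) <- list(sample_cols, df$locus_id)
    genotype_matrix(calls,
                    reproducibility = df$reproducibility,
                    call_rate = df$call_rate)
  }
}

read_vcf_genotypes <- function(path, multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    if (multiallelic == "reject")
      ds_stop(sprintf("multiallelic record(s) at %s; set multiallelic='drop' to skip",
                      paste(utils::head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 3),
                            collapse = ", ")), "ds_parse")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  code_gt <- function(g) {
    g <- sub(":.*", "", g)
    alleles <- strsplit(g, "[/|]")
    vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == "."))
        return(NA_integer_)
      ai <- suppressWarnings(as.integer(a))
      if (any(is.na(ai)) || any(ai > 1L))
        return(NA_integer_)
      sum(ai)
    }, integer(1))
  }
  mixed <- grepl("^[0-9.]+$", gt) & !is.na(gt)  # haploid-looking entries
  if (any(mixed))
    ds_stop("mixed or non-diploid GT field encountered in VCF", "ds_parse")
  calls <- apply(gt, 2L, code_gt)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1L)
  calls <- t(calls)  # samples x loci
  dimnames(calls) <- list(colnames(gt), ids)
  genotype_matrix(calls)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF v4.2 file with one biallelic record per locus (REF `A`,
#' ALT `T` placeholders when no allele information is carried) and diploid
#' unphased `GT` fields. Loci are written on a single synthetic contig in
#' matrix column order.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @param chrom Contig name used for all records.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path, chrom = "sim1") {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", chrom),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_along(gm$locus_ids)) {
    g <- gm$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    writeLines(paste(c(chrom, j, gm$locus_ids[j], "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a genotype matrix as a DArT-style CSV
#'
#' One marker row per locus scored 0/1/2 with samples in columns, plus
#' `reproducibility` and `call_rate` metadata columns when present.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_dart <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.frame(locus_id = gm$locus_ids, stringsAsFactors = FALSE)
  if (!is.null(gm$reproducibility)) df$reproducibility <- unname(gm$reproducibility)
  if (!is.null(gm$call_rate)) df$call_rate <- unname(gm$call_rate)
  df <- cbind(df, as.data.frame(t(gm$calls)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter loci on platform quality metadata
#'
#' Retains loci whose reproducibility and call rate both meet their
#' thresholds (boundary values are kept). Call rate is recomputed from the
#' observed calls when absent; reproducibility cannot be recomputed, so an
#' active reproducibility threshold with no metadata is an error. Samples are
#' never dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param min_reproducibility Minimum reproducibility average (default 0.96).
#'   Set to `NULL` or 0 to disable.
#' @param min_call_rate Minimum call rate (default 0.80).
#' @return The filtered `genotype_matrix`, with a `filter_report` attribute:
#'   a list with kept/dropped counts per criterion.
#' @export
filter_markers <- function(gm, min_reproducibility = 0.96, min_call_rate = 0.80) {
  stopifnot(inherits(gm, "genotype_matrix"))
  for (thr in c(min_reproducibility, min_call_rate))
    if (!is.null(thr) && (thr < 0 || thr > 1))
      ds_stop("thresholds must lie in [0, 1]", "ds_invalid")
  n <- length(gm$locus_ids)
  cr <- gm$call_rate %||% locus_call_rate(gm)
  fail_cr <- if (is.null(min_call_rate)) rep(FALSE, n) else cr < min_call_rate
  if (!is.null(min_reproducibility) && min_reproducibility > 0) {
    if (is.null(gm$reproducibility))
      ds_stop("reproducibility metadata absent but min_reproducibility is active",
              "ds_config")
    fail_rep <- gm$reproducibility < min_reproducibility
  } else {
    fail_rep <- rep(FALSE, n)
  }
  keep <- !(fail_rep | fail_cr)
  if (!any(keep))
    ds_stop("all loci removed by marker filtering", "ds_empty")
  out <- subset_genotypes(gm, loci = which(keep))
  attr(out, "filter_report") <- list(
    n_input = n, n_kept = sum(keep),
    n_fail_reproducibility = sum(fail_rep),
    n_fail_call_rate = sum(fail_cr),
    n_fail_both = sum(fail_rep & fail_cr))
  out
}
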