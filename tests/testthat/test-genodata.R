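# IO, validation and quality filtering.

make_qc_gm <- function() {
  # 10 loci: 3 fail reproducibility only, 2 fail call rate only, 1 fails
  # both, 4 pass
  set.seed(3)
  calls <- matrix(sample(c(0L, 1L, 2L), 60, replace = TRUE), 6, 10)
  rep_v <- c(0.99, 0.95, 0.99, 0.90, 0.99, 0.80, 0.99, 0.96, 0.99, 0.50)
  cr_v <- c(0.99, 0.99, 0.70, 0.99, 0.75, 0.99, 0.99, 0.80, 0.99, 0.60)
  genotype_matrix(calls, reproducibility = rep_v, call_rate = cr_v)
}

test_that("marker filter keeps exactly the loci passing both thresholds", {
  gm <- make_qc_gm()
  out <- filter_markers(gm)
  expect_equal(ncol(out$calls), 4L)
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_fail_reproducibility, 4L)  # 3 rep-only + 1 both
  expect_equal(rep$n_fail_call_rate, 3L)        # 2 cr-only + 1 both
  expect_equal(rep$n_fail_both, 1L)
  expect_equal(nrow(out$calls), 6L)             # samples untouched
})

test_that("filter boundaries are inclusive: 0.96 / 0.80 kept, 0.79 dropped", {
  calls <- matrix(0:2, 3, 3)
  gm <- genotype_matrix(calls, reproducibility = c(0.96, 0.96, 0.99),
                        call_rate = c(0.80, 0.79, 0.99))
  out <- filter_markers(gm)
  expect_equal(out$locus_ids, gm$locus_ids[c(1, 3)])
})

test_that("marker filtering is idempotent and monotone in thresholds", {
  gm <- make_qc_gm()
  once <- filter_markers(gm)
  twice <- filter_markers(once)
  expect_identical(once$calls, twice$calls)
  loose <- filter_markers(gm, min_call_rate = 0.5)
  strict <- filter_markers(gm, min_call_rate = 0.9)
  expect_true(all(strict$locus_ids %in% loose$locus_ids))
})

test_that("marker filter errors are explicit", {
  gm <- make_qc_gm()
  expect_error(filter_markers(gm, min_reproducibility = 1, min_call_rate = 1),
               class = "ds_empty")
  gm2 <- genotype_matrix(matrix(0:2, 3, 3))
  expect_error(filter_markers(gm2), class = "ds_config")  # no reproducibility
  # call rate recomputed when absent
  out <- filter_markers(gm2, min_reproducibility = NULL)
  expect_equal(ncol(out$calls), 3L)
})

test_that("DArT CSV round-trips a genotype matrix exactly", {
  set.seed(5)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 40, TRUE), 5, 8)
  gm <- genotype_matrix(calls, reproducibility = runif(8, 0.9, 1),
                        call_rate = locus_call_rate(genotype_matrix(calls)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes_dart(gm, path)
  back <- read_genotypes(path, "dart_csv")
  expect_identical(back$calls, gm$calls)
  expect_equal(back$reproducibility, gm$reproducibility)
})

test_that("two-row DArT encoding collapses to dosages with conflicts missing", {
  df <- data.frame(
    locus_id = rep(c("L1", "L2"), each = 2),
    allele_row = rep(c("ref", "snp"), 2),
    s1 = c(1L, 0L, 1L, 1L),   # L1: ref only -> 0 ; L2: both -> 1
    s2 = c(0L, 1L, 0L, 0L),   # L1: snp only -> 2 ; L2: neither -> NA
    s3 = c(1L, 1L, NA, 0L))   # L1: both -> 1    ; L2: NA -> NA
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  gm <- read_genotypes(path, "dart_csv")
  expect_equal(unname(gm$calls[, "L1"]), c(0L, 2L, 1L))
  expect_equal(unname(gm$calls[, "L2"]), c(1L, NA, NA))
})

test_that("an all-missing sample is retained, not silently dropped", {
  df <- data.frame(locus_id = c("L1", "L2"), s1 = c(0L, 1L), s2 = c(NA, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  gm <- read_genotypes(path, "dart_csv")
  expect_equal(nrow(gm$calls), 2L)
  expect_true(all(is.na(gm$calls["s2", ])))
})

test_that("VCF diploid GT fields are encoded as alternate-allele dosage", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "a", "b", "c"), collapse = "\t"),
           paste(c("chr1", "5", "snp1", "A", "T", ".", "PASS", ".", "GT",
                   "0/0", "0/1", "1/1"), collapse = "\t"),
           paste(c("chr1", "9", "snp2", "G", "C", ".", "PASS", ".", "GT",
                   "0|1", "./.", "1/1"), collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gm <- read_genotypes(path, "vcf")
  expect_equal(unname(gm$calls[, "snp1"]), c(0L, 1L, 2L))
  expect_equal(unname(gm$calls[, "snp2"]), c(1L, NA, 2L))
  expect_equal(gm$sample_ids, c("a", "b", "c"))
})

test_that("VCF writing round-trips simulated calls", {
  cfg <- quick_config(seed = 31)
  ds <- simulate_dataset(cfg, include_cp = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(ds$genotype_matrix, path)
  back <- read_genotypes(path, "vcf")
  expect_identical(unname(back$calls), unname(ds$genotype_matrix$calls))
})

test_that("multiallelic VCF records are rejected or dropped per config", {
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "a", "b"), collapse = "\t"),
           paste(c("chr1", "5", "m1", "A", "T,G", ".", "PASS", ".", "GT",
                   "0/0", "0/1"), collapse = "\t"),
           paste(c("chr1", "9", "s1", "G", "C", ".", "PASS", ".", "GT",
                   "0/1", "1/1"), collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_error(read_genotypes(path, "vcf"), class = "ds_parse")
  gm <- read_genotypes(path, "vcf", multiallelic = "drop")
  expect_equal(gm$locus_ids, "s1")
})

test_that("duplicate sample ids are a parse error", {
  expect_error(genotype_matrix(matrix(0L, 2, 2), sample_ids = c("a", "a")),
               class = "ds_parse")
})

test_that("cp variant filter applies coverage, consensus and annotation rules", {
  # 6 variants x 2 samples: variant 2 non-synonymous (removed), variant 4
  # below coverage everywhere (all-missing), boundary variant 1 retained
  variants <- data.frame(position = 1:6, alleles = "A/G",
                         annotation = c("synonymous", "non_synonymous",
                                        "non_coding", "synonymous",
                                        "non_coding", "synonymous"))
  calls <- matrix("A", 6, 2)
  coverage <- matrix(20, 6, 2)
  coverage[1, ] <- 8          # boundary: kept
  coverage[4, ] <- 7          # below: masked everywhere
  consensus <- matrix(0.9, 6, 2)
  consensus[1, ] <- 0.60      # boundary: kept
  consensus[5, 2] <- 0.59     # one call masked
  tbl <- cp_variant_table(variants, calls, coverage, consensus)
  out <- filter_cp_variants(tbl)
  expect_equal(nrow(out$variants), 5L)             # non-synonymous removed
  expect_false(2 %in% out$variants$position)
  expect_true(all(is.na(out$calls[out$variants$position == 4, ])))
  expect_false(anyNA(out$calls[out$variants$position == 1, ]))
  expect_true(is.na(out$calls[out$variants$position == 5, 2]))
  expect_equal(attr(out, "filter_report")$n_removed_nonsynonymous, 1L)
})

test_that("per-variant scope removes variants failing on aggregate", {
  variants <- data.frame(position = 1:3, alleles = "A/G")
  coverage <- rbind(c(20, 20), c(5, 6), c(20, 2))   # means 20, 5.5, 11
  consensus <- matrix(0.9, 3, 2)
  tbl <- cp_variant_table(variants, matrix("A", 3, 2), coverage, consensus)
  out <- filter_cp_variants(tbl, drop_nonsynonymous = FALSE,
                            scope = "per_variant")
  expect_equal(out$variants$position, c(1L, 3L))
  expect_false(anyNA(out$calls))  # aggregate scope never masks single calls
})

test_that("cp variant filtering is idempotent and checks configuration", {
  variants <- data.frame(position = 1:2, alleles = "A/G")
  tbl <- cp_variant_table(variants, matrix("A", 2, 2), matrix(10, 2, 2),
                          matrix(0.9, 2, 2))
  expect_error(filter_cp_variants(tbl), class = "ds_config")
  out1 <- filter_cp_variants(tbl, drop_nonsynonymous = FALSE)
  out2 <- filter_cp_variants(out1, drop_nonsynonymous = FALSE)
  expect_identical(out1$calls, out2$calls)
})

test_that("alignment IO enforces equal lengths and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTAC", ">s3", "ACGTACGTAC"),
             path)
  aln <- read_alignment(path)
  expect_equal(dim(aln), c(3L, 10L))
  writeLines(c(">s1", "ACGT", ">s2", "ACG", ">s3", "ACGT"), path)
  expect_error(read_alignment(path), "s2", class = "ds_parse")
  # gapped column retained, reported in ambiguity counts
  writeLines(c(">s1", "AC-T", ">s2", "ACGT"), path)
  aln2 <- read_alignment(path)
  expect_equal(ncol(aln2), 4L)
  expect_equal(unname(attr(aln2, "ambiguity_report")["s1"]), 1)
  # round trip of a simulated cp alignment
  ds <- simulate_dataset(quick_config(seed = 12, cp_sequence_length = 500))
  write_alignment(ds$cp_alignment, path)
  back <- read_alignment(path)
  expect_equal(unclass(back)[, ], unclass(ds$cp_alignment)[, ],
               ignore_attr = TRUE)
})

test_that("sample metadata validation catches bad coordinates", {
  df <- data.frame(sample_id = "a", site_code = "X", latitude = 95,
                   longitude = 0)
  expect_error(sample_metadata(df), class = "ds_invalid")
})
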