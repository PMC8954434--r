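# Decision matrix, cohort screening, trait-group summaries.

sig <- function(s) signal_result(s)

traits_tbl <- function() species_traits(data.frame(
  species_id = c("big", "small"),
  max_fruit_width_mm = c(45, 12),
  dispersal_class = "fleshy",
  indigenous_use = c(TRUE, FALSE)))

test_that("fruit-size classes derive from the 30 mm boundary inclusively", {
  tr <- species_traits(data.frame(species_id = c("a", "b", "c"),
                                  max_fruit_width_mm = c(30, 29.9, 62),
                                  dispersal_class = "fleshy",
                                  indigenous_use = FALSE))
  expect_equal(tr$fruit_size_class, c("large", "small", "large"))
  expect_error(species_traits(data.frame(species_id = "a",
                                         max_fruit_width_mm = -1,
                                         dispersal_class = "fleshy",
                                         indigenous_use = TRUE)),
               class = "ds_invalid")
})

test_that("profiles aggregate detector outputs losslessly", {
  p <- assemble_profile("big", sig("detected"), sig("not_detected"), NULL,
                        NULL)
  expect_equal(p$signal1$signal, "detected")
  expect_equal(p$signal3$signal, "not_assessable")
  expect_equal(p$signal4$signal, "not_assessable")
  # four not_assessable inputs still classify
  p0 <- assemble_profile("big", NULL, NULL, NULL, NULL)
  r0 <- classify_species(p0, traits_tbl())
  expect_equal(r0$n_detected, 0L)
  expect_false(r0$candidate)
})

test_that("the candidate rule follows the expected-pattern matrix", {
  tr <- traits_tbl()
  # large fruit, signals 1+2: candidate (the southern-range staple-food case)
  r <- classify_species(assemble_profile("big", sig("detected"),
                                         sig("detected"), sig("not_detected"),
                                         sig("not_detected")), tr)
  expect_true(r$candidate)
  expect_equal(r$history_label, "post_isolation_dispersal")
  # large fruit, only the haplotype-LDD signal: still a candidate
  r2 <- classify_species(assemble_profile("big", sig("not_detected"),
                                          sig("not_detected"),
                                          sig("not_detected"),
                                          sig("detected")), tr)
  expect_true(r2$candidate)
  # small fruit with three signals: never a candidate (faunal vectors
  # cannot be excluded)
  r3 <- classify_species(assemble_profile("small", sig("detected"),
                                          sig("detected"),
                                          sig("not_detected"),
                                          sig("detected")), tr)
  expect_false(r3$candidate)
  # large fruit, no signals: long-term isolation
  r4 <- classify_species(assemble_profile("big", sig("not_detected"),
                                          sig("not_detected"),
                                          sig("not_detected"),
                                          sig("not_detected")), tr)
  expect_equal(r4$history_label, "long_term_isolation")
  expect_false(r4$candidate)
  # one nuclear signal only (outliers): not a candidate
  r5 <- classify_species(assemble_profile("big", sig("not_detected"),
                                          sig("not_detected"),
                                          sig("detected"),
                                          sig("not_detected")), tr)
  expect_false(r5$candidate)
  # not_assessable never counts toward the tally
  r6 <- classify_species(assemble_profile("big", sig("detected"),
                                          sig("not_assessable"),
                                          sig("not_assessable"),
                                          sig("not_assessable")), tr)
  expect_equal(r6$n_detected, 1L)
  expect_false(r6$candidate)
})

test_that("classification is a pure function of profile and traits", {
  tr <- traits_tbl()
  p <- assemble_profile("big", sig("detected"), sig("detected"),
                        sig("not_detected"), sig("not_assessable"))
  r1 <- classify_species(p, tr)
  r2 <- classify_species(p, tr)
  expect_identical(r1[setdiff(names(r1), "profile")],
                   r2[setdiff(names(r2), "profile")])
  expect_error(classify_species(assemble_profile("ghost", NULL, NULL, NULL,
                                                 NULL), tr),
               class = "ds_invalid")
})

test_that("an empty cohort produces an empty report without error", {
  rep <- screen_cohort(list(), traits_tbl())
  expect_s3_class(rep, "cohort_report")
  expect_equal(nrow(rep$table), 0L)
  expect_length(rep$errors, 0L)
})

test_that("per-species failures are isolated and reported", {
  tr <- traits_tbl()
  good_cfg <- build_scenario("iso", n_demes = 3, n_nuclear_sites = 8e5,
                             samples_per_deme_nuclear = 6, seed = 61)
  good <- simulate_dataset(good_cfg, include_cp = FALSE)
  bad_gm <- genotype_matrix(matrix(c(0L, 1L, 1L, 2L), 2, 2))
  bad_meta <- sample_metadata(data.frame(
    sample_id = bad_gm$sample_ids, site_code = "only_one",
    latitude = -28, longitude = 153))
  rep <- screen_cohort(
    list(big = list(genotype_matrix = good$genotype_matrix,
                    sample_metadata = good$sample_metadata),
         small = list(genotype_matrix = bad_gm, sample_metadata = bad_meta)),
    tr, config = list(k_max = 3, k_replicates = 2, n_perm = 99), seed = 2)
  expect_equal(rep$table$species_id, "big")
  expect_named(rep$errors, "small")
})

test_that("cohort screening is deterministic under fixed seeds", {
  tr <- traits_tbl()
  ds <- simulate_dataset(build_scenario("iso", n_demes = 3,
                                        n_nuclear_sites = 8e5,
                                        samples_per_deme_nuclear = 6,
                                        seed = 62),
                         include_cp = FALSE)
  datasets <- list(big = list(genotype_matrix = ds$genotype_matrix,
                              sample_metadata = ds$sample_metadata))
  cfgl <- list(k_max = 3, k_replicates = 2, n_perm = 99)
  r1 <- screen_cohort(datasets, tr, config = cfgl, seed = 7)
  r2 <- screen_cohort(datasets, tr, config = cfgl, seed = 7)
  expect_identical(r1$table, r2$table)
})

test_that("trait groups summarise binned Fst in long format", {
  tr <- species_traits(data.frame(
    species_id = c("lfu", "sfu", "lf", "sf", "w"),
    max_fruit_width_mm = c(50, 10, 50, 10, 8),
    dispersal_class = c("fleshy", "fleshy", "fleshy", "fleshy", "wind"),
    indigenous_use = c(TRUE, TRUE, FALSE, FALSE, FALSE)))
  mk_binned <- function(val) {
    bins <- data.frame(lower = c(0, 50), upper = c(50, 100),
                       mean_fst = val, n_pairs = c(2L, 1L))
    structure(list(bins = bins,
                   pooled = data.frame(lower = 300, upper = 700,
                                       mean_fst = NA_real_, n_pairs = 0L),
                   n_excluded = 0L), class = "binned_fst")
  }
  out <- trait_group_fst_summary(
    list(lfu = mk_binned(0.4), sfu = mk_binned(0.1), lf = mk_binned(0.3),
         sf = mk_binned(0.05), w = mk_binned(0.02)), tr)
  expect_setequal(unique(out$trait_group),
                  c("large fleshy, recorded use", "small fleshy, recorded use",
                    "large fleshy", "small fleshy", "wind dispersed"))
  med <- tapply(out$mean_fst, out$trait_group, stats::median)
  expect_equal(unname(med["large fleshy, recorded use"]), 0.4)
  # species with no in-range pairs is omitted with a warning
  empty <- mk_binned(c(NA_real_, NA_real_))
  expect_warning(out2 <- trait_group_fst_summary(
    list(lfu = mk_binned(0.4), sfu = empty), tr), "sfu")
  expect_false("sfu" %in% out2$species_id)
})

test_that("isolation-derived cohorts out-differentiate faunal cohorts per bin", {
  mk <- function(sid, seed) {
    cfg <- build_scenario(sid, n_nuclear_sites = 6e5,
                          samples_per_deme_nuclear = 6, seed = seed)
    ds <- simulate_dataset(cfg, include_cp = FALSE)
    f <- pairwise_fst(ds$genotype_matrix, ds$sample_metadata$site_code)
    d <- geographic_distances(ds$sample_metadata, sites = f$site_codes)
    bin_fst_by_distance(f, d)
  }
  iso_b <- mk("iso", 71)
  fd1_b <- mk("fd1", 72)
  ok <- !is.na(iso_b$bins$mean_fst) & !is.na(fd1_b$bins$mean_fst)
  expect_gt(mean(iso_b$bins$mean_fst[ok] > fd1_b$bins$mean_fst[ok]), 0.5)
})
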