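# Haplotype collapsing, network construction, Signal 4.

aln_from <- function(...) {
  seqs <- c(...)
  haploid_alignment(do.call(rbind, lapply(strsplit(seqs, ""), identity)))
}

test_that("identical sequences collapse to one haplotype", {
  hs <- collapse_haplotypes(aln_from("ACGT", "ACGT", "ACGT", "ACGT"))
  expect_equal(nrow(hs$haplotypes), 1L)
  expect_equal(hs$counts, 4L)
})

test_that("distinct sequences split with correct counts", {
  hs <- collapse_haplotypes(aln_from("AAT", "AAT", "ACT"))
  expect_equal(nrow(hs$haplotypes), 2L)
  expect_equal(sort(hs$counts), c(1L, 2L))
  expect_equal(sum(hs$counts), 3L)
})

test_that("ambiguous sequences merge into the most frequent compatible haplotype", {
  seqs <- c(rep("ACGT", 5), rep("ACGA", 2), "ACGN")
  hs <- collapse_haplotypes(aln_from(seqs))
  expect_equal(nrow(hs$haplotypes), 2L)
  expect_equal(max(hs$counts), 6L)  # the N joined the count-5 haplotype
})

test_that("complete_columns drops unresolved columns, erroring when none remain", {
  aln <- aln_from("A-GT", "ACGT")
  hs <- collapse_haplotypes(aln, missing_policy = "complete_columns")
  expect_equal(ncol(hs$haplotypes), 3L)
  expect_equal(hs$used_columns, c(1L, 3L, 4L))
  allbad <- aln_from("--", "--")
  expect_error(collapse_haplotypes(allbad, missing_policy = "complete_columns"),
               class = "ds_empty")
})

test_that("a single haplotype yields one node and no edges", {
  hs <- collapse_haplotypes(aln_from("ACGT", "ACGT"))
  net <- build_network(hs)
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("a linear series forms a chain without median nodes", {
  hs <- collapse_haplotypes(aln_from("AAA", "AAT", "ATT"))
  net <- build_network(hs)
  expect_equal(nrow(net$nodes), 3L)
  expect_true(all(net$nodes$sampled))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(sort(net$edges$mutations), c(1, 1))
})

test_that("a star around an unsampled centre gains one median node", {
  # four sequences each one mutation from AAAA, pairwise two apart
  hs <- collapse_haplotypes(aln_from("TAAA", "ATAA", "AATA", "AAAT"))
  net <- build_network(hs)
  expect_equal(sum(!net$nodes$sampled), 1L)
  med <- net$sequences[!net$nodes$sampled, ]
  expect_equal(paste(med, collapse = ""), "AAAA")
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(deg[net$nodes$id[!net$nodes$sampled]]), 4L)
  expect_true(all(net$edges$mutations == 1))
})

test_that("median augmentation never lengthens the network (epsilon = 0)", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    mat <- matrix(sample(c("A", "C", "G", "T"), n * 5, TRUE), n, 5)
    mat <- mat[!duplicated(apply(mat, 1, paste, collapse = "")), , drop = FALSE]
    hs <- collapse_haplotypes(haploid_alignment(mat))
    net <- build_network(hs)
    sampled_only <- hs$haplotypes
    D <- matrix(0, nrow(sampled_only), nrow(sampled_only))
    for (i in seq_len(nrow(D))) for (j in seq_len(nrow(D)))
      D[i, j] <- sum(sampled_only[i, ] != sampled_only[j, ])
    expect_lte(network_mst_length(net), dispersalscreen:::mst_length(D))
  }
})

test_that("network length matches exhaustive minimum-length search on tiny cases", {
  cases <- list(
    c("TAAA", "ATAA", "AATA", "AAAT"),
    c("AAA", "AAT", "ATT", "TTT"),
    c("ACGT", "ACGA", "TCGA"),
    c("AACC", "CCAA", "ACAC", "CACA"))
  for (cs in cases) {
    hs <- collapse_haplotypes(aln_from(cs))
    net <- build_network(hs)
    expect_equal(network_mst_length(net),
                 brute_force_min_length(hs$haplotypes))
  }
})

test_that("network construction is deterministic", {
  set.seed(9)
  mat <- matrix(sample(c("A", "T"), 36, TRUE), 6, 6)
  hs <- collapse_haplotypes(haploid_alignment(mat))
  n1 <- build_network(hs)
  n2 <- build_network(hs)
  expect_identical(n1$edges, n2$edges)
  expect_error(build_network(hs, epsilon = 1), class = "ds_config")
})

test_that("network exports are well formed and igraph-readable", {
  hs <- collapse_haplotypes(aln_from("TAAA", "ATAA", "AATA", "AAAT"))
  net <- build_network(hs)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, tsv)
  edges <- utils::read.delim(tsv)
  expect_equal(nrow(edges), nrow(net$edges))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::edge_attr(g, "mutations"), net$edges$mutations)
})

test_that("haplotype counts are conserved per site", {
  ds <- simulate_dataset(quick_config("iso", seed = 41,
                                      cp_sequence_length = 2e4))
  hs <- collapse_haplotypes(ds$cp_alignment)
  site <- ds$sample_metadata$site_code[
    match(names(hs$sample_map), ds$sample_metadata$sample_id)]
  counts <- haplotype_site_counts(hs, site)
  expect_equal(sum(counts), length(hs$sample_map))
  expect_equal(unname(rowSums(counts)), unname(hs$counts))
})

signal4_fixture <- function(fst_ab = 0.3) {
  # haplotype H1 shared by distant sites A and B; all others private
  seqs <- c("AAAA", "AAAA", "TTAA", "TTAA", "GGGG", "GGGG")
  aln <- aln_from(seqs)
  rownames(aln) <- paste0("x", 1:6)
  hs <- collapse_haplotypes(aln)
  site <- c("A", "B", "A", "A", "B", "B")
  coords <- data.frame(site_code = c("A", "B"),
                       latitude = c(-28, -25.3), longitude = 153)
  sites <- c("A", "B")
  fstv <- matrix(c(NA, fst_ab, fst_ab, NA), 2, 2,
                 dimnames = list(sites, sites))
  fst <- structure(list(site_codes = sites, values = fstv,
                        n_loci_used = matrix(10L, 2, 2),
                        n_samples = c(3L, 3L), undefined_pairs = list()),
                   class = "fst_matrix")
  list(hs = hs, net = build_network(hs), site = site, coords = coords,
       fst = fst)
}

test_that("signal 4 flags shared haplotypes between distant differentiated sites", {
  fx <- signal4_fixture()
  res <- detect_signal4(fx$net, fx$hs, fx$site, fx$coords,
                        nuclear_fst = fx$fst, min_km = 100)
  expect_equal(res$signal, "detected")
  expect_true("LDD" %in% res$pattern)
  expect_true("H1" %in% res$evidence$ldd_pairs$haplotype_1)
  # with low nuclear differentiation the same sharing is unremarkable
  fx2 <- signal4_fixture(fst_ab = 0.02)
  res2 <- detect_signal4(fx2$net, fx2$hs, fx2$site, fx2$coords,
                         nuclear_fst = fx2$fst, min_km = 100)
  expect_equal(res2$signal, "not_detected")
})

test_that("private divergent haplotypes do not trigger signal 4", {
  aln <- aln_from("AAAAAAAA", "AAAAAAAA", "TTTTTTTT", "TTTTTTTT")
  rownames(aln) <- paste0("x", 1:4)
  hs <- collapse_haplotypes(aln)
  net <- build_network(hs)
  site <- c("A", "A", "B", "B")
  coords <- data.frame(site_code = c("A", "B"),
                       latitude = c(-28, -25.3), longitude = 153)
  sites <- c("A", "B")
  fstv <- matrix(c(NA, 0.5, 0.5, NA), 2, 2, dimnames = list(sites, sites))
  fst <- structure(list(site_codes = sites, values = fstv,
                        n_loci_used = matrix(10L, 2, 2),
                        n_samples = c(2L, 2L), undefined_pairs = list()),
                   class = "fst_matrix")
  res <- detect_signal4(net, hs, site, coords, nuclear_fst = fst,
                        min_km = 100)
  expect_equal(res$signal, "not_detected")
})

test_that("a single widespread haplotype is flagged as the widespread pattern", {
  seqs <- c(rep("AAAA", 9), "ATAA")
  aln <- aln_from(seqs)
  rownames(aln) <- paste0("x", 1:10)
  hs <- collapse_haplotypes(aln)
  net <- build_network(hs)
  site <- rep(c("A", "B"), 5)
  coords <- data.frame(site_code = c("A", "B"),
                       latitude = c(-28, -27.8), longitude = 153)
  res <- detect_signal4(net, hs, site, coords, nuclear_fst = NULL,
                        min_km = 1000)  # suppress the LDD route
  expect_equal(res$signal, "detected")
  expect_equal(res$pattern, "widespread")
  expect_equal(res$evidence$widespread_haplotypes, "H1")
})

test_that("windowed secondary contact leaves more plastid LDD than isolation", {
  rate <- function(sid, reps) {
    hits <- 0
    for (r in seq_len(reps)) {
      cfg <- build_scenario(sid, n_nuclear_sites = 5e5,
                            samples_per_deme_nuclear = 6, seed = 950 + r)
      ds <- simulate_dataset(cfg)
      f <- pairwise_fst(ds$genotype_matrix, ds$sample_metadata$site_code)
      hs <- collapse_haplotypes(ds$cp_alignment)
      net <- build_network(hs)
      meta <- ds$sample_metadata
      site <- meta$site_code[match(names(hs$sample_map), meta$sample_id)]
      sc <- unique(meta[, c("site_code", "latitude", "longitude")])
      s4 <- detect_signal4(net, hs, site, sc, nuclear_fst = f)
      if (s4$signal == "detected" && "LDD" %in% s4$pattern) hits <- hits + 1
    }
    hits
  }
  expect_gte(rate("hd3", 4), rate("iso", 4))
})
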