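# Shared fixtures and independent oracle implementations.

# Small genotype matrix from explicit call vectors (samples x loci).
toy_gm <- function(calls, ...) {
  genotype_matrix(calls, ...)
}

# Independent scalar reference implementation of the two-population
# Weir-type multilocus estimator, written as plain per-locus loops from
# the published component formulas (kept deliberately separate from the
# package's vectorised implementation).
reference_pairwise_fst <- function(calls1, calls2) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(calls1))) {
    g1 <- calls1[, l]; g1 <- g1[!is.na(g1)]
    g2 <- calls2[, l]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# A quick, small scenario configuration for pipeline smoke tests.
quick_config <- function(scenario_id = "iso", seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_nuclear_sites = 4e5, samples_per_deme_nuclear = 6L,
         samples_per_deme_cp = 3L, seed = seed),
    list(...))
  do.call(build_scenario, c(list(scenario_id), args))
}

# Exhaustive minimum spanning length over a haplotype set allowing up to
# `max_add` extra (median) nodes drawn from every sequence composable from
# the characters observed per column. Brute force; feasible only for tiny
# instances.
brute_force_min_length <- function(haps, max_add = 2L) {
  stopifnot(nrow(haps) <= 6L, ncol(haps) <= 6L)
  ham <- function(a, b) sum(a != b)
  mstlen <- function(S) {
    n <- nrow(S)
    if (n <= 1) return(0)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- ham(S[i, ], S[j, ])
    in_tree <- c(TRUE, rep(FALSE, n - 1)); best <- D[1, ]; tot <- 0
    for (s in seq_len(n - 1)) {
      cand <- which(!in_tree); j <- cand[which.min(best[cand])]
      tot <- tot + best[j]; in_tree[j] <- TRUE; best <- pmin(best, D[j, ])
    }
    tot
  }
  alphabet <- lapply(seq_len(ncol(haps)), function(j) unique(haps[, j]))
  all_seqs <- as.matrix(expand.grid(alphabet, stringsAsFactors = FALSE))
  existing <- apply(haps, 1, paste, collapse = "")
  cand <- all_seqs[!apply(all_seqs, 1, paste, collapse = "") %in% existing, ,
                   drop = FALSE]
  best <- mstlen(haps)
  if (max_add >= 1L) for (i in seq_len(nrow(cand))) {
    best <- min(best, mstlen(rbind(haps, cand[i, ])))
    if (max_add >= 2L && nrow(cand) >= 2L && i < nrow(cand))
      for (j in (i + 1L):nrow(cand))
        best <- min(best, mstlen(rbind(haps, cand[i, ], cand[j, ])))
  }
  best
}

# Network total spanning length (over its realised edge set interpreted as
# an MST of the node set).
network_mst_length <- function(net) {
  n <- nrow(net$sequences)
  if (n <= 1) return(0)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sum(net$sequences[i, ] != net$sequences[j, ])
  dispersalscreen:::mst_length(D)
}
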