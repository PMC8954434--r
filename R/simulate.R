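# Demographic simulation engine.
#
# Nuclear SNPs: exact forward Wright-Fisher simulation of allele
# frequencies per deme. The shared panmictic ancestor (size
# n_demes * deme_size) contributes standing variation with frequencies
# drawn from the neutral 1/p site-frequency spectrum; each generation
# applies deterministic migration mixing followed by binomial drift.
# Diploid genotypes are then sampled binomially (Hardy-Weinberg) from the
# present-day deme frequencies and monomorphic-in-sample sites dropped.
#
# Chloroplast: structured coalescent on the haploid, uniparentally
# inherited plastid (effective size deme_size / 2 per deme), with
# piecewise-constant migration across epochs, founding events, and an
# ancestral panmictic phase beyond divergence_time. Poisson mutations on
# branches yield haploid sequences of length cp_sequence_length.

# Epoch index applying to a given year BP (first epoch covers [0, end1)).
epoch_at <- function(cfg, year) {
  for (k in seq_along(cfg$epochs)) {
    e <- cfg$epochs[[k]]
    if (year >= e$start && year < e$end) return(k)
  }
  length(cfg$epochs)
}

simulate_nuclear <- function(cfg) {
  d <- cfg$n_demes
  N <- cfg$deme_size
  gt <- cfg$generation_time
  N_anc <- d * N
  # Expected density of segregating sites in the ancestral population:
  # 4 N mu per site times the harmonic sum ~ log(2N) across frequencies.
  L0 <- max(1L, round(cfg$n_nuclear_sites * 4 * N_anc * cfg$mutation_rate *
                        log(2 * N_anc)))
  pmin <- 1 / (2 * N_anc)
  p0 <- pmin^(1 - stats::runif(L0))  # inverse-CDF draw from density 1/p
  p <- matrix(p0, L0, d)

  G <- floor(cfg$divergence_time / gt)
  fe <- cfg$founding_events
  founded_pending <- rep(FALSE, d)
  if (nrow(fe)) founded_pending[fe$deme] <- TRUE

  # Precompute full migration matrices (receiver x source, diag = stay)
  Mfull <- lapply(cfg$epochs, function(e) {
    M <- e$M
    diag(M) <- 1 - rowSums(M)
    M
  })
  has_mig <- vapply(cfg$epochs, function(e) any(e$M > 0), logical(1))

  two_n <- 2 * N
  for (s in seq_len(G)) {
    year_after <- (G - s) * gt
    k <- epoch_at(cfg, min(year_after, cfg$epochs[[length(cfg$epochs)]]$end - 1e-9))
    if (has_mig[k]) {
      p <- p %*% t(Mfull[[k]])
    }
    p <- matrix(stats::rbinom(L0 * d, two_n, p), L0, d) / two_n
    if (any(founded_pending)) {
      for (f in which(founded_pending)) {
        row <- fe[fe$deme == f, ]
        if (year_after >= row$time) {
          p[, f] <- p[, row$source]      # deme not yet founded: mirrors source
        } else {
          p[, f] <- stats::rbinom(L0, two_n, p[, row$source]) / two_n
          founded_pending[f] <- FALSE    # founder sampling; now independent
        }
      }
    }
  }

  ns <- cfg$samples_per_deme_nuclear
  calls <- matrix(NA_integer_, d * ns, L0)
  for (i in seq_len(d)) {
    rows <- (i - 1L) * ns + seq_len(ns)
    calls[rows, ] <- matrix(stats::rbinom(ns * L0, 2L, rep(p[, i], each = ns)),
                            ns, L0)
  }
  ac <- colSums(calls)
  seg <- ac >= 1L & ac <= 2L * nrow(calls) - 1L
  if (!any(seg))
    ds_stop("no variation: simulation produced zero segregating sites",
            "ds_novariation")
  calls <- calls[, seg, drop = FALSE]
  sample_ids <- paste0("d", rep(seq_len(d), each = ns), "_s",
                       rep(seq_len(ns), d))
  locus_ids <- sprintf("L%05d", seq_len(ncol(calls)))
  dimnames(calls) <- list(sample_ids, locus_ids)
  gm <- genotype_matrix(calls,
                        reproducibility = rep(1, ncol(calls)),
                        call_rate = rep(1, ncol(calls)))
  list(gm = gm, deme = rep(seq_len(d), each = ns))
}

# Structured-coalescent genealogy of gene copies sampled across demes.
# `coal_size` is the number of gene copies per deme on this genome
# (chloroplast: deme_size / 2, haploid and uniparental; nuclear:
# 2 * deme_size); the ancestral pool holds n_demes times that. Returns
# parent pointers and node times (generations) plus tip deme assignments.
simulate_genealogy <- function(cfg, tips_per_deme, coal_size) {
  d <- cfg$n_demes
  gt <- cfg$generation_time
  Ncp <- coal_size
  Ncp_anc <- d * coal_size
  nper <- tips_per_deme
  n_tips <- d * nper
  if (n_tips < 1L) ds_stop("no samples requested", "ds_invalid")

  tip_deme <- rep(seq_len(d), each = nper)
  # event times backward, in generations
  bounds <- sort(unique(c(
    vapply(cfg$epochs, function(e) e$end, numeric(1)) / gt,
    cfg$founding_events$time / gt,
    cfg$divergence_time / gt)))
  div_gen <- cfg$divergence_time / gt

  active <- seq_len(n_tips)          # node ids of active lineages
  lin_deme <- tip_deme
  node_time <- rep(0, n_tips)
  parent <- integer(0)               # parent[i] of node i (grown as needed)
  next_node <- n_tips + 1L
  parent <- rep(NA_integer_, n_tips)
  t_now <- 0
  ancestral <- FALSE

  pick2 <- function(idx) if (length(idx) == 2L) idx else sample(idx, 2L)

  while (length(active) > 1L) {
    if (!ancestral && t_now >= div_gen - 1e-12) {
      ancestral <- TRUE
      lin_deme[] <- 1L
    }
    if (ancestral) {
      k <- length(active)
      rate <- k * (k - 1) / 2 / Ncp_anc
      t_now <- t_now + stats::rexp(1, rate)
      pair <- pick2(seq_along(active))
      new_id <- next_node; next_node <- next_node + 1L
      parent <- c(parent, NA_integer_)
      node_time <- c(node_time, t_now)
      parent[active[pair]] <- new_id
      active <- c(active[-pair], new_id)
      lin_deme <- c(lin_deme[-pair], 1L)
      next
    }
    k_epoch <- epoch_at(cfg, t_now * gt + 1e-9)
    M <- cfg$epochs[[k_epoch]]$M
    counts <- tabulate(lin_deme, nbins = d)
    coal_rates <- counts * (counts - 1) / 2 / Ncp
    mig_rates <- rowSums(M)[lin_deme]          # per-lineage total backward rate
    total <- sum(coal_rates) + sum(mig_rates)
    nb <- bounds[bounds > t_now + 1e-12]
    t_next_bound <- if (length(nb)) nb[1] else Inf
    if (total <= 0) {
      t_new <- t_next_bound
    } else {
      t_new <- t_now + stats::rexp(1, total)
    }
    if (t_new >= t_next_bound) {
      t_now <- t_next_bound
      # founding events: backward, lineages in the founded deme move to source
      fe <- cfg$founding_events
      if (nrow(fe)) {
        hit <- which(abs(fe$time / gt - t_now) < 1e-9)
        for (h in hit) lin_deme[lin_deme == fe$deme[h]] <- fe$source[h]
      }
      next
    }
    t_now <- t_new
    u <- stats::runif(1, 0, total)
    if (u < sum(coal_rates)) {
      i <- which(cumsum(coal_rates) >= u)[1L]
      idx <- which(lin_deme == i)
      pair <- pick2(idx)
      new_id <- next_node; next_node <- next_node + 1L
      parent <- c(parent, NA_integer_)
      node_time <- c(node_time, t_now)
      parent[active[pair]] <- new_id
      keep <- setdiff(seq_along(active), pair)
      active <- c(active[keep], new_id)
      lin_deme <- c(lin_deme[keep], i)
    } else {
      u2 <- u - sum(coal_rates)
      cum <- cumsum(mig_rates)
      li <- which(cum >= u2)[1L]
      r <- lin_deme[li]
      dest_p <- M[r, ]
      lin_deme[li] <- sample.int(d, 1L, prob = dest_p)
    }
  }
  list(parent = parent, node_time = node_time, n_tips = n_tips,
       tip_deme = tip_deme, root = active[1L])
}

simulate_cp_genealogy <- function(cfg) {
  simulate_genealogy(cfg, cfg$samples_per_deme_cp, cfg$deme_size / 2)
}

# tip x site derived-allele matrix from Poisson mutations on a genealogy
# (infinite-sites: every mutation is a new segregating column).
genealogy_snp_matrix <- function(gen, mu_locus) {
  n_nodes <- length(gen$parent)
  # descendant tip sets, computed root-down
  ord <- order(gen$node_time)  # tips first
  desc <- vector("list", n_nodes)
  for (v in ord) {
    if (v <= gen$n_tips) desc[[v]] <- v
  }
  for (v in ord) {
    p <- gen$parent[v]
    if (!is.na(p)) desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  cols <- list()
  for (v in seq_len(n_nodes)) {
    p <- gen$parent[v]
    if (is.na(p)) next
    bl <- gen$node_time[p] - gen$node_time[v]
    nm <- stats::rpois(1, mu_locus * bl)
    if (nm > 0) {
      col <- integer(gen$n_tips)
      col[desc[[v]]] <- 1L
      for (q in seq_len(nm)) cols[[length(cols) + 1L]] <- col
    }
  }
  if (!length(cols)) return(matrix(integer(0), gen$n_tips, 0L))
  do.call(cbind, cols)
}

# Equilibrium-capable nuclear simulation through the structured coalescent:
# n_loci independent non-recombining loci of equal length partitioning
# n_nuclear_sites, 2 gene copies per sampled diploid.
simulate_nuclear_coalescent <- function(cfg, n_loci = 200L) {
  d <- cfg$n_demes
  ns <- cfg$samples_per_deme_nuclear
  mu_locus <- cfg$mutation_rate * cfg$n_nuclear_sites / n_loci
  hap_cols <- list()
  for (l in seq_len(n_loci)) {
    gen <- simulate_genealogy(cfg, tips_per_deme = 2L * ns,
                              coal_size = 2 * cfg$deme_size)
    m <- genealogy_snp_matrix(gen, mu_locus)
    if (ncol(m)) hap_cols[[length(hap_cols) + 1L]] <- m
  }
  if (!length(hap_cols))
    ds_stop("no variation: simulation produced zero segregating sites",
            "ds_novariation")
  haps <- do.call(cbind, hap_cols)
  # consecutive gene-copy pairs form diploid individuals
  odd <- seq(1L, nrow(haps), by = 2L)
  calls <- haps[odd, , drop = FALSE] + haps[odd + 1L, , drop = FALSE]
  ac <- colSums(calls)
  seg <- ac >= 1L & ac <= 2L * nrow(calls) - 1L
  if (!any(seg))
    ds_stop("no variation: simulation produced zero segregating sites",
            "ds_novariation")
  calls <- calls[, seg, drop = FALSE]
  sample_ids <- paste0("d", rep(seq_len(d), each = ns), "_s",
                       rep(seq_len(ns), d))
  dimnames(calls) <- list(sample_ids, sprintf("L%05d", seq_len(ncol(calls))))
  gm <- genotype_matrix(calls,
                        reproducibility = rep(1, ncol(calls)),
                        call_rate = rep(1, ncol(calls)))
  list(gm = gm, deme = rep(seq_len(d), each = ns))
}

# Drop mutations on the genealogy and emit the tip alignment.
cp_sequences_from_genealogy <- function(gen, cfg, tip_ids) {
  L <- cfg$cp_sequence_length
  mu <- cfg$mutation_rate
  n_nodes <- length(gen$parent)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)

  # per-node sparse state: positions where the node differs from ref
  changes <- vector("list", n_nodes)
  # process nodes from root down (decreasing time)
  ord <- order(gen$node_time, decreasing = TRUE)
  for (v in ord) {
    p <- gen$parent[v]
    if (is.na(p)) { changes[[v]] <- list(pos = integer(0), base = character(0)); next }
    bl <- gen$node_time[p] - gen$node_time[v]
    nm <- stats::rpois(1, mu * L * bl)
    ch <- changes[[p]]
    if (nm > 0) {
      pos <- sample.int(L, nm, replace = TRUE)
      for (q in pos) {
        j <- match(q, ch$pos)
        cur <- if (!is.na(j)) ch$base[j] else ref[q]
        newb <- sample(setdiff(bases, cur), 1L)
        if (!is.na(j)) {
          ch$base[j] <- newb
        } else {
          ch$pos <- c(ch$pos, q)
          ch$base <- c(ch$base, newb)
        }
      }
    }
    changes[[v]] <- ch
  }
  aln <- matrix(rep(ref, each = gen$n_tips), nrow = gen$n_tips)
  for (i in seq_len(gen$n_tips)) {
    ch <- changes[[i]]
    if (length(ch$pos)) aln[i, ch$pos] <- ch$base
  }
  rownames(aln) <- tip_ids
  haploid_alignment(aln)
}

#' Simulate a dataset under a dispersal scenario
#'
#' Runs the demographic engine for one configuration: a forward
#' Wright-Fisher simulation of nuclear SNP frequencies (with binomially
#' sampled diploid genotypes at the present) and, optionally, a structured
#' coalescent of the haploid chloroplast locus with Poisson mutations.
#' All randomness flows from `config$seed`; the same configuration
#' reproduces the dataset exactly.
#'
#' @param config A [build_scenario()] configuration.
#' @param include_cp Simulate the chloroplast alignment too (default `TRUE`).
#' @param engine Nuclear engine: `"wright_fisher"` (default; exact forward
#'   simulation of standing ancestral variation, suited to the epoch-bounded
#'   scenarios) or `"coalescent"` (structured coalescent with infinite-sites
#'   mutation, suited to equilibrium designs such as a constant island
#'   model, where variation must be at mutation-drift-migration
#'   stationarity).
#' @param n_loci For the coalescent engine: number of independent
#'   non-recombining loci partitioning `n_nuclear_sites` (default 200).
#' @return A `simulated_dataset`: list with `genotype_matrix`
#'   ([genotype_matrix()]), `cp_alignment` (`haploid_alignment` or `NULL`),
#'   `sample_metadata` ([sample_metadata()]; cp-sequenced samples carry the
#'   first sample indices of each deme), and `truth` (scenario id, seed and
#'   the configuration).
#' @export
simulate_dataset <- function(config, include_cp = TRUE,
                             engine = c("wright_fisher", "coalescent"),
                             n_loci = 200L) {
  engine <- match.arg(engine)
  validate_scenario_config(config)
  set.seed(config$seed)
  nuc <- if (engine == "wright_fisher") simulate_nuclear(config)
         else simulate_nuclear_coalescent(config, n_loci = n_loci)
  d <- config$n_demes
  coords <- config$deme_coordinates
  meta <- sample_metadata(data.frame(
    sample_id = nuc$gm$sample_ids,
    species_id = paste0("sim_", config$scenario_id),
    site_code = paste0("D", nuc$deme),
    latitude = coords$latitude[nuc$deme],
    longitude = coords$longitude[nuc$deme],
    region_label = ifelse(nuc$deme <= ceiling(d / 2), "S", "N"),
    stringsAsFactors = FALSE))
  cp <- NULL
  if (include_cp && config$samples_per_deme_cp > 0) {
    gen <- simulate_cp_genealogy(config)
    ns <- config$samples_per_deme_nuclear
    ncp <- config$samples_per_deme_cp
    tip_ids <- paste0("d", rep(seq_len(d), each = ncp), "_s",
                      rep(seq_len(min(ncp, ns)), d))
    if (ncp > ns)
      tip_ids <- paste0("d", rep(seq_len(d), each = ncp), "_cp",
                        rep(seq_len(ncp), d))
    cp <- cp_sequences_from_genealogy(gen, config, tip_ids)
  }
  structure(list(genotype_matrix = nuc$gm,
                 cp_alignment = cp,
                 sample_metadata = meta,
                 truth = list(scenario_id = config$scenario_id,
                              seed = config$seed, config = config)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset '%s' (seed %s): %d samples x %d SNPs%s\n",
              x$truth$scenario_id, format(x$truth$seed),
              nrow(x$genotype_matrix$calls), ncol(x$genotype_matrix$calls),
              if (is.null(x$cp_alignment)) "" else
                sprintf(", %d cp sequences of %d bp",
                        nrow(x$cp_alignment), ncol(x$cp_alignment))))
  invisible(x)
}

#' Replicate Fst profile of a scenario
#'
#' Simulates a scenario repeatedly and computes the multilocus pairwise Fst
#' matrix between demes for every replicate, summarising each deme pair over
#' replicates. Per-replicate simulation failures are propagated with the
#' replicate index attached.
#'
#' @param config A [build_scenario()] configuration.
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Base seed; replicate seeds are derived from it.
#' @param engine,n_loci Passed to [simulate_dataset()].
#' @return A list of class `scenario_fst_profile`: `replicates` (list of
#'   [pairwise_fst()] matrices), `summary` (data frame keyed by scenario and
#'   deme pair with mean and sd), `grand_means` (per-replicate mean of all
#'   off-diagonal pairs).
#' @export
scenario_fst_profile <- function(config, n_replicates, seed = config$seed,
                                 engine = "wright_fisher", n_loci = 200L) {
  if (n_replicates < 1) ds_stop("n_replicates must be >= 1", "ds_invalid")
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(seed, "fst_profile_rep", r)
    reps[[r]] <- tryCatch({
      ds <- simulate_dataset(cfg_r, include_cp = FALSE, engine = engine,
                             n_loci = n_loci)
      pairwise_fst(ds$genotype_matrix,
                   site_assignment = ds$sample_metadata$site_code)
    }, error = function(e) {
      stop(sprintf("replicate %d: %s", r, conditionMessage(e)), call. = FALSE)
    })
  }
  pairs <- upper_pairs(config$n_demes)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    vals <- vapply(reps, function(f) f$values[i, j], numeric(1))
    data.frame(scenario = config$scenario_id, deme_i = i, deme_j = j,
               mean_fst = mean(vals, na.rm = TRUE),
               sd_fst = stats::sd(vals), n_replicates = n_replicates)
  })
  grand <- vapply(reps, function(f) mean(f$values[upper.tri(f$values)], na.rm = TRUE),
                  numeric(1))
  structure(list(replicates = reps, summary = do.call(rbind, rows),
                 grand_means = grand),
            class = "scenario_fst_profile")
}

#' Closed-form island-model Fst expectation
#'
#' Finite-island equilibrium approximation
#' `1 / (1 + 4 N m (d/(d-1))^2)` for `d` demes of diploid size `N`
#' exchanging migrants pairwise at rate `m` with every other deme
#' (`m` here is the total per-generation immigration fraction).
#'
#' @param N Diploid deme size.
#' @param m Total immigration fraction per generation.
#' @param d Number of demes.
#' @return Expected equilibrium Fst.
#' @export
island_model_fst <- function(N, m, d) {
  1 / (1 + 4 * N * m * (d / (d - 1))^2)
}

#' Closed-form pairwise island-model Fst expectation
#'
#' Expectation of the two-deme Weir-type estimator between islands at
#' equilibrium, `1 / (1 + 4 N m d/(d-1))`, from coalescence times
#' `T_within = 2Nd` and `T_between = 2Nd + (d-1)/(2m)` (the pairwise
#' estimand is `1 - T_within / T_between` in the low-mutation limit). This
#' differs from the total-population GST form of [island_model_fst()] by
#' one factor of `d/(d-1)`: pooled-frequency GST and mean pairwise Fst are
#' distinct statistics on the same model.
#'
#' @inheritParams island_model_fst
#' @return Expected equilibrium pairwise Fst.
#' @export
island_model_pairwise_fst <- function(N, m, d) {
  1 / (1 + 4 * N * m * d / (d - 1))
}
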