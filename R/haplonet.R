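# Chloroplast haplotype collapsing and mutation-weighted networks.

is_resolved <- function(ch) ch %in% c("A", "C", "G", "T")

# Hamming distance ignoring positions unresolved in either sequence.
hamming_pairwise <- function(s1, s2) {
  ok <- is_resolved(s1) & is_resolved(s2)
  sum(s1[ok] != s2[ok])
}

#' Collapse aligned sequences into haplotypes
#'
#' Groups identical sequences over the used alignment columns into
#' haplotypes. Under `"complete_columns"`, columns containing any gap or
#' ambiguity character are dropped before collapsing. Under
#' `"pairwise_complete"` (default), all columns are kept and unresolved
#' positions act as wildcards: a sequence merges into a haplotype if it is
#' compatible at every resolved position; when several haplotypes are
#' compatible the most frequent wins, then the lexicographically smallest
#' sequence.
#'
#' @param alignment A `haploid_alignment` (or character matrix),
#'   sequences x columns.
#' @param missing_policy `"pairwise_complete"` or `"complete_columns"`.
#' @return A `haplotype_set`: `haplotypes` (character matrix, one row per
#'   haplotype over used columns), `counts`, `sample_map` (sequence id ->
#'   haplotype index), `used_columns` (1-based original column indices).
#' @export
collapse_haplotypes <- function(alignment,
                                missing_policy = c("pairwise_complete",
                                                   "complete_columns")) {
  missing_policy <- match.arg(missing_policy)
  aln <- as.matrix(alignment)
  ids <- rownames(aln) %||% paste0("seq", seq_len(nrow(aln)))
  used <- seq_len(ncol(aln))
  if (missing_policy == "complete_columns") {
    keep <- apply(aln, 2L, function(col) all(is_resolved(col)))
    if (!any(keep))
      ds_stop("all alignment columns dropped under complete_columns policy",
              "ds_empty")
    aln <- aln[, keep, drop = FALSE]
    used <- used[keep]
  }
  resolved_count <- rowSums(matrix(is_resolved(aln), nrow(aln)))
  # fully resolved sequences first (then by input order) so they seed the
  # haplotype list before wildcard merging
  ord <- order(resolved_count < ncol(aln), seq_len(nrow(aln)))
  hap_seqs <- list()
  counts <- integer(0)
  assign <- integer(nrow(aln))
  for (i in ord) {
    s <- aln[i, ]
    compat <- which(vapply(hap_seqs, function(h) {
      ok <- is_resolved(s) & is_resolved(h)
      all(s[ok] == h[ok])
    }, logical(1)))
    if (length(compat) == 0L) {
      hap_seqs[[length(hap_seqs) + 1L]] <- s
      counts <- c(counts, 1L)
      assign[i] <- length(hap_seqs)
    } else {
      if (length(compat) > 1L) {
        cc <- counts[compat]
        best <- compat[cc == max(cc)]
        if (length(best) > 1L) {
          keys <- vapply(hap_seqs[best], paste, character(1), collapse = "")
          best <- best[order(keys)][1L]
        } else best <- best[1L]
      } else best <- compat
      # fill wildcards of the haplotype from the new member where possible
      h <- hap_seqs[[best]]
      fill <- !is_resolved(h) & is_resolved(s)
      h[fill] <- s[fill]
      hap_seqs[[best]] <- h
      counts[best] <- counts[best] + 1L
      assign[i] <- best
    }
  }
  haps <- do.call(rbind, hap_seqs)
  rownames(haps) <- paste0("H", seq_len(nrow(haps)))
  names(assign) <- ids
  structure(list(haplotypes = haps, counts = counts,
                 sample_map = assign, used_columns = used),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes from %d sequences\n",
              nrow(x$haplotypes), length(x$sample_map)))
  invisible(x)
}

#' Per-site haplotype counts
#'
#' @param hs A `haplotype_set`.
#' @param site_assignment Named or positional site codes, one per sequence
#'   in `hs$sample_map` order.
#' @return Matrix of counts, haplotypes x sites.
#' @export
haplotype_site_counts <- function(hs, site_assignment) {
  stopifnot(inherits(hs, "haplotype_set"))
  site_assignment <- as.character(site_assignment)
  sites <- unique(site_assignment)
  tab <- table(factor(hs$sample_map, levels = seq_len(nrow(hs$haplotypes))),
               factor(site_assignment, levels = sites))
  m <- matrix(as.integer(tab), nrow(hs$haplotypes), length(sites),
              dimnames = list(rownames(hs$haplotypes), sites))
  m
}

# Minimum-spanning-tree total length over a distance matrix (Prim).
mst_length <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1L, ]
  total <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    total <- total + best[j]
    in_tree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  total
}

# Minimum-spanning-network edges: for each distance level (ascending), add
# every edge at that level joining two components as defined by strictly
# smaller levels (classic MSN).
msn_edges <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(matrix(numeric(0), ncol = 3L,
                             dimnames = list(NULL, c("from", "to", "weight"))))
  comp <- seq_len(n)
  edges <- NULL
  pairs <- upper_pairs(n)
  w <- D[pairs]
  for (lev in sort(unique(w))) {
    at <- which(w == lev)
    keep <- at[comp[pairs[at, 1L]] != comp[pairs[at, 2L]]]
    for (e in keep)
      edges <- rbind(edges, c(pairs[e, 1L], pairs[e, 2L], lev))
    # merge components after the whole level is processed
    for (e in keep) {
      c1 <- comp[pairs[e, 1L]]; c2 <- comp[pairs[e, 2L]]
      if (c1 != c2) comp[comp == c2] <- c1
    }
    if (length(unique(comp)) == 1L) break
  }
  colnames(edges) <- c("from", "to", "weight")
  edges
}

# Candidate median (consensus) sequences of node triples: per column the
# majority character among the three (no candidate change if all differ).
triple_median <- function(s1, s2, s3) {
  med <- s1
  agree23 <- s2 == s3
  med[agree23] <- s2[agree23]
  med
}

#' Build a mutation-weighted haplotype network
#'
#' Constructs a minimum-spanning network over pairwise Hamming distances
#' between haplotypes, then augments it with inferred (unsampled) median
#' nodes in the median-joining style. With `epsilon = 0` (the default and
#' the only tightness implemented exactly), a median is accepted only if it
#' strictly reduces the total spanning length of the node set; candidates
#' are the per-column majority consensus of connected node triples,
#' evaluated iteratively until no candidate improves the network. Ties are
#' broken by haplotype frequency, then lexicographic sequence order, so the
#' result is deterministic under a fixed input ordering.
#'
#' @param hs A `haplotype_set` from [collapse_haplotypes()].
#' @param epsilon Median-joining tolerance parameter; only 0 is supported
#'   (medians must strictly reduce total length).
#' @return A `haplo_network`: `nodes` (data frame: id, sampled flag,
#'   count), `edges` (data frame: from, to, mutations), `sequences`
#'   (matrix including median nodes), `epsilon`.
#' @export
build_network <- function(hs, epsilon = 0) {
  stopifnot(inherits(hs, "haplotype_set"))
  if (epsilon != 0)
    ds_stop("only epsilon = 0 networks are implemented", "ds_config")
  seqs_full <- hs$haplotypes
  n0 <- nrow(seqs_full)
  counts <- hs$counts
  sampled <- rep(TRUE, n0)
  # distances, medians and lengths depend only on columns where sampled
  # haplotypes differ (or are unresolved); restrict the search to them
  var_cols <- which(apply(seqs_full, 2L, function(col) {
    r <- col[is_resolved(col)]
    length(unique(r)) > 1L || length(r) < length(col)
  }))
  seqs <- seqs_full[, var_cols, drop = FALSE]
  expand_seq <- function(v) {
    out <- seqs_full[1L, ]
    out[var_cols] <- v
    out
  }
  if (n0 == 1L) {
    return(structure(list(
      nodes = data.frame(id = "H1", sampled = TRUE, count = counts[1L]),
      edges = data.frame(from = character(0), to = character(0),
                         mutations = numeric(0)),
      sequences = seqs_full, epsilon = 0), class = "haplo_network"))
  }
  dist_mat <- function(S) {
    n <- nrow(S)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- hamming_pairwise(S[i, ], S[j, ])
    D
  }
  D <- dist_mat(seqs)
  repeat {
    cur_len <- mst_length(D)
    edges <- msn_edges(D)
    # enumerate candidate medians over connected triples (two edges sharing
    # a node)
    adj <- lapply(seq_len(nrow(seqs)), function(i)
      unique(c(edges[edges[, 1L] == i, 2L], edges[edges[, 2L] == i, 1L])))
    cands <- list()
    for (b in seq_len(nrow(seqs))) {
      nb <- adj[[b]]
      if (length(nb) < 2L) next
      for (pair in utils::combn(nb, 2L, simplify = FALSE)) {
        med <- triple_median(seqs[pair[1L], ], seqs[b, ], seqs[pair[2L], ])
        key <- paste(med, collapse = "")
        if (!key %in% names(cands)) cands[[key]] <- med
      }
    }
    if (!length(cands)) break
    # drop candidates identical to existing nodes
    existing <- apply(seqs, 1L, paste, collapse = "")
    cands <- cands[!names(cands) %in% existing]
    if (!length(cands)) break
    best_gain <- 0; best_med <- NULL
    for (key in sort(names(cands))) {
      med <- cands[[key]]
      dnew <- apply(seqs, 1L, hamming_pairwise, s2 = med)
      D2 <- rbind(cbind(D, dnew), c(dnew, 0))
      gain <- cur_len - mst_length(D2)
      if (gain > best_gain + 1e-9) { best_gain <- gain; best_med <- med }
    }
    if (is.null(best_med)) break
    seqs <- rbind(seqs, best_med)
    rownames(seqs)[nrow(seqs)] <- paste0("M", nrow(seqs) - n0)
    counts <- c(counts, 0L)
    sampled <- c(sampled, FALSE)
    D <- dist_mat(seqs)
  }
  # prune median nodes that ended up as leaves (they cannot shorten paths)
  repeat {
    edges <- msn_edges(D)
    deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = nrow(seqs))
    drop <- which(!sampled & deg <= 1L)
    if (!length(drop)) break
    seqs <- seqs[-drop, , drop = FALSE]
    counts <- counts[-drop]
    sampled <- sampled[-drop]
    D <- dist_mat(seqs)
  }
  edges <- msn_edges(D)
  seqs_out <- t(apply(seqs, 1L, expand_seq))
  rownames(seqs_out) <- rownames(seqs)
  structure(list(
    nodes = data.frame(id = rownames(seqs), sampled = sampled, count = counts,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = rownames(seqs)[edges[, 1L]],
                       to = rownames(seqs)[edges[, 2L]],
                       mutations = edges[, 3L], stringsAsFactors = FALSE),
    sequences = seqs_out, epsilon = 0), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d nodes (%d sampled), %d edges, epsilon = %g\n",
              nrow(x$nodes), sum(x$nodes$sampled), nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Export a haplotype network as an edge-list TSV
#'
#' @param net A `haplo_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a haplotype network as GraphML
#'
#' Writes nodes (with `sampled` flag and sample counts) and
#' mutation-weighted edges in GraphML, readable by igraph, Gephi or
#' Cytoscape.
#'
#' @param net A `haplo_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="sampled" for="node" attr.name="sampled" attr.type="boolean"/>',
    '  <key id="count" for="node" attr.name="count" attr.type="int"/>',
    '  <key id="mutations" for="edge" attr.name="mutations" attr.type="int"/>',
    '  <graph id="haplonet" edgedefault="undirected">'), con)
  for (i in seq_len(nrow(net$nodes))) {
    writeLines(sprintf(
      '    <node id="%s"><data key="sampled">%s</data><data key="count">%d</data></node>',
      net$nodes$id[i], tolower(as.character(net$nodes$sampled[i])),
      net$nodes$count[i]), con)
  }
  for (i in seq_len(nrow(net$edges))) {
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="mutations">%d</data></edge>',
      net$edges$from[i], net$edges$to[i], as.integer(net$edges$mutations[i])),
      con)
  }
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}

#' Signal 4: haplotype long-distance dispersal or a single widespread
#' haplotype
#'
#' Two patterns are searched. `"LDD"`: a haplotype (or pair of haplotypes
#' within `max_mut` mutations) shared between two sites separated by at
#' least `min_km` whose nuclear Fst is at least `min_fst` (or, when nuclear
#' Fst is unavailable for the pair, whose declared regions differ) —
#' closely related plastids in otherwise strongly differentiated or
#' disjunct sites. `"widespread"`: one haplotype carrying at least
#' `widespread_fraction` of all samples and present at every sampled site —
#' the footprint of recent rapid range-wide dispersal.
#'
#' @param net A `haplo_network` from [build_network()].
#' @param hs The `haplotype_set` behind it.
#' @param site_assignment One site code per sequence in `hs$sample_map`
#'   order.
#' @param site_coords Data frame with `site_code`, `latitude`, `longitude`
#'   for every haplotype-bearing site.
#' @param nuclear_fst Optional `fst_matrix` of nuclear differentiation for
#'   (a superset of) the same sites.
#' @param site_regions Optional named character vector site -> region label
#'   (used when a pair's nuclear Fst is unavailable).
#' @param max_mut Maximum mutations separating "closely related" haplotypes
#'   (default 2).
#' @param min_fst Nuclear differentiation threshold (default 0.15).
#' @param min_km Minimum distance for "disjunct" sites; default
#'   (`NULL`) is the median between-site distance, making the criterion
#'   scale-free across species ranges.
#' @param widespread_fraction Sample fraction for the widespread pattern
#'   (default 0.80).
#' @return A `signal_result` whose evidence lists the matched pattern(s)
#'   and triggering haplotype/site pairs with distances and Fst values.
#' @export
detect_signal4 <- function(net, hs, site_assignment, site_coords,
                           nuclear_fst = NULL, site_regions = NULL,
                           max_mut = 2, min_fst = 0.15, min_km = NULL,
                           widespread_fraction = 0.80) {
  stopifnot(inherits(net, "haplo_network"), inherits(hs, "haplotype_set"))
  site_assignment <- as.character(site_assignment)
  counts <- haplotype_site_counts(hs, site_assignment)
  sites <- colnames(counts)
  missing_coord <- setdiff(sites, site_coords$site_code)
  if (length(missing_coord))
    ds_stop(paste0("no coordinates for site(s): ",
                   paste(missing_coord, collapse = ", ")), "ds_invalid")
  co <- site_coords[match(sites, site_coords$site_code), ]
  k <- length(sites)
  dk <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j)
    dk[i, j] <- dk[j, i] <- geosphere::distHaversine(
      c(co$longitude[i], co$latitude[i]), c(co$longitude[j], co$latitude[j]),
      r = 6371.0088)
  if (is.null(min_km)) {
    bd <- dk[upper.tri(dk)]
    min_km <- if (length(bd)) stats::median(bd) else 0
  }
  # haplotype pairwise mutation distances (sampled haplotypes only)
  H <- nrow(hs$haplotypes)
  hd <- matrix(0, H, H)
  if (H > 1L) for (i in seq_len(H - 1L)) for (j in (i + 1L):H)
    hd[i, j] <- hd[j, i] <- hamming_pairwise(hs$haplotypes[i, ],
                                             hs$haplotypes[j, ])
  hits <- NULL
  for (h1 in seq_len(H)) for (h2 in h1:H) {
    if (hd[h1, h2] > max_mut) next
    s1 <- which(counts[h1, ] > 0L)
    s2 <- which(counts[h2, ] > 0L)
    for (i in s1) for (j in s2) {
      if (i == j) next
      if (dk[i, j] < min_km) next
      fst_ij <- NA_real_
      if (!is.null(nuclear_fst) &&
          all(c(sites[i], sites[j]) %in% nuclear_fst$site_codes))
        fst_ij <- nuclear_fst$values[sites[i], sites[j]]
      ok <- if (!is.na(fst_ij)) {
        fst_ij >= min_fst
      } else if (!is.null(site_regions)) {
        !identical(site_regions[[sites[i]]], site_regions[[sites[j]]])
      } else FALSE
      if (ok) {
        hits <- rbind(hits, data.frame(
          haplotype_1 = rownames(hs$haplotypes)[h1],
          haplotype_2 = rownames(hs$haplotypes)[h2],
          mutations = hd[h1, h2],
          site_1 = sites[i], site_2 = sites[j],
          distance_km = dk[i, j], nuclear_fst = fst_ij,
          stringsAsFactors = FALSE))
      }
    }
  }
  total <- sum(hs$counts)
  widespread <- which(hs$counts / total >= widespread_fraction &
                        apply(counts > 0L, 1L, all))
  patterns <- c(if (!is.null(hits)) "LDD",
                if (length(widespread)) "widespread")
  ev <- list(ldd_pairs = hits,
             widespread_haplotypes = rownames(hs$haplotypes)[widespread],
             min_km = min_km, max_mut = max_mut, min_fst = min_fst,
             widespread_fraction = widespread_fraction)
  res <- signal_result(if (length(patterns)) "detected" else "not_detected", ev)
  res$pattern <- patterns
  res
}
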