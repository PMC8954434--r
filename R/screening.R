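# The four-signal decision matrix: combine signal detectors with fruit
# traits into a dispersal-history label and a candidate call.

#' Species trait table
#'
#' Validates and completes a species trait table. The fruit-size class is
#' derived from maximum fruit width: `large` when >= 30 mm (the maximum
#' size ingestible whole by the largest volant dispersers of the study
#' system), else `small`.
#'
#' @param df Data frame with columns `species_id`, `max_fruit_width_mm`
#'   (positive), `dispersal_class` (`"fleshy"` or `"wind"`),
#'   `indigenous_use` (logical).
#' @return The table with a `fruit_size_class` column, class
#'   `species_traits`.
#' @export
species_traits <- function(df) {
  df <- as.data.frame(df)
  need <- c("species_id", "max_fruit_width_mm", "dispersal_class",
            "indigenous_use")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ds_stop(paste0("traits missing column(s): ", paste(miss, collapse = ", ")),
            "ds_invalid")
  if (any(df$max_fruit_width_mm <= 0, na.rm = TRUE))
    ds_stop("max_fruit_width_mm must be positive", "ds_invalid")
  if (!all(df$dispersal_class %in% c("fleshy", "wind")))
    ds_stop("dispersal_class must be 'fleshy' or 'wind'", "ds_invalid")
  df$fruit_size_class <- ifelse(df$max_fruit_width_mm >= 30, "large", "small")
  class(df) <- c("species_traits", "data.frame")
  df
}

#' Assemble a four-signal profile
#'
#' Lossless aggregation of the four detector outputs for one species (or
#' species-by-region subset).
#'
#' @param species_id Species identifier.
#' @param signal1,signal2,signal3,signal4 `signal_result` objects (from
#'   [detect_signal1()] etc.), or `NULL` for a data layer that is entirely
#'   absent (recorded as `not_assessable`).
#' @param region_label Optional region qualifier when a species is split by
#'   region.
#' @return A `signal_profile`.
#' @export
assemble_profile <- function(species_id, signal1, signal2, signal3, signal4,
                             region_label = NA_character_) {
  as_sig <- function(x, layer) {
    if (is.null(x))
      return(signal_result("not_assessable",
                           list(reason = paste0(layer, " data absent"))))
    stopifnot(inherits(x, "signal_result"))
    x
  }
  structure(list(species_id = species_id, region_label = region_label,
                 signal1 = as_sig(signal1, "nuclear"),
                 signal2 = as_sig(signal2, "nuclear"),
                 signal3 = as_sig(signal3, "nuclear"),
                 signal4 = as_sig(signal4, "cpDNA")),
            class = "signal_profile")
}

profile_states <- function(profile) {
  vapply(profile[c("signal1", "signal2", "signal3", "signal4")],
         function(s) s$signal, character(1))
}

#' Classify a species from its signal profile and traits
#'
#' Applies the expected-pattern decision matrix. The history label is
#' advisory: `long_term_isolation` for large-fruited species with no
#' detected signal, `long_term_faunal` for small-fruited species whose only
#' patterns are homogeneity or IBD, `post_isolation_dispersal` when any
#' signal of dispersal following isolation is detected, else `ambiguous`.
#' The operative output is the candidate flag: a species is a candidate for
#' investigating human-mediated dispersal if and only if it is large
#' fruited and shows at least two detected signals or Signal 4 (haplotype
#' long-distance dispersal). Small-fruited species are never candidates
#' because volant faunal vectors cannot be excluded for them.
#' `not_assessable` signals never count toward the tally.
#'
#' @param profile A `signal_profile`.
#' @param traits A one-row slice of [species_traits()] (or the full table;
#'   the row matching `profile$species_id` is used).
#' @return A `screening_result`: species and region ids, fruit size class,
#'   signal states, `history_label`, `candidate`, `n_detected`, and a text
#'   `rationale`.
#' @export
classify_species <- function(profile, traits) {
  stopifnot(inherits(profile, "signal_profile"))
  tr <- traits[traits$species_id == profile$species_id, , drop = FALSE]
  if (nrow(tr) != 1L)
    ds_stop(paste0("traits unresolved for species ", profile$species_id),
            "ds_invalid")
  states <- profile_states(profile)
  n_det <- sum(states == "detected")
  large <- tr$fruit_size_class == "large"
  s4 <- states[["signal4"]] == "detected"
  candidate <- large && (n_det >= 2L || s4)
  history <- if (n_det == 0L) {
    if (large) "long_term_isolation" else "long_term_faunal"
  } else if (candidate || s4 || n_det >= 2L) {
    "post_isolation_dispersal"
  } else if (!large && states[["signal1"]] == "detected") {
    # low Fst / no IBD alone in a small-fruited species: widespread faunal
    "long_term_faunal"
  } else "ambiguous"
  rationale <- sprintf(
    "%s fruit; %d signal(s) detected [%s]; signal4 %s => %s",
    tr$fruit_size_class, n_det,
    paste(names(states)[states == "detected"], collapse = ","),
    states[["signal4"]],
    if (candidate) "candidate" else "not a candidate")
  structure(list(species_id = profile$species_id,
                 region_label = profile$region_label,
                 fruit_size_class = tr$fruit_size_class,
                 indigenous_use = tr$indigenous_use,
                 signals = states, n_detected = n_det,
                 history_label = history, candidate = candidate,
                 rationale = rationale, profile = profile),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("%s%s: %s\n", x$species_id,
              if (is.na(x$region_label)) "" else paste0(" (", x$region_label, ")"),
              x$rationale))
  invisible(x)
}

#' Classify a pre-computed signal matrix
#'
#' Applies [classify_species()] to a table of already-determined signal
#' states (e.g. a published screening summary), bypassing the detectors.
#'
#' @param signal_df Data frame with columns `species_id`, optional
#'   `region_label`, `large_fruit` (logical), `indigenous_use` (logical),
#'   and `signal1`..`signal4` each one of `"detected"`, `"not_detected"`,
#'   `"not_assessable"`.
#' @return Data frame with one row per input row plus `candidate`,
#'   `n_detected` and `history_label` columns.
#' @export
classify_signal_matrix <- function(signal_df) {
  need <- c("species_id", "large_fruit", "indigenous_use",
            paste0("signal", 1:4))
  miss <- setdiff(need, names(signal_df))
  if (length(miss))
    ds_stop(paste0("signal matrix missing column(s): ",
                   paste(miss, collapse = ", ")), "ds_invalid")
  out <- signal_df
  out$candidate <- FALSE
  out$n_detected <- 0L
  out$history_label <- NA_character_
  for (i in seq_len(nrow(signal_df))) {
    row <- signal_df[i, ]
    traits <- species_traits(data.frame(
      species_id = row$species_id,
      max_fruit_width_mm = if (row$large_fruit) 40 else 20,
      dispersal_class = "fleshy",
      indigenous_use = row$indigenous_use))
    prof <- assemble_profile(
      row$species_id,
      signal_result(row$signal1), signal_result(row$signal2),
      signal_result(row$signal3), signal_result(row$signal4),
      region_label = if ("region_label" %in% names(row))
        row$region_label else NA_character_)
    res <- classify_species(prof, traits)
    out$candidate[i] <- res$candidate
    out$n_detected[i] <- res$n_detected
    out$history_label[i] <- res$history_label
  }
  out
}

#' Path to the bundled east Australian rainforest signal matrix
#'
#' A 17-row signal/trait matrix reported for 15 east Australian rainforest
#' tree species (two species split by region) screened for dispersal
#' history; used as the worked example for [classify_signal_matrix()].
#'
#' @return File path of the CSV.
#' @export
eastoz_signal_matrix_path <- function() {
  system.file("extdata", "eastoz_rainforest_signals.csv",
              package = "dispersalscreen", mustWork = TRUE)
}

#' Run the full screen over a cohort of species datasets
#'
#' For every species (or species-by-region) dataset: filter markers,
#' compute pairwise Fst and the Mantel test, run admixture model selection
#' and PCA, build the chloroplast haplotype network when an alignment is
#' supplied, evaluate the four signals, and classify. Per-species failures
#' are caught and reported; the cohort run continues.
#'
#' @param datasets Named list; each element is a list with components
#'   `genotype_matrix`, `sample_metadata`, optional `cp_alignment`
#'   (`haploid_alignment` with row names matching sample ids), optional
#'   `region_label`.
#' @param traits A [species_traits()] table covering every dataset's
#'   species id (element names are used as `species_id`, unless the element
#'   carries its own).
#' @param config Optional list of threshold overrides (see
#'   [default_thresholds()]).
#' @param seed Base seed for the admixture and Mantel stages.
#' @return A `cohort_report`: `results` (list of `screening_result`),
#'   `table` (signal-matrix data frame with candidate stars), `errors`
#'   (named list of failure messages).
#' @export
screen_cohort <- function(datasets, traits, config = list(), seed = 1L) {
  thr <- utils::modifyList(default_thresholds(), config)
  results <- list()
  errors <- list()
  if (length(datasets) == 0L) {
    return(structure(list(results = list(),
                          table = data.frame(), errors = list()),
                     class = "cohort_report"))
  }
  for (nm in names(datasets)) {
    res <- tryCatch(
      screen_one(datasets[[nm]], species_id = datasets[[nm]]$species_id %||% nm,
                 traits = traits, thr = thr,
                 seed = derive_seed(seed, "screen", match(nm, names(datasets)))),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
    } else {
      results[[nm]] <- res
    }
  }
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    species_id = r$species_id, region_label = r$region_label,
    fruit_size_class = r$fruit_size_class,
    signal1 = r$signals[["signal1"]], signal2 = r$signals[["signal2"]],
    signal3 = r$signals[["signal3"]], signal4 = r$signals[["signal4"]],
    n_detected = r$n_detected, history_label = r$history_label,
    candidate = r$candidate, stringsAsFactors = FALSE)))
  if (!is.null(tab)) rownames(tab) <- NULL
  structure(list(results = results, table = tab %||% data.frame(),
                 errors = errors),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  if (nrow(x$table) == 0L) {
    cat("cohort_report: empty\n")
  } else {
    cat(sprintf("cohort_report: %d dataset(s), %d candidate(s)\n",
                nrow(x$table), sum(x$table$candidate)))
    print(x$table, row.names = FALSE)
  }
  if (length(x$errors))
    cat("failures:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

# One species/region through the whole pipeline.
screen_one <- function(dataset, species_id, traits, thr, seed) {
  gm <- dataset$genotype_matrix
  meta <- dataset$sample_metadata
  stopifnot(inherits(gm, "genotype_matrix"))
  meta <- meta[match(gm$sample_ids, meta$sample_id), ]
  site <- meta$site_code
  gm_f <- tryCatch(
    filter_markers(gm, thr$min_reproducibility, thr$min_call_rate),
    ds_config = function(e) {
      # QC metadata absent on simulated/derived data: fall back to call rate
      filter_markers(gm, min_reproducibility = NULL,
                     min_call_rate = thr$min_call_rate)
    })
  fst <- pairwise_fst(gm_f, site)
  dists <- geographic_distances(meta, sites = fst$site_codes)
  mant <- tryCatch(
    mantel_ibd(fst, dists, n_perm = thr$n_perm,
               seed = derive_seed(seed, "mantel"), cap_fst = TRUE),
    ds_toofewsites = function(e) NULL)
  s1 <- detect_signal1(fst, mant, thr$low_fst_threshold, thr$r_threshold)
  ks <- select_k(gm_f, k_range = seq(thr$k_min, thr$k_max),
                 replicates = thr$k_replicates,
                 seed = derive_seed(seed, "snmf"), alpha = thr$alpha,
                 max_iter = thr$snmf_max_iter)
  fit <- ks$best_fit
  pca <- pca_genotypes(gm_f, n_axes = 3L)
  s2 <- detect_signal2(fit, site, thr$dominance_threshold, thr$site_majority)
  s3 <- detect_signal3(fit, pca, site, thr$foreign_dominance)
  s4 <- NULL
  if (!is.null(dataset$cp_alignment)) {
    cp_ids <- rownames(dataset$cp_alignment)
    cp_meta <- meta[match(cp_ids, meta$sample_id), ]
    hs <- collapse_haplotypes(dataset$cp_alignment)
    net <- build_network(hs, epsilon = thr$epsilon)
    site_coords <- unique(data.frame(site_code = meta$site_code,
                                     latitude = meta$latitude,
                                     longitude = meta$longitude))
    site_coords <- stats::aggregate(
      cbind(latitude, longitude) ~ site_code, data = site_coords, FUN = mean)
    regions <- tapply(meta$region_label, meta$site_code, function(v) v[1L])
    s4 <- detect_signal4(net, hs, cp_meta$site_code, site_coords,
                         nuclear_fst = fst, site_regions = regions,
                         max_mut = thr$max_mut, min_fst = thr$min_fst,
                         widespread_fraction = thr$widespread_fraction)
  }
  prof <- assemble_profile(species_id, s1, s2, s3, s4,
                           region_label = dataset$region_label %||% NA_character_)
  classify_species(prof, traits)
}

#' Default pipeline thresholds
#'
#' The screening workflow's tunable thresholds with their defaults: marker
#' reproducibility 0.96 and call rate 0.80; cp variant coverage 8 and
#' consensus 0.60; fruit-size boundary 30 mm; Signal 1 median-Fst 0.05 and
#' Mantel r 0.30; Signal 2 dominance 0.75 with site majority 0.5; Signal 3
#' foreign dominance 0.60; Signal 4 max 2 mutations, nuclear Fst 0.15,
#' widespread fraction 0.80; 999 Mantel permutations; admixture K range
#' 1-10 with 10 replicates; 50 km distance bins to 700 km; network epsilon
#' 0.
#'
#' @return Named list of defaults.
#' @export
default_thresholds <- function() {
  list(min_reproducibility = 0.96, min_call_rate = 0.80,
       min_coverage = 8, min_consensus = 0.60,
       fruit_size_boundary_mm = 30,
       low_fst_threshold = 0.05, r_threshold = 0.30,
       dominance_threshold = 0.75, site_majority = 0.5,
       foreign_dominance = 0.60,
       max_mut = 2, min_fst = 0.15, widespread_fraction = 0.80,
       n_perm = 999, k_min = 1, k_max = 10, k_replicates = 10,
       alpha = 10, snmf_max_iter = 200,
       bin_width_km = 50, max_km = 700, epsilon = 0)
}

#' Trait-group Fst summary across species
#'
#' Combines per-species distance-binned Fst summaries into the five
#' fruit-trait groups (large/small fleshy crossed with recorded human use,
#' plus wind dispersed), in long plot-ready format with the pooled
#' long-distance display bin appended.
#'
#' @param binned_list Named list of `binned_fst` objects (names =
#'   species ids).
#' @param traits A [species_traits()] table covering those species.
#' @return Data frame with columns `trait_group`, `species_id`, `lower`,
#'   `upper`, `mean_fst`, `n_pairs`. Species with no in-range pairs are
#'   omitted with a warning; empty trait groups are absent from the output.
#' @export
trait_group_fst_summary <- function(binned_list, traits) {
  stopifnot(inherits(traits, "species_traits"))
  group_of <- function(tr) {
    if (tr$dispersal_class == "wind") return("wind dispersed")
    size <- tr$fruit_size_class
    if (isTRUE(tr$indigenous_use)) paste(size, "fleshy, recorded use")
    else paste(size, "fleshy")
  }
  rows <- list()
  for (sp in names(binned_list)) {
    tr <- traits[traits$species_id == sp, , drop = FALSE]
    if (nrow(tr) != 1L)
      ds_stop(paste0("traits unresolved for species ", sp), "ds_invalid")
    b <- binned_list[[sp]]
    stopifnot(inherits(b, "binned_fst"))
    df <- rbind(b$bins, b$pooled)
    df <- df[!is.na(df$mean_fst), , drop = FALSE]
    if (nrow(df) == 0L) {
      warning("species ", sp, " has no in-range site pairs; omitted")
      next
    }
    df$species_id <- sp
    df$trait_group <- group_of(tr)
    rows[[sp]] <- df[, c("trait_group", "species_id", "lower", "upper",
                         "mean_fst", "n_pairs")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out %||% data.frame()
}
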