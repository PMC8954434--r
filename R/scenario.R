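#' Nine dispersal-scenario presets
#'
#' Identifiers of the built-in demographic scenarios: two faunal dispersal
#' models (`fd1`, `fd2`), one post-megafauna isolation model (`iso`), and six
#' human-dispersal models (`hd1`-`hd6`). See [build_scenario()] for their
#' demographic semantics.
#'
#' @export
scenario_ids <- function() c("fd1", "fd2", "iso", paste0("hd", 1:6))

# Chain coordinates: demes ~100 km apart along a coastal latitudinal
# transect (0.8993 degrees of latitude ~ 100 km).
default_deme_coords <- function(n_demes) {
  data.frame(deme = seq_len(n_demes),
             latitude = -28 + (seq_len(n_demes) - 1L) * 0.899321,
             longitude = rep(153.0, n_demes))
}

# Distance matrix (km) between deme coordinates.
deme_distances_km <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j)
      d[i, j] <- geosphere::distHaversine(
        c(coords$longitude[i], coords$latitude[i]),
        c(coords$longitude[j], coords$latitude[j]), r = 6371.0088) # km
  }
  d
}

island_matrix <- function(n, m) {
  M <- matrix(m, n, n); diag(M) <- 0; M
}

chain_oneway_matrix <- function(n, m) {
  # deme i+1 receives fraction m of its gametes from deme i each generation
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) M[i + 1L, i] <- m
  M
}

distance_weighted_matrix <- function(dists, m0, lambda_km) {
  M <- m0 * exp(-dists / lambda_km)
  diag(M) <- 0
  M
}

#' Build a dispersal-scenario configuration
#'
#' Returns a fully populated demographic configuration for one of the nine
#' preset scenarios. All presets share a panmictic ancestral population of
#' size `n_demes * deme_size` that splits into demes at `divergence_time`;
#' epochs (ordered present to past, years before present) then define the
#' per-generation migration fractions between demes. Migration matrices are
#' oriented receiver-by-source: `M[i, j]` is the fraction of deme `i`'s
#' gametes drawn from deme `j` each generation.
#'
#' Preset semantics:
#' \describe{
#'   \item{fd1}{Distance-weighted (faunal) migration
#'     `m0 * exp(-d_ij / 150 km)` ongoing since the post-glacial re-expansion
#'     (16 kya).}
#'   \item{fd2}{As `fd1` with a dispersal barrier between demes 3 and 4:
#'     migration across the barrier is multiplied by 0.01.}
#'   \item{iso}{All migration zero since the megafauna-extinction epoch
#'     (30 kya): pure drift.}
#'   \item{hd1}{Isolation as in `iso`, then symmetric island-model migration
#'     from 8 kya to the present (human dispersal network).}
#'   \item{hd2}{`hd1` at ten-fold lower migration.}
#'   \item{hd3}{Island-model migration confined to a 5000-4000 years BP
#'     window, isolation otherwise.}
#'   \item{hd4}{No migration; deme 2 is founded from deme 1 at 4 kya
#'     (range expansion).}
#'   \item{hd5}{One-way chain (directional) migration from 8 kya to present.}
#'   \item{hd6}{One-way chain migration confined to 5000-4000 years BP.}
#' }
#'
#' @param scenario_id One of [scenario_ids()].
#' @param ... Named overrides of configuration fields (`n_demes`,
#'   `deme_size`, `generation_time`, `mutation_rate`, `n_nuclear_sites`,
#'   `cp_sequence_length`, `samples_per_deme_nuclear`, `samples_per_deme_cp`,
#'   `seed`, `m` to scale the preset's migration intensity,
#'   `deme_coordinates`, `epochs`, `founding_events`, `divergence_time`).
#' @return An object of class `scenario_config`. Deterministic: no
#'   randomness is consumed.
#' @export
build_scenario <- function(scenario_id, ...) {
  if (!is.character(scenario_id) || length(scenario_id) != 1L ||
      !scenario_id %in% scenario_ids())
    ds_stop(paste0("unknown scenario_id '", paste(scenario_id, collapse = ","),
                   "'; valid ids: ", paste(scenario_ids(), collapse = ", ")),
            "ds_invalid")
  ov <- list(...)
  allowed <- c("n_demes", "deme_size", "generation_time", "mutation_rate",
               "n_nuclear_sites", "cp_sequence_length",
               "samples_per_deme_nuclear", "samples_per_deme_cp", "seed", "m",
               "deme_coordinates", "epochs", "founding_events",
               "divergence_time")
  bad <- setdiff(names(ov), allowed)
  if (length(bad))
    ds_stop(paste0("unknown override field(s): ", paste(bad, collapse = ", ")),
            "ds_invalid")

  n_demes <- ov$n_demes %||% 6L
  deme_size <- ov$deme_size %||% 1000
  coords <- ov$deme_coordinates %||% default_deme_coords(n_demes)
  dists <- deme_distances_km(coords)

  # preset migration intensities (per-generation fractions); `m` override
  # rescales the preset's base rate
  base_m <- switch(scenario_id,
                   fd1 = 0.005, fd2 = 0.005, iso = 0,
                   hd1 = 0.002, hd2 = 0.0002, hd3 = 0.003,
                   hd4 = 0, hd5 = 0.005, hd6 = 0.003)
  if (!is.null(ov$m)) base_m <- ov$m

  zero <- matrix(0, n_demes, n_demes)
  epochs <- switch(scenario_id,
    fd1 = list(list(start = 0, end = 16000,
                    M = distance_weighted_matrix(dists, base_m, 150))),
    fd2 = {
      M <- distance_weighted_matrix(dists, base_m, 150)
      if (n_demes >= 4L) {
        south <- seq_len(3L); north <- 4L:n_demes
        M[south, north] <- M[south, north] * 0.01
        M[north, south] <- M[north, south] * 0.01
      }
      list(list(start = 0, end = 16000, M = M))
    },
    iso = list(list(start = 0, end = 30000, M = zero)),
    hd1 = list(list(start = 0, end = 8000, M = island_matrix(n_demes, base_m)),
               list(start = 8000, end = 30000, M = zero)),
    hd2 = list(list(start = 0, end = 8000, M = island_matrix(n_demes, base_m)),
               list(start = 8000, end = 30000, M = zero)),
    hd3 = list(list(start = 0, end = 4000, M = zero),
               list(start = 4000, end = 5000, M = island_matrix(n_demes, base_m)),
               list(start = 5000, end = 30000, M = zero)),
    hd4 = list(list(start = 0, end = 30000, M = zero)),
    hd5 = list(list(start = 0, end = 8000, M = chain_oneway_matrix(n_demes, base_m)),
               list(start = 8000, end = 30000, M = zero)),
    hd6 = list(list(start = 0, end = 4000, M = zero),
               list(start = 4000, end = 5000, M = chain_oneway_matrix(n_demes, base_m)),
               list(start = 5000, end = 30000, M = zero)))
  divergence_time <- switch(scenario_id, fd1 = 16000, fd2 = 16000, 30000)
  founding <- if (scenario_id == "hd4" && n_demes >= 2L) {
    data.frame(deme = 2L, time = 4000, source = 1L)
  } else {
    data.frame(deme = integer(0), time = numeric(0), source = integer(0))
  }

  cfg <- structure(list(
    scenario_id = scenario_id,
    n_demes = as.integer(n_demes),
    deme_coordinates = coords,
    deme_size = deme_size,
    epochs = ov$epochs %||% epochs,
    founding_events = ov$founding_events %||% founding,
    divergence_time = ov$divergence_time %||% divergence_time,
    generation_time = ov$generation_time %||% 30,
    mutation_rate = ov$mutation_rate %||% 1e-8,
    n_nuclear_sites = ov$n_nuclear_sites %||% 2.5e6,
    cp_sequence_length = ov$cp_sequence_length %||% 1e5,
    samples_per_deme_nuclear = ov$samples_per_deme_nuclear %||% 10L,
    samples_per_deme_cp = ov$samples_per_deme_cp %||% 3L,
    seed = ov$seed %||% 1L), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks the structural invariants of a demographic configuration: epochs
#' contiguous from the present, non-overlapping and ordered present to past;
#' migration matrices non-negative with zero diagonal and row sums below 1;
#' founding events inside the simulated time span.
#'
#' @param cfg A `scenario_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n_demes
  if (n < 1L) ds_stop("n_demes must be >= 1", "ds_invalid")
  if (nrow(cfg$deme_coordinates) != n)
    ds_stop("deme_coordinates must have one row per deme", "ds_invalid")
  ep <- cfg$epochs
  if (length(ep) == 0L) ds_stop("at least one epoch required", "ds_invalid")
  prev_end <- 0
  for (k in seq_along(ep)) {
    e <- ep[[k]]
    if (e$start != prev_end)
      ds_stop("epochs must be contiguous, ordered present to past", "ds_invalid")
    if (e$end <= e$start)
      ds_stop("epoch end must exceed start (years BP)", "ds_invalid")
    M <- e$M
    if (!is.matrix(M) || any(dim(M) != n))
      ds_stop("migration matrix dimensions must equal n_demes", "ds_invalid")
    if (any(M < 0) || any(diag(M) != 0))
      ds_stop("migration matrices must be non-negative with zero diagonal",
              "ds_invalid")
    if (any(rowSums(M) >= 1))
      ds_stop("migration matrix row sums must be < 1", "ds_invalid")
    prev_end <- e$end
  }
  if (cfg$divergence_time < prev_end)
    ds_stop("divergence_time must be at or beyond the oldest epoch end",
            "ds_invalid")
  fe <- cfg$founding_events
  if (nrow(fe)) {
    if (any(fe$time <= 0 | fe$time >= cfg$divergence_time))
      ds_stop("founding times must fall inside the simulated time span",
              "ds_invalid")
    if (any(fe$deme < 1 | fe$deme > n | fe$source < 1 | fe$source > n) ||
        any(fe$deme == fe$source))
      ds_stop("founding events must name two distinct demes", "ds_invalid")
  }
  if (cfg$samples_per_deme_nuclear > 2 * cfg$deme_size)
    ds_stop("cannot sample more individuals than a deme holds", "ds_invalid")
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config '%s': %d demes of size %g, divergence %g y BP, %d epoch(s)\n",
              x$scenario_id, x$n_demes, x$deme_size, x$divergence_time,
              length(x$epochs)))
  invisible(x)
}
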