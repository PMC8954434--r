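#' Read an aligned FASTA of haploid sequences
#'
#' Reads a chloroplast (or other haploid) alignment from FASTA via the ape
#' package, enforcing equal sequence lengths. IUPAC ambiguity codes and gap
#' characters are tolerated; their per-sequence counts are recorded in an
#' `ambiguity_report` attribute. Sequence order and identifiers follow the
#' file.
#'
#' @param path FASTA file path (gzip accepted).
#' @return A character matrix (sequences x alignment columns) of upper-case
#'   single characters, with sequence ids as row names, class
#'   `haploid_alignment`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) ds_stop(paste0("file not found: ", path), "ds_io")
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L) {
    tab <- table(lens)
    modal <- as.integer(names(tab)[which.max(tab)])
    bad <- names(dna)[lens != modal]
    ds_stop(paste0("ragged alignment; offending ids: ",
                   paste(bad, collapse = ", ")), "ds_parse")
  }
  mat <- toupper(as.character(as.matrix(dna)))
  haploid_alignment(mat)
}

#' Construct a haploid alignment from a character matrix
#'
#' @param mat Character matrix, rows = sequences, columns = alignment
#'   positions (reported 1-based).
#' @return The matrix with class `haploid_alignment` and an
#'   `ambiguity_report` attribute counting non-ACGT characters per sequence.
#' @export
haploid_alignment <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("seq", seq_len(nrow(mat)))
  mat[] <- toupper(mat)
  amb <- rowSums(matrix(!(mat %in% c("A", "C", "G", "T")), nrow(mat)))
  names(amb) <- rownames(mat)
  structure(mat, class = c("haploid_alignment", class(mat)),
            ambiguity_report = amb)
}

#' Write a haploid alignment to FASTA
#'
#' @param aln A `haploid_alignment` (or plain character matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  aln <- as.matrix(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    seqchars <- aln[i, ]
    # wrap at 80 columns
    starts <- seq(1L, length(seqchars), by = 80L)
    for (s in starts)
      writeLines(paste(seqchars[s:min(s + 79L, length(seqchars))], collapse = ""), con)
  }
  invisible(path)
}

#' Sample metadata table
#'
#' Validates a per-sample metadata table: coordinates in decimal degrees,
#' one row per sample.
#'
#' @param df Data frame with columns `sample_id`, `site_code`, `latitude`,
#'   `longitude`, and optionally `species_id` and `region_label`.
#' @return The validated data frame with class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "site_code", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ds_stop(paste0("sample metadata missing column(s): ",
                   paste(miss, collapse = ", ")), "ds_invalid")
  if (anyDuplicated(df$sample_id))
    ds_stop("duplicate sample_id in metadata", "ds_invalid")
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE) ||
      any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE))
    ds_stop("coordinates out of range", "ds_invalid")
  class(df) <- c("sample_metadata", "data.frame")
  df
}
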