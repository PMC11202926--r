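# Alignment input/output, coding-integrity QC and alignment-level statistics.

#' Read an aligned barcode dataset
#'
#' Reads an equal-length (pre-aligned, indel-free or gap-padded) FASTA file
#' together with a tab-separated specimen metadata table and joins them into
#' a tidy record table, one row per specimen, in FASTA order.
#'
#' The metadata file must have a header with at least the columns
#' `specimen_id`, `morphological_label`, `genus`, `family`; `station`,
#' `depth_m` and `molecular_label` are optional and filled with `NA` when
#' absent. Every FASTA identifier must have a metadata row.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param metadata_path Path to the tab-separated metadata table.
#' @return A tibble with columns `specimen_id`, `sequence`,
#'   `morphological_label`, `molecular_label`, `genus`, `family`, `station`,
#'   `depth_m`.
#' @examples
#' sim <- simulate_barcodes(sim_config(n_species = 2, specimens_per_species = 2,
#'   n_genera = 2, n_families = 1, length = 60, seed = 1))
#' fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
#' write_barcodes(sim$records, fa, tsv)
#' read_barcodes(fa, tsv)
#' @export
read_barcodes <- function(fasta_path, metadata_path) {
  seqs <- read_fasta_aligned(fasta_path)
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  if ("depth_m" %in% names(meta)) meta$depth_m <- as.numeric(meta$depth_m)
  required <- c("specimen_id", "morphological_label", "genus", "family")
  miss_col <- setdiff(required, names(meta))
  if (length(miss_col) > 0) {
    abort(paste0("metadata is missing required column(s): ",
                 paste(miss_col, collapse = ", ")))
  }
  for (opt in c("molecular_label", "station")) {
    if (!opt %in% names(meta)) meta[[opt]] <- NA_character_
  }
  if (!"depth_m" %in% names(meta)) meta$depth_m <- NA_real_
  if (anyDuplicated(meta$specimen_id)) {
    abort("duplicated specimen_id in metadata")
  }
  orphan <- setdiff(names(seqs), meta$specimen_id)
  if (length(orphan) > 0) {
    abort(paste0("no metadata row for FASTA id(s): ",
                 paste(orphan, collapse = ", ")))
  }
  tibble(specimen_id = names(seqs), sequence = unname(seqs)) |>
    dplyr::left_join(
      dplyr::select(meta, "specimen_id", "morphological_label",
                    "molecular_label", "genus", "family", "station",
                    "depth_m"),
      by = "specimen_id"
    )
}

# FASTA reader: enforces a single shared alignment length and the
# {ACGT, IUPAC ambiguity, '-'} alphabet. Returns a named uppercase
# character vector.
read_fasta_aligned <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) abort("empty FASTA file")
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  names(seqs) <- names(dna)
  if (anyDuplicated(names(seqs))) abort("duplicated FASTA identifiers")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[lens != max(lens)]
    abort(paste0(
      "alignment error: sequences differ in length (",
      paste(unique(lens), collapse = ", "), " bp); offending id(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  allowed <- c("A", "C", "G", "T", IUPAC_AMBIG, "-", "?")
  chars <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0) {
    abort(paste0("invalid characters in alignment: ",
                 paste(bad, collapse = ", ")))
  }
  seqs
}

#' Write an aligned barcode dataset
#'
#' Inverse of [read_barcodes()]: writes the sequences as FASTA and (optionally)
#' the remaining columns as a tab-separated metadata table, so that a
#' write/read round trip reproduces identifiers and sequences exactly.
#'
#' @param records A record tibble as returned by [read_barcodes()] or
#'   [simulate_barcodes()].
#' @param fasta_path Output FASTA path.
#' @param metadata_path Optional output path for the metadata table.
#' @return `records`, invisibly.
#' @export
write_barcodes <- function(records, fasta_path, metadata_path = NULL) {
  stopifnot(is.data.frame(records),
            all(c("specimen_id", "sequence") %in% names(records)))
  mat <- do.call(rbind, strsplit(tolower(records$sequence), "", fixed = TRUE))
  rownames(mat) <- records$specimen_id
  ape::write.FASTA(ape::as.DNAbin(mat), fasta_path)
  if (!is.null(metadata_path)) {
    meta_cols <- intersect(
      c("specimen_id", "morphological_label", "molecular_label", "genus",
        "family", "station", "depth_m"),
      names(records)
    )
    readr::write_tsv(records[meta_cols], metadata_path)
  }
  invisible(records)
}

# number of stop codons among complete, unambiguous codons of `s` read in
# `frame` (0, 1 or 2)
count_frame_stops <- function(s, frame) {
  n <- nchar(s)
  n_codons <- (n - frame) %/% 3
  if (n_codons < 1) return(0L)
  pos <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(s, pos, pos + 2L)
  sum(codons %in% VERT_MITO_STOPS)
}

#' Coding-integrity quality control
#'
#' Checks each barcode sequence for hallmarks of a functional protein-coding
#' mitochondrial fragment: no alignment gaps and no internal stop codons
#' under the vertebrate mitochondrial genetic code. When `frame` is not
#' given, the reading frame is auto-detected as the frame (0, 1 or 2) with
#' the fewest stop codons, ties broken by the lowest frame index.
#'
#' @param records A record tibble (columns `specimen_id`, `sequence`).
#' @param frame Optional fixed reading frame (0, 1 or 2) applied to all
#'   sequences; `NULL` auto-detects per sequence.
#' @return A tibble with one row per specimen: `specimen_id`, `length`,
#'   `has_gap`, `has_internal_stop`, `chosen_frame`, `ambiguous_site_count`.
#' @export
check_coding_integrity <- function(records, frame = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (!is.null(frame) && !frame %in% 0:2) {
    abort("frame must be 0, 1 or 2")
  }
  purrr::map2(records$specimen_id, records$sequence, function(id, s) {
    if (nchar(s) == 0) abort(paste0("empty sequence for ", id))
    stops <- vapply(0:2, function(f) count_frame_stops(s, f), integer(1))
    f <- if (is.null(frame)) which.min(stops) - 1L else as.integer(frame)
    tibble(
      specimen_id = id,
      length = nchar(s),
      has_gap = grepl("-", s, fixed = TRUE),
      has_internal_stop = stops[f + 1L] > 0L,
      chosen_frame = f,
      ambiguous_site_count =
        nchar(gsub(paste0("[^", paste(IUPAC_AMBIG, collapse = ""), "?]"),
                   "", s))
    )
  }) |>
    purrr::list_rbind()
}

#' Alignment-level composition and site statistics
#'
#' Computes mean base composition (per-sequence percentages averaged across
#' sequences), the number of polymorphic sites (columns with at least two
#' distinct unambiguous bases) and of parsimony-informative sites (columns
#' with at least two bases each present in at least two sequences).
#' Ambiguity codes and gaps are treated as missing throughout.
#'
#' @param records A record tibble with at least two rows.
#' @return A one-row tibble: `length`, `polymorphic_sites`,
#'   `parsimony_informative_sites`, `pct_a`, `pct_c`, `pct_g`, `pct_t`.
#' @export
alignment_stats <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 2) {
    abort("alignment_stats requires at least 2 records")
  }
  m <- seq_char_matrix(records)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1) counts <- matrix(counts, nrow = 1,
                                     dimnames = list(NULL, bases))
  polymorphic <- rowSums(counts > 0) >= 2
  informative <- rowSums(counts >= 2) >= 2
  per_seq_pct <- t(apply(m, 1, function(row) {
    n <- vapply(bases, function(b) sum(row == b), numeric(1))
    100 * n / sum(n)
  }))
  comp <- colMeans(per_seq_pct)
  tibble(
    length = ncol(m),
    polymorphic_sites = sum(polymorphic),
    parsimony_informative_sites = sum(informative),
    pct_a = comp[["A"]], pct_c = comp[["C"]],
    pct_g = comp[["G"]], pct_t = comp[["T"]]
  )
}

# records -> n x L uppercase character matrix with specimen_id rownames
seq_char_matrix <- function(records) {
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L) {
    abort("alignment error: sequences differ in length")
  }
  m <- do.call(rbind, strsplit(toupper(records$sequence), "", fixed = TRUE))
  rownames(m) <- records$specimen_id
  m
}
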