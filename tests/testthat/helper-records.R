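# fixture builders shared across test files

make_records <- function(seqs, species = NULL, genus = NULL, family = NULL,
                         ids = NULL) {
  n <- length(seqs)
  ids <- ids %||% names(seqs) %||% sprintf("s%02d", seq_len(n))
  tibble::tibble(
    specimen_id = ids,
    sequence = unname(seqs),
    morphological_label = species %||% rep("Species one", n),
    molecular_label = NA_character_,
    genus = genus %||% rep("Genus", n),
    family = family %||% rep("Family", n),
    station = NA_character_,
    depth_m = NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a sequence pair of length L with exactly n_ts transition and n_tv
# transversion differences (A->G transitions, A->C transversions)
patterned_pair <- function(L, n_ts, n_tv) {
  a <- rep("A", L)
  b <- a
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "C"
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

taxonomy_of <- function(records) {
  tibble::tibble(
    specimen_id = records$specimen_id,
    species = records$morphological_label,
    genus = records$genus,
    family = records$family
  )
}

species_vec <- function(records, col = "morphological_label") {
  stats::setNames(records[[col]], records$specimen_id)
}
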