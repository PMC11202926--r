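# Reference-library identification at a percent-identity threshold and
# morphology-versus-molecular concordance classification.

#' Identify query sequences against a reference library
#'
#' Computes percent identity (100 x (1 - p-distance) over pairwise-deleted
#' sites) between each query and every reference, and reports the best hit.
#' A query is `identified` when its best identity reaches the threshold
#' (default 98), `unidentified` otherwise. Identity ties are broken by
#' lexicographically smallest reference label.
#'
#' @param queries A record tibble (columns `specimen_id`, `sequence`) or a
#'   named character vector of sequences.
#' @param references A tibble with columns `label` and `sequence` (several
#'   references may share a label) or a character vector of sequences named
#'   by label.
#' @param threshold Identity threshold in percent (default 98).
#' @return A tibble with one row per query: `query_id`,
#'   `best_reference_label`, `identity` (percent), `status`.
#' @export
identify_specimens <- function(queries, references, threshold = 98) {
  if (NROW(references) == 0 || length(references) == 0) {
    abort("empty reference set")
  }
  q <- as_seq_vector(queries, c("specimen_id", "sequence"))
  r <- as_seq_vector(references, c("label", "sequence"))
  if (length(unique(nchar(c(q, r)))) != 1) {
    abort("queries and references must be aligned to a common length")
  }
  rcodes <- do.call(rbind, lapply(r, seq_codes))
  purrr::imap(q, function(s, id) {
    qc <- seq_codes(s)
    ident <- apply(rcodes, 1, function(rc) {
      ok <- !is.na(qc) & !is.na(rc)
      ns <- sum(ok)
      if (ns == 0) return(NA_real_)
      100 * sum(qc[ok] == rc[ok]) / ns
    })
    if (all(is.na(ident))) {
      return(tibble(query_id = id, best_reference_label = NA_character_,
                    identity = NA_real_, status = "unidentified"))
    }
    best <- max(ident, na.rm = TRUE)
    lab <- sort(names(r)[!is.na(ident) & ident == best])[1]
    tibble(
      query_id = id,
      best_reference_label = lab,
      identity = best,
      status = if (best >= threshold) "identified" else "unidentified"
    )
  }) |>
    purrr::list_rbind()
}

as_seq_vector <- function(x, cols) {
  if (is.data.frame(x)) {
    stopifnot(all(cols %in% names(x)))
    setNames(x[[cols[2]]], x[[cols[1]]])
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    x
  }
}

seq_codes <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

#' Parse a taxonomic specimen label
#'
#' Extracts genus and species epithet from a label as printed in specimen
#' tables: markdown emphasis is stripped, authority strings ("Regan, 1913",
#' parenthesised or not, including stray parentheses) are ignored, and a
#' `sp.`/`sp.1`/`spp.` token anywhere after the genus marks a genus-level
#' label.
#'
#' @param label Character vector of labels.
#' @return A tibble with columns `label`, `genus`, `epithet` (`NA` for
#'   genus-level labels) and `genus_only`.
#' @export
parse_taxon_label <- function(label) {
  purrr::map(label, function(lab) {
    x <- gsub("*", "", lab, fixed = TRUE)
    x <- stringr::str_squish(x)
    if (x == "") abort("unparsable label: empty")
    tokens <- strsplit(x, " ", fixed = TRUE)[[1]]
    clean <- gsub("^[(\\[]+|[)\\],]+$", "", tokens)
    if (!grepl("^[A-Z][A-Za-z-]+$", clean[1])) {
      abort(paste0("unparsable label: ", lab))
    }
    genus <- clean[1]
    rest <- clean[-1]
    genus_only <- any(grepl("^spp?\\.[0-9]*$", rest))
    epithet <- NA_character_
    if (!genus_only) {
      hit <- grep("^[a-z][a-z-]+$", rest, value = TRUE)
      if (length(hit) == 0) abort(paste0("unparsable label: ", lab))
      epithet <- hit[1]
    }
    tibble(label = lab, genus = genus, epithet = epithet,
           genus_only = genus_only)
  }) |>
    purrr::list_rbind()
}

#' Classify morphology-versus-molecular concordance
#'
#' For each (morphological label, molecular label) pair:
#' * `matched` — same genus and same species epithet (authorities ignored);
#' * `refined` — the morphological label is genus-level (`sp.`/`spp.`) and
#'   the molecular genus equals the morphological genus (identification
#'   resolved to species within the expected genus);
#' * `invalid` — anything else (the morphological identification is
#'   contradicted).
#'
#' @param morph_label,mol_label Character vectors (recycled to common
#'   length) of morphological and molecular labels.
#' @return A character vector in `{matched, refined, invalid}`.
#' @examples
#' classify_concordance("Macrourus whitsoni (Regan, 1913)",
#'                      "Macrourus whitsoni (Regan, 1913)")
#' classify_concordance("Bathylagus Gunther, 1878 sp.",
#'                      "Bathylagus antarcticus Gunther, 1878")
#' @export
classify_concordance <- function(morph_label, mol_label) {
  n <- max(length(morph_label), length(mol_label))
  morph <- parse_taxon_label(rep_len(morph_label, n))
  mol <- parse_taxon_label(rep_len(mol_label, n))
  dplyr::case_when(
    !morph$genus_only & !mol$genus_only &
      morph$genus == mol$genus & morph$epithet == mol$epithet ~ "matched",
    morph$genus_only & morph$genus == mol$genus ~ "refined",
    TRUE ~ "invalid"
  )
}

#' Summarise concordance classes
#'
#' @param records A tibble with either a `klass` column or both
#'   `morph_label` and `mol_label` columns (classified on the fly).
#' @return A tibble with one row per class (`matched`, `refined`,
#'   `invalid`): `klass`, `n`, `pct` (percent of records, 2 decimals).
#' @export
concordance_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (!"klass" %in% names(records)) {
    stopifnot(all(c("morph_label", "mol_label") %in% names(records)))
    records$klass <- classify_concordance(records$morph_label,
                                          records$mol_label)
  }
  lv <- c("matched", "refined", "invalid")
  bad <- setdiff(unique(records$klass), lv)
  if (length(bad) > 0) abort(paste0("unknown class: ", paste(bad, collapse = ", ")))
  records |>
    dplyr::count(klass = factor(.data$klass, levels = lv),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(klass = as.character(.data$klass),
                  pct = round(100 * .data$n / sum(.data$n), 2))
}

#' Shared taxa between two occurrence lists
#'
#' Compares two species occurrence lists (for example a survey result
#' against historical records) and counts shared taxa at species, genus and
#' family rank. Genus-level entries (`sp.`/`spp.`) contribute their genus at
#' genus rank only; species are matched by exact binomial after authority
#' stripping.
#'
#' @param list_a,list_b Tibbles with columns `family` and `species` (labels
#'   may be binomials or genus-level `Genus spp.` entries).
#' @return A tibble with one row per rank: `rank`, `n_a`, `n_b`, `n_shared`.
#' @export
occurrence_overlap <- function(list_a, list_b) {
  side <- function(df) {
    stopifnot(is.data.frame(df), all(c("family", "species") %in% names(df)))
    p <- parse_taxon_label(df$species)
    list(
      species = unique(paste(p$genus, p$epithet)[!p$genus_only]),
      genus = unique(p$genus),
      family = unique(df$family)
    )
  }
  a <- side(list_a)
  b <- side(list_b)
  purrr::map(c("species", "genus", "family"), function(rk) {
    tibble(rank = rk, n_a = length(a[[rk]]), n_b = length(b[[rk]]),
           n_shared = length(intersect(a[[rk]], b[[rk]])))
  }) |>
    purrr::list_rbind()
}

#' Packaged specimen concordance table (98 Antarctic fish barcodes)
#'
#' The packaged transcription of the study's specimen table: 98 demersal
#' fish specimens trawled in the Cosmonaut Sea, each with its field
#' (morphological) identification and the species label assigned by COI
#' barcoding, plus station and depth. `flagged` marks the rows annotated as
#' initially ambiguous or incorrectly identified.
#'
#' @return A tibble with columns `specimen_id`, `cruise`, `station`,
#'   `depth_m`, `morph_label`, `mol_label`, `flagged`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_specimens.tsv",
                      package = "barcodegap", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    specimen_id = readr::col_character(),
    cruise = readr::col_character(),
    station = readr::col_character(),
    depth_m = readr::col_double(),
    morph_label = readr::col_character(),
    mol_label = readr::col_character(),
    flagged = readr::col_logical()
  )) |>
    dplyr::mutate(dplyr::across(c("morph_label", "mol_label"),
                                ~ gsub("*", "", .x, fixed = TRUE)))
}

#' Packaged occurrence lists (Cosmonaut Sea fishes)
#'
#' Two occurrence lists for demersal fishes of the Cosmonaut Sea: the
#' historical records compiled in the regional literature and the species
#' recovered by the barcoding survey. Suitable input for
#' [occurrence_overlap()].
#'
#' @return A named list of two tibbles (`historical`, `survey`), each with
#'   columns `family` and `species`.
#' @export
table2_occurrence <- function() {
  read_one <- function(f) {
    readr::read_tsv(
      system.file("extdata", f, package = "barcodegap", mustWork = TRUE),
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  list(historical = read_one("table2_historical.tsv"),
       survey = read_one("table2_survey.tsv"))
}

#' Packaged per-species divergence table (Cosmonaut Sea fishes)
#'
#' The published per-species gap table of the barcoding survey: minimum and
#' mean interspecific and maximum and mean intraspecific K2P distances for
#' the 24 species, converted to percent. Shaped like the output of
#' [gap_table()] (without `nearest_species`), so it can be fed directly to
#' [overlap_report()].
#'
#' @return A `gap_table` tibble with columns `species`, `min_inter`,
#'   `mean_inter`, `max_intra`, `mean_intra` (percent).
#' @export
table4_divergence <- function() {
  path <- system.file("extdata", "table4_divergence.tsv",
                      package = "barcodegap", mustWork = TRUE)
  out <- readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(), .default = readr::col_double()
  )) |>
    dplyr::mutate(dplyr::across(-"species", ~ 100 * .x))
  class(out) <- c("gap_table", class(out))
  out
}

#' Packaged rank-level divergence summary (Cosmonaut Sea fishes)
#'
#' The published divergence summary across taxonomic ranks (percent):
#' maximum, minimum, mean and standard error of the K2P distance within
#' species, within genus and within family.
#'
#' @return A tibble with columns `rank`, `max`, `min`, `mean`, `se`.
#' @export
table3_rank_divergence <- function() {
  path <- system.file("extdata", "table3_rank_divergence.tsv",
                      package = "barcodegap", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_character(), .default = readr::col_double()
  ))
}
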