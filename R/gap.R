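# Barcoding-gap testing (per-species gap table, 10x criterion, overlap
# verdict) and gap-scored single-linkage threshold partitioning.

#' Per-species barcoding-gap table
#'
#' For each species: the distance to its nearest heterospecific specimen
#' (`min_inter`), the mean over all heterospecific pairs (`mean_inter`), and
#' the maximum and mean conspecific distance (`max_intra`, `mean_intra`,
#' `NA` for singletons). All values in percent. Nearest-neighbour ties are
#' broken by lexicographic species name.
#'
#' @param x A `k2p_dist` object.
#' @param species Species labels: a tibble with columns `specimen_id` and
#'   `species`, or a character vector named by specimen id.
#' @return A `gap_table` tibble with columns `species`, `n`,
#'   `min_inter`, `mean_inter`, `max_intra`, `mean_intra`,
#'   `nearest_species`.
#' @export
gap_table <- function(x, species) {
  sp <- species_lookup(x, species)
  if (length(unique(sp)) < 2) {
    abort("gap_table requires at least 2 species (no interspecific pairs)")
  }
  pairs <- tidy(x)
  pairs$sp1 <- sp[pairs$id1]
  pairs$sp2 <- sp[pairs$id2]
  n_na <- sum(is.na(pairs$distance))
  if (n_na > 0) {
    warn(paste0(n_na, " undefined distance(s) excluded from gap table"))
    pairs <- pairs[!is.na(pairs$distance), ]
  }
  species_names <- sort(unique(sp))
  rows <- purrr::map(species_names, function(s) {
    inter <- pairs[(pairs$sp1 == s) != (pairs$sp2 == s), ]
    intra <- pairs[pairs$sp1 == s & pairs$sp2 == s, ]
    other <- ifelse(inter$sp1 == s, inter$sp2, inter$sp1)
    dmin <- min(inter$distance)
    nn <- sort(other[inter$distance == dmin])[1]
    tibble(
      species = s,
      n = sum(sp == s),
      min_inter = 100 * dmin,
      mean_inter = 100 * mean(inter$distance),
      max_intra = if (nrow(intra) > 0) 100 * max(intra$distance) else NA_real_,
      mean_intra = if (nrow(intra) > 0) 100 * mean(intra$distance) else NA_real_,
      nearest_species = nn
    )
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("gap_table", class(out))
  out
}

species_lookup <- function(x, species) {
  if (is.data.frame(species)) {
    stopifnot(all(c("specimen_id", "species") %in% names(species)))
    sp <- setNames(species$species, species$specimen_id)
  } else {
    sp <- species
  }
  missing <- setdiff(x$ids, names(sp))
  if (length(missing) > 0) {
    abort(paste0("species labels missing for: ",
                 paste(missing, collapse = ", ")))
  }
  sp[x$ids]
}

#' The 10x barcoding-gap criterion
#'
#' A barcoding gap is supported when mean interspecific divergence is at
#' least `min_ratio` (default 10) times the mean intraspecific divergence.
#' A mean intraspecific divergence of exactly zero passes with an infinite
#' ratio.
#'
#' @param mean_inter Mean interspecific divergence (percent).
#' @param mean_intra Mean intraspecific divergence (percent).
#' @param min_ratio Required ratio (default 10).
#' @return A one-row tibble: `ratio`, `passes`.
#' @examples
#' tenfold_criterion(8.94, 0.63)
#' @export
tenfold_criterion <- function(mean_inter, mean_intra, min_ratio = 10) {
  stopifnot(is.numeric(mean_inter), is.numeric(mean_intra),
            length(mean_inter) == 1, length(mean_intra) == 1)
  if (mean_inter < 0 || mean_intra < 0) {
    abort("divergences must be non-negative")
  }
  ratio <- if (mean_intra == 0) Inf else mean_inter / mean_intra
  tibble(ratio = ratio, passes = ratio >= min_ratio)
}

#' Barcoding-gap verdict with overlap detection
#'
#' Combines the 10x criterion with a global overlap scan: an overlap is
#' recorded for every ordered species pair (including a species against its
#' own nearest-neighbour distance) whose maximum intraspecific divergence
#' exceeds the other's minimum interspecific divergence. The gap is valid
#' only when the ratio criterion passes and no overlap exists.
#'
#' @param rows A [gap_table()] tibble.
#' @param mean_intra Mean intraspecific divergence (percent) used for the
#'   ratio; defaults to the mean of the table's `mean_intra` column
#'   (mean of species means). Pass a pooled over-all-conspecific-pairs mean
#'   for the pooled convention.
#' @param min_ratio Required interspecific/intraspecific ratio (default 10).
#' @return A `gap_verdict` object (list): `ratio`, `passes_tenfold`,
#'   `overlaps` (tibble), `gap_valid`, `indeterminate` (no species with
#'   intraspecific data). [tidy()] returns the overlap table, [glance()] a
#'   one-row summary.
#' @export
overlap_report <- function(rows, mean_intra = NULL, min_ratio = 10) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 2)
  indeterminate <- all(is.na(rows$mean_intra))
  if (is.null(mean_intra)) {
    mean_intra <- if (indeterminate) 0 else mean(rows$mean_intra, na.rm = TRUE)
  }
  tf <- tenfold_criterion(mean(rows$min_inter), mean_intra,
                          min_ratio = min_ratio)
  with_intra <- rows[!is.na(rows$max_intra), ]
  grid <- tidyr::expand_grid(i = seq_len(nrow(with_intra)),
                             j = seq_len(nrow(rows)))
  hit <- with_intra$max_intra[grid$i] > rows$min_inter[grid$j]
  overlaps <- tibble(
    species_high_intra = with_intra$species[grid$i][hit],
    max_intra = with_intra$max_intra[grid$i][hit],
    species_low_min_inter = rows$species[grid$j][hit],
    min_inter = rows$min_inter[grid$j][hit]
  ) |>
    dplyr::arrange(.data$species_high_intra, .data$species_low_min_inter)
  structure(
    list(
      ratio = tf$ratio,
      passes_tenfold = tf$passes,
      overlaps = overlaps,
      gap_valid = !indeterminate && tf$passes && nrow(overlaps) == 0,
      indeterminate = indeterminate
    ),
    class = "gap_verdict"
  )
}

#' @export
print.gap_verdict <- function(x, ...) {
  cat("Barcoding-gap verdict\n")
  cat(sprintf("  inter/intra ratio: %.2f (%s)\n", x$ratio,
              if (x$passes_tenfold) "passes 10x criterion" else "fails"))
  cat(sprintf("  overlaps: %d\n", nrow(x$overlaps)))
  if (x$indeterminate) {
    cat("  verdict: indeterminate (no species with >1 specimen)\n")
  } else {
    cat(sprintf("  gap valid: %s\n", x$gap_valid))
  }
  invisible(x)
}

#' @export
tidy.gap_verdict <- function(x, ...) x$overlaps

#' @export
glance.gap_verdict <- function(x, ...) {
  tibble(ratio = x$ratio, passes_tenfold = x$passes_tenfold,
         n_overlaps = nrow(x$overlaps), gap_valid = x$gap_valid,
         indeterminate = x$indeterminate)
}

#' Gap-scored single-linkage threshold sweep
#'
#' Partitions specimens into molecular taxonomic units at every candidate
#' distance threshold and ranks the resulting partitions by the relative
#' width of the distance gap they sit in. Candidate thresholds are the
#' midpoints between consecutive distinct single-linkage merge heights plus
#' one threshold below the smallest and one above the largest height. The
#' gap score of an internal candidate in the empty interval
#' \eqn{(d_{lo}, d_{hi})} is \eqn{(d_{hi}-d_{lo})/d_{hi}}; the two boundary
#' candidates, whose interval has no finite observed bound, score 0.
#' Duplicate partitions are removed (best score kept) and the ranking is by
#' gap score descending, ties broken by fewer units.
#'
#' This is a deliberately simplified, fully deterministic relative of
#' hierarchical species-partitioning tools such as ASAP: the single-linkage
#' ladder supplies the candidate partitions and a pure gap-width score
#' replaces probabilistic panmixia scoring.
#'
#' @param x A `k2p_dist` object with no undefined entries.
#' @return A `partition_sweep` object: `candidates` (tibble `rank`,
#'   `threshold`, `n_units`, `gap_score`) and `assignments` (list of named
#'   integer unit vectors, parallel to `candidates`). [top_partition()]
#'   extracts a partition; [tidy()] returns the candidate table.
#' @export
threshold_sweep <- function(x) {
  stopifnot(inherits(x, "k2p_dist"))
  if (length(x$ids) < 2) abort("threshold_sweep requires >= 2 specimens")
  check_defined(x, "threshold_sweep")
  hc <- hclust(stats::as.dist(x$d), method = "single")
  # zero-height merges join identical sequences (haplotype collapsing, no
  # evidence about species limits); candidate thresholds come from the
  # distinct positive merge heights
  h <- sort(unique(hc$height[hc$height > 1e-12]))
  if (length(h) == 0) {
    # all sequences identical: one unit at any positive threshold
    h <- 1e-6
    thresholds <- h
    gap_scores <- 0
  } else {
    thresholds <- c(
      h[1] / 2,
      if (length(h) > 1) (head(h, -1) + h[-1]) / 2,
      h[length(h)] * 1.05
    )
    # relative width of the empty height interval containing the threshold;
    # the two boundary candidates have no finite observed interval -> 0
    gap_scores <- c(
      0,
      if (length(h) > 1) (h[-1] - head(h, -1)) / h[-1],
      0
    )
  }
  parts <- lapply(thresholds, function(thr) {
    relabel_units(cutree(hc, h = thr)[x$ids])
  })
  keys <- vapply(parts, paste, character(1), collapse = ",")
  # dedupe: keep the highest-scoring candidate for each distinct partition
  ord <- order(-gap_scores)
  first <- ord[!duplicated(keys[ord])]
  first <- sort(first)
  cand <- tibble(
    threshold = thresholds[first],
    n_units = vapply(parts[first], max, integer(1)),
    gap_score = gap_scores[first]
  )
  rk <- order(-cand$gap_score, cand$n_units)
  cand <- cand[rk, ]
  cand$rank <- seq_len(nrow(cand))
  cand <- cand[, c("rank", "threshold", "n_units", "gap_score")]
  structure(
    list(candidates = cand, assignments = parts[first][rk], ids = x$ids),
    class = "partition_sweep"
  )
}

# contiguous unit indices 1..k in order of first appearance
relabel_units <- function(u) {
  setNames(as.integer(match(u, unique(u))), names(u))
}

check_defined <- function(x, where) {
  ut <- which(upper.tri(x$d) & is.na(x$d), arr.ind = TRUE)
  if (nrow(ut) > 0) {
    pairs <- paste0(x$ids[ut[, 1]], "/", x$ids[ut[, 2]])
    abort(paste0(where, ": undefined distance(s) for pair(s): ",
                 paste(pairs, collapse = ", ")))
  }
}

#' @export
print.partition_sweep <- function(x, ...) {
  cat("Threshold sweep:", nrow(x$candidates), "candidate partition(s) over",
      length(x$ids), "specimens\n")
  top <- x$candidates[1, ]
  cat(sprintf("  top: %d unit(s) at threshold %.4f (gap score %.3f)\n",
              top$n_units, top$threshold, top$gap_score))
  invisible(x)
}

#' @export
tidy.partition_sweep <- function(x, ...) x$candidates

#' @export
glance.partition_sweep <- function(x, ...) {
  dplyr::bind_cols(tibble(n_candidates = nrow(x$candidates)),
                   x$candidates[1, c("threshold", "n_units", "gap_score")])
}

#' Extract a partition from a threshold sweep
#'
#' @param x A `partition_sweep` object.
#' @param rank Which ranked candidate to extract (default 1, the best).
#' @return A tibble with columns `specimen_id` and `unit` (contiguous
#'   integers from 1).
#' @export
top_partition <- function(x, rank = 1) {
  stopifnot(inherits(x, "partition_sweep"),
            rank >= 1, rank <= nrow(x$candidates))
  u <- x$assignments[[rank]]
  tibble(specimen_id = names(u), unit = unname(u))
}

#' Splits and lumps of a partition relative to nominal species
#'
#' Compares a molecular partition with nominal (for example morphological)
#' species labels: a *split* is a species whose specimens fall into more
#' than one unit (candidate cryptic species); a *lump* is a unit containing
#' more than one species.
#'
#' @param partition A tibble with columns `specimen_id` and `unit` (as from
#'   [top_partition()]).
#' @param species Species labels (tibble `specimen_id`/`species` or named
#'   character vector) covering all specimens in the partition.
#' @return A `split_lump` list: `splits` (tibble `species`, `n_units`,
#'   `units`), `lumps` (tibble `unit`, `n_species`, `species`) and
#'   `concordant` (no splits and no lumps).
#' @export
split_lump_report <- function(partition, species) {
  stopifnot(is.data.frame(partition),
            all(c("specimen_id", "unit") %in% names(partition)))
  if (is.data.frame(species)) {
    sp <- setNames(species$species, species$specimen_id)
  } else {
    sp <- species
  }
  missing <- setdiff(partition$specimen_id, names(sp))
  if (length(missing) > 0) {
    abort(paste0("species labels missing for: ",
                 paste(missing, collapse = ", ")))
  }
  df <- dplyr::mutate(partition, species = unname(sp[.data$specimen_id]))
  splits <- df |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_units = dplyr::n_distinct(.data$unit),
                     units = paste(sort(unique(.data$unit)), collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$n_units > 1)
  lumps <- df |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                     species = paste(sort(unique(.data$species)),
                                     collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$n_species > 1)
  structure(
    list(splits = splits, lumps = lumps,
         concordant = nrow(splits) == 0 && nrow(lumps) == 0),
    class = "split_lump"
  )
}

#' @export
print.split_lump <- function(x, ...) {
  cat("Partition vs nominal species:",
      if (x$concordant) "concordant\n" else "\n")
  if (nrow(x$splits) > 0) {
    cat("  split species:", paste(x$splits$species, collapse = ", "), "\n")
  }
  if (nrow(x$lumps) > 0) {
    cat("  lumped units:", paste(x$lumps$species, collapse = "; "), "\n")
  }
  invisible(x)
}
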