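# Kimura two-parameter distances and divergence summaries by taxonomic rank.

# numeric encoding A=1 C=2 G=3 T=4; everything else (IUPAC ambiguity, '-',
# '?') is NA and excluded pair by pair (pairwise deletion)
encode_codes <- function(records) {
  m <- seq_char_matrix(records)
  codes <- matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m),
                  dimnames = list(rownames(m), NULL))
  codes
}

# transition partner of each code (A<->G, C<->T)
TS_PARTNER <- c(3L, 4L, 1L, 2L)

#' Count site patterns between two aligned sequences
#'
#' Tallies the inputs of the K2P distance for one sequence pair: the number
#' of comparable sites (both bases unambiguous A/C/G/T, pairwise deletion)
#' and the observed transition and transversion proportions.
#'
#' @param a,b Equal-length sequence strings.
#' @return A one-row tibble: `compared_sites`, `p_transition`,
#'   `q_transversion`. With zero comparable sites the proportions are `NA`
#'   (undefined-distance signal).
#' @examples
#' count_site_patterns("AAAA", "GAAA")
#' @export
count_site_patterns <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("sequences must have equal length")
  ca <- match(strsplit(toupper(a), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  cb <- match(strsplit(toupper(b), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  if (n == 0) {
    warn("zero comparable sites: distance undefined for this pair")
    return(tibble(compared_sites = 0L, p_transition = NA_real_,
                  q_transversion = NA_real_))
  }
  diff <- ok & ca != cb
  ts <- sum(diff & cb == TS_PARTNER[ca], na.rm = TRUE)
  tv <- sum(diff) - ts
  tibble(compared_sites = n, p_transition = ts / n, q_transversion = tv / n)
}

#' Kimura two-parameter distance
#'
#' Evaluates the K2P closed form
#' \deqn{d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)}
#' from observed transition (`P`) and transversion (`Q`) proportions.
#' Outside the log domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`, a saturated
#' pair) the distance is undefined and `NA` is returned.
#'
#' @param P,Q Transition and transversion proportions (fractions,
#'   vectorised, recycled to common length).
#' @return Numeric vector of distances (substitutions per site, fraction).
#' @examples
#' k2p(0.1, 0.05)
#' @export
k2p <- function(P, Q) {
  stopifnot(is.numeric(P), is.numeric(Q))
  if (any(P < 0 | Q < 0, na.rm = TRUE)) abort("P and Q must be non-negative")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- ifelse(w1 > 0 & w2 > 0,
              -0.5 * log(w1 * sqrt(pmax(w2, 0))),
              NA_real_)
  as.numeric(d)
}

#' K2P distance matrix over a barcode dataset
#'
#' Computes all pairwise K2P distances with pairwise deletion of ambiguous
#' or gapped sites. Saturated pairs (log-domain violation) and pairs with no
#' comparable sites are flagged as `NA`.
#'
#' @param records A record tibble with at least two aligned sequences.
#' @return An object of class `k2p_dist`: a list with `ids`, the symmetric
#'   distance matrix `d` (fractions, zero diagonal), matrices `sites`, `P`
#'   and `Q` of per-pair inputs, and `n_undefined`. Use [tidy()] for a long
#'   pair table and `as.matrix()`/`as.dist()` for the raw matrix.
#' @export
k2p_matrix <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 2) {
    abort("k2p_matrix requires at least 2 records")
  }
  if (anyDuplicated(records$specimen_id)) abort("duplicated specimen_id")
  codes <- encode_codes(records)
  n <- nrow(codes)
  ids <- rownames(codes)
  d <- Pm <- Qm <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(ncol(codes), n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    ci <- codes[i, ]
    for (j in seq(i + 1, n)) {
      cj <- codes[j, ]
      ok <- !is.na(ci) & !is.na(cj)
      ns <- sum(ok)
      sites[i, j] <- sites[j, i] <- ns
      if (ns == 0) {
        Pm[i, j] <- Pm[j, i] <- Qm[i, j] <- Qm[j, i] <- NA_real_
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      diff <- ok & ci != cj
      ts <- sum(diff & cj == TS_PARTNER[ci], na.rm = TRUE)
      tv <- sum(diff) - ts
      Pm[i, j] <- Pm[j, i] <- ts / ns
      Qm[i, j] <- Qm[j, i] <- tv / ns
      d[i, j] <- d[j, i] <- k2p(ts / ns, tv / ns)
    }
  }
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0) {
    warn(paste0(n_undef, " pair(s) have undefined (saturated) K2P distances"))
  }
  structure(
    list(ids = ids, d = d, sites = sites, P = Pm, Q = Qm,
         n_undefined = n_undef),
    class = "k2p_dist"
  )
}

#' @export
as.matrix.k2p_dist <- function(x, ...) x$d

#' @export
as.dist.k2p_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("K2P distance matrix over", length(x$ids), "specimens\n")
  vals <- x$d[upper.tri(x$d)]
  cat(sprintf("  range %.4f-%.4f, mean %.4f; %d undefined pair(s)\n",
              min(vals, na.rm = TRUE), max(vals, na.rm = TRUE),
              mean(vals, na.rm = TRUE), x$n_undefined))
  invisible(x)
}

#' Tidy a K2P distance matrix into a pair table
#'
#' @param x A `k2p_dist` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `id1`, `id2`,
#'   `distance`, `compared_sites`, `p_transition`, `q_transversion`.
#' @export
tidy.k2p_dist <- function(x, ...) {
  n <- length(x$ids)
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    id1 = x$ids[ut[, 1]],
    id2 = x$ids[ut[, 2]],
    distance = x$d[ut],
    compared_sites = x$sites[ut],
    p_transition = x$P[ut],
    q_transversion = x$Q[ut]
  )
}

#' @export
glance.k2p_dist <- function(x, ...) {
  vals <- x$d[upper.tri(x$d)]
  tibble(
    n_specimens = length(x$ids),
    n_pairs = length(vals),
    n_undefined = x$n_undefined,
    min = min(vals, na.rm = TRUE),
    mean = mean(vals, na.rm = TRUE),
    max = max(vals, na.rm = TRUE)
  )
}

#' Write / read a K2P distance matrix as tab-separated text
#'
#' The on-disk format is a square matrix with an `id` header column and one
#' header row of specimen ids.
#'
#' @param x A `k2p_dist` object (writer) or a path (reader).
#' @param path Output path.
#' @return The path (writer, invisibly); a `k2p_dist`-like object with
#'   `ids` and `d` (reader).
#' @export
write_k2p_matrix <- function(x, path) {
  stopifnot(inherits(x, "k2p_dist"))
  df <- as_tibble(x$d, rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_k2p_matrix
#' @export
read_k2p_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  if (!identical(rownames(m), colnames(m))) {
    abort("distance matrix header row and column disagree")
  }
  structure(
    list(ids = rownames(m), d = m, sites = NULL, P = NULL, Q = NULL,
         n_undefined = sum(is.na(m[upper.tri(m)]))),
    class = "k2p_dist"
  )
}

# assign each unordered pair to its lowest shared taxonomic rank
pair_rank_table <- function(x, taxonomy) {
  stopifnot(inherits(x, "k2p_dist"))
  required <- c("specimen_id", "species", "genus", "family")
  if (!all(required %in% names(taxonomy))) {
    abort(paste0("taxonomy must have columns: ",
                 paste(required, collapse = ", ")))
  }
  missing <- setdiff(x$ids, taxonomy$specimen_id)
  if (length(missing) > 0) {
    abort(paste0("taxonomy missing specimen(s): ",
                 paste(missing, collapse = ", ")))
  }
  tax <- taxonomy[match(x$ids, taxonomy$specimen_id), ]
  pairs <- tidy(x)
  i1 <- match(pairs$id1, x$ids)
  i2 <- match(pairs$id2, x$ids)
  pairs$species1 <- tax$species[i1]
  pairs$species2 <- tax$species[i2]
  pairs$rank <- dplyr::case_when(
    tax$species[i1] == tax$species[i2] ~ "within_species",
    tax$genus[i1] == tax$genus[i2] ~ "within_genus",
    tax$family[i1] == tax$family[i2] ~ "within_family",
    TRUE ~ NA_character_
  )
  pairs
}

#' Divergence summaries across taxonomic ranks
#'
#' Assigns every specimen pair to its lowest shared rank (conspecific pairs
#' to `within_species`, congeneric heterospecific pairs to `within_genus`,
#' confamilial heterogeneric pairs to `within_family`; pairs from different
#' families are not summarised) and reports per-rank minimum, mean, maximum
#' and standard error of the K2P distance, in percent.
#'
#' The standard error is the sample standard deviation of the pairwise
#' distances divided by the square root of the pair count. Undefined
#' distances are excluded with a warning.
#'
#' @param x A `k2p_dist` object.
#' @param taxonomy A tibble with columns `specimen_id`, `species`, `genus`,
#'   `family` covering all specimens in `x`.
#' @return A tibble with columns `rank`, `n_pairs`, `min`, `mean`, `max`,
#'   `se` (all divergence values in percent). Ranks with zero pairs are
#'   omitted with a message.
#' @export
rank_summaries <- function(x, taxonomy) {
  pairs <- pair_rank_table(x, taxonomy)
  n_na <- sum(is.na(pairs$distance))
  if (n_na > 0) {
    warn(paste0(n_na, " undefined distance(s) excluded from rank summaries"))
    pairs <- pairs[!is.na(pairs$distance), ]
  }
  ranks <- c("within_species", "within_genus", "within_family")
  out <- pairs |>
    dplyr::filter(!is.na(.data$rank)) |>
    dplyr::group_by(rank = factor(.data$rank, levels = ranks)) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      min = 100 * min(.data$distance),
      mean = 100 * mean(.data$distance),
      max = 100 * max(.data$distance),
      se = 100 * sd(.data$distance) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(rank = as.character(.data$rank))
  absent <- setdiff(ranks, out$rank)
  if (length(absent) > 0) {
    inform(paste0("no pairs at rank(s): ", paste(absent, collapse = ", ")))
  }
  out
}
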