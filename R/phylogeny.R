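# Neighbour-joining trees from K2P distances, bootstrap support and
# per-species monophyly checks. Tree inference is delegated to ape;
# this module owns the resampling scheme, support accounting and the
# bipartition-based monophyly test.

#' Neighbour-joining tree from a K2P distance matrix
#'
#' Standard NJ agglomeration on the pairwise distances. Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero. Undefined (saturated) distances are an error listing the offending
#' pairs.
#'
#' @param x A `k2p_dist` object (or any object coercible with `as.matrix`
#'   to a symmetric distance matrix with id dimnames) over at least 3 taxa.
#' @return An unrooted `phylo` tree whose tip labels are the specimen ids.
#' @export
nj_tree <- function(x) {
  if (inherits(x, "k2p_dist")) {
    check_defined(x, "nj_tree")
    m <- x$d
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) < 3) abort("nj_tree requires >= 3 taxa")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree of K2P distances for every replicate, and reports for each internal
#' edge of the full-data tree the percentage of replicates containing the
#' same bipartition. Replicates whose resampled distance matrix contains an
#' undefined distance are dropped from the denominator (their count is
#' reported).
#'
#' @param records A record tibble of aligned sequences (>= 3).
#' @param B Number of bootstrap replicates (default 5000).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @return The full-data NJ `phylo` tree with `node.label` set to rounded
#'   support percentages (root label empty) and attributes
#'   `support` (numeric per internal node), `B` and `B_effective`.
#' @export
bootstrap_support <- function(records, B = 5000, seed = 1) {
  if (!is.numeric(B) || length(B) != 1 || B < 1) {
    abort("B must be a positive integer")
  }
  B <- as.integer(B)
  full_dist <- suppressWarnings(k2p_matrix(records))
  full <- nj_tree(full_dist)
  codes <- encode_codes(records)
  L <- ncol(codes)
  boots <- withr::with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      d <- codes_k2p_matrix(codes[, cols, drop = FALSE])
      if (anyNA(d[upper.tri(d)])) return(NULL)
      tr <- ape::nj(stats::as.dist(d))
      tr$edge.length <- pmax(tr$edge.length, 0)
      tr
    })
  })
  ok <- !vapply(boots, is.null, logical(1))
  trees <- boots[ok]
  if (length(trees) == 0) abort("all bootstrap replicates were saturated")
  counts <- ape::prop.clades(full, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / length(trees)
  # the root "bipartition" is the trivial full tip set; leave it unlabelled
  support[1] <- NA_real_
  full$node.label <- ifelse(is.na(support), "",
                            formatC(support, format = "f", digits = 1))
  attr(full, "support") <- support
  attr(full, "B") <- B
  attr(full, "B_effective") <- length(trees)
  full
}

# K2P distance matrix straight from an integer code matrix (internal fast
# path shared with the bootstrap loop)
codes_k2p_matrix <- function(codes) {
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  for (i in seq_len(n - 1)) {
    ci <- codes[i, ]
    for (j in seq(i + 1, n)) {
      cj <- codes[j, ]
      ok <- !is.na(ci) & !is.na(cj)
      ns <- sum(ok)
      if (ns == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      diff <- ok & ci != cj
      ts <- sum(diff & cj == TS_PARTNER[ci], na.rm = TRUE)
      tv <- sum(diff) - ts
      d[i, j] <- d[j, i] <- k2p(ts / ns, tv / ns)
    }
  }
  d
}

#' Per-species monophyly on a tree
#'
#' A species is monophyletic when some edge of the (unrooted) tree separates
#' exactly its specimens from everything else; singleton species are
#' monophyletic by convention.
#'
#' @param tree A `phylo` tree.
#' @param species Species labels (tibble `specimen_id`/`species` or named
#'   character vector) covering all tips.
#' @return A tibble with columns `species`, `n` and `monophyletic`.
#' @export
monophyly_check <- function(tree, species) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(species)) {
    sp <- setNames(species$species, species$specimen_id)
  } else {
    sp <- species
  }
  missing <- setdiff(tree$tip.label, names(sp))
  if (length(missing) > 0) {
    abort(paste0("species labels missing for tip(s): ",
                 paste(missing, collapse = ", ")))
  }
  tips <- tree$tip.label
  n_tip <- length(tips)
  # clades of the arbitrarily rooted representation; a tip set is a
  # bipartition of the unrooted tree iff it or its complement is a clade
  parts <- lapply(ape::prop.part(tree), sort)
  sp_tips <- split(seq_len(n_tip), sp[tips])
  purrr::imap(sp_tips, function(idx, s) {
    idx <- sort(idx)
    mono <- length(idx) == 1 ||
      any(vapply(parts, identical, logical(1), idx)) ||
      any(vapply(parts, identical, logical(1), sort(setdiff(seq_len(n_tip),
                                                            idx))))
    tibble(species = s, n = length(idx), monophyletic = mono)
  }) |>
    purrr::list_rbind()
}
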