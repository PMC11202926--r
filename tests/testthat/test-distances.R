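test_that("site-pattern counts follow pairwise deletion and ts/tv typing", {
  expect_equal(count_site_patterns("AAAA", "AAAA"),
               tibble::tibble(compared_sites = 4L, p_transition = 0,
                              q_transversion = 0))
  # A<->G is a transition
  expect_equal(count_site_patterns("AAAA", "GAAA")$p_transition, 0.25)
  expect_equal(count_site_patterns("AAAA", "GAAA")$q_transversion, 0)
  # N site deleted; A<->C transversion over the 3 remaining sites
  pc <- count_site_patterns("AAAN", "ACAA")
  expect_equal(pc$compared_sites, 3L)
  expect_equal(pc$p_transition, 0)
  expect_equal(pc$q_transversion, 1 / 3)
  # zero comparable sites signals an undefined distance
  expect_warning(pc0 <- count_site_patterns("NNNN", "ACGT"), "undefined")
  expect_true(is.na(pc0$p_transition))
})

test_that("K2P closed form matches frozen high-precision values", {
  expect_equal(k2p(0, 0), 0)
  expect_equal(k2p(0.1, 0.05), 0.170181165140347, tolerance = 1e-12)
  expect_equal(k2p(1 / 3, 0), 0.549306144334055, tolerance = 1e-12)
  expect_equal(k2p(0, 1 / 3), 0.477385626221110, tolerance = 1e-12)
  expect_equal(k2p(0.05, 0.02), 0.0741221843850062, tolerance = 1e-12)
  # domain boundary: 1 - 2P - Q = 0 is saturated
  expect_true(is.na(k2p(0.45, 0.10)))
  expect_true(is.na(k2p(0.2, 0.5)))
  expect_error(k2p(-0.1, 0), "non-negative")
})

test_that("K2P agrees with an independent implementation on a (P, Q) grid", {
  L <- 600
  grid <- expand.grid(ts = c(0, 6, 30, 90, 150), tv = c(0, 6, 30, 60))
  for (r in seq_len(nrow(grid))) {
    pair <- patterned_pair(L, grid$ts[r], grid$tv[r])
    rec <- make_records(pair, ids = c("x", "y"))
    mine <- as.matrix(k2p_matrix(rec))["x", "y"]
    dnabin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(pair), "")))
    rownames(dnabin) <- c("x", "y")
    ref <- as.matrix(ape::dist.dna(dnabin, model = "K80",
                                   pairwise.deletion = TRUE))["x", "y"]
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("K2P corrects upward from p-distance and is monotone in P and Q", {
  withr::with_seed(11, {
    for (i in 1:50) {
      P <- runif(1, 0, 0.3)
      Q <- runif(1, 0, 0.25)
      if (1 - 2 * P - Q <= 0.05) next
      expect_gte(k2p(P, Q), P + Q)
      expect_gt(k2p(P + 0.01, Q), k2p(P, Q))
      expect_gt(k2p(P, Q + 0.01), k2p(P, Q))
    }
  })
})

test_that("distance matrix is symmetric with zero diagonal and NA flags", {
  expect_equal(as.matrix(k2p_matrix(make_records(c("ACGT", "ACGT"),
                                                 ids = c("a", "b"))))["a", "b"],
               0)
  sim <- simulate_barcodes(sim_config(n_species = 3, specimens_per_species = 3,
    n_genera = 2, n_families = 1, length = 240, seed = 2))
  d <- as.matrix(k2p_matrix(sim$records))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] >= 0))
  # saturated pair is flagged undefined
  sat <- patterned_pair(10, 5, 1)  # P = 0.5 -> outside log domain
  expect_warning(ds <- k2p_matrix(make_records(sat, ids = c("a", "b"))),
                 "undefined")
  expect_true(is.na(as.matrix(ds)["a", "b"]))
  expect_equal(ds$n_undefined, 1L)
})

test_that("tidy pair table matches the matrix entries", {
  sim <- simulate_barcodes(sim_config(n_species = 2, specimens_per_species = 3,
    n_genera = 1, n_families = 1, length = 150, seed = 9))
  d <- k2p_matrix(sim$records)
  td <- tidy(d)
  expect_equal(nrow(td), choose(nrow(sim$records), 2))
  m <- as.matrix(d)
  for (r in sample(nrow(td), 5)) {
    expect_equal(td$distance[r], m[td$id1[r], td$id2[r]])
  }
})

test_that("distance matrix text round-trip preserves values", {
  sim <- simulate_barcodes(sim_config(n_species = 2, specimens_per_species = 2,
    n_genera = 1, n_families = 1, length = 120, seed = 13))
  d <- k2p_matrix(sim$records)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_k2p_matrix(d, f)
  back <- read_k2p_matrix(f)
  expect_equal(back$d, d$d, tolerance = 1e-12)
  expect_identical(back$ids, d$ids)
})

test_that("pairs are summarised at their lowest shared rank", {
  # two species x two specimens, distances hand-computable from constructed
  # sequences: conspecifics differ at 1 transition, heterospecifics at many
  seqs <- c(a1 = strrep("A", 100),
            a2 = paste0("G", strrep("A", 99)),
            b1 = paste0(strrep("C", 10), strrep("A", 90)),
            b2 = paste0(strrep("C", 10), "G", strrep("A", 89)))
  rec <- make_records(seqs, species = c("sp a", "sp a", "sp b", "sp b"))
  d <- k2p_matrix(rec)
  rs <- rank_summaries(d, taxonomy_of(rec))
  expect_identical(rs$rank, c("within_species", "within_genus"))
  # brute force over the 6 pairs
  m <- as.matrix(d)
  intra <- c(m["a1", "a2"], m["b1", "b2"])
  inter <- c(m["a1", "b1"], m["a1", "b2"], m["a2", "b1"], m["a2", "b2"])
  expect_equal(rs$mean[1], 100 * mean(intra))
  expect_equal(rs$mean[2], 100 * mean(inter))
  expect_equal(rs$se[2], 100 * sd(inter) / 2)
})

test_that("all-conspecific data yield only a within-species summary", {
  rec <- make_records(c("ACGTACGT", "ACGTACGA", "ACGTACGC"))
  d <- k2p_matrix(rec)
  expect_message(rs <- rank_summaries(d, taxonomy_of(rec)), "no pairs")
  expect_identical(rs$rank, "within_species")
  expect_equal(rs$n_pairs, 3L)
})

test_that("divergence means increase with taxonomic rank on simulated data", {
  sim <- simulate_barcodes(sim_config(n_species = 6, specimens_per_species = 3,
    n_genera = 3, n_families = 2, length = 652, seed = 17))
  rs <- rank_summaries(k2p_matrix(sim$records), sim$truth)
  expect_identical(rs$rank,
                   c("within_species", "within_genus", "within_family"))
  expect_true(all(diff(rs$mean) > 0))
  expect_true(all(rs$min <= rs$mean & rs$mean <= rs$max))
})
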