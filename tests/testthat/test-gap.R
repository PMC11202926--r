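two_species_dist <- function() {
  seqs <- c(a1 = strrep("A", 200),
            a2 = paste0("G", strrep("A", 199)),
            b1 = paste0(strrep("C", 30), strrep("A", 170)),
            b2 = paste0(strrep("C", 30), "G", strrep("A", 169)))
  rec <- make_records(seqs, species = c("sp a", "sp a", "sp b", "sp b"))
  list(rec = rec, d = k2p_matrix(rec))
}

test_that("gap table rows match brute force over all pairs", {
  x <- two_species_dist()
  gt <- gap_table(x$d, species_vec(x$rec))
  m <- as.matrix(x$d)
  cross <- c(m["a1", "b1"], m["a1", "b2"], m["a2", "b1"], m["a2", "b2"])
  expect_equal(gt$min_inter, rep(100 * min(cross), 2))
  expect_equal(gt$mean_inter, rep(100 * mean(cross), 2))
  expect_equal(gt$max_intra[1], 100 * m["a1", "a2"])
  expect_equal(gt$mean_intra[2], 100 * m["b1", "b2"])
  expect_true(all(gt$min_inter <= gt$mean_inter))
  expect_true(all(gt$max_intra >= gt$mean_intra, na.rm = TRUE))
})

test_that("singleton species get NA intraspecific fields", {
  seqs <- c(a1 = strrep("A", 60), a2 = strrep("A", 60),
            b1 = paste0(strrep("C", 10), strrep("A", 50)))
  rec <- make_records(seqs, species = c("sp a", "sp a", "sp b"))
  gt <- gap_table(k2p_matrix(rec), species_vec(rec))
  expect_true(is.na(gt$max_intra[gt$species == "sp b"]))
  expect_true(is.na(gt$mean_intra[gt$species == "sp b"]))
  expect_equal(gt$n[gt$species == "sp b"], 1L)
})

test_that("a single species is an error (no interspecific pairs)", {
  rec <- make_records(c("ACGT", "ACGA", "ACGC"))
  expect_error(gap_table(k2p_matrix(rec), species_vec(rec)),
               "at least 2 species")
})

test_that("the 10x criterion handles ratio, failure and the zero boundary", {
  tf <- tenfold_criterion(8.94, 0.63)
  expect_equal(tf$ratio, 8.94 / 0.63, tolerance = 1e-12)
  expect_true(tf$passes)
  expect_false(tenfold_criterion(0.63, 0.63)$passes)
  z <- tenfold_criterion(5.0, 0)
  expect_true(z$passes)
  expect_identical(z$ratio, Inf)
  expect_error(tenfold_criterion(-1, 0.5), "non-negative")
})

test_that("overlap detection records intra/inter conflicts and verdict", {
  rows <- tibble::tibble(
    species = c("A", "B", "C"),
    n = c(3L, 3L, 3L),
    min_inter = c(2.35, 8, 9),
    mean_inter = c(10, 12, 13),
    max_intra = c(0.5, 3.29, 0.4),
    mean_intra = c(0.3, 2.0, 0.2)
  )
  v <- overlap_report(rows, mean_intra = 0.63)
  expect_s3_class(v, "gap_verdict")
  # species B's max intra 3.29 exceeds species A's min inter 2.35
  expect_identical(tidy(v)$species_high_intra, "B")
  expect_identical(tidy(v)$species_low_min_inter, "A")
  expect_false(v$gap_valid)
  expect_true(v$passes_tenfold)

  # no conflicts and a passing ratio -> valid gap
  clean <- dplyr::mutate(rows, max_intra = c(0.5, 0.6, 0.4),
                         mean_intra = c(0.3, 0.4, 0.2))
  expect_true(overlap_report(clean, mean_intra = 0.4)$gap_valid)

  # row order is irrelevant
  v2 <- overlap_report(rows[c(3, 1, 2), ], mean_intra = 0.63)
  expect_equal(glance(v2), glance(v))
  expect_equal(tidy(v2), tidy(v))
})

test_that("all-singleton gap tables give an indeterminate verdict", {
  rows <- tibble::tibble(species = c("A", "B"), n = c(1L, 1L),
                         min_inter = c(5, 5), mean_inter = c(5, 5),
                         max_intra = NA_real_, mean_intra = NA_real_)
  v <- overlap_report(rows)
  expect_true(v$indeterminate)
  expect_false(v$gap_valid)
  expect_equal(nrow(tidy(v)), 0)
})

test_that("threshold sweep separates two tight blobs at the true gap", {
  x <- two_species_dist()
  sw <- threshold_sweep(x$d)
  top <- top_partition(sw)
  expect_equal(sw$candidates$n_units[1], 2L)
  expect_identical(top$unit, c(1L, 1L, 2L, 2L))
  # the top threshold sits inside the empty interval between intra and
  # inter single-linkage heights
  m <- as.matrix(x$d)
  expect_gt(sw$candidates$threshold[1], max(m["a1", "a2"], m["b1", "b2"]))
  expect_lt(sw$candidates$threshold[1], min(m["a1", "b1"], m["a2", "b2"]))
})

test_that("identical sequences form one unit at any positive threshold", {
  rec <- make_records(rep("ACGTACGTACGT", 4))
  sw <- threshold_sweep(k2p_matrix(rec))
  expect_equal(nrow(sw$candidates), 1L)
  expect_equal(sw$candidates$n_units[1], 1L)
})

test_that("partitions are nested as the threshold rises", {
  sim <- simulate_barcodes(sim_config(n_species = 5, specimens_per_species = 4,
    n_genera = 3, n_families = 2, length = 400, seed = 31))
  sw <- threshold_sweep(k2p_matrix(sim$records))
  cand <- sw$candidates[order(sw$candidates$threshold), ]
  assign_by_thr <- sw$assignments[order(sw$candidates$threshold)]
  for (k in seq_len(nrow(cand) - 1)) {
    lo <- assign_by_thr[[k]]
    hi <- assign_by_thr[[k + 1]]
    # coarser partition must not split any unit of the finer one
    expect_true(all(tapply(hi, lo, function(u) length(unique(u))) == 1))
    expect_gte(cand$n_units[k], cand$n_units[k + 1])
  }
})

test_that("a simulated cryptic species is split into two units", {
  cf <- sim_config(n_species = 3, specimens_per_species = 4,
    n_genera = 2, n_families = 1, length = 652,
    cryptic_species = 2, seed = 11)
  sim <- simulate_barcodes(cf)
  sw <- threshold_sweep(k2p_matrix(sim$records))
  sl <- split_lump_report(top_partition(sw),
                          setNames(sim$truth$species, sim$truth$specimen_id))
  expect_identical(sl$splits$species, cf$species[2])
  expect_equal(sl$splits$n_units, 2L)
  # and the split follows the true hidden clusters
  part <- top_partition(sw)
  cr <- sim$truth[sim$truth$species == cf$species[2], ]
  units <- part$unit[match(cr$specimen_id, part$specimen_id)]
  expect_equal(length(unique(units[cr$cryptic_cluster == 1])), 1L)
  expect_equal(length(unique(units[cr$cryptic_cluster == 2])), 1L)
  expect_false(any(units[cr$cryptic_cluster == 1] %in%
                     units[cr$cryptic_cluster == 2]))
})

test_that("split/lump reports agree with constructed partitions", {
  part <- tibble::tibble(specimen_id = sprintf("s%02d", 1:6),
                         unit = c(1L, 1L, 2L, 2L, 3L, 3L))
  sp_same <- setNames(c("a", "a", "b", "b", "c", "c"), part$specimen_id)
  r <- split_lump_report(part, sp_same)
  expect_true(r$concordant)

  sp_split <- setNames(c("a", "a", "a", "a", "c", "c"), part$specimen_id)
  r2 <- split_lump_report(part, sp_split)
  expect_identical(r2$splits$species, "a")

  # three species lumped into one unit
  part3 <- tibble::tibble(specimen_id = part$specimen_id,
                          unit = c(1L, 1L, 1L, 1L, 1L, 1L))
  r3 <- split_lump_report(part3, sp_same)
  expect_equal(r3$lumps$n_species, 3L)
  expect_identical(r3$lumps$species, "a,b,c")
})
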