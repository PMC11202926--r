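# barcodegap

Distance-based species discrimination with DNA barcodes, for biodiversity
surveys that sequence a standardised marker (typically a ~650 bp COI
fragment) from every specimen and need to answer: are the sequences
credible coding barcodes, is there a *barcoding gap* between intra- and
interspecific divergence, how do specimens partition into molecular
taxonomic units, and do the molecular assignments confirm, refine or
contradict the morphological identifications?

The package implements, on pre-aligned indel-free fragments:

* **QC** under the vertebrate mitochondrial genetic code
  (`check_coding_integrity()`: gaps, internal stops, frame
  auto-detection) and alignment statistics (`alignment_stats()`:
  polymorphic and parsimony-informative sites, base composition);
* **K2P distances** with pairwise deletion (`k2p()`, `k2p_matrix()`),
  where the Kimura two-parameter distance from transition proportion *P*
  and transversion proportion *Q* is
  *d* = −½·ln[(1 − 2P − Q)·√(1 − 2Q)],
  and divergence summaries by taxonomic rank (`rank_summaries()`);
* **Barcoding-gap tests**: the 10× criterion (mean interspecific ≥ 10 ×
  mean intraspecific, `tenfold_criterion()`), per-species
  nearest-neighbour gap tables (`gap_table()`) and global intra/inter
  overlap detection (`overlap_report()`);
* **Species delimitation** by a gap-scored single-linkage threshold
  sweep (`threshold_sweep()`, `top_partition()`) with split/lump
  reporting against nominal species (`split_lump_report()`);
* **NJ trees** with column-resampling bootstrap supports and monophyly
  checks (`nj_tree()`, `bootstrap_support()`, `monophyly_check()`);
* **Identification** against a reference library at 98% identity
  (`identify_specimens()`) and morphology-vs-molecular concordance
  classification into matched / refined / invalid
  (`classify_concordance()`, `concordance_summary()`), plus occurrence
  list comparison (`occurrence_overlap()`);
* a **calibrated coding-sequence simulator** (`simulate_barcodes()`)
  and an end-to-end **pipeline** with a JSON manifest
  (`run_barcode_pipeline()`).

Packaged fixtures transcribe the specimen, occurrence and divergence
tables of an Antarctic demersal-fish barcoding survey of the Cosmonaut
Sea (98 specimens, 24 species), used throughout the tests
(`table1_fixture()`, `table2_occurrence()`, `table3_rank_divergence()`,
`table4_divergence()`).

## Worked example

Simulate a small survey (6 species, 3 genera, 2 families, 4 specimens
each, 652 bp, 0.5% / 5% / 10% expected divergence at the three ranks),
then walk the analysis:

```r
library(barcodegap)

sim <- simulate_barcodes(sim_config(n_species = 6, specimens_per_species = 4,
                                    n_genera = 3, n_families = 2, seed = 42))
d <- k2p_matrix(sim$records)
rank_summaries(d, sim$truth)
#> # A tibble: 3 × 6
#>   rank           n_pairs   min   mean    max     se
#>   <chr>            <int> <dbl>  <dbl>  <dbl>  <dbl>
#> 1 within_species      36 0.154  0.591  0.927 0.0329
#> 2 within_genus        48 3.13   4.49   5.76  0.119
#> 3 within_family       64 9.00  10.3   11.5   0.0831
```

The realised means (0.59%, 4.5%, 10.3%) recover the simulation targets
and show the hierarchical increase expected of a healthy barcode marker.
Per species, the nearest heterospecific specimen is far above the worst
conspecific distance:

```r
gt <- gap_table(d, setNames(sim$truth$species, sim$truth$specimen_id))
gt
#> # A tibble: 6 × 7
#>   species          n min_inter mean_inter max_intra mean_intra nearest_species
#>   <chr>        <int>     <dbl>      <dbl>     <dbl>      <dbl> <chr>
#> 1 Genusaa spaa     4      3.97       10.6     0.927      0.617 Genusaa spad
#> 2 Genusaa spad     4      3.97       10.8     0.773      0.463 Genusaa spaa
#> 3 Genusab spab     4      3.13       12.1     0.772      0.616 Genusab spae
#> # … 3 more rows

glance(overlap_report(gt))
#> # A tibble: 1 × 5
#>   ratio passes_tenfold n_overlaps gap_valid indeterminate
#>   <dbl> <lgl>               <int> <lgl>     <lgl>
#> 1  6.88 FALSE                   0 FALSE     FALSE
```

No species overlaps (every `max_intra` < every `min_inter`), but the
nearest-neighbour ratio 6.88 misses the strict 10× criterion at these
simulation settings — the verdict machinery reports both facts
separately. The threshold sweep still recovers the true six species as
the top-ranked partition:

```r
glance(threshold_sweep(d))
#> # A tibble: 1 × 4
#>   n_candidates threshold n_units gap_score
#>          <int>     <dbl>   <int>     <dbl>
#> 1           16    0.0195       6     0.754
```

On the packaged 98-specimen survey table, concordance classification
reproduces the published census:

```r
t1 <- table1_fixture()
t1$klass <- classify_concordance(t1$morph_label, t1$mol_label)
concordance_summary(t1)
#> # A tibble: 3 × 3
#>   klass       n   pct
#>   <chr>   <int> <dbl>
#> 1 matched    72 73.5
#> 2 refined     5  5.1
#> 3 invalid    21 21.4
```

72 of 98 field identifications (73.47%) are confirmed by the barcode,
5 genus-level identifications (5.10%) are resolved to species, and 21
(21.43%) are contradicted.

## Documentation

The methods vignette (`vignettes/barcoding-gap-analysis.Rmd`) describes
the distance model, the gap tests and their conventions, the partition
score, the simulator calibration and the package's limitations.
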