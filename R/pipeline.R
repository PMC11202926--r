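# End-to-end orchestration: QC -> stats -> distances -> gap -> partition ->
# tree -> (optional) identification -> concordance, with a JSON manifest of
# parameters and per-stage outcomes.

#' Run the full barcoding analysis pipeline
#'
#' Executes every analysis stage on one dataset and writes stable
#' tab-separated/JSON reports plus a manifest to `outdir`. A stage that
#' fails records its error in the manifest; stages depending on it are
#' skipped with a notice, independent stages still run.
#'
#' Stages and outputs: `qc` (`qc_report.tsv`), `stats`
#' (`alignment_stats.tsv`), `dist` (`k2p_matrix.tsv`), `gap`
#' (`gap_table.tsv`, `gap_verdict.json`), `delimit` (`partition.tsv`,
#' `partition_sweep.tsv`, `split_lump.json`), `tree` (`nj_tree.nwk`, with
#' bootstrap supports), `identify` (`identification.tsv`, only when
#' `references` is given), `concord` (`concordance.tsv`,
#' `concordance_summary.tsv`, only when molecular labels are present).
#'
#' @param records A record tibble ([read_barcodes()] /
#'   [simulate_barcodes()] layout). Species labels for the gap and tree
#'   stages are taken from `morphological_label`.
#' @param outdir Output directory (created if needed).
#' @param identity_threshold Percent identity for the identification stage
#'   (default 98).
#' @param min_ratio Required interspecific/intraspecific ratio for the gap
#'   verdict (default 10).
#' @param bootstrap_B Bootstrap replicates for the tree stage (default
#'   5000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param references Optional reference library for [identify_specimens()].
#' @param mean_intra_convention `"pooled"` (mean over all conspecific
#'   pairs, the default) or `"species_mean"` (mean of species means) for
#'   the 10x criterion input.
#' @return The manifest, invisibly (also written to
#'   `results_manifest.json`).
#' @export
run_barcode_pipeline <- function(records, outdir,
                                 identity_threshold = 98,
                                 min_ratio = 10,
                                 bootstrap_B = 5000,
                                 seed = 1,
                                 references = NULL,
                                 mean_intra_convention = c("pooled",
                                                           "species_mean")) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  mean_intra_convention <- match.arg(mean_intra_convention)
  if (identity_threshold <= 0 || min_ratio <= 0) {
    abort("thresholds must be positive")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package = "barcodegap",
    version = as.character(utils::packageVersion("barcodegap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(
      identity_threshold = identity_threshold, min_ratio = min_ratio,
      bootstrap_B = bootstrap_B, seed = seed,
      mean_intra_convention = mean_intra_convention,
      n_records = nrow(records)
    ),
    stages = list()
  )
  state <- new.env(parent = emptyenv())
  state$failed <- character()

  run_stage <- function(name, deps, fun) {
    bad_dep <- intersect(deps, state$failed)
    if (length(bad_dep) > 0) {
      inform(paste0("[", name, "] skipped: upstream stage failed (",
                    paste(bad_dep, collapse = ", "), ")"))
      manifest$stages[[name]] <<- list(status = "skipped",
                                       reason = paste0("depends on failed: ",
                                                       paste(bad_dep,
                                                             collapse = ", ")))
      state$failed <- c(state$failed, name)
      return(invisible(NULL))
    }
    res <- tryCatch(
      {
        out <- fun()
        manifest$stages[[name]] <<- list(status = "ok", outputs = out)
        inform(paste0("[", name, "] ok"))
      },
      error = function(e) {
        manifest$stages[[name]] <<- list(status = "error",
                                         message = conditionMessage(e))
        inform(paste0("[", name, "] error: ", conditionMessage(e)))
        state$failed <- c(state$failed, name)
      }
    )
    invisible(NULL)
  }
  path <- function(f) file.path(outdir, f)
  rel <- function(...) basename(c(...))

  run_stage("qc", character(), function() {
    qc <- check_coding_integrity(records)
    readr::write_tsv(qc, path("qc_report.tsv"))
    rel(path("qc_report.tsv"))
  })
  run_stage("stats", character(), function() {
    st <- alignment_stats(records)
    readr::write_tsv(st, path("alignment_stats.tsv"))
    rel(path("alignment_stats.tsv"))
  })
  run_stage("dist", character(), function() {
    state$dist <- k2p_matrix(records)
    write_k2p_matrix(state$dist, path("k2p_matrix.tsv"))
    rel(path("k2p_matrix.tsv"))
  })
  run_stage("gap", "dist", function() {
    sp <- setNames(records$morphological_label, records$specimen_id)
    gt <- gap_table(state$dist, sp)
    pooled <- if (mean_intra_convention == "pooled") {
      pr <- tidy(state$dist)
      conspecific <- sp[pr$id1] == sp[pr$id2]
      if (any(conspecific)) 100 * mean(pr$distance[conspecific], na.rm = TRUE)
      else NULL
    } else NULL
    verdict <- overlap_report(gt, mean_intra = pooled, min_ratio = min_ratio)
    readr::write_tsv(gt, path("gap_table.tsv"))
    jsonlite::write_json(
      c(as.list(glance(verdict)),
        list(overlaps = tidy(verdict))),
      path("gap_verdict.json"), auto_unbox = TRUE, digits = NA, na = "null"
    )
    rel(path("gap_table.tsv"), path("gap_verdict.json"))
  })
  run_stage("delimit", "dist", function() {
    sw <- threshold_sweep(state$dist)
    part <- top_partition(sw)
    sl <- split_lump_report(
      part, setNames(records$morphological_label, records$specimen_id))
    readr::write_tsv(part, path("partition.tsv"))
    readr::write_tsv(tidy(sw), path("partition_sweep.tsv"))
    jsonlite::write_json(
      list(splits = sl$splits, lumps = sl$lumps, concordant = sl$concordant),
      path("split_lump.json"), auto_unbox = TRUE, digits = NA
    )
    rel(path("partition.tsv"), path("partition_sweep.tsv"),
        path("split_lump.json"))
  })
  run_stage("tree", "dist", function() {
    tr <- bootstrap_support(records, B = bootstrap_B, seed = seed)
    ape::write.tree(tr, path("nj_tree.nwk"))
    mono <- monophyly_check(
      tr, setNames(records$morphological_label, records$specimen_id))
    readr::write_tsv(mono, path("monophyly.tsv"))
    rel(path("nj_tree.nwk"), path("monophyly.tsv"))
  })
  if (!is.null(references)) {
    run_stage("identify", character(), function() {
      hits <- identify_specimens(records, references,
                                 threshold = identity_threshold)
      readr::write_tsv(hits, path("identification.tsv"))
      rel(path("identification.tsv"))
    })
  }
  run_stage("concord", character(), function() {
    if (!"molecular_label" %in% names(records) ||
        all(is.na(records$molecular_label))) {
      abort("no molecular labels available")
    }
    rec <- tibble(
      specimen_id = records$specimen_id,
      morph_label = records$morphological_label,
      mol_label = records$molecular_label
    )
    rec$klass <- classify_concordance(rec$morph_label, rec$mol_label)
    readr::write_tsv(rec, path("concordance.tsv"))
    readr::write_tsv(concordance_summary(rec), path("concordance_summary.tsv"))
    rel(path("concordance.tsv"), path("concordance_summary.tsv"))
  })

  jsonlite::write_json(manifest, path("results_manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
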