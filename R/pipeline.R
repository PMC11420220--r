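# Orchestration: one configured, seeded, logged run of the whole pipeline.

#' Configure a pipeline run
#'
#' All tunable thresholds default to the study values: VS rule 3 SD above
#' the batch mean (absolute 0.34 in fixed mode), log2-ratio cutoffs
#' (-0.45, +0.35) unless `calibrate = TRUE`, CNV size floor 10 Mb (strict),
#' 95% meiotic uniformity, 0.5 reciprocal overlap, 20%-80% mosaic bands.
#' One master `seed` drives deterministically derived per-stage seeds.
#'
#' @param out_dir Run directory (created).
#' @param scenarios List of [embryo_scenario()] objects to simulate, or
#'   `NULL` with `bins` pointing at binned-count files ([read_bins()]).
#' @param bins Optional input path for pre-binned counts.
#' @param genome A [genome_model()]; defaults to the full-scale model.
#' @param rna Optional [rna_scenario()] to run the RNA branch.
#' @param seed Master seed.
#' @param vs_mode,vs_cutoff QC policy ([qc_filter()]).
#' @param calibrate If `TRUE`, calibrate cutoffs from the pooled batch
#'   ([calibrate_cutoffs()]); else use `loss_cutoff` / `gain_cutoff`.
#' @param loss_cutoff,gain_cutoff Fixed log2-ratio cutoffs.
#' @param min_cnv_size,whole_fraction,meiotic_threshold,overlap,mosaic_bands,n_perm
#'   Downstream thresholds (see the stage functions).
#' @return A `mosaic_config` list.
#' @export
mosaic_config <- function(out_dir, scenarios = NULL, bins = NULL,
                          genome = NULL, rna = NULL, seed = 1,
                          vs_mode = "batch", vs_cutoff = 0.34,
                          calibrate = FALSE,
                          loss_cutoff = -0.45, gain_cutoff = 0.35,
                          min_cnv_size = 10e6, whole_fraction = 0.8,
                          meiotic_threshold = 0.95, overlap = 0.5,
                          mosaic_bands = c(0.2, 0.8), n_perm = 1000) {
  abort_if(is.null(scenarios) && is.null(bins),
           "provide scenarios to simulate or a bins input path")
  structure(as.list(environment()), class = "mosaic_config")
}

#' Run the full pipeline
#'
#' Stages: (1) simulate or load binned counts; (2) GC/mappability
#' correction; (3) VS computation and QC filtering; (4) cutoff selection;
#' (5) per-cell CNV calling; (6) per-embryo summaries, complementary pairs
#' with permutation null, lineage trees (Newick); (7) optional RNA branch
#' (filter, features, calls, DNA validation, summaries). Every stage logs
#' its record counts into a JSON manifest together with the config hash,
#' and all tables are written as TSV into `out_dir`. Identical config +
#' seed reproduces byte-identical outputs.
#'
#' @param config A [mosaic_config()].
#' @return Invisibly, a list with all in-memory results (`qc`, `cutoffs`,
#'   `calls`, `embryos`, `pairs`, `null`, `trees`, `rna`, `manifest`).
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "mosaic_config"), "need a mosaic_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- config$genome %||% genome_model()
  counts_log <- list()

  # stage 1: inputs
  if (!is.null(config$scenarios)) {
    sims <- lapply(config$scenarios, function(sc) {
      sc$seed <- child_seed(config$seed, paste0("sim-", sc$embryo_id))
      simulate_embryo(genome, sc)
    })
    names(sims) <- vapply(config$scenarios, `[[`, character(1), "embryo_id")
    profiles <- purrr::map_dfr(names(sims), function(eid) {
      dplyr::mutate(sims[[eid]]$profiles, embryo_id = eid)
    })
    truth <- purrr::map_dfr(names(sims), function(eid) {
      dplyr::mutate(sims[[eid]]$truth, embryo_id = eid)
    })
  } else {
    profiles <- dplyr::mutate(read_bins(config$bins), embryo_id = "input")
    truth <- NULL
  }
  counts_log$n_cells_input <- dplyr::n_distinct(profiles$cell_id)

  # stages 2-3: correction and QC
  corrected <- correct_profile(profiles)
  qc <- compute_vs(corrected) |>
    qc_filter(mode = config$vs_mode, cutoff = config$vs_cutoff)
  counts_log$n_cells_excluded_qc <- sum(!qc$passed)
  passed_cells <- qc$cell_id[qc$passed]
  abort_if(length(passed_cells) == 0, "QC excluded every cell")
  corr_pass <- dplyr::filter(corrected, .data$cell_id %in% passed_cells)

  # stage 4: cutoffs
  cutoffs <- if (isTRUE(config$calibrate)) {
    calibrate_cutoffs(pool_chrom_log2(corr_pass))
  } else {
    tibble::tibble(loss_cutoff = config$loss_cutoff,
                   gain_cutoff = config$gain_cutoff,
                   calibration_mode = "fixed")
  }

  # stage 5: calls
  calls <- call_cnvs(corr_pass, cutoffs, min_size = config$min_cnv_size,
                     whole_fraction = config$whole_fraction)
  cell2embryo <- dplyr::distinct(profiles, .data$cell_id, .data$embryo_id)
  calls <- dplyr::left_join(calls, cell2embryo, by = "cell_id")
  counts_log$n_calls <- nrow(calls)

  # stage 6: embryo level
  embryo_ids <- unique(cell2embryo$embryo_id)
  per_embryo <- purrr::map(embryo_ids, function(eid) {
    cells <- intersect(cell2embryo$cell_id[cell2embryo$embryo_id == eid],
                       passed_cells)
    ec <- dplyr::filter(calls, .data$embryo_id == eid)
    cls <- classify_meiotic(ec, cells, config$meiotic_threshold)
    list(summary = summarize_embryo(ec, cells, eid, config$meiotic_threshold),
         mitotic = dplyr::mutate(cls$mitotic_calls, embryo_id = eid),
         tree = reconstruct_lineage(cls$mitotic_calls, cells, eid,
                                    config$overlap))
  })
  embryos <- purrr::map_dfr(per_embryo, "summary")
  mitotic_all <- purrr::map_dfr(per_embryo, "mitotic")
  trees <- purrr::map(per_embryo, "tree")
  names(trees) <- embryo_ids
  pairs <- mitotic_all |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::group_modify(~ find_complementary(.x, config$overlap)) |>
    dplyr::ungroup()
  null <- if (length(embryo_ids) >= 2 && nrow(mitotic_all) > 0) {
    complementary_null(mitotic_all, n_perm = config$n_perm,
                       seed = child_seed(config$seed, "perm"),
                       overlap = config$overlap)
  } else NULL
  counts_log$n_embryos <- length(embryo_ids)
  counts_log$n_complementary_pairs <- nrow(pairs)

  # stage 7: RNA branch
  rna <- NULL
  if (!is.null(config$rna)) {
    sc <- config$rna
    sc$seed <- child_seed(config$seed, "rna")
    sim <- simulate_rna(sc)
    filt <- filter_matrix(sim$counts)
    feats <- build_features(filt, sim$genes, sim$alleles)
    rcalls <- call_aneuploidy(feats)
    rna <- list(calls = rcalls,
                validation = validate_against_dna(rcalls, sim$truth),
                summary = summarize_rna_embryos(rcalls, sim$meta),
                filter_log = attr(filt, "filter_log"))
    counts_log$n_rna_cells <- ncol(filt)
  }

  # outputs
  od <- config$out_dir
  readr::write_tsv(dplyr::select(qc, -"per_chrom_sd"),
                   file.path(od, "qc.tsv"))
  readr::write_tsv(cutoffs, file.path(od, "cutoffs.tsv"))
  write_calls(calls, file.path(od, "calls.tsv"))
  readr::write_tsv(
    embryos |>
      dplyr::mutate(meiotic = vapply(.data$meiotic, function(m) {
        paste(paste0(m$chrom, ":", m$direction), collapse = ",")
      }, character(1))),
    file.path(od, "embryo_summary.tsv"))
  readr::write_tsv(pairs, file.path(od, "complementary_pairs.tsv"))
  dir.create(file.path(od, "trees"), showWarnings = FALSE)
  for (eid in names(trees)) {
    writeLines(lineage_newick(trees[[eid]]),
               file.path(od, "trees", paste0(eid, ".nwk")))
    jsonlite::write_json(trees[[eid]]$events,
                         file.path(od, "trees", paste0(eid, ".events.json")))
  }
  if (!is.null(rna)) {
    readr::write_tsv(rna$calls, file.path(od, "rna_calls.tsv"))
    readr::write_tsv(rna$validation, file.path(od, "rna_validation.tsv"))
  }
  cfg_serial <- config[setdiff(names(config), c("scenarios", "rna", "genome"))]
  manifest <- list(
    package = "mosaicscan",
    version = as.character(utils::packageVersion("mosaicscan")),
    config = cfg_serial,
    config_hash = rlang::hash(config),
    counts = counts_log)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(paste(names(cfg_serial),
                   vapply(cfg_serial, function(v) paste(format(v), collapse = ","),
                          character(1)), sep = " = "),
             file.path(od, "config.txt"))
  invisible(list(qc = qc, cutoffs = cutoffs, calls = calls, truth = truth,
                 embryos = embryos, pairs = pairs, null = null, trees = trees,
                 rna = rna, manifest = manifest))
}
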