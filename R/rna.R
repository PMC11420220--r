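# Aneuploidy calling from scRNA-seq: expression + allelic-imbalance
# z-scores with evaluability filtering and DNA-truth validation.

#' Filter an expression count matrix for aneuploidy inference
#'
#' Cell filter first: cells whose number of expressed genes (count >= 1) is
#' strictly greater than `min_genes_per_cell` are retained. Gene filters on
#' the retained cells: expressed in at least `min_cells` cells AND median
#' expression strictly greater than `min_median` counts.
#'
#' @param counts Genes x cells integer matrix with dimnames.
#' @param min_genes_per_cell Strict lower bound on expressed genes per cell.
#' @param min_cells Minimal number of cells a gene is expressed in.
#' @param min_median Strict lower bound on a gene's median expression.
#' @return Filtered matrix with attribute `filter_log` (tibble of what each
#'   filter removed). Errors if nothing survives.
#' @export
filter_matrix <- function(counts, min_genes_per_cell = 2000, min_cells = 3,
                          min_median = 50) {
  abort_if(is.null(dim(counts)), "counts must be a matrix")
  cell_keep <- colSums(counts >= 1) > min_genes_per_cell
  kept <- counts[, cell_keep, drop = FALSE]
  expr_keep <- rowSums(kept >= 1) >= min_cells
  med_keep <- apply(kept, 1, stats::median) > min_median
  out <- kept[expr_keep & med_keep, , drop = FALSE]
  log_ <- tibble::tibble(
    filter = c("cells_low_complexity", "genes_too_few_cells",
               "genes_low_median"),
    removed = c(sum(!cell_keep), sum(!expr_keep),
                sum(expr_keep & !med_keep)))
  abort_if(nrow(out) == 0 || ncol(out) == 0,
           paste0("no data survive filtering (removed: ",
                  paste(log_$filter, log_$removed, sep = "=", collapse = ", "),
                  ")"))
  attr(out, "filter_log") <- log_
  out
}

#' Build per-(cell, chromosome) aneuploidy features
#'
#' Expression is normalised per cell to a fixed scale factor of 100,000
#' counts and log-transformed (`log1p`). The raw expression score of a
#' chromosome in a cell is the mean normalised expression of the
#' chromosome's (filtered) genes divided by the across-cell mean of that
#' quantity; `z_expr` is its z-score across cells, per chromosome. The raw
#' allelic-imbalance score is the deviation of the chromosome's aggregate
#' oriented-allele fraction from the across-cell median; `z_ai` is its
#' z-score across cells. Both are therefore invariant to per-cell library
#' scaling. A chromosome is evaluable only with more than `min_snp` SNP
#' split reads.
#'
#' Z-scores are robust by default (median centre, MAD scale), so the
#' reference distribution is the euploid cell majority and a handful of
#' aberrant cells on the same chromosome cannot inflate the scale and mask
#' each other; `robust = FALSE` gives plain mean/SD z-scores.
#'
#' The allele input is oriented: `a_count` counts reads from the haplotype
#' whose dosage rises under a gain, so gains push the fraction above 1/2
#' and losses (of that haplotype) toward 0 — the convention under which the
#' sign-asymmetric calling thresholds are meaningful.
#'
#' @param counts Filtered matrix from [filter_matrix()].
#' @param genes Tibble mapping `gene_id` to `chrom`.
#' @param alleles Tibble `cell_id`, `chrom`, `a_count`, `b_count` (and
#'   optionally `snp_split_reads`; defaults to `a + b`).
#' @param min_snp Strict SNP split-read floor for evaluability.
#' @param min_cells_for_z Minimal number of cells for stable z-scoring.
#' @param robust Use median/MAD z-scores (default) instead of mean/SD.
#' @return Tibble: `cell_id`, `chrom`, `z_expr`, `z_ai`, `snp_split_reads`,
#'   `evaluable`.
#' @export
build_features <- function(counts, genes, alleles, min_snp = 100,
                           min_cells_for_z = 20, robust = TRUE) {
  abort_if(ncol(counts) < min_cells_for_z,
           "need >= 20 cells for stable across-cell z-scores")
  zfun <- if (robust) robust_z else function(x) as.numeric(scale(x))
  norm <- log1p(t(t(counts) / colSums(counts)) * 1e5)
  gmap <- genes$chrom[match(rownames(counts), genes$gene_id)]
  abort_if(anyNA(gmap), "every gene in counts must map to a chromosome")
  chroms <- unique(gmap)
  expr <- purrr::map_dfr(chroms, function(ch) {
    rows <- which(gmap == ch)
    score <- colMeans(norm[rows, , drop = FALSE])
    ratio <- score / mean(score)
    tibble::tibble(cell_id = colnames(counts), chrom = ch,
                   z_expr = zfun(ratio))
  })
  if (!"snp_split_reads" %in% names(alleles)) {
    alleles$snp_split_reads <- alleles$a_count + alleles$b_count
  }
  ai <- alleles |>
    dplyr::filter(.data$cell_id %in% colnames(counts)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      frac = .data$a_count / pmax(.data$a_count + .data$b_count, 1),
      raw_ai = .data$frac - stats::median(.data$frac),
      z_ai = zfun(.data$raw_ai)) |>
    dplyr::ungroup() |>
    dplyr::select("cell_id", "chrom", "z_ai", "snp_split_reads")
  expr |>
    dplyr::full_join(ai, by = c("cell_id", "chrom")) |>
    dplyr::mutate(evaluable = !is.na(.data$z_expr) & !is.na(.data$z_ai) &
                    .data$snp_split_reads > min_snp)
}

#' Call whole-chromosome aneuploidy from RNA features
#'
#' Dual-evidence rule with fixed z thresholds: gain requires
#' `z_expr > 5.6` AND `z_ai > 0.05`; loss requires `z_expr < -3.65` AND
#' `z_ai < -1.6`. Chromosomes failing the SNP split-read floor are
#' `not_evaluable`. No call is ever made from one evidence channel alone.
#'
#' @param features Tibble from [build_features()].
#' @param gain_expr,gain_ai Gain thresholds.
#' @param loss_expr,loss_ai Loss thresholds.
#' @return `features` with a `call` column in
#'   `{gain, loss, euploid, not_evaluable}`.
#' @export
call_aneuploidy <- function(features, gain_expr = 5.6, gain_ai = 0.05,
                            loss_expr = -3.65, loss_ai = -1.6) {
  features |>
    dplyr::mutate(call = dplyr::case_when(
      !.data$evaluable ~ "not_evaluable",
      .data$z_expr > gain_expr & .data$z_ai > gain_ai ~ "gain",
      .data$z_expr < loss_expr & .data$z_ai < loss_ai ~ "loss",
      TRUE ~ "euploid"))
}

#' Validate RNA aneuploidy calls against DNA truth
#'
#' DNA calls are the gold standard. The false-positive rate is the fraction
#' of RNA-called aberrations not confirmed (same cell, chromosome and
#' direction) in DNA; the false-negative rate is the fraction of
#' RNA-negative (euploid-called) chromosomes not confirmed euploid in DNA.
#'
#' @param rna_calls Tibble from [call_aneuploidy()].
#' @param dna_truth Tibble `cell_id`, `chrom`, `direction` of true
#'   aberrations (absence means euploid).
#' @return A one-row `rna_validation` tibble: `n_called`,
#'   `n_called_confirmed`, `n_negative`, `n_negative_confirmed`, `fp_rate`,
#'   `fn_rate`. `fp_rate` is `NA` when nothing was called.
#' @export
validate_against_dna <- function(rna_calls, dna_truth) {
  ev <- dplyr::filter(rna_calls, .data$call != "not_evaluable")
  joined <- ev |>
    dplyr::left_join(dplyr::mutate(dna_truth, dna = .data$direction),
                     by = c("cell_id", "chrom"))
  called <- dplyr::filter(joined, .data$call %in% c("gain", "loss"))
  neg <- dplyr::filter(joined, .data$call == "euploid")
  n_called <- nrow(called)
  n_called_confirmed <- sum(!is.na(called$dna) & called$dna == called$call)
  n_negative <- nrow(neg)
  n_negative_confirmed <- sum(is.na(neg$dna))
  out <- tibble::tibble(
    n_called = n_called, n_called_confirmed = n_called_confirmed,
    n_negative = n_negative, n_negative_confirmed = n_negative_confirmed,
    fp_rate = if (n_called > 0) (n_called - n_called_confirmed) / n_called
    else NA_real_,
    fn_rate = if (n_negative > 0)
      (n_negative - n_negative_confirmed) / n_negative else NA_real_)
  class(out) <- c("rna_validation", class(out))
  out
}

#' Summarise RNA aneuploidy calls per embryo, stage and lineage
#'
#' Rates are aneuploid cells over evaluable cells (a cell is evaluable with
#' at least one evaluable chromosome; aneuploid with at least one gain or
#' loss call). Lineage rates are compared with a Kruskal-Wallis rank test
#' on per-(embryo, lineage) rates.
#'
#' @param calls Tibble from [call_aneuploidy()].
#' @param meta Tibble `cell_id`, `embryo_id`, `stage`, `lineage`.
#' @return An `rna_summary` list of tibbles: `per_embryo`, `per_stage`,
#'   `per_lineage`, `aberration_histogram`, plus `lineage_test`
#'   (`htest`-derived one-row tibble).
#' @export
summarize_rna_embryos <- function(calls, meta) {
  per_cell <- calls |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      evaluable = any(.data$evaluable),
      n_aberrations = sum(.data$call %in% c("gain", "loss")),
      .groups = "drop") |>
    dplyr::inner_join(meta, by = "cell_id")
  dropped <- per_cell |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(ok = any(.data$evaluable), .groups = "drop")
  if (any(!dropped$ok)) {
    rlang::warn(paste0(sum(!dropped$ok),
                       " embryo(s) with zero evaluable cells excluded"))
  }
  pc <- dplyr::filter(per_cell, .data$evaluable)
  per_embryo <- pc |>
    dplyr::group_by(.data$embryo_id, .data$stage) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_aneuploid = sum(.data$n_aberrations > 0),
                     rate = .data$n_aneuploid / .data$n_cells,
                     .groups = "drop")
  per_stage <- per_embryo |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(mean_rate = mean(.data$rate), sd_rate = stats::sd(.data$rate),
                     n_embryos = dplyr::n(), .groups = "drop")
  per_lineage <- pc |>
    dplyr::group_by(.data$lineage) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_aneuploid = sum(.data$n_aberrations > 0),
                     rate = .data$n_aneuploid / .data$n_cells,
                     .groups = "drop")
  aneup <- dplyr::filter(pc, .data$n_aberrations > 0)
  hist_ <- aneup |>
    dplyr::mutate(bin = ifelse(.data$n_aberrations == 1, "1",
                               ifelse(.data$n_aberrations == 2, "2", ">2"))) |>
    dplyr::count(.data$bin) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  el_rates <- pc |>
    dplyr::group_by(.data$embryo_id, .data$lineage) |>
    dplyr::summarise(rate = mean(.data$n_aberrations > 0), .groups = "drop")
  lineage_test <- if (dplyr::n_distinct(el_rates$lineage) >= 2) {
    kt <- stats::kruskal.test(rate ~ factor(lineage), data = el_rates)
    tibble::tibble(statistic = unname(kt$statistic),
                   df = unname(kt$parameter), p_value = kt$p.value)
  } else {
    tibble::tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  structure(list(per_embryo = per_embryo, per_stage = per_stage,
                 per_lineage = per_lineage, aberration_histogram = hist_,
                 lineage_test = lineage_test,
                 mosaic_embryo_fraction = mean(per_embryo$n_aneuploid > 0)),
            class = "rna_summary")
}

#' @export
print.rna_summary <- function(x, ...) {
  cat("RNA aneuploidy summary:", nrow(x$per_embryo), "embryos;",
      sprintf("%.1f%%", 100 * x$mosaic_embryo_fraction), "mosaic\n")
  cat("per-lineage rates:\n")
  print(x$per_lineage)
  invisible(x)
}
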