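# Per-cell quality control: the variability score (VS) and batch filtering.

#' Compute the variability score of each cell
#'
#' The VS of a cell is the median, over scorable chromosomes, of the
#' standard deviation of corrected bin counts within the chromosome. Cells
#' with chaotic, unevenly amplified genomes have inflated SDs on every
#' chromosome and hence a high VS, while a genuine aneuploidy shifts only
#' the affected chromosomes and barely moves the median.
#'
#' Chromosomes with fewer than two usable bins have no defined SD and are
#' excluded from the median with a warning. Cells flagged unusable by
#' [correct_profile()] get `vs = NA`.
#'
#' @param profiles A corrected profile tibble from [correct_profile()].
#' @return A tibble with one row per cell: `cell_id`, `vs`, `n_chrom_used`,
#'   `total_count`, and a list-column `per_chrom_sd` of named SD vectors.
#' @export
compute_vs <- function(profiles) {
  abort_if(!"corrected_count" %in% names(profiles),
           "profiles must be corrected first (see correct_profile())")
  profiles |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      tot <- sum(df$count)
      if (!any(df$cell_usable)) {
        return(tibble::tibble(vs = NA_real_, n_chrom_used = 0L,
                              total_count = tot, per_chrom_sd = list(NULL)))
      }
      ok <- df$usable
      sds <- tapply(df$corrected_count[ok], df$chrom[ok], function(v) {
        if (length(v) < 2) NA_real_ else stats::sd(v)
      })
      sds <- sds[unique(df$chrom)]
      if (anyNA(sds)) {
        rlang::warn(paste0("cell ", key$cell_id[1], ": ",
                           sum(is.na(sds)),
                           " chromosome(s) with < 2 usable bins excluded from VS"))
      }
      keep <- sds[!is.na(sds)]
      tibble::tibble(vs = stats::median(keep), n_chrom_used = length(keep),
                     total_count = tot, per_chrom_sd = list(keep))
    }) |>
    dplyr::ungroup()
}

#' Filter cells on their variability score
#'
#' Two policies are provided. The batch-adaptive policy (`mode = "batch"`)
#' excludes cells whose VS exceeds `mean(vs) + 3 * sd(vs)` of the batch,
#' reading the study's "VS > 3 SD" rule as three standard deviations above
#' the batch mean; it requires at least `min_batch` cells. The fixed policy
#' (`mode = "fixed"`) uses an absolute cutoff (the study's printed value is
#' 0.34). Cells with fewer than `min_total_count` reads, or with undefined
#' VS, always fail.
#'
#' @param qc A VS table from [compute_vs()].
#' @param mode `"batch"` or `"fixed"`.
#' @param cutoff Absolute VS cutoff for `mode = "fixed"`.
#' @param min_batch Minimum batch size for the adaptive policy.
#' @param min_total_count Minimum total read count per cell (depth floor).
#' @return `qc` with added columns `passed` and `vs_threshold`.
#' @export
qc_filter <- function(qc, mode = c("batch", "fixed"), cutoff = 0.34,
                      min_batch = 10, min_total_count = 0) {
  mode <- match.arg(mode)
  abort_if(nrow(qc) == 0, "qc table is empty")
  vs <- qc$vs
  if (mode == "batch") {
    abort_if(sum(!is.na(vs)) < min_batch,
             "batch-adaptive QC needs >= 10 cells; use mode = 'fixed' with an absolute cutoff")
    s <- stats::sd(vs, na.rm = TRUE)
    thr <- mean(vs, na.rm = TRUE) + 3 * (if (is.na(s)) 0 else s)
  } else {
    thr <- cutoff
  }
  qc |>
    dplyr::mutate(
      vs_threshold = thr,
      passed = !is.na(.data$vs) & .data$vs <= thr &
        .data$total_count >= min_total_count
    )
}
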