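# GC/mappability correction of binned read counts. Re-implements the
# correction contract of the usual low-pass single-cell CNV workflow:
# mappability-masked bins, division by mappability, robust loess fit of
# count vs GC divided out, median scaled to 1, log2 ratio.

#' Correct binned read-depth profiles for GC and mappability bias
#'
#' For each cell: bins with mappability below `map_floor` are flagged
#' unusable and excluded from every downstream statistic; counts are divided
#' by mappability, median-normalised, a robust loess trend of normalised
#' count versus GC is fitted on usable bins and divided out, and the result
#' is re-scaled so the median of usable bins is exactly 1. `log2_ratio` is
#' the log2 of the corrected count (floored far below the monosomy level so
#' empty bins cannot produce infinities).
#'
#' Cells whose usable bins are all zero are marked unusable
#' (`cell_usable = FALSE`, corrected values `NA`) rather than dropped.
#'
#' @param profiles Tibble of raw binned counts with columns `cell_id`,
#'   `chrom`, `start`, `end`, `gc`, `mappability`, `count` (one or many
#'   cells), e.g. from [simulate_embryo()].
#' @param map_floor Minimum mappability for a bin to be usable.
#' @param span Loess span for the GC trend.
#' @return The input tibble with added columns `usable`, `cell_usable`,
#'   `corrected_count`, `log2_ratio`, classed `binned_profile`.
#' @export
correct_profile <- function(profiles, map_floor = 0.8, span = 0.6) {
  abort_if(!all(c("cell_id", "chrom", "start", "end", "gc", "mappability",
                  "count") %in% names(profiles)),
           "profiles must have cell_id, chrom, start, end, gc, mappability, count")
  out <- profiles |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ correct_one_cell(.x, map_floor, span)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cell_id, match(.data$chrom, unique(profiles$chrom)),
                   .data$start)
  class(out) <- c("binned_profile", class(out))
  out
}

correct_one_cell <- function(df, map_floor, span) {
  df$usable <- df$mappability >= map_floor
  u <- df$usable
  df$corrected_count <- NA_real_
  df$log2_ratio <- NA_real_
  if (!any(u) || sum(df$count[u]) == 0) {
    df$cell_usable <- FALSE
    return(df)
  }
  df$cell_usable <- TRUE
  x <- df$count / df$mappability
  x <- x / stats::median(x[u])
  gc <- df$gc
  trend <- rep(1, nrow(df))
  if (length(unique(gc[u])) >= 5) {
    fit <- try(stats::loess(x[u] ~ gc[u], span = span, degree = 2,
                            family = "symmetric"),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      tr <- stats::predict(fit, newdata = gc)
      tr[!is.finite(tr)] <- 1
      trend <- pmax(tr, 0.05)
    }
  }
  corr <- x / trend
  corr <- corr / stats::median(corr[u])
  df$corrected_count[u] <- corr[u]
  # floor far below the monosomy log2 level (-1); protects against empty bins
  df$log2_ratio[u] <- log2(pmax(corr[u], 2^-8))
  df
}
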