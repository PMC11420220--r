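# Pooled multicell biopsies: simulation and mosaic-fraction assessment.

#' Simulate a pooled multicell biopsy profile
#'
#' Samples `n_cells_biopsied` cells (without replacement) from a simulated
#' embryo and pools their true copy-number profiles: the pooled log2 ratio
#' of bin b is `log2(mean copy number / 2)` plus Gaussian noise with SD
#' `noise_sd / sqrt(n_cells_biopsied)` (pooling averages amplification
#' noise). The true sampled fraction of every aberrant event is recorded,
#' which is what the mosaic-fraction estimator is benchmarked against.
#'
#' @param genome A [genome_model()].
#' @param scenario An [embryo_scenario()].
#' @param n_cells_biopsied Number of cells in the biopsy (<= `n_cells`;
#'   equal to `n_cells` pools the whole embryo deterministically).
#' @param noise_sd Per-cell log2 noise SD; 0 gives the exact closed form.
#' @param seed Integer seed.
#' @return List: `profile` (tibble `chrom`, `start`, `end`, `log2_ratio`),
#'   `sampled` (cell table of sampled cells), `truth_fraction` (tibble
#'   `chrom`, `start`, `end`, `direction`, `f_true`).
#' @export
simulate_biopsy <- function(genome, scenario, n_cells_biopsied,
                            noise_sd = 0.1, seed = 1) {
  abort_if(n_cells_biopsied < 1, "n_cells_biopsied must be >= 1")
  abort_if(n_cells_biopsied > scenario$n_cells,
           "biopsy cannot contain more cells than the embryo")
  assign_ <- clone_assignment(scenario)
  cn_by_clone <- lapply(c(list(NULL), scenario$clones), function(cl) {
    cn <- apply_events(rep(2L, nrow(genome)), genome, scenario$meiotic_events)
    if (!is.null(cl)) cn <- apply_events(cn, genome, cl$events)
    cn
  })
  res <- with_seed(seed, {
    idx <- if (n_cells_biopsied == scenario$n_cells) {
      seq_len(scenario$n_cells)
    } else {
      sample(scenario$n_cells, n_cells_biopsied)
    }
    cn_mat <- vapply(idx, function(i) cn_by_clone[[assign_[i] + 1L]],
                     numeric(nrow(genome)))
    r <- log2(pmax(rowMeans(cn_mat), 2^-8) / 2)
    if (noise_sd > 0) {
      r <- r + stats::rnorm(length(r), 0, noise_sd / sqrt(n_cells_biopsied))
    }
    list(idx = idx, r = r)
  })
  lens <- chrom_lengths(genome)
  truth_fraction <- purrr::imap_dfr(scenario$clones, function(cl, k) {
    f <- mean(assign_[res$idx] == k)
    if (nrow(cl$events) == 0 || f == 0) return(NULL)
    cl$events |>
      dplyr::mutate(start = ifelse(is.na(start), 0, start),
                    end = ifelse(is.na(end), unname(lens[chrom]), end),
                    f_true = f)
  })
  list(
    profile = tibble::tibble(chrom = genome$chrom, start = genome$start,
                             end = genome$end, log2_ratio = res$r),
    sampled = tibble::tibble(cell_index = res$idx, clone = assign_[res$idx]),
    truth_fraction = truth_fraction
  )
}

#' Assess a pooled biopsy profile for aneuploidy and mosaic level
#'
#' Scans the pooled log2-ratio profile for aberrant regions and inverts the
#' pooling arithmetic to estimate the aberrant-cell fraction f of each:
#' for a trisomic fraction f the pooled ratio is `r = log2((2 + f)/2)`, so
#' `f = 2 * (2^r - 1)` for gains and `f = 2 * (1 - 2^r)` for losses,
#' clipped to `[0, 1]`. Regions are classified euploid (`f <` lower band),
#' mosaic (within the bands) or aneuploid (`f >` upper band); the default
#' 20%-80% bands follow the intermediate-copy-number convention of clinical
#' PGT-A reporting.
#'
#' Detection: bins whose (running-median smoothed) ratio exceeds the log2
#' level implied by the lower band edge form candidate runs; maximal
#' same-direction runs spanning more than `min_size` bp are assessed.
#'
#' @param profile Tibble `chrom`, `start`, `end`, `log2_ratio`.
#' @param bands Mosaic band edges `c(lower, upper)` on f.
#' @param min_size Minimal region span in bp (strict).
#' @param whole_fraction Chromosome fraction for `scope = "whole"`.
#' @param smooth Running-median window (odd; 1 disables smoothing).
#' @param sample_id Label.
#' @return Tibble of assessed regions: `sample_id`, `chrom`, `start`, `end`,
#'   `direction`, `scope`, `mean_log2_ratio`, `f`, `classification`; zero
#'   rows means the sample is euploid.
#' @export
assess_biopsy <- function(profile, bands = c(0.2, 0.8), min_size = 10e6,
                          whole_fraction = 0.8, smooth = 5,
                          sample_id = "biopsy") {
  abort_if(!all(c("chrom", "start", "end", "log2_ratio") %in% names(profile)),
           "profile needs chrom, start, end, log2_ratio")
  r_gain_min <- log2(1 + bands[1] / 2) # f = lower band edge, gain side
  r_loss_max <- log2(1 - bands[1] / 2)
  empty <- tibble::tibble(start = numeric(), end = numeric(),
                          direction = character(), scope = character(),
                          mean_log2_ratio = numeric(), f = numeric(),
                          classification = character())
  out <- profile |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$start)
      r <- df$log2_ratio
      rs <- if (smooth > 1 && length(r) > smooth) {
        stats::runmed(r, smooth, endrule = "median")
      } else r
      state <- ifelse(rs > r_gain_min, 1L, ifelse(rs < r_loss_max, -1L, 0L))
      runs <- state_runs(state)
      runs <- runs[runs$state != 0L, , drop = FALSE]
      if (nrow(runs) == 0) return(empty)
      chrom_len <- max(df$end)
      regions <- purrr::pmap_dfr(runs, function(state, first, last) {
        start <- df$start[first]
        end <- df$end[last]
        if ((end - start) <= min_size) return(NULL)
        mr <- mean(r[first:last])
        f <- if (state == 1L) 2 * (2^mr - 1) else 2 * (1 - 2^mr)
        f <- min(max(f, 0), 1)
        tibble::tibble(
          start = start, end = end,
          direction = if (state == 1L) "gain" else "loss",
          scope = if ((end - start) >= whole_fraction * chrom_len)
            "whole" else "segmental",
          mean_log2_ratio = mr, f = f,
          classification = if (f < bands[1]) "euploid"
          else if (f <= bands[2]) "mosaic" else "aneuploid")
      })
      if (nrow(regions) == 0) empty else regions
    }) |>
    dplyr::ungroup()
  dplyr::bind_cols(tibble::tibble(sample_id = rep(sample_id, nrow(out))), out)
}
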