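# Three-state HMM segmentation of per-bin log2 ratios and CNV calling.

# Viterbi decoding for a 3-state Gaussian-emission HMM with symmetric
# transitions. States: 1 = loss, 2 = neutral, 3 = gain. Log space.
viterbi3 <- function(x, means, sd, p_stay = 1 - 1e-5) {
  n <- length(x)
  k <- 3L
  log_a <- matrix(log((1 - p_stay) / (k - 1)), k, k)
  diag(log_a) <- log(p_stay)
  emit <- vapply(means, function(m) stats::dnorm(x, m, sd, log = TRUE),
                 numeric(n))
  v <- matrix(-Inf, n, k)
  bp <- matrix(0L, n, k)
  v[1, ] <- log(1 / k) + emit[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in 1:k) {
        cand <- v[t - 1, ] + log_a[, j]
        bp[t, j] <- which.max(cand)
        v[t, j] <- cand[bp[t, j]] + emit[t, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- bp[t + 1, path[t + 1]]
  path
}

# Run-length segments of a state path; rows: state, first, last (indices).
state_runs <- function(path) {
  r <- rle(path)
  last <- cumsum(r$lengths)
  tibble::tibble(state = r$values, first = last - r$lengths + 1L, last = last)
}

# Merge same-state aberrant segments separated by <= gap neutral bins.
merge_runs <- function(runs, gap = 2L) {
  if (nrow(runs) < 3) return(runs)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i <= nrow(runs) - 2L) {
      a <- runs[i, ]; b <- runs[i + 1L, ]; c <- runs[i + 2L, ]
      if (a$state != 2L && c$state == a$state && b$state == 2L &&
          (b$last - b$first + 1L) <= gap) {
        runs$last[i] <- c$last
        runs <- runs[-c(i + 1L, i + 2L), ]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  runs
}

#' Call copy-number variants per cell
#'
#' Segments each cell's per-bin log2 ratios with a three-state (loss /
#' neutral / gain) Gaussian HMM decoded by Viterbi, merges aberrant
#' segments separated by at most `merge_gap` neutral bins, and reports
#' segments whose mean log2 ratio lies beyond the matching cutoff and whose
#' genomic span strictly exceeds `min_size` bp. Emission means are
#' `(loss_cutoff - 0.2, 0, gain_cutoff + 0.2)`; the shared emission SD is
#' estimated from the cell's neutral bins (floored at `min_sd`).
#'
#' A call is `scope = "whole"` when it covers at least `whole_fraction` of
#' its chromosome, else `"segmental"`.
#'
#' @param profiles Corrected profiles from [correct_profile()]; only
#'   QC-passed cells should be supplied.
#' @param cutoffs A cutoff tibble from [calibrate_cutoffs()] or
#'   [default_cutoffs()].
#' @param min_size Minimal genomic span in bp; strictly greater-than
#'   (a 10.0 Mb segment is not reported at the default).
#' @param whole_fraction Fraction of the chromosome a call must cover to be
#'   a whole-chromosome call.
#' @param merge_gap Maximal number of intervening neutral bins merged over.
#' @param p_stay HMM self-transition probability.
#' @param min_sd Floor on the emission SD.
#' @return Tibble of calls: `cell_id`, `chrom`, `start`, `end`, `direction`,
#'   `size_bp`, `scope`, `mean_log2_ratio`.
#' @export
call_cnvs <- function(profiles, cutoffs = default_cutoffs(),
                      min_size = 10e6, whole_fraction = 0.8,
                      merge_gap = 2L, p_stay = 1 - 1e-5, min_sd = 0.05) {
  abort_if(!"log2_ratio" %in% names(profiles),
           "profiles must be corrected first (see correct_profile())")
  lc <- cutoffs$loss_cutoff[1]
  gcut <- cutoffs$gain_cutoff[1]
  abort_if(!(lc < 0 && gcut > 0), "need loss_cutoff < 0 < gain_cutoff")
  means <- c(lc - 0.2, 0, gcut + 0.2)

  out <- profiles |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      abort_if(!any(df$cell_usable),
               paste0("cell ", key$cell_id[1], " is unusable; filter before calling"))
      chrom_len <- tapply(df$end, df$chrom, max)
      neutral_x <- df$log2_ratio[df$usable & df$log2_ratio > lc &
                                   df$log2_ratio < gcut]
      sd_hat <- max(stats::sd(neutral_x), min_sd, na.rm = TRUE)
      purrr::map_dfr(unique(df$chrom), function(ch) {
        sub <- df[df$chrom == ch & df$usable, ]
        if (nrow(sub) == 0) {
          rlang::inform(paste0("cell ", key$cell_id[1], ": ", ch,
                               " has no usable bins; no calls there"))
          return(NULL)
        }
        path <- viterbi3(sub$log2_ratio, means, sd_hat, p_stay)
        runs <- merge_runs(state_runs(path), merge_gap)
        runs <- runs[runs$state != 2L, , drop = FALSE]
        if (nrow(runs) == 0) return(NULL)
        seg <- purrr::pmap_dfr(runs, function(state, first, last) {
          bins <- sub[first:last, ]
          tibble::tibble(
            chrom = ch, start = bins$start[1], end = bins$end[nrow(bins)],
            direction = if (state == 1L) "loss" else "gain",
            mean_log2_ratio = mean(bins$log2_ratio)
          )
        })
        seg$size_bp <- seg$end - seg$start
        keep <- seg$size_bp > min_size &
          ((seg$direction == "gain" & seg$mean_log2_ratio > gcut) |
             (seg$direction == "loss" & seg$mean_log2_ratio < lc))
        seg <- seg[keep, , drop = FALSE]
        if (nrow(seg) == 0) return(NULL)
        seg$scope <- ifelse(seg$size_bp >= whole_fraction * chrom_len[[ch]],
                            "whole", "segmental")
        seg
      })
    }) |>
    dplyr::ungroup()

  if (nrow(out) == 0) {
    return(tibble::tibble(cell_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          direction = character(), size_bp = numeric(),
                          scope = character(), mean_log2_ratio = numeric()))
  }
  dplyr::select(out, "cell_id", "chrom", "start", "end", "direction",
                "size_bp", "scope", "mean_log2_ratio")
}

#' Per-cell karyotype summary
#'
#' @param calls Call tibble from [call_cnvs()].
#' @param cell_ids All QC-passed cell ids (so euploid cells appear).
#' @return Tibble: `cell_id`, `n_calls`, `n_gain`, `n_loss`, `is_euploid`.
#' @export
karyotype_summary <- function(calls, cell_ids) {
  per <- calls |>
    dplyr::count(.data$cell_id, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  out <- tibble::tibble(cell_id = cell_ids) |>
    dplyr::left_join(per, by = "cell_id")
  for (col in c("gain", "loss")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out |>
    dplyr::mutate(n_gain = .data$gain, n_loss = .data$loss,
                  n_calls = .data$n_gain + .data$n_loss,
                  is_euploid = .data$n_calls == 0L) |>
    dplyr::select("cell_id", "n_calls", "n_gain", "n_loss", "is_euploid")
}
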