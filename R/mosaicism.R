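# Embryo-level aggregation: meiotic vs mitotic classification, rate and
# category summaries, complementary (reciprocal gain/loss) cell detection
# and its permutation null.

#' Classify meiotic-origin aneuploidies of one embryo
#'
#' A (chromosome, direction) is scored meiotic when at least
#' `threshold` (default 95%) of the embryo's QC-passed cells carry a
#' whole-chromosome call of that direction on it; a meiotic error arises in
#' the gametes and is expected in essentially every cell. Chromosomes
#' flagged meiotic are removed entirely from the mitotic view, so they never
#' enter mitotic rates, categories, complementary pairs or lineage events.
#' Fractions are compared exactly (19/20 qualifies at 0.95; 18/20 does not).
#'
#' @param calls Calls of one embryo ([call_cnvs()]).
#' @param cell_ids All QC-passed cell ids of the embryo (including euploid
#'   cells).
#' @param threshold Carrier fraction at or above which a uniform aneuploidy
#'   is scored meiotic.
#' @return List with `meiotic` (tibble: `chrom`, `direction`,
#'   `carrier_fraction`) and `mitotic_calls` (calls excluding meiotic
#'   chromosomes).
#' @export
classify_meiotic <- function(calls, cell_ids, threshold = 0.95) {
  n <- length(cell_ids)
  abort_if(n < 1, "need >= 1 QC-passed cell")
  meiotic <- calls |>
    dplyr::filter(.data$scope == "whole") |>
    dplyr::distinct(.data$cell_id, .data$chrom, .data$direction) |>
    dplyr::count(.data$chrom, .data$direction, name = "carriers") |>
    dplyr::mutate(carrier_fraction = .data$carriers / n) |>
    dplyr::filter(.data$carrier_fraction >= threshold) |>
    dplyr::select("chrom", "direction", "carrier_fraction")
  list(meiotic = meiotic,
       mitotic_calls = dplyr::filter(calls, !.data$chrom %in% meiotic$chrom))
}

#' Summarise one embryo's mosaicism
#'
#' Computes the mitotic aneuploidy rate (cells with at least one mitotic
#' call over all QC-passed cells) and the two cell-category breakdowns:
#' by direction (gain-only / loss-only / both) and by scope (whole-only /
#' segmental-only / both). Each breakdown partitions the aneuploid cells.
#'
#' @param calls Calls of one embryo.
#' @param cell_ids All QC-passed cell ids.
#' @param embryo_id Label.
#' @param threshold Meiotic carrier-fraction threshold.
#' @return One-row tibble with rate, category fractions, meiotic chromosomes
#'   (list-column) and complementary-pair count.
#' @export
summarize_embryo <- function(calls, cell_ids, embryo_id = "embryo",
                             threshold = 0.95) {
  abort_if(length(cell_ids) == 0, "zero cells")
  cls <- classify_meiotic(calls, cell_ids, threshold)
  mit <- cls$mitotic_calls
  n <- length(cell_ids)
  per <- mit |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      any_gain = any(.data$direction == "gain"),
      any_loss = any(.data$direction == "loss"),
      any_whole = any(.data$scope == "whole"),
      any_seg = any(.data$scope == "segmental"),
      .groups = "drop")
  pairs <- find_complementary(mit)
  tibble::tibble(
    embryo_id = embryo_id,
    n_cells = n,
    n_aneuploid = nrow(per),
    mitotic_rate = nrow(per) / n,
    frac_gain_only = sum(per$any_gain & !per$any_loss) / n,
    frac_loss_only = sum(per$any_loss & !per$any_gain) / n,
    frac_gain_and_loss = sum(per$any_gain & per$any_loss) / n,
    frac_whole_only = sum(per$any_whole & !per$any_seg) / n,
    frac_seg_only = sum(per$any_seg & !per$any_whole) / n,
    frac_whole_and_seg = sum(per$any_whole & per$any_seg) / n,
    meiotic = list(cls$meiotic),
    n_meiotic = nrow(cls$meiotic),
    n_complementary_pairs = nrow(pairs),
    is_mosaic = nrow(per) > 0
  )
}

# Reciprocal overlap of two intervals; whole-vs-whole pairs give 1.
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Find complementary gain/loss cell pairs within an embryo
#'
#' Two distinct cells of the same embryo form a complementary pair when one
#' carries a gain and the other a loss of the same region: the same
#' chromosome for whole-chromosome calls, or segments with reciprocal
#' overlap at least `overlap` for segmental calls. Complementary cells are
#' the signature of a mitotic nondisjunction event and can cancel out in
#' pooled multicell biopsies. Supply mitotic calls only (see
#' [classify_meiotic()]).
#'
#' @param calls Mitotic calls of one embryo.
#' @param overlap Minimal reciprocal overlap for a pair.
#' @return Tibble: `chrom`, `region_type`, `gain_cell_id`, `loss_cell_id`,
#'   `reciprocal_overlap`.
#' @export
find_complementary <- function(calls, overlap = 0.5) {
  gains <- dplyr::filter(calls, .data$direction == "gain")
  losses <- dplyr::filter(calls, .data$direction == "loss")
  if (nrow(gains) == 0 || nrow(losses) == 0) {
    return(tibble::tibble(chrom = character(), region_type = character(),
                          gain_cell_id = character(), loss_cell_id = character(),
                          reciprocal_overlap = numeric()))
  }
  cross <- dplyr::inner_join(
    dplyr::select(gains, "chrom", gain_cell_id = "cell_id",
                  g_start = "start", g_end = "end", g_scope = "scope"),
    dplyr::select(losses, "chrom", loss_cell_id = "cell_id",
                  l_start = "start", l_end = "end", l_scope = "scope"),
    by = "chrom", relationship = "many-to-many")
  cross |>
    dplyr::filter(.data$gain_cell_id != .data$loss_cell_id) |>
    dplyr::mutate(
      reciprocal_overlap = reciprocal_overlap(.data$g_start, .data$g_end,
                                              .data$l_start, .data$l_end),
      region_type = ifelse(.data$g_scope == "whole" & .data$l_scope == "whole",
                           "whole", "segmental")) |>
    dplyr::filter(.data$reciprocal_overlap >= overlap) |>
    dplyr::select("chrom", "region_type", "gain_cell_id", "loss_cell_id",
                  "reciprocal_overlap") |>
    dplyr::distinct()
}

# Statistic for the permutation null: number of embryos with >= 1 pair.
n_embryos_with_pair <- function(calls, overlap) {
  if (nrow(calls) == 0) return(0L)
  calls |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::group_map(~ nrow(find_complementary(.x, overlap)) > 0) |>
    unlist() |>
    sum()
}

#' Permutation null for the prevalence of complementary cells
#'
#' Tests whether the observed number of embryos harbouring at least one
#' complementary gain/loss pair could arise by chance from the same
#' aberration configuration. Calls are first clustered into distinct
#' aberration events per embryo (a whole-chromosome gain/loss shared by a
#' clone is one event; overlapping segmental calls likewise), because one
#' mitotic error produces every call of its descendant clone -- the event,
#' not the per-cell call, is the exchangeable unit. The null then shuffles
#' the gain/loss labels among events on the same chromosome (across
#' embryos), preserving every embryo's event count and every chromosome's
#' genome-wide gain/loss event totals, and recomputes the statistic. The
#' p-value uses the add-one estimator
#' `(1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param calls Mitotic calls across embryos, with an `embryo_id` column.
#' @param n_perm Number of permutations (warning below 1,000).
#' @param seed Integer seed.
#' @param overlap Reciprocal-overlap threshold for segmental pairs.
#' @return One-row tibble: `observed`, `p_value`, `n_perm`.
#' @export
complementary_null <- function(calls, n_perm = 1000, seed = 1, overlap = 0.5) {
  abort_if(!"embryo_id" %in% names(calls), "calls need an embryo_id column")
  if (nrow(calls) > 0 && dplyr::n_distinct(calls$embryo_id) < 2) {
    rlang::warn(paste("calls from a single embryo: labels can only mix",
                      "within it, so the p-value is conservative"))
  }
  if (n_perm < 1000) rlang::warn("n_perm < 1000 gives a coarse p-value")
  if (nrow(calls) == 0) {
    return(tibble::tibble(observed = 0L, p_value = 1, n_perm = n_perm))
  }
  # one row per (embryo, event): representative interval + carrier cells
  ev <- calls |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::group_modify(function(df, key) {
      labels <- aberration_events(df, overlap)
      df |>
        dplyr::inner_join(labels, by = "cell_id",
                          relationship = "many-to-many") |>
        dplyr::filter(startsWith(.data$event,
                                 paste0(.data$chrom, ":",
                                        .data$direction, ":"))) |>
        dplyr::group_by(.data$event, .data$chrom, .data$direction) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         cells = list(unique(.data$cell_id)),
                         .groups = "drop")
    }) |>
    dplyr::ungroup()
  # candidate event pairs: same embryo + chromosome, overlapping, and not
  # carried by one single shared cell
  emb_chr <- paste(ev$embryo_id, ev$chrom, sep = "\r")
  cand <- list()
  for (idx in split(seq_len(nrow(ev)), emb_chr)) {
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        ci <- ev$cells[[i]]; cj <- ev$cells[[j]]
        if (length(ci) == 1 && length(cj) == 1 && ci == cj) next
        if (reciprocal_overlap(ev$start[i], ev$end[i],
                               ev$start[j], ev$end[j]) >= overlap) {
          cand[[length(cand) + 1L]] <- c(i, j)
        }
      }
    }
  }
  stat_for <- function(dirs) {
    if (length(cand) == 0) return(0L)
    hit <- vapply(cand, function(p) dirs[p[1]] != dirs[p[2]], logical(1))
    length(unique(ev$embryo_id[vapply(cand[hit], `[`, integer(1), 1)]))
  }
  obs <- stat_for(ev$direction)
  chrom_groups <- split(seq_len(nrow(ev)), ev$chrom)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      dirs <- ev$direction
      for (g in chrom_groups) dirs[g] <- dirs[g][sample.int(length(g))]
      stat_for(dirs)
    }, integer(1))
  })
  tibble::tibble(observed = as.integer(obs),
                 p_value = (1 + sum(perm_stats >= obs)) / (1 + n_perm),
                 n_perm = n_perm)
}
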