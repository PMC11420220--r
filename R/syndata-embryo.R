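# Synthetic low-pass scWGS: per-cell binned read counts for a whole embryo,
# coupled to a ground-truth table of every planted aberration.

#' Describe a set of copy-number events
#'
#' Convenience constructor for the event tables used by [embryo_scenario()].
#' `start`/`end` of `NA` means the whole chromosome.
#'
#' @param chrom Chromosome name(s), recycled.
#' @param direction `"gain"` or `"loss"`, recycled.
#' @param start,end Segment bounds in bp (0-based half-open), `NA` for whole
#'   chromosome events.
#' @return A tibble with columns `chrom`, `start`, `end`, `direction`.
#' @export
cnv_events <- function(chrom, direction, start = NA_real_, end = NA_real_) {
  out <- tibble::tibble(chrom = chrom, start = start, end = end,
                        direction = direction)
  abort_if(!all(out$direction %in% c("gain", "loss")),
           "direction must be 'gain' or 'loss'")
  out
}

#' Specify a synthetic embryo
#'
#' An embryo is a mixture of a euploid background, zero or more mitotic
#' clones (cell subsets sharing a truth aberration set), and optional
#' meiotic events carried by every cell. Clone fractions are applied
#' deterministically: clone k receives `round(fraction_k * n_cells)` cells in
#' order, and the remainder stays euploid.
#'
#' @param embryo_id Label for the embryo.
#' @param n_cells Number of cells to simulate.
#' @param meiotic_events Event table ([cnv_events()]) present in all cells.
#' @param clones List of `list(fraction =, events =)` entries; `events` is a
#'   [cnv_events()] tibble.
#' @param complementary_pairs Optional list of `list(chrom =, gain_clone =,
#'   loss_clone =)` declarations; validated against `clones` so the scenario
#'   is self-consistent.
#' @param noise Negative-binomial dispersion of per-bin counts (0 = noiseless
#'   expectation). Models MALBAC/MDA-style amplification overdispersion.
#' @param noise_cv Lognormal coefficient of variation of per-cell dispersion
#'   around `noise` (cell-to-cell amplification variability).
#' @param chaotic_cells Number of cells (taken from the euploid remainder)
#'   whose dispersion is multiplied by `chaotic_factor`; emulates cells with
#'   chaotically amplified genomes that QC must reject.
#' @param chaotic_factor Dispersion multiplier for chaotic cells.
#' @param gc_bias_strength Strength of the multiplicative GC bias curve
#'   (0 = flat).
#' @param mean_reads_per_bin Expected reads per 1 Mb bin for a diploid bin;
#'   ~2000 corresponds to ~0.3x coverage at 1 Mb resolution.
#' @param seed Integer seed; identical scenario + seed gives bit-identical
#'   output.
#' @return An `embryo_scenario` list.
#' @export
embryo_scenario <- function(embryo_id = "E01", n_cells = 30,
                            meiotic_events = NULL, clones = list(),
                            complementary_pairs = NULL,
                            noise = 0.02, noise_cv = 0.3,
                            chaotic_cells = 0, chaotic_factor = 10,
                            gc_bias_strength = 1,
                            mean_reads_per_bin = 2000, seed = 1) {
  abort_if(n_cells < 1, "n_cells must be >= 1")
  fractions <- vapply(clones, function(cl) cl$fraction, numeric(1))
  abort_if(length(fractions) > 0 && sum(fractions) > 1 + 1e-12,
           "clone fractions must sum to <= 1")
  abort_if(noise < 0, "noise (dispersion) must be >= 0")
  for (pr in complementary_pairs %||% list()) {
    gev <- clones[[pr$gain_clone]]$events
    lev <- clones[[pr$loss_clone]]$events
    ok <- any(gev$chrom == pr$chrom & gev$direction == "gain") &&
      any(lev$chrom == pr$chrom & lev$direction == "loss")
    abort_if(!ok, paste0("complementary pair on ", pr$chrom,
                         " does not match opposite-sign events in the named clones"))
  }
  structure(
    list(embryo_id = embryo_id, n_cells = n_cells,
         meiotic_events = meiotic_events %||% cnv_events(character(), character()),
         clones = clones, complementary_pairs = complementary_pairs %||% list(),
         noise = noise, noise_cv = noise_cv,
         chaotic_cells = chaotic_cells, chaotic_factor = chaotic_factor,
         gc_bias_strength = gc_bias_strength,
         mean_reads_per_bin = mean_reads_per_bin, seed = seed),
    class = "embryo_scenario")
}

# Multiplicative GC bias: smooth unimodal curve, quadratic in GC on the log
# scale, rescaled to mean 1 so mean_reads_per_bin keeps its meaning.
gc_bias_curve <- function(gc, strength) {
  if (strength == 0) return(rep(1, length(gc)))
  g <- exp(-strength * ((gc - 0.43) / 0.15)^2)
  g / mean(g)
}

# Deterministic clone membership: cell indices per clone, in declaration
# order; remainder euploid.
clone_assignment <- function(scenario) {
  n <- scenario$n_cells
  sizes <- vapply(scenario$clones, function(cl) round(cl$fraction * n), numeric(1))
  abort_if(sum(sizes) > n, "rounded clone sizes exceed n_cells")
  idx <- integer(n) # 0 = euploid background
  at <- 1L
  for (k in seq_along(sizes)) {
    if (sizes[k] > 0) idx[at:(at + sizes[k] - 1L)] <- k
    at <- at + as.integer(sizes[k])
  }
  idx
}

# Integer copy number per bin for one set of events, starting from cn.
apply_events <- function(cn, genome, events) {
  if (nrow(events) == 0) return(cn)
  for (j in seq_len(nrow(events))) {
    ev <- events[j, ]
    hit <- genome$chrom == ev$chrom
    if (!is.na(ev$start)) hit <- hit & genome$end > ev$start & genome$start < ev$end
    cn[hit] <- cn[hit] + if (ev$direction == "gain") 1L else -1L
  }
  pmax(cn, 0L)
}

#' Simulate binned read counts for all cells of one embryo
#'
#' Expected count in bin b of cell i is proportional to
#' `copy_number(i,b)/2 * gc_curve(gc_b) * mappability_b`, with
#' negative-binomial overdispersion set by the cell's dispersion. With
#' `noise = 0` counts equal their expectation exactly (noise-free profiles
#' for oracle checks).
#'
#' @param genome A [genome_model()] tibble.
#' @param scenario An [embryo_scenario()].
#' @return A list with `profiles` (tibble: `cell_id`, `chrom`, `start`,
#'   `end`, `gc`, `mappability`, `count`), `truth` (tibble of every
#'   non-diploid segment per cell: `cell_id`, `chrom`, `start`, `end`,
#'   `direction`, `origin`, `clone`), and `cells` (tibble: `cell_id`,
#'   `clone`, `dispersion`, `chaotic`).
#' @export
simulate_embryo <- function(genome, scenario) {
  abort_if(!inherits(scenario, "embryo_scenario"), "scenario must be an embryo_scenario")
  abort_if(nrow(genome) == 0, "genome has no bins")
  n <- scenario$n_cells
  cell_ids <- sprintf("%s_c%03d", scenario$embryo_id, seq_len(n))
  assign_ <- clone_assignment(scenario)
  gbias <- gc_bias_curve(genome$gc, scenario$gc_bias_strength)
  base_mu <- scenario$mean_reads_per_bin * gbias * genome$mappability
  lens <- chrom_lengths(genome)

  # per-clone copy-number vectors (clone 0 = euploid background)
  cn_by_clone <- lapply(c(list(NULL), scenario$clones), function(cl) {
    cn <- apply_events(rep(2L, nrow(genome)), genome, scenario$meiotic_events)
    if (!is.null(cl)) cn <- apply_events(cn, genome, cl$events)
    cn
  })

  chaotic <- rep(FALSE, n)
  if (scenario$chaotic_cells > 0) {
    bg <- which(assign_ == 0L)
    abort_if(length(bg) < scenario$chaotic_cells,
             "not enough euploid background cells to mark as chaotic")
    chaotic[utils::tail(bg, scenario$chaotic_cells)] <- TRUE
  }

  sim <- with_seed(scenario$seed, {
    disp <- if (scenario$noise == 0) rep(0, n) else {
      scenario$noise * stats::rlnorm(n, -scenario$noise_cv^2 / 2, scenario$noise_cv)
    }
    disp[chaotic] <- disp[chaotic] * scenario$chaotic_factor
    counts <- lapply(seq_len(n), function(i) {
      mu <- base_mu * cn_by_clone[[assign_[i] + 1L]] / 2
      if (disp[i] == 0) mu else stats::rnbinom(length(mu), mu = mu, size = 1 / disp[i])
    })
    list(disp = disp, counts = counts)
  })

  profiles <- tibble::tibble(
    cell_id = rep(cell_ids, each = nrow(genome)),
    chrom = rep(genome$chrom, n),
    start = rep(genome$start, n),
    end = rep(genome$end, n),
    gc = rep(genome$gc, n),
    mappability = rep(genome$mappability, n),
    count = unlist(sim$counts, use.names = FALSE)
  )

  truth <- purrr::map_dfr(seq_len(n), function(i) {
    evs <- dplyr::bind_rows(
      if (nrow(scenario$meiotic_events) > 0)
        dplyr::mutate(scenario$meiotic_events, origin = "meiotic"),
      if (assign_[i] > 0)
        dplyr::mutate(scenario$clones[[assign_[i]]]$events, origin = "mitotic")
    )
    if (is.null(evs) || nrow(evs) == 0) return(NULL)
    evs$cell_id <- cell_ids[i]
    evs$clone <- assign_[i]
    evs
  })
  if (nrow(truth) > 0) {
    truth <- dplyr::mutate(truth,
      start = ifelse(is.na(start), 0, start),
      end = ifelse(is.na(end), unname(lens[chrom]), end)
    )
    truth <- dplyr::select(truth, "cell_id", "chrom", "start", "end",
                           "direction", "origin", "clone")
  } else {
    truth <- tibble::tibble(cell_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            direction = character(), origin = character(),
                            clone = integer())
  }

  list(profiles = profiles, truth = truth,
       cells = tibble::tibble(cell_id = cell_ids, clone = assign_,
                              dispersion = sim$disp, chaotic = chaotic))
}
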