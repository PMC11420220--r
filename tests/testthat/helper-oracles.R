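# Shared fixtures and independent oracles used across the suite.

tiny_genome <- function(scale = 0.1) genome_model(scale = scale)

# Independent brute-force CNV oracle: threshold each usable bin, take
# maximal same-state runs, report runs with genomic span strictly > min_size
# whose mean log2 ratio lies beyond the matching cutoff.
oracle_calls <- function(corrected_one_cell, loss_cutoff = -0.45,
                         gain_cutoff = 0.35, min_size = 10e6) {
  df <- corrected_one_cell[corrected_one_cell$usable, ]
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    st <- ifelse(sub$log2_ratio > gain_cutoff, 1L,
                 ifelse(sub$log2_ratio < loss_cutoff, -1L, 0L))
    r <- rle(st)
    last <- cumsum(r$lengths)
    first <- last - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L) next
      s <- sub$start[first[k]]
      e <- sub$end[last[k]]
      if ((e - s) <= min_size) next
      m <- mean(sub$log2_ratio[first[k]:last[k]])
      ok <- if (r$values[k] == 1L) m > gain_cutoff else m < loss_cutoff
      if (!ok) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e,
        direction = if (r$values[k] == 1L) "gain" else "loss")
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character()))
  }
  do.call(rbind, out)
}

# Analytic three-Gaussian mixture density and its fine-grid valley minima.
mixture_density <- function(x, modes = c(-1, 0, log2(3 / 2)),
                            sd = 0.08, w = c(0.1, 0.8, 0.1)) {
  w[1] * dnorm(x, modes[1], sd) + w[2] * dnorm(x, modes[2], sd) +
    w[3] * dnorm(x, modes[3], sd)
}

mixture_valleys <- function() {
  grid1 <- seq(-1, 0, by = 1e-4)
  grid2 <- seq(0, log2(3 / 2), by = 1e-4)
  c(loss = grid1[which.min(mixture_density(grid1))],
    gain = grid2[which.min(mixture_density(grid2))])
}

# Exact permutation distribution of the "number of embryos with >= 1
# complementary pair" statistic under per-chromosome direction shuffling,
# by enumerating all orderings of each chromosome's label vector.
exact_perm_tail <- function(calls, overlap = 0.5) {
  chroms <- unique(calls$chrom)
  perms_of <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  label_sets <- lapply(chroms, function(ch) perms_of(calls$direction[calls$chrom == ch]))
  obs <- mosaicscan:::n_embryos_with_pair(calls, overlap)
  idx <- lapply(label_sets, seq_along)
  grid <- expand.grid(idx)
  stats_ <- apply(grid, 1, function(row) {
    shuffled <- calls
    for (k in seq_along(chroms)) {
      shuffled$direction[shuffled$chrom == chroms[k]] <-
        label_sets[[k]][[row[k]]]
    }
    mosaicscan:::n_embryos_with_pair(shuffled, overlap)
  })
  mean(stats_ >= obs)
}

# Minimal corrected-profile tibble built directly from values, bypassing
# simulation, for arithmetic-level checks.
manual_profile <- function(cell_id, chrom, values, bin_size = 1e6) {
  n <- length(values)
  tibble::tibble(
    cell_id = cell_id, chrom = chrom,
    start = (seq_len(n) - 1) * bin_size, end = seq_len(n) * bin_size,
    gc = 0.4, mappability = 1, count = values,
    usable = TRUE, cell_usable = TRUE,
    corrected_count = values, log2_ratio = log2(pmax(values, 2^-8)))
}

# Convenience: simulate, correct and call one scenario end to end.
run_scwgs <- function(genome, scenario, cutoffs = default_cutoffs(), ...) {
  sim <- simulate_embryo(genome, scenario)
  corr <- correct_profile(sim$profiles)
  list(sim = sim, corr = corr, calls = call_cnvs(corr, cutoffs, ...))
}
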