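# Genome model: the binned scaffold every profile lives on.

# hg38-proportional chromosome lengths in Mb (chr1-22 + X). chrY is never
# scored: blastocysts in the motivating design include 46,XX embryos and the
# variability score is defined over 23 chromosomes.
.hg38_mb <- c(
  chr1 = 249, chr2 = 242, chr3 = 198, chr4 = 190, chr5 = 182, chr6 = 171,
  chr7 = 159, chr8 = 145, chr9 = 138, chr10 = 134, chr11 = 135, chr12 = 133,
  chr13 = 114, chr14 = 107, chr15 = 102, chr16 = 90, chr17 = 83, chr18 = 80,
  chr19 = 59, chr20 = 64, chr21 = 47, chr22 = 51, chrX = 156
)

#' Build a binned genome model
#'
#' Tiles 23 scorable chromosomes (chr1-22 + X, lengths proportional to hg38)
#' into fixed-size bins and attaches deterministic per-bin GC and mappability
#' tracks. Coordinates are 0-based half-open (BED convention). The default
#' yields ~3,030 bins of 1 Mb; `scale` shrinks chromosome lengths
#' proportionally for fast experimentation.
#'
#' GC varies smoothly around 0.41 with bin-position waves so that a GC-bias
#' curve applied by the simulator produces a visible, correctable trend.
#' Mappability is high (~0.95-1) with a sparse deterministic set of
#' low-mappability bins that downstream correction must mask.
#'
#' @param bin_size Bin width in bp (default 1e6).
#' @param scale Multiplier on chromosome lengths in (0, 1].
#' @param low_map_every Every k-th bin gets mappability 0.5 (masked by the
#'   default usability floor); set `Inf` to disable.
#' @return A tibble with columns `chrom`, `start`, `end`, `gc`, `mappability`,
#'   plus attribute `chrom_lengths` (named bp vector).
#' @export
genome_model <- function(bin_size = 1e6, scale = 1, low_map_every = 41) {
  stopifnot(bin_size > 0, scale > 0, scale <= 1)
  lens <- pmax(round(.hg38_mb * 1e6 * scale), bin_size)
  bins <- purrr::imap_dfr(lens, function(len, chrom) {
    starts <- seq(0L, len - 1, by = bin_size)
    tibble::tibble(
      chrom = chrom,
      start = as.numeric(starts),
      end = pmin(starts + bin_size, len)
    )
  })
  n <- nrow(bins)
  i <- seq_len(n)
  bins$gc <- 0.41 +
    0.06 * sin(i / 7.3) + 0.035 * sin(i / 2.1) + 0.015 * cos(i / 23.7)
  bins$mappability <- 0.97 + 0.025 * cos(i / 5.1)
  if (is.finite(low_map_every)) {
    bins$mappability[i %% low_map_every == 0L] <- 0.5
  }
  bins$gc <- pmin(pmax(bins$gc, 0.25), 0.62)
  attr(bins, "chrom_lengths") <- lens
  attr(bins, "bin_size") <- bin_size
  class(bins) <- c("genome_model", class(bins))
  bins
}

#' Chromosome lengths of a genome model
#' @param genome A genome model tibble from [genome_model()].
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  cl <- attr(genome, "chrom_lengths")
  if (!is.null(cl)) return(cl)
  tapply(genome$end, genome$chrom, max)[unique(genome$chrom)]
}
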