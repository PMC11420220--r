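# Packaged worked-example scenario.

#' The packaged 33-cell blastocyst scenario
#'
#' A blastocyst of 33 cells with three mitotic clades on a euploid
#' background: 5 cells with a chr14 loss, 3 cells with a chr7 gain and 2
#' cells with a chrX loss (23 cells euploid). Clade-size arithmetic places
#' the chr14 event at the ~8-cell stage: `2^round(log2(33/5)) = 8`.
#'
#' @param seed Integer seed.
#' @param noise Per-bin dispersion (default as in [embryo_scenario()]).
#' @return An [embryo_scenario()].
#' @export
b14_scenario <- function(seed = 14, noise = 0.02) {
  embryo_scenario(
    embryo_id = "B14", n_cells = 33,
    clones = list(
      list(fraction = 5 / 33, events = cnv_events("chr14", "loss")),
      list(fraction = 3 / 33, events = cnv_events("chr7", "gain")),
      list(fraction = 2 / 33, events = cnv_events("chrX", "loss"))
    ),
    noise = noise, seed = seed)
}
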