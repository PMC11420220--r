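# Broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a lineage tree into its clade table
#' @param x A `lineage_tree`.
#' @param ... Unused.
#' @return Tibble of clades with parent links and event sets.
#' @export
tidy.lineage_tree <- function(x, ...) {
  dplyr::mutate(x$nodes,
                events = vapply(x$nodes$events, paste, character(1),
                                collapse = "|"),
                cell_ids = NULL)
}

#' One-row summary of a lineage tree
#' @param x A `lineage_tree`.
#' @param ... Unused.
#' @export
glance.lineage_tree <- function(x, ...) {
  aberrant <- x$nodes$n_cells[x$nodes$label != "euploid" &
                                !startsWith(x$nodes$label, "nondisjunction")]
  tibble::tibble(embryo_id = x$embryo_id, n_cells = x$n_total,
                 n_clades = nrow(x$nodes),
                 n_aberrant_clades = sum(aberrant > 0),
                 earliest_stage = if (nrow(x$events)) min(x$events$stage_cells)
                 else NA_real_)
}

#' Tidy an RNA validation result
#' @param x An `rna_validation`.
#' @param ... Unused.
#' @export
tidy.rna_validation <- function(x, ...) {
  tibble::tibble(
    metric = c("fp_rate", "fn_rate"),
    numerator = c(x$n_called - x$n_called_confirmed,
                  x$n_negative - x$n_negative_confirmed),
    denominator = c(x$n_called, x$n_negative),
    estimate = c(x$fp_rate, x$fn_rate))
}

#' One-row summary of an RNA validation result
#' @param x An `rna_validation`.
#' @param ... Unused.
#' @export
glance.rna_validation <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy an RNA cohort summary
#' @param x An `rna_summary`.
#' @param ... Unused.
#' @return The per-embryo rate table.
#' @export
tidy.rna_summary <- function(x, ...) x$per_embryo

#' One-row summary of an RNA cohort
#' @param x An `rna_summary`.
#' @param ... Unused.
#' @export
glance.rna_summary <- function(x, ...) {
  tibble::tibble(n_embryos = nrow(x$per_embryo),
                 mosaic_embryo_fraction = x$mosaic_embryo_fraction,
                 kruskal_statistic = x$lineage_test$statistic,
                 kruskal_p = x$lineage_test$p_value)
}

#' Plot corrected log2-ratio profiles along the genome
#'
#' One panel per cell, bins coloured by state relative to the cutoffs.
#' @param object A `binned_profile` from [correct_profile()].
#' @param cutoffs Cutoff tibble for the guide lines and colouring.
#' @param cells Optional subset of cell ids to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_profile <- function(object, cutoffs = default_cutoffs(),
                                    cells = NULL, ...) {
  df <- dplyr::filter(object, .data$usable)
  if (!is.null(cells)) df <- dplyr::filter(df, .data$cell_id %in% cells)
  chrs <- unique(object$chrom)
  offs <- c(0, cumsum(tapply(object$end, factor(object$chrom, chrs), max)))
  names(offs) <- c(chrs, "end")
  df$pos <- df$start + offs[df$chrom]
  df$state <- ifelse(df$log2_ratio > cutoffs$gain_cutoff[1], "gain",
                     ifelse(df$log2_ratio < cutoffs$loss_cutoff[1],
                            "loss", "neutral"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$log2_ratio,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::geom_hline(yintercept = c(cutoffs$loss_cutoff[1], 0,
                                       cutoffs$gain_cutoff[1]),
                        linetype = c("dashed", "solid", "dashed"),
                        linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = unname(offs), linewidth = 0.1,
                        colour = "grey70") +
    ggplot2::scale_colour_manual(values = c(gain = "#c0392b",
                                            neutral = "grey40",
                                            loss = "#27ae60")) +
    ggplot2::facet_wrap(~cell_id, ncol = 1) +
    ggplot2::labs(x = "genome position", y = "log2 copy ratio") +
    ggplot2::theme_minimal()
}

#' Plot the batch VS distribution with its exclusion threshold
#' @param qc A filtered QC table ([qc_filter()]).
#' @return A ggplot object.
#' @export
plot_vs_distribution <- function(qc) {
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$vs, fill = .data$passed)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = qc$vs_threshold[1], linetype = "dashed") +
    ggplot2::labs(x = "variability score (median per-chromosome SD)",
                  y = "cells") +
    ggplot2::theme_minimal()
}

#' Plot pooled log2-ratio density with calibrated cutoffs
#' @param values Pooled per-(cell, chromosome) values ([pool_chrom_log2()]).
#' @param cutoffs Cutoff tibble.
#' @return A ggplot object.
#' @export
plot_cutoff_density <- function(values, cutoffs) {
  ggplot2::ggplot(tibble::tibble(x = values), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = c(cutoffs$loss_cutoff[1],
                                       cutoffs$gain_cutoff[1]),
                        linetype = "dashed", colour = "#c0392b") +
    ggplot2::labs(x = "per-(cell, chromosome) mean log2 copy ratio",
                  y = "density") +
    ggplot2::theme_minimal()
}
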