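# Synthetic scRNA-seq with matched DNA truth: expression counts, per-
# chromosome allele aggregates and SNP split-read depths, coupled to a
# per-(cell, chromosome) truth table.

#' Specify a synthetic scRNA-seq cohort
#'
#' Every cell carries a per-chromosome DNA truth (gain / loss / euploid).
#' Truth can be given explicitly (`truth_calls`), as an exact number of
#' aberrant cells (`n_aberrant_cells`, one random whole-chromosome event
#' each), or as per-lineage aneuploidy probabilities (`lineage_rates`).
#'
#' A chromosome gain multiplies resident gene expression by
#' `1 + expr_effect_per_copy` (default 1.5x, the 3/2 dosage ratio) and
#' shifts the oriented allele fraction from 1/2 to 2/3; a loss halves
#' expression and shifts the fraction to 0 (the oriented haplotype is the
#' one lost). `ai_effect_scale` scales these allelic shifts (0 disables).
#'
#' @param n_cells,n_genes Cohort dimensions.
#' @param n_embryos Cells are split evenly across embryos (D8-D14 stages
#'   cycled across embryos).
#' @param truth_calls Optional tibble `cell_index`, `chrom`, `direction`.
#' @param n_aberrant_cells Exact number of aberrant cells when `truth_calls`
#'   is `NULL` (ignored if `lineage_rates` given).
#' @param lineage_rates Optional named probabilities, e.g.
#'   `c(EPI = .025, PE = .05, TE = .08)`.
#' @param lineage_fractions Cell-lineage composition (named, sums to 1).
#' @param expr_effect_per_copy Relative expression change per extra copy
#'   (must be >= 0; gains up, losses down).
#' @param ai_effect_scale Scale on allele-fraction shifts (must be >= 0).
#' @param snp_depth_mean,snp_depth_dispersion Negative-binomial parameters
#'   of per-(cell, chromosome) SNP split-read depth.
#' @param gene_mean_high,frac_high Mean expression of "informative" genes
#'   and their fraction; the remainder have mean `gene_mean_low` and are
#'   intended to fail the median-expression filter.
#' @param gene_mean_low Mean of low-expression genes.
#' @param gene_dispersion Per-gene negative-binomial dispersion.
#' @param libsize_cv Lognormal CV of per-cell library-size factors.
#' @param seed Integer seed.
#' @return An `rna_scenario` list.
#' @export
rna_scenario <- function(n_cells = 280, n_genes = 3000, n_embryos = 10,
                         truth_calls = NULL, n_aberrant_cells = 20,
                         lineage_rates = NULL,
                         lineage_fractions = c(EPI = 0.25, PE = 0.25, TE = 0.5),
                         expr_effect_per_copy = 0.5, ai_effect_scale = 1,
                         snp_depth_mean = 500, snp_depth_dispersion = 0.2,
                         gene_mean_high = 200, frac_high = 0.35,
                         gene_mean_low = 5, gene_dispersion = 0.08,
                         libsize_cv = 0.2, seed = 1) {
  abort_if(expr_effect_per_copy < 0,
           "expr_effect_per_copy must be >= 0 (gains raise expression)")
  abort_if(ai_effect_scale < 0, "ai_effect_scale must be >= 0")
  structure(as.list(environment()), class = "rna_scenario")
}

.rna_chroms <- names(.hg38_mb)

#' Simulate an scRNA-seq cohort with matched DNA truth
#'
#' @param scenario An [rna_scenario()].
#' @return List: `counts` (genes x cells integer matrix), `genes` (tibble
#'   `gene_id`, `chrom`, `base_mean`), `alleles` (tibble `cell_id`, `chrom`,
#'   `a_count`, `b_count`, `snp_split_reads`; `a` is the oriented haplotype
#'   whose dosage rises under gain), `truth` (tibble `cell_id`, `chrom`,
#'   `direction` for non-euploid truth only), `meta` (tibble `cell_id`,
#'   `embryo_id`, `stage`, `lineage`).
#' @export
simulate_rna <- function(scenario) {
  abort_if(!inherits(scenario, "rna_scenario"), "need an rna_scenario")
  s <- scenario
  cell_ids <- sprintf("rna_c%04d", seq_len(s$n_cells))
  chroms <- .rna_chroms
  with_seed(s$seed, {
    # metadata
    embryo <- sprintf("RE%02d", 1 + (seq_len(s$n_cells) - 1) %% s$n_embryos)
    stages <- c("D8", "D10", "D12", "D14")
    stage <- stages[1 + (as.integer(factor(embryo, unique(embryo))) - 1) %%
                      length(stages)]
    lineage <- sample(names(s$lineage_fractions), s$n_cells, replace = TRUE,
                      prob = s$lineage_fractions)
    meta <- tibble::tibble(cell_id = cell_ids, embryo_id = embryo,
                           stage = stage, lineage = lineage)
    # truth
    truth <- if (!is.null(s$truth_calls)) {
      tibble::tibble(cell_id = cell_ids[s$truth_calls$cell_index],
                     chrom = s$truth_calls$chrom,
                     direction = s$truth_calls$direction)
    } else if (!is.null(s$lineage_rates)) {
      hit <- stats::runif(s$n_cells) < s$lineage_rates[lineage]
      tibble::tibble(cell_id = cell_ids[hit],
                     chrom = sample(chroms, sum(hit), replace = TRUE),
                     direction = sample(c("gain", "loss"), sum(hit),
                                        replace = TRUE))
    } else {
      idx <- sample(s$n_cells, s$n_aberrant_cells)
      tibble::tibble(cell_id = cell_ids[idx],
                     chrom = sample(chroms, s$n_aberrant_cells, replace = TRUE),
                     direction = sample(c("gain", "loss"), s$n_aberrant_cells,
                                        replace = TRUE))
    }
    # genes
    gene_chrom <- chroms[1 + (seq_len(s$n_genes) - 1) %% length(chroms)]
    high <- stats::runif(s$n_genes) < s$frac_high
    base <- ifelse(high,
                   s$gene_mean_high * stats::rlnorm(s$n_genes, 0, 0.4),
                   s$gene_mean_low * stats::rlnorm(s$n_genes, 0, 0.6))
    genes <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(s$n_genes)),
                            chrom = gene_chrom, base_mean = base)
    # copy factor per (cell, chrom): 1 + effect*(cn-2)
    cf <- matrix(1, length(chroms), s$n_cells, dimnames = list(chroms, cell_ids))
    if (nrow(truth) > 0) {
      for (i in seq_len(nrow(truth))) {
        cf[truth$chrom[i], truth$cell_id[i]] <-
          1 + s$expr_effect_per_copy *
          (if (truth$direction[i] == "gain") 1 else -1)
      }
    }
    lib <- stats::rlnorm(s$n_cells, -s$libsize_cv^2 / 2, s$libsize_cv)
    mu <- outer(base, lib) * cf[gene_chrom, , drop = FALSE]
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / s$gene_dispersion),
                     nrow = s$n_genes,
                     dimnames = list(genes$gene_id, cell_ids))
    # allele aggregates: oriented fraction h per (cell, chrom)
    h <- matrix(0.5, length(chroms), s$n_cells, dimnames = list(chroms, cell_ids))
    if (nrow(truth) > 0) {
      for (i in seq_len(nrow(truth))) {
        h[truth$chrom[i], truth$cell_id[i]] <-
          if (truth$direction[i] == "gain") 2 / 3 else 0
      }
    }
    p <- 0.5 + s$ai_effect_scale * (h - 0.5)
    depth <- matrix(stats::rnbinom(length(h), mu = s$snp_depth_mean,
                                   size = 1 / s$snp_depth_dispersion),
                    nrow = length(chroms))
    a <- matrix(stats::rbinom(length(h), size = depth, prob = p),
                nrow = length(chroms))
    alleles <- tibble::tibble(
      cell_id = rep(cell_ids, each = length(chroms)),
      chrom = rep(chroms, s$n_cells),
      a_count = as.vector(a),
      b_count = as.vector(depth - a),
      snp_split_reads = as.vector(depth))
    list(counts = counts, genes = genes, alleles = alleles,
         truth = truth, meta = meta)
  })
}
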