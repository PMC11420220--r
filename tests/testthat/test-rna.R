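# RNA-based aneuploidy calling: filters, features, thresholds, validation.

test_that("matrix filters apply the stated rules, cell filter first", {
  # 10 genes x 5 cells with hand-set counts; oracle = direct rule check
  set.seed(1)
  m <- matrix(60L, 10, 5,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:5)))
  m[1, ] <- c(0L, 0L, 0L, 60L, 60L)     # expressed in only 2 cells
  m[2, ] <- c(10L, 10L, 10L, 10L, 10L)  # median 10 <= 50
  m[3, ] <- c(0L, 60L, 60L, 60L, 60L)   # expressed in 4 cells, median 60
  f <- filter_matrix(m, min_genes_per_cell = 5, min_cells = 3,
                     min_median = 50)
  expect_false("g1" %in% rownames(f))
  expect_false("g2" %in% rownames(f))
  expect_true("g3" %in% rownames(f))
  expect_equal(ncol(f), 5)
  # brute-force oracle over all genes
  keep_oracle <- sapply(1:10, function(i) {
    sum(m[i, ] >= 1) >= 3 && median(m[i, ]) > 50
  })
  expect_setequal(rownames(f), rownames(m)[keep_oracle])

  # a cell with exactly min_genes_per_cell expressed genes is removed
  m2 <- matrix(100L, 30, 4,
               dimnames = list(paste0("g", 1:30), paste0("c", 1:4)))
  m2[21:30, 1] <- 0L # cell 1 expresses exactly 20 genes
  f2 <- filter_matrix(m2, min_genes_per_cell = 20, min_cells = 2,
                      min_median = 50)
  expect_false("c1" %in% colnames(f2))
  expect_equal(ncol(f2), 3)
  expect_error(filter_matrix(m2, min_genes_per_cell = 1000), "survive")
})

test_that("an average cell scores zero on both channels and stays euploid", {
  sc <- rna_scenario(n_cells = 60, n_aberrant_cells = 0, seed = 5)
  sim <- simulate_rna(sc)
  f <- build_features(filter_matrix(sim$counts), sim$genes, sim$alleles)
  calls <- call_aneuploidy(f)
  expect_true(all(calls$call[calls$evaluable] == "euploid"))
  expect_true(all(abs(f$z_expr) < 5.6, na.rm = TRUE))
  # z-scores centred: median per chromosome ~ 0
  meds <- tapply(f$z_expr, f$chrom, median)
  expect_true(all(abs(meds) < 0.3))
})

test_that("z-scores are invariant to per-cell library scaling", {
  sc <- rna_scenario(n_cells = 40, n_aberrant_cells = 4, seed = 6)
  sim <- simulate_rna(sc)
  filt <- filter_matrix(sim$counts)
  f1 <- build_features(filt, sim$genes, sim$alleles)
  scaled <- filt
  fac <- rep(c(2L, 5L), length.out = ncol(scaled))
  scaled <- sweep(scaled, 2, fac, "*")
  f2 <- build_features(scaled, sim$genes, sim$alleles)
  expect_equal(f1$z_expr, f2$z_expr, tolerance = 0.02)
})

test_that("the dual-evidence thresholds are applied verbatim", {
  base <- tibble::tibble(cell_id = "c", chrom = "chr1",
                         snp_split_reads = 200L, evaluable = TRUE)
  expect_equal(call_aneuploidy(dplyr::mutate(base, z_expr = 6, z_ai = 0.10))$call,
               "gain")
  expect_equal(call_aneuploidy(dplyr::mutate(base, z_expr = 6, z_ai = 0.01))$call,
               "euploid") # expression alone never calls
  expect_equal(call_aneuploidy(dplyr::mutate(base, z_expr = 2, z_ai = 5))$call,
               "euploid") # imbalance alone never calls
  expect_equal(call_aneuploidy(dplyr::mutate(base, z_expr = -4, z_ai = -2))$call,
               "loss")
  expect_equal(call_aneuploidy(dplyr::mutate(base, z_expr = -4, z_ai = -1))$call,
               "euploid")
  low_snp <- dplyr::mutate(base, z_expr = -4, z_ai = -2,
                           snp_split_reads = 90L, evaluable = FALSE)
  expect_equal(call_aneuploidy(low_snp)$call, "not_evaluable")
  # exactly 100 SNP reads is not evaluable (strict >)
  sc <- rna_scenario(n_cells = 25, n_aberrant_cells = 0, seed = 2)
  sim <- simulate_rna(sc)
  al <- sim$alleles
  al$snp_split_reads[1] <- 100L
  f <- build_features(filter_matrix(sim$counts), sim$genes, al)
  expect_false(f$evaluable[f$cell_id == al$cell_id[1] &
                             f$chrom == al$chrom[1]])
})

test_that("planted trisomies and monosomies are detected at default effects", {
  hits <- total <- 0
  for (s in 1:3) {
    sc <- rna_scenario(n_cells = 280, n_aberrant_cells = 20, seed = 40 + s)
    sim <- simulate_rna(sc)
    f <- build_features(filter_matrix(sim$counts), sim$genes, sim$alleles)
    calls <- call_aneuploidy(f)
    tr <- dplyr::inner_join(calls, sim$truth, by = c("cell_id", "chrom"))
    ev <- tr[tr$evaluable, ]
    hits <- hits + sum(ev$call == ev$direction)
    total <- total + nrow(ev)
  }
  expect_gte(hits / total, 0.9)
})

test_that("validation arithmetic reproduces confusion-count rates", {
  # construct calls/truth giving 27 called (25 confirmed) and 361 negative
  # (353 confirmed euploid)
  calls <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:388),
    chrom = "chr1",
    z_expr = 0, z_ai = 0, snp_split_reads = 200L, evaluable = TRUE,
    call = c(rep("gain", 27), rep("euploid", 361)))
  truth <- tibble::tibble(
    cell_id = c(sprintf("c%03d", 1:25),          # confirm 25 of the calls
                sprintf("c%03d", 28:35)),        # 8 negatives aberrant in DNA
    chrom = "chr1",
    direction = "gain")
  v <- validate_against_dna(calls, truth)
  expect_equal(v$n_called, 27L)
  expect_equal(v$n_called_confirmed, 25L)
  expect_equal(v$n_negative, 361L)
  expect_equal(v$n_negative_confirmed, 353L)
  expect_equal(round(100 * v$fp_rate, 2), 7.41) # 2/27
  expect_equal(round(100 * v$fn_rate, 2), 2.22) # 8/361
  g <- glance(v)
  expect_equal(g$fp_rate, 2 / 27)
  t <- tidy(v)
  expect_equal(t$estimate, c(2 / 27, 8 / 361))
  # perfect agreement and the empty-call edge
  v0 <- validate_against_dna(calls[28:388, ], truth[26:33, ])
  expect_equal(v0$n_called, 0L)
  expect_true(is.na(v0$fp_rate))
})

test_that("cohort summaries recover planted per-lineage rates", {
  sc <- rna_scenario(n_cells = 1500, n_embryos = 15,
                     lineage_rates = c(EPI = 0.025, PE = 0.05, TE = 0.08),
                     lineage_fractions = c(EPI = 1, PE = 1, TE = 1) / 3,
                     seed = 77)
  sim <- simulate_rna(sc)
  f <- build_features(filter_matrix(sim$counts), sim$genes, sim$alleles)
  calls <- call_aneuploidy(f)
  s <- summarize_rna_embryos(calls, sim$meta)
  pl <- s$per_lineage
  truth_rate <- sim$truth |>
    dplyr::distinct(.data$cell_id) |>
    dplyr::inner_join(sim$meta, by = "cell_id") |>
    dplyr::count(.data$lineage)
  for (ln in c("EPI", "PE", "TE")) {
    planted <- truth_rate$n[truth_rate$lineage == ln] /
      pl$n_cells[pl$lineage == ln]
    expect_lt(abs(pl$rate[pl$lineage == ln] - planted), 0.015)
  }
  expect_gt(pl$rate[pl$lineage == "TE"], pl$rate[pl$lineage == "EPI"])
  expect_true(is.finite(s$lineage_test$statistic))
  g <- glance(s)
  expect_true(g$mosaic_embryo_fraction >= 0 && g$mosaic_embryo_fraction <= 1)
})

test_that("aberration-count histogram fractions count aneuploid cells", {
  calls <- purrr::map_dfr(1:100, function(i) {
    n_ab <- if (i <= 87) 1 else 2
    tibble::tibble(cell_id = sprintf("c%03d", i),
                   chrom = paste0("chr", 1:22),
                   z_expr = 0, z_ai = 0, snp_split_reads = 500L,
                   evaluable = TRUE,
                   call = c(rep("gain", n_ab), rep("euploid", 22 - n_ab)))
  })
  meta <- tibble::tibble(cell_id = sprintf("c%03d", 1:100),
                         embryo_id = "E1", stage = "D8", lineage = "TE")
  s <- summarize_rna_embryos(calls, meta)
  h <- s$aberration_histogram
  expect_equal(h$fraction[h$bin == "1"], 0.87)
  expect_equal(h$fraction[h$bin == "2"], 0.13)
})

test_that("zero-effect scenarios yield essentially no false calls", {
  sc <- rna_scenario(n_cells = 250, n_aberrant_cells = 0,
                     expr_effect_per_copy = 0, ai_effect_scale = 0,
                     seed = 123)
  sim <- simulate_rna(sc)
  f <- build_features(filter_matrix(sim$counts), sim$genes, sim$alleles)
  calls <- call_aneuploidy(f)
  ev <- calls[calls$evaluable, ]
  expect_gte(nrow(ev), 5000)
  expect_lt(mean(ev$call != "euploid"), 0.001)
})

test_that("inconsistent effect signs are rejected", {
  expect_error(rna_scenario(expr_effect_per_copy = -0.5), "gains raise")
  expect_error(rna_scenario(ai_effect_scale = -1), ">= 0")
})
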