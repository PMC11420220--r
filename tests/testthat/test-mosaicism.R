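# Meiotic/mitotic classification, embryo summaries, complementary pairs.

mk_call <- function(cell, chrom, dir, start = 0, end = 100e6,
                    scope = "whole") {
  tibble::tibble(cell_id = cell, chrom = chrom, start = start, end = end,
                 direction = dir, size_bp = end - start, scope = scope,
                 mean_log2_ratio = ifelse(dir == "gain", 0.58, -1))
}

test_that("uniform trisomy is flagged meiotic and excluded downstream", {
  cells <- sprintf("c%02d", 1:20)
  calls <- dplyr::bind_rows(
    mk_call(cells, "chr16", "gain"),           # all 20 cells
    mk_call(cells[1:4], "chr7", "loss"))       # mitotic subset
  cls <- classify_meiotic(calls, cells)
  expect_equal(cls$meiotic$chrom, "chr16")
  expect_equal(cls$meiotic$direction, "gain")
  expect_false("chr16" %in% cls$mitotic_calls$chrom)
  expect_true(all(cls$mitotic_calls$chrom == "chr7"))
  s <- summarize_embryo(calls, cells, "B17")
  expect_equal(s$n_meiotic, 1L)
  expect_equal(s$mitotic_rate, 4 / 20)
})

test_that("the 95% meiotic rule is an exact threshold", {
  cells <- sprintf("c%02d", 1:20)
  cls19 <- classify_meiotic(mk_call(cells[1:19], "chr21", "gain"), cells)
  expect_equal(nrow(cls19$meiotic), 1) # 19/20 = 0.95 qualifies
  cls18 <- classify_meiotic(mk_call(cells[1:18], "chr21", "gain"), cells)
  expect_equal(nrow(cls18$meiotic), 0) # 18/20 = 0.90 stays mitotic
  expect_equal(nrow(cls18$mitotic_calls), 18)
  # all-euploid embryo: empty meiotic set
  empty <- classify_meiotic(mk_call(character(), character(), character()),
                            cells)
  expect_equal(nrow(empty$meiotic), 0)
})

test_that("embryo summary counts rates and categories by partition", {
  cells <- sprintf("c%02d", 1:33)
  calls <- dplyr::bind_rows(
    mk_call(cells[1:6], "chr4", "gain"),
    mk_call(cells[7:9], "chr9", "loss"),
    mk_call(cells[10], "chr2", "gain", 0, 15e6, scope = "segmental"),
    mk_call(cells[10], "chr5", "loss"))
  s <- summarize_embryo(calls, cells, "E")
  expect_equal(s$n_aneuploid, 10L)
  expect_equal(s$mitotic_rate, 10 / 33, tolerance = 1e-12)
  expect_equal(s$frac_gain_only, 6 / 33)
  expect_equal(s$frac_loss_only, 3 / 33)
  expect_equal(s$frac_gain_and_loss, 1 / 33) # cell 10 counted once, as both
  expect_equal(s$frac_whole_only + s$frac_seg_only + s$frac_whole_and_seg,
               s$mitotic_rate)
  s0 <- summarize_embryo(mk_call(character(), character(), character()),
                         cells)
  expect_equal(s0$mitotic_rate, 0)
  expect_false(s0$is_mosaic)
  expect_error(summarize_embryo(calls, character()), "zero")
})

test_that("whole-chromosome complementary pairs are detected", {
  calls <- dplyr::bind_rows(mk_call("B02_061", "chr4", "gain"),
                            mk_call("B02_051", "chr4", "loss"))
  p <- find_complementary(calls)
  expect_equal(nrow(p), 1)
  expect_equal(p$gain_cell_id, "B02_061")
  expect_equal(p$loss_cell_id, "B02_051")
  expect_equal(p$region_type, "whole")
  expect_equal(p$reciprocal_overlap, 1)
  # same direction only -> nothing
  same <- dplyr::bind_rows(mk_call("a", "chr4", "gain"),
                           mk_call("b", "chr4", "gain"))
  expect_equal(nrow(find_complementary(same)), 0)
  # opposite directions in the same cell -> not a pair
  self <- dplyr::bind_rows(mk_call("a", "chr4", "gain"),
                           mk_call("a", "chr4", "loss"))
  expect_equal(nrow(find_complementary(self)), 0)
})

test_that("segmental pairs follow the reciprocal-overlap rule", {
  a <- mk_call("A", "chr2", "gain", 10e6, 40e6, scope = "segmental")
  b <- mk_call("B", "chr2", "loss", 20e6, 50e6, scope = "segmental")
  p <- find_complementary(dplyr::bind_rows(a, b))
  expect_equal(nrow(p), 1)
  expect_equal(p$reciprocal_overlap, 20 / 30, tolerance = 1e-12)
  c_ <- mk_call("C", "chr2", "loss", 38e6, 80e6, scope = "segmental")
  expect_equal(nrow(find_complementary(dplyr::bind_rows(a, c_))), 0)
})

test_that("complementary detection is symmetric and relabeling-invariant", {
  a <- mk_call("A", "chr2", "gain", 10e6, 40e6, scope = "segmental")
  b <- mk_call("B", "chr2", "loss", 20e6, 50e6, scope = "segmental")
  p1 <- find_complementary(dplyr::bind_rows(a, b))
  flipped <- dplyr::bind_rows(a, b) |>
    dplyr::mutate(direction = ifelse(.data$direction == "gain",
                                     "loss", "gain"))
  p2 <- find_complementary(flipped)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$reciprocal_overlap, p2$reciprocal_overlap)
  relab <- dplyr::bind_rows(a, b) |>
    dplyr::mutate(cell_id = paste0("x_", .data$cell_id))
  expect_equal(find_complementary(relab)$reciprocal_overlap,
               p1$reciprocal_overlap)
})

test_that("permuting cell order never changes embryo statistics", {
  cells <- sprintf("c%02d", 1:15)
  calls <- dplyr::bind_rows(mk_call(cells[c(2, 5, 9)], "chr3", "gain"),
                            mk_call(cells[11], "chr8", "loss"))
  s1 <- summarize_embryo(calls, cells)
  set.seed(1)
  s2 <- summarize_embryo(calls[sample(nrow(calls)), ], sample(cells))
  expect_equal(s1$mitotic_rate, s2$mitotic_rate)
  expect_equal(s1$frac_gain_only, s2$frac_gain_only)
  expect_equal(s1$n_complementary_pairs, s2$n_complementary_pairs)
})

test_that("permutation p-value is 1 with no opposite-direction calls", {
  calls <- dplyr::bind_rows(mk_call("a", "chr1", "gain"),
                            mk_call("b", "chr2", "gain")) |>
    dplyr::mutate(embryo_id = c("E1", "E2"))
  res <- complementary_null(calls, n_perm = 1000, seed = 1)
  expect_equal(res$observed, 0L)
  expect_equal(res$p_value, 1)
  empty <- calls[0, ]
  expect_equal(complementary_null(empty, n_perm = 1000, seed = 1)$p_value, 1)
  expect_warning(complementary_null(calls, n_perm = 10, seed = 1), "coarse")
})

test_that("permutation p matches exhaustive enumeration on a micro-instance", {
  # 3 embryos, 4 calls on one chromosome: 2 gains + 2 losses
  calls <- dplyr::bind_rows(
    dplyr::mutate(mk_call("e1c1", "chr4", "gain"), embryo_id = "E1"),
    dplyr::mutate(mk_call("e1c2", "chr4", "loss"), embryo_id = "E1"),
    dplyr::mutate(mk_call("e2c1", "chr4", "gain"), embryo_id = "E2"),
    dplyr::mutate(mk_call("e3c1", "chr4", "loss"), embryo_id = "E3"))
  exact <- exact_perm_tail(calls)
  res <- complementary_null(calls, n_perm = 4000, seed = 7)
  expect_equal(res$observed, 1L)
  # add-one estimator vs exact tail probability, within Monte-Carlo error
  mc_se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(res$p_value - exact), 4 * mc_se + 1 / 4000)
})

test_that("engineered complementary cohorts are far beyond chance", {
  # 20 embryos with loss-dominated scattered mitotic calls (losses outnumber
  # gains roughly 3:1 in blastocysts); 14 embryos additionally carry an
  # engineered reciprocal gain/loss pair
  set.seed(42)
  chroms <- paste0("chr", 1:22)
  calls <- purrr::map_dfr(1:20, function(e) {
    eid <- sprintf("E%02d", e)
    df <- mk_call(paste0(eid, "_c", 1:8), sample(chroms, 8),
                  sample(c("gain", "loss"), 8, replace = TRUE,
                         prob = c(0.27, 0.73)))
    if (e <= 14) {
      ch <- sample(chroms, 1)
      df <- dplyr::bind_rows(df, mk_call(paste0(eid, "_p1"), ch, "gain"),
                             mk_call(paste0(eid, "_p2"), ch, "loss"))
    }
    dplyr::mutate(df, embryo_id = eid)
  })
  res <- complementary_null(calls, n_perm = 10000, seed = 3)
  expect_equal(res$observed, 14L)
  expect_lt(res$p_value, 0.001)
})
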