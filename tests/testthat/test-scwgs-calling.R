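# Cutoff calibration and HMM CNV calling against brute-force oracles.

test_that("three-peak mixtures calibrate to the analytic density minima", {
  set.seed(77)
  n <- 3000
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.1, 0.8, 0.1))
  vals <- rnorm(n, c(-1, 0, log2(3 / 2))[comp], 0.08)
  cut <- calibrate_cutoffs(vals)
  expect_equal(cut$calibration_mode, "calibrated")
  truth <- mixture_valleys()
  expect_lt(abs(cut$loss_cutoff - truth["loss"]), 0.07)
  expect_lt(abs(cut$gain_cutoff - truth["gain"]), 0.07)
  expect_lt(cut$loss_cutoff, 0)
  expect_gt(cut$gain_cutoff, 0)
})

test_that("unimodal values fall back to the fixed defaults", {
  set.seed(5)
  cut <- calibrate_cutoffs(rnorm(500, 0, 0.1))
  expect_equal(cut$calibration_mode, "default_fallback")
  expect_equal(cut$loss_cutoff, -0.45)
  expect_equal(cut$gain_cutoff, 0.35)
  expect_error(calibrate_cutoffs(rnorm(50)), "100")
})

test_that("flat euploid profiles yield zero calls", {
  g <- tiny_genome()
  res <- run_scwgs(g, embryo_scenario(n_cells = 3, noise = 0.02, seed = 4))
  expect_equal(nrow(res$calls), 0)
  ks <- karyotype_summary(res$calls, unique(res$corr$cell_id))
  expect_true(all(ks$is_euploid))
})

test_that("a 20-bin gain is called once; an 8-bin gain is below the floor", {
  vals20 <- c(rep(1, 30), rep(1.5, 20), rep(1, 50))
  prof <- manual_profile("c1", "chr1", vals20)
  calls <- call_cnvs(prof)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "gain")
  expect_equal(calls$size_bp, 20e6)
  expect_equal(calls$scope, "segmental")
  expect_equal(calls$start, 30e6)
  expect_equal(calls$mean_log2_ratio, log2(1.5), tolerance = 1e-9)
  # matches the brute-force thresholded-run oracle
  orc <- oracle_calls(prof)
  expect_equal(calls[, c("chrom", "start", "end", "direction")],
               tibble::as_tibble(orc))

  vals8 <- c(rep(1, 30), rep(1.5, 8), rep(1, 62))
  expect_equal(nrow(call_cnvs(manual_profile("c2", "chr1", vals8))), 0)
  # exactly 10 Mb is rejected ("larger than" is strict)
  vals10 <- c(rep(1, 30), rep(1.5, 10), rep(1, 60))
  expect_equal(nrow(call_cnvs(manual_profile("c3", "chr1", vals10))), 0)
  vals11 <- c(rep(1, 30), rep(1.5, 11), rep(1, 59))
  expect_equal(nrow(call_cnvs(manual_profile("c4", "chr1", vals11))), 1)
})

test_that("whole-chromosome scope uses the 0.8 coverage fraction", {
  whole <- manual_profile("w", "chr1", rep(1.5, 100))
  expect_equal(call_cnvs(whole)$scope, "whole")
  part <- manual_profile("p", "chr1", c(rep(1.5, 79), rep(1, 21)))
  expect_equal(call_cnvs(part)$scope, "segmental")
  part2 <- manual_profile("p2", "chr1", c(rep(1.5, 80), rep(1, 20)))
  expect_equal(call_cnvs(part2)$scope, "whole")
})

test_that("caller equals the thresholded-run oracle on random noise-free plants", {
  g <- tiny_genome()
  big_chroms <- c("chr1", "chr2", "chr3", "chr4", "chr5", "chr6", "chr7",
                  "chrX") # > 14 Mb at this scale
  set.seed(1234)
  for (rep_i in 1:60) {
    n_ev <- sample(0:3, 1)
    chs <- sample(big_chroms, n_ev)
    events <- NULL
    if (n_ev > 0) {
      events <- purrr::map_dfr(chs, function(ch) {
        len <- chrom_lengths(g)[[ch]]
        whole <- runif(1) < 0.5
        if (whole) {
          cnv_events(ch, sample(c("gain", "loss"), 1))
        } else {
          nb <- len / 1e6
          w <- sample(11:min(nb, 16), 1)
          s <- sample(0:(nb - w), 1) * 1e6
          cnv_events(ch, sample(c("gain", "loss"), 1), s, s + w * 1e6)
        }
      })
    }
    sc <- embryo_scenario(n_cells = 1, noise = 0, gc_bias_strength = 0,
                          clones = if (is.null(events)) list() else
                            list(list(fraction = 1, events = events)),
                          seed = rep_i)
    corr <- correct_profile(simulate_embryo(g, sc)$profiles)
    calls <- call_cnvs(corr)
    orc <- oracle_calls(corr)
    orc <- orc[order(orc$chrom, orc$start), ]
    calls <- calls[order(calls$chrom, calls$start), ]
    expect_equal(nrow(calls), nrow(orc))
    if (nrow(calls) > 0) {
      expect_equal(calls$chrom, orc$chrom)
      expect_equal(calls$start, orc$start)
      expect_equal(calls$end, orc$end)
      expect_equal(calls$direction, orc$direction)
    }
  }
})

test_that("adding an aberration never decreases the call count", {
  g <- tiny_genome()
  for (s in 1:5) {
    base_sc <- embryo_scenario(n_cells = 1, noise = 0.02, seed = 300 + s)
    n_base <- nrow(run_scwgs(g, base_sc)$calls)
    aug_sc <- embryo_scenario(n_cells = 1, noise = 0.02, seed = 300 + s,
                              clones = list(list(fraction = 1,
                                                 events = cnv_events("chr3", "gain"))))
    n_aug <- nrow(run_scwgs(g, aug_sc)$calls)
    expect_gte(n_aug, n_base)
  }
})

test_that("calls never overlap within a cell and stay inside chromosomes", {
  g <- tiny_genome()
  sc <- embryo_scenario(n_cells = 12, noise = 0.05, clones = list(
    list(fraction = 0.5, events = cnv_events(c("chr1", "chr2"),
                                             c("gain", "loss"))),
    list(fraction = 0.5, events = cnv_events("chr1", "gain", 0, 12e6))),
    seed = 9)
  calls <- run_scwgs(g, sc)$calls
  lens <- chrom_lengths(g)
  expect_true(all(calls$start >= 0 & calls$end <= lens[calls$chrom]))
  by_cc <- split(calls, paste(calls$cell_id, calls$chrom))
  for (grp in by_cc) {
    grp <- grp[order(grp$start), ]
    if (nrow(grp) > 1) {
      expect_true(all(grp$start[-1] >= grp$end[-nrow(grp)]))
    }
  }
})
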