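test_that("threshold calibration follows the interpolated-quantile convention", {
  prof <- tibble::tibble(bin = 1:100, zscore = c(rep(0, 99), 10))
  t99 <- get_threshold(prof, 99)
  expect_equal(t99$value, unname(quantile(prof$zscore, 0.99, type = 7)))
  expect_gt(t99$value, 0)
  expect_lt(t99$value, 10)
  t100 <- get_threshold(prof, 100)
  expect_equal(t100$value, 10)
  expect_error(get_threshold(tibble::tibble(bin = 1:4, zscore = rep(1, 4)), 99),
               "degenerate")
  expect_error(get_threshold(prof, 0), "percentile")
})

test_that("hot-bin calls use a strict inequality at the threshold", {
  prof <- tibble::tibble(bin = 1:6, zscore = c(0, 5, 10, 10, 20, -1))
  expect_equal(call_hotbins(prof, threshold_spec(100)), integer(0))
  expect_message(hb <- call_hotbins(prof, threshold_spec(10)), "threshold")
  expect_equal(hb, 5L)
  # planted exceedances are recovered exactly
  set.seed(4)
  z <- rnorm(200)
  z[c(17, 90, 154)] <- 50
  prof2 <- tibble::tibble(bin = 1:200, zscore = z)
  expect_equal(call_hotbins(prof2, threshold_spec(25)), c(17L, 90L, 154L))
  expect_error(call_hotbins(prof2, threshold_spec(5, score = "rate")), "rate")
})

test_that("hot-bin runs refine to nearest-VIS boundaries", {
  g <- tibble::tibble(chrom = "chrA", length = 5e6)
  p <- partition_genome(g)
  # single hot-bin (1-2 Mb); member VIS at 1.2 and 1.8 Mb, none nearer outside
  vis <- tibble::tibble(chrom = "chrA",
                        pos = c(1.2e6, 1.8e6, 0.5e6, 3.5e6))
  hs <- refine_hotspots(2L, dplyr::arrange(vis, pos), p)
  expect_equal(nrow(hs), 1)
  expect_equal(c(hs$start, hs$end), c(1.2e6, 1.8e6))
  expect_equal(hs$n_vis, 2L)
  # two adjacent hot-bins group into one hot-spot
  hs2 <- refine_hotspots(c(2L, 3L), dplyr::arrange(vis, pos), p)
  expect_equal(nrow(hs2), 1)
  # a gap of one non-hot bin keeps runs separate
  hs3 <- refine_hotspots(c(2L, 4L), dplyr::arrange(vis, pos), p)
  expect_equal(nrow(hs3), 2)
})

test_that("boundary refinement may cross the bin edge to a nearer VIS", {
  g <- tibble::tibble(chrom = "chrA", length = 5e6)
  p <- partition_genome(g)
  # hot-bin (1-2 Mb); the VIS nearest the right edge sits just outside it
  vis <- tibble::tibble(chrom = "chrA", pos = c(1.1e6, 1.5e6, 2.05e6))
  hs <- refine_hotspots(2L, vis, p)
  expect_equal(c(hs$start, hs$end), c(1.1e6, 2.05e6))
  expect_equal(hs$n_vis, 3L)
})

test_that("hot-bin runs without VIS fall back to bin edges with a warning", {
  g <- tibble::tibble(chrom = c("chrA", "chrB"), length = c(3e6, 3e6))
  p <- partition_genome(g)
  vis <- tibble::tibble(chrom = "chrA", pos = c(1.2e6, 1.4e6))
  expect_warning(hs <- refine_hotspots(5L, vis, p), "no VIS")
  expect_equal(hs$chrom, "chrB")
  expect_equal(c(hs$start, hs$end), c(1e6 + 1, 2e6))
})

test_that("hot-spot calls are deterministic under bin-order round trips", {
  fx <- mixed_fixture(seed = 31)
  prof <- add_zscores(bin_counts(fx$vis, fx$partition))
  thr <- threshold_spec(get_threshold(prof, 99)$value)
  hb1 <- call_hotbins(prof, thr)
  set.seed(2)
  perm <- sample(nrow(prof))
  restored <- dplyr::arrange(prof[perm, ], bin)
  hb2 <- call_hotbins(restored, thr)
  expect_identical(hb1, hb2)
  hs1 <- refine_hotspots(hb1, fx$vis, fx$partition)
  hs2 <- refine_hotspots(hb2, fx$vis, fx$partition)
  expect_identical(hs1, hs2)
  expect_true(all(hs1$n_vis >= 1))
})

test_that("planted clusters separate cleanly from uniform background", {
  fx <- mixed_fixture(seed = 77)
  prof <- add_zscores(bin_counts(fx$vis, fx$partition))
  truth_bins <- sort(unique(prof$bin[prof$chrom %in% fx$clusters$chrom &
    prof$start < fx$clusters$center[match(prof$chrom, fx$clusters$chrom)] &
    prof$end >= fx$clusters$center[match(prof$chrom, fx$clusters$chrom)]]))
  bg_max <- max(prof$zscore[!prof$bin %in% truth_bins])
  cl_min <- min(prof$zscore[prof$bin %in% truth_bins])
  expect_gt(cl_min, bg_max) # calibration property: a separating band exists
  mid <- (bg_max + cl_min) / 2
  hb <- call_hotbins(prof, threshold_spec(mid))
  expect_equal(hb, truth_bins) # 100% recall, 0 false hot-bins
})
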