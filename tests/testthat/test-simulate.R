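test_that("subsampling is without replacement, uniform and reproducible", {
  g <- tiny_genome(2, 5e6)
  vis <- generate_synthetic_vis(g, 50, seed = 3)
  full <- subsample_vis(vis, nrow(vis), seed = 1)
  expect_equal(full, vis)
  s1 <- subsample_vis(vis, 10, seed = 7)
  s2 <- subsample_vis(vis, 10, seed = 7)
  s3 <- subsample_vis(vis, 10, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_equal(nrow(dplyr::distinct(s1, chrom, pos)), 10)
  expect_true(all(paste(s1$chrom, s1$pos) %in% paste(vis$chrom, vis$pos)))
  expect_error(subsample_vis(vis, 51), "exceeds")
})

test_that("every record is equally likely to be subsampled", {
  g <- tibble::tibble(chrom = "chr1", length = 1e6)
  toy <- tibble::tibble(chrom = "chr1", pos = (1:10) * 1000)
  draws <- integer(10)
  for (k in 1:10000) {
    s <- subsample_vis(toy, 1, seed = k)
    draws[s$pos / 1000] <- draws[s$pos / 1000] + 1L
  }
  gof <- chisq.test(draws)
  expect_gt(gof$p.value, 0.001)
})

test_that("the synthetic generator plants clusters where asked", {
  g <- tiny_genome(2, 1e7)
  cl <- tibble::tibble(chrom = "chr2", center = 5e6, width = 1e5, n_vis = 20)
  vis <- generate_synthetic_vis(g, 0, cl, seed = 9)
  expect_equal(nrow(vis), 20)
  expect_true(all(vis$chrom == "chr2"))
  expect_true(all(vis$pos >= 5e6 - 5e4 & vis$pos <= 5e6 + 5e4))
  expect_true(all(vis$truth == "cluster1"))
  expect_identical(vis, generate_synthetic_vis(g, 0, cl, seed = 9))
  bad <- tibble::tibble(chrom = "chr1", center = 100, width = 1e4, n_vis = 3)
  expect_error(generate_synthetic_vis(g, 0, bad, seed = 1), "bounds")
  over <- tibble::tibble(chrom = c("chr1", "chr1"), center = c(5e6, 5.02e6),
                         width = c(1e5, 1e5), n_vis = c(3, 3))
  expect_warning(generate_synthetic_vis(g, 0, over, seed = 1), "overlapping")
})

test_that("sparse uniform background rarely produces CIS calls", {
  big <- tibble::tibble(chrom = paste0("chr", 1:3), length = 1e9)
  n_cis <- sapply(1:3, function(s) {
    vis <- generate_synthetic_vis(big, 1000, seed = s)
    nrow(cis_scan(vis))
  })
  expect_true(all(n_cis <= 1)) # ~1 pair in 30 kb expected; triples very rare
})

test_that("all three detectors recover the planted clusters", {
  fx <- mixed_fixture(seed = 19)
  prof <- add_zscores(bin_counts(fx$vis, fx$partition))
  thr <- threshold_spec(get_threshold(prof, 99)$value)
  covers_all <- function(hs) {
    all(sapply(seq_len(nrow(fx$clusters)), function(k)
      any(hs$chrom == fx$clusters$chrom[k] &
            hs$start <= fx$clusters$center[k] &
            hs$end >= fx$clusters$center[k])))
  }
  hs_cis <- cis_scan(fx$vis)
  expect_true(covers_all(hs_cis))
  hs_z <- refine_hotspots(call_hotbins(prof, thr), fx$vis, fx$partition)
  expect_true(covers_all(hs_z))
  fit <- bcp_fit(prof, iterations = 600, seed = 4)
  hs_b <- refine_hotspots(bcp_hotbins(fit, thr), fx$vis, fx$partition,
                          method = "bcp")
  expect_true(covers_all(hs_b))
})

test_that("subsample chromosome proportions track the source proportions", {
  fx <- mixed_fixture(seed = 23, n_background = 1500)
  src_prop <- prop.table(table(fx$vis$chrom))
  reps <- sapply(1:10, function(k) {
    s <- subsample_vis(fx$vis, 400, seed = 100 + k)
    prop.table(table(factor(s$chrom, levels = names(src_prop))))
  })
  env_min <- apply(reps, 1, min); env_max <- apply(reps, 1, max)
  expect_true(all(src_prop >= env_min - 0.05 & src_prop <= env_max + 0.05))
})

test_that("the size-invariance study fills the design grid", {
  fx <- mixed_fixture(seed = 47, n_background = 560,
                      cluster_n = c(50, 45, 45))
  prof <- add_zscores(bin_counts(fx$vis, fx$partition))
  ref <- generate_synthetic_vis(fx$genome, 280, seed = 480)
  thr <- get_threshold(add_zscores(bin_counts(ref, fx$partition)), 99.92)
  study <- size_invariance_study(fx$vis, fx$partition, thr,
                                 sizes = c(200, 300, 450, 650),
                                 replicates = 3,
                                 methods = c("cis", "zthreshold", "bcp"),
                                 seed = 5, bcp_iterations = 150)
  expect_equal(nrow(study$results), 4 * 3 * 3)
  bcp200 <- dplyr::filter(study$results, method == "bcp", size == 200)
  expect_true(all(!bcp200$applicable)) # below the 300-VIS rule
  expect_true(all(is.na(bcp200$pct_vis_in_hotspots)))
  expect_equal(sort(unique(study$spearman$method)),
               c("bcp", "cis", "zthreshold"))
  expect_true(all(study$results$pct_vis_in_hotspots >= 0 |
                    is.na(study$results$pct_vis_in_hotspots)))
  # reproducibility of the full study under the master seed
  study2 <- size_invariance_study(fx$vis, fx$partition, thr,
                                  sizes = c(200, 300, 450, 650),
                                  replicates = 3,
                                  methods = c("cis", "zthreshold", "bcp"),
                                  seed = 5, bcp_iterations = 150)
  expect_identical(study$results, study2$results)
})
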