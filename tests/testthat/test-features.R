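hs1 <- tibble::tibble(chrom = "chr1", start = 1000001, end = 1500001,
                      n_vis = 5L, pct_vis = 1, size_mb = 0.5,
                      pct_density = 2, method = "bcp")

test_that("feature densities count any-overlap features once per hot-spot", {
  track <- tibble::tibble(chrom = "chr1",
                          start = c(1.1e6, 1.2e6), end = c(1.11e6, 1.21e6),
                          name = c("g1", "g2"))
  fd <- feature_density(hs1, track)
  expect_equal(fd$feature_density, 4) # 2 features / 0.5 Mb
  # straddling features count once (checked against direct intersection)
  straddle <- tibble::tibble(chrom = "chr1", start = c(9e5, 1.49e6),
                             end = c(1.05e6, 1.6e6), name = c("a", "b"))
  fd2 <- feature_density(hs1, straddle)
  manual <- sum(straddle$end + 1 > hs1$start & straddle$start < hs1$end)
  expect_equal(fd2$n_features, manual)
  empty <- track[0, ]
  expect_equal(feature_density(hs1, empty)$feature_density, 0)
})

test_that("genome density profile and median match a sort-based oracle", {
  g <- tibble::tibble(chrom = "chrA", length = 1e7)
  p <- partition_genome(g) # 10 bins
  uniform <- tibble::tibble(chrom = "chrA", start = (0:9) * 1e6 + 100,
                            end = (0:9) * 1e6 + 200,
                            name = paste0("f", 1:10))
  gd <- genome_density_profile(uniform, p)
  expect_equal(gd$median, 1)
  half <- uniform[1:5, ]
  half2 <- dplyr::bind_rows(half, dplyr::mutate(half, start = start + 300,
                                                end = end + 300,
                                                name = paste0(name, "b")))
  gd2 <- genome_density_profile(half2, p)
  expect_equal(gd2$median, 1) # densities 2,2,2,2,2,0,0,0,0,0
  set.seed(6)
  rnd <- tibble::tibble(chrom = "chrA",
                        start = sort(sample(0:(1e7 - 200), 40)))
  rnd$end <- rnd$start + 150
  rnd$name <- paste0("r", 1:40)
  gd3 <- genome_density_profile(rnd, p)
  counts <- sapply(1:10, function(k)
    sum(rnd$end + 1 > p$start[k] + 1 & rnd$start < p$end[k]))
  expect_equal(gd3$per_bin$n_features, as.integer(counts))
  expect_equal(gd3$median, sort(counts)[5:6] |> mean())
})

test_that("rank-sum comparison to the genome behaves under null and extremes", {
  set.seed(17)
  genome_d <- rpois(200, 5)
  null_p <- replicate(25, {
    compare_to_genome(sample(genome_d, 6), genome_d)$wilcoxon_p
  })
  expect_gt(median(null_p), 0.2)
  # all hot-spot densities above the genome maximum: hand rank arithmetic
  # (tie-free values so the plain normal-approximation variance applies)
  gsub <- seq_len(20) + 0.5
  hot <- max(gsub) + (1:5)
  res <- compare_to_genome(hot, gsub)
  mu <- 5 * 20 / 2
  sg <- sqrt(5 * 20 * 26 / 12)
  p_hand <- 2 * (1 - pnorm((100 - mu - 0.5) / sg))
  expect_equal(res$wilcoxon_p, p_hand, tolerance = 1e-10)
  expect_lt(res$wilcoxon_p, 0.001)
  # single hot-spot still runs, flagged low power
  one <- compare_to_genome(3, genome_d)
  expect_true(one$low_power)
  expect_gt(one$wilcoxon_p, 0.001)
  # scale invariance of the rank test
  a <- c(1.2, 3.4, 5.6, 2.2); b <- rpois(50, 3) + 0.5
  expect_equal(compare_to_genome(a, b)$wilcoxon_p,
               compare_to_genome(10 * a, 10 * b)$wilcoxon_p)
})

test_that("cancer-gene percentages control for hot-spot gene counts", {
  res <- cancer_gene_pct(paste0("g", 1:7), "g3",
                         genome_genes = paste0("g", 1:100))
  expect_equal(res$pct_cancer, 100 / 7, tolerance = 1e-9)
  expect_equal(res$n_cancer, 1L)
  expect_gt(res$fisher_p, 0.05) # 1 of 7 is not significant
  res0 <- cancer_gene_pct(paste0("g", 1:10), character(0), paste0("g", 1:100))
  expect_equal(res0$pct_cancer, 0)
  none <- cancer_gene_pct(character(0), "g1", paste0("g", 1:100))
  expect_true(is.na(none$pct_cancer))
})

test_that("random hot-spot gene draws give calibrated enrichment p-values", {
  set.seed(41)
  genome_genes <- paste0("g", 1:200)
  cancer <- paste0("g", 1:20) # known 10% cancer fraction
  ps <- replicate(200, {
    cancer_gene_pct(sample(genome_genes, 15), cancer, genome_genes)$fisher_p
  })
  expect_lt(mean(ps < 0.05), 0.07) # conservative under the null
})

test_that("hot-spot genes are retrieved by overlap", {
  track <- tibble::tibble(chrom = "chr1",
                          start = c(9e5, 1.2e6, 3e6),
                          end = c(1.05e6, 1.3e6, 3.1e6),
                          name = c("EVI1", "MDS1", "FAR"))
  expect_setequal(hotspot_genes(hs1, track), c("EVI1", "MDS1"))
})
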