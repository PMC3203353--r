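test_that("constant signals give flat posterior means and prior-level changes", {
  fit <- bcp_fit(rep(2, 30), iterations = 400, seed = 1)
  expect_true(all(fit$profile$post_mean == fit$profile$post_mean[1]))
  expect_equal(fit$profile$post_mean[1], 2)
  expect_true(all(fit$boundaries$change_prob < 0.2)) # below the p0 cap
  expect_equal(bcp_hotbins(fit, threshold_spec(10)), integer(0))
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  set.seed(99)
  z <- rnorm(80)
  f1 <- bcp_fit(z, iterations = 500, seed = 42)
  f2 <- bcp_fit(z, iterations = 500, seed = 42)
  expect_identical(f1$profile$post_mean, f2$profile$post_mean)
  expect_identical(f1$boundaries$change_prob, f2$boundaries$change_prob)
  f3 <- bcp_fit(z, iterations = 500, seed = 43)
  expect_false(identical(f1$profile$post_mean, f3$profile$post_mean))
})

test_that("posterior means shrink within the data range", {
  set.seed(5)
  z <- c(rnorm(40), rnorm(10, 8), rnorm(30, -3))
  fit <- bcp_fit(z, iterations = 800, seed = 2)
  expect_true(all(fit$profile$post_mean >= min(z) - 1e-9))
  expect_true(all(fit$profile$post_mean <= max(z) + 1e-9))
  expect_true(all(fit$boundaries$change_prob >= 0 &
                    fit$boundaries$change_prob <= 1))
})

test_that("p0 -> 0 degenerates to a single block at the overall mean", {
  set.seed(8)
  z <- rnorm(50, sd = 3)
  fit <- bcp_fit(z, iterations = 300, p0 = 1e-10, seed = 1)
  expect_equal(fit$profile$post_mean, rep(mean(z), 50), tolerance = 1e-12)
})

test_that("planted steps are recovered: hot-bins and change-point locations", {
  set.seed(12)
  z <- rnorm(120)
  z[61:66] <- 40 + rnorm(6)
  fit <- bcp_fit(z, iterations = 2000, seed = 6)
  expect_equal(bcp_hotbins(fit, threshold_spec(20)), 61:66)
  # the two step boundaries are the argmax change probabilities
  top2 <- order(fit$boundaries$change_prob, decreasing = TRUE)[1:2]
  expect_setequal(top2, c(60, 66))
  expect_true(all(fit$boundaries$change_prob[c(60, 66)] > 0.9))
})

test_that("posterior agrees with exact partition enumeration on small signals", {
  set.seed(14)
  x <- c(rnorm(5, 0, 0.5), rnorm(4, 6, 0.5), rnorm(5, 1, 0.5))
  exact <- oracle_bcp(x)
  seeds <- 1:10
  fits <- lapply(seeds, function(s) bcp_fit(x, iterations = 3000, seed = s))
  P <- sapply(fits, function(f) f$boundaries$change_prob)
  M <- sapply(fits, function(f) f$profile$post_mean)
  p_hat <- rowMeans(P); p_se <- apply(P, 1, sd) / sqrt(length(seeds))
  m_hat <- rowMeans(M); m_se <- apply(M, 1, sd) / sqrt(length(seeds))
  expect_true(all(abs(p_hat - exact$change_prob) <= 3 * p_se + 1e-3))
  expect_true(all(abs(m_hat - exact$post_mean) <= 3 * m_se + 1e-3))
})

test_that("convergence report flags stability across seeds", {
  rep_const <- check_convergence(rep(1.5, 20), iterations = 200, n_seeds = 3,
                                 threshold = threshold_spec(5))
  expect_true(all(rep_const$per_bin$range == 0))
  expect_equal(rep_const$inconsistent_bins, integer(0))

  set.seed(20)
  z <- rnorm(100)
  z[41:45] <- 60
  rep_step <- check_convergence(z, iterations = 1500, n_seeds = 5,
                                threshold = threshold_spec(30))
  expect_equal(rep_step$inconsistent_bins, integer(0))
  expect_true(all(rep_step$per_bin$n_seeds_hot[41:45] == 5))
  # low-signal bins vary more across short runs than high-signal bins
  short <- check_convergence(z, iterations = 60, n_seeds = 4,
                             threshold = threshold_spec(30))
  hot <- 41:45
  expect_gt(median(short$per_bin$range[-hot]) + 1e-12,
            0) # background ranges exist
  expect_lt(mean(short$per_bin$range[hot] / abs(short$per_bin$mean[hot])),
            mean(short$per_bin$range[-hot] / pmax(abs(short$per_bin$mean[-hot]), 0.1)))
})

test_that("method selection rules route datasets correctly", {
  expect_equal(as.character(select_method(922, 0.936)), "bcp")
  expect_equal(as.character(select_method(250, 0.95)), "zthreshold")
  expect_equal(as.character(select_method(384, 0.999)), "zthreshold")
  expect_equal(as.character(select_method(300, 0.5)), "bcp")
  expect_error(select_method(100, 0.5), "100 VIS")
})

test_that("tidy and glance expose the fit as tibbles", {
  set.seed(2)
  fit <- bcp_fit(rnorm(30), iterations = 200, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("zscore", "post_mean", "change_prob") %in% names(td)))
  expect_equal(nrow(td), 30)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$cluster_score, 1 - fit$p_bar)
  expect_equal(gl$iterations, 200L)
})
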