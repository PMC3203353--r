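#' Fit the Bayesian change-point model to bin z-scores
#'
#' Runs a Gibbs sampler for the Barry-Hartigan product-partition Gaussian
#' model on the z-scores of the strung-together genome: the bin sequence is
#' partitioned into contiguous blocks of constant mean, with uniform priors
#' on the block-boundary probability (up to `p0`) and on the ratio of error
#' variance to total variance (up to `w0`). Chromosome boundaries are not
#' forced change-points; the whole genome is modelled as one sequence so
#' that density context is shared across chromosomes. Each sweep updates
#' every internal boundary indicator from its exact conditional odds
#' (one-dimensional integrals over the two priors, in incomplete-beta form);
#' after burn-in the per-sweep block means (shrunk toward the genome mean by
#' the conditional posterior mean of the variance ratio) are averaged into
#' posterior bin means, and boundary indicators into change probabilities.
#'
#' @param profile Bin profile with a `zscore` column (see [add_zscores()]),
#'   or a bare numeric vector of scores.
#' @param iterations Post-burn-in Gibbs sweeps (default 10000; the model's
#'   conventional default of 500 is raised for convergence — estimates of
#'   hot-bin posterior means stabilise to within ~0.007 SD by 5000 sweeps).
#' @param burnin Discarded initial sweeps (default 50).
#' @param p0 Prior cap on the change probability, in (0, 1] (default 0.2).
#' @param w0 Prior cap on the variance ratio, in (0, 1] (default 0.2).
#' @param seed Integer seed; same seed and configuration give bit-identical
#'   results.
#' @return An object of class `bcp_fit`: a list with `profile` (the input
#'   augmented with `post_mean` and, per internal boundary, `change_prob`
#'   in a separate tibble `boundaries`), `p_bar` (mean change probability),
#'   `mean_blocks`, `mean_w`, and `config`.
#' @export
bcp_fit <- function(profile, iterations = 10000, burnin = 50,
                    p0 = 0.2, w0 = 0.2, seed = 1) {
  if (is.numeric(profile) && is.null(dim(profile))) {
    k <- seq_along(profile)
    profile <- tibble::tibble(bin = k, chrom = "seq", start = k - 1, end = k,
                              count = NA_integer_,
                              zscore = as.numeric(profile))
  }
  if (!"zscore" %in% names(profile)) abort("profile lacks a 'zscore' column")
  z <- profile$zscore
  if (length(z) < 3) abort("need at least 3 bins")
  if (any(!is.finite(z))) abort("non-finite z-scores")
  if (iterations < 1) abort("iterations must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  raw <- bcp_gibbs(z, as.integer(iterations), as.integer(burnin), p0, w0)
  prof <- dplyr::mutate(profile, post_mean = raw$post_mean)
  for (a in c("bin_size", "shift", "chrom_sizes", "n_vis"))
    attr(prof, a) <- attr(profile, a)
  boundaries <- tibble::tibble(after_bin = profile$bin[-length(z)],
                               change_prob = raw$change_prob)
  structure(list(
    profile = prof,
    boundaries = boundaries,
    p_bar = mean(raw$change_prob),
    mean_blocks = raw$mean_blocks,
    mean_w = raw$mean_w,
    config = list(iterations = as.integer(iterations),
                  burnin = as.integer(burnin), p0 = p0, w0 = w0,
                  seed = as.integer(seed))
  ), class = "bcp_fit")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.bcp_fit <- function(x, ...) {
  cat(sprintf(paste0("<bcp_fit> %d bins, %d sweeps (burn-in %d), ",
                     "p0=%g w0=%g seed=%d\n"),
              nrow(x$profile), x$config$iterations, x$config$burnin,
              x$config$p0, x$config$w0, x$config$seed))
  cat(sprintf("  mean change probability: %.4f (1 - P_bar = %.4f)\n",
              x$p_bar, 1 - x$p_bar))
  cat(sprintf("  mean blocks: %.1f  mean variance ratio: %.4f\n",
              x$mean_blocks, x$mean_w))
  invisible(x)
}

#' @rdname bcp_fit
#' @param x A `bcp_fit` object.
#' @param ... Unused.
#' @export
tidy.bcp_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$profile)
  out$change_prob <- c(x$boundaries$change_prob, NA_real_)
  out
}

#' @rdname bcp_fit
#' @export
glance.bcp_fit <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$profile), p_bar = x$p_bar,
                 cluster_score = 1 - x$p_bar, mean_blocks = x$mean_blocks,
                 mean_w = x$mean_w, iterations = x$config$iterations,
                 burnin = x$config$burnin, p0 = x$config$p0,
                 w0 = x$config$w0, seed = x$config$seed)
}

#' Call hot-bins from a BCP fit
#'
#' Applies the same threshold used for z-scores to the posterior bin means.
#'
#' @param fit A `bcp_fit`.
#' @param threshold A `threshold_spec` or bare number (default 422).
#' @return Sorted hot-bin indices; refine with [refine_hotspots()].
#' @export
bcp_hotbins <- function(fit, threshold = threshold_spec()) {
  stopifnot(inherits(fit, "bcp_fit"))
  call_hotbins(fit$profile, threshold, score = "post_mean")
}

#' Assess convergence of the BCP sampler across seeds
#'
#' Re-runs [bcp_fit()] under `n_seeds` different seeds and summarises, per
#' bin, the range and standard deviation of the posterior means, and whether
#' the hot-bin call (posterior mean above `threshold`) is consistent across
#' seeds. Runs are considered converged at the published stability level
#' when hot-bin posterior means have SD at most 0.007; otherwise at least
#' 5000 sweeps are recommended.
#'
#' @inheritParams bcp_fit
#' @param n_seeds Number of differently seeded runs (>= 2, default 5).
#' @param threshold Hot-bin threshold applied to the posterior means.
#' @return A list with `per_bin` (tibble: bin, mean/min/max/sd of posterior
#'   means, hot-bin call consistency), `inconsistent_bins`,
#'   `max_sd_hotbins`, and `recommendation`.
#' @export
check_convergence <- function(profile, iterations = 10000, burnin = 50,
                              p0 = 0.2, w0 = 0.2, seed = 1, n_seeds = 5,
                              threshold = threshold_spec()) {
  if (n_seeds < 2) abort("n_seeds must be >= 2")
  if (!inherits(threshold, "threshold_spec")) threshold <- threshold_spec(threshold)
  fits <- purrr::map(seq_len(n_seeds) - 1L, function(k)
    bcp_fit(profile, iterations, burnin, p0, w0, seed = seed + k))
  mu <- do.call(cbind, purrr::map(fits, ~ .x$profile$post_mean))
  hot <- mu > threshold$value
  per_bin <- tibble::tibble(
    bin = fits[[1]]$profile$bin,
    mean = rowMeans(mu),
    min = apply(mu, 1, min),
    max = apply(mu, 1, max),
    range = apply(mu, 1, function(v) diff(range(v))),
    sd = apply(mu, 1, sd),
    n_seeds_hot = rowSums(hot),
    consistent = rowSums(hot) %in% c(0L, n_seeds)
  )
  inconsistent <- per_bin$bin[!per_bin$consistent]
  hot_any <- per_bin$n_seeds_hot > 0
  max_sd_hot <- if (any(hot_any)) max(per_bin$sd[hot_any]) else 0
  rec <- if (length(inconsistent) > 0 || max_sd_hot > 0.007)
    "increase run length to at least 5000 iterations" else
    "converged at the current run length"
  list(per_bin = per_bin, inconsistent_bins = inconsistent,
       max_sd_hotbins = max_sd_hot, recommendation = rec,
       n_seeds = n_seeds, iterations = iterations)
}

#' Choose the hot-spot method for a dataset
#'
#' Encodes the method-selection rules for genome-wide hot-spot analysis:
#' the BCP method is used for datasets with at least 300 VIS unless the
#' dataset is highly clustered (cluster score `1 - P_bar` above 0.98), in
#' which case the z-threshold method is used; datasets with 101-300 VIS are
#' analysed by the z-threshold method; datasets with at most 100 VIS are
#' refused, as no rule is defined for them.
#'
#' @param n_vis Number of VIS in the dataset.
#' @param cluster_score `1 - P_bar` from a completed BCP run (see
#'   [cluster_metrics()]).
#' @return `"bcp"` or `"zthreshold"`, with attribute `"reason"`.
#' @export
select_method <- function(n_vis, cluster_score) {
  if (n_vis <= 100)
    abort(paste0("no hot-spot rule is defined for datasets with <= 100 VIS (",
                 n_vis, " given); collect more VIS or analyse descriptively"))
  if (n_vis < 300)
    return(structure("zthreshold",
                     reason = "dataset in (100, 300] VIS: z-threshold rule"))
  if (cluster_score > 0.98)
    return(structure("zthreshold",
                     reason = "highly clustered (1 - P_bar > 0.98): z-threshold rule"))
  structure("bcp", reason = ">= 300 VIS and not highly clustered: BCP rule")
}
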