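#' Generate a synthetic VIS dataset
#'
#' Draws `n_background` insertion positions uniformly over the genome
#' (chromosomes weighted by length) plus, for each planted cluster, `n_vis`
#' positions uniform within a window of the given width centred at `center`.
#' Ground-truth labels (`"background"` or `"cluster<k>"`) are kept in a
#' `truth` column so detector recall and false-positive rates can be
#' measured. Overlapping cluster definitions are allowed but flagged.
#'
#' @param chrom_sizes Chromosome-sizes tibble.
#' @param n_background Number of uniform background VIS.
#' @param clusters Tibble (or data.frame) with columns `chrom`, `center`,
#'   `width`, `n_vis`; `NULL` for pure background.
#' @param seed Integer seed; fixed seed gives a bit-identical dataset.
#' @return Sorted VIS tibble with columns `chrom`, `pos`, `truth`.
#' @export
generate_synthetic_vis <- function(chrom_sizes, n_background,
                                   clusters = NULL, seed = 1) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  parts <- list()
  if (n_background > 0) {
    w <- chrom_sizes$length / sum(chrom_sizes$length)
    ch <- sample(chrom_sizes$chrom, n_background, replace = TRUE, prob = w)
    len <- chrom_sizes$length[match(ch, chrom_sizes$chrom)]
    pos <- floor(stats::runif(n_background) * len) + 1
    parts$bg <- tibble::tibble(chrom = ch, pos = pmin(pos, len),
                               truth = "background")
  }
  if (!is.null(clusters) && nrow(clusters) > 0) {
    cl <- tibble::as_tibble(clusters)
    lo <- cl$center - cl$width / 2
    hi <- cl$center + cl$width / 2
    len <- chrom_sizes$length[match(cl$chrom, chrom_sizes$chrom)]
    if (any(is.na(len)) || any(lo < 1) || any(hi > len))
      abort("cluster window outside chromosome bounds")
    iv <- GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(lo, hi))
    if (any(GenomicRanges::countOverlaps(iv, iv) > 1))
      warn("overlapping cluster definitions")
    parts$cl <- dplyr::bind_rows(purrr::imap(
      split(cl, seq_len(nrow(cl))), function(row, k) {
        p <- floor(stats::runif(row$n_vis, row$center - row$width / 2,
                                row$center + row$width / 2)) + 1
        tibble::tibble(chrom = row$chrom, pos = p,
                       truth = paste0("cluster", k))
      }))
  }
  vis <- dplyr::bind_rows(parts)
  if (nrow(vis) == 0) abort("empty synthetic dataset requested")
  suppressWarnings(validate_vis(vis, chrom_sizes, source = "synthetic",
                                name = "synthetic"))
}

#' Subsample a VIS dataset without replacement
#'
#' Uniform sampling without replacement (no VIS sampled more than once),
#' used to build simulated datasets of a given size from a source dataset.
#'
#' @param vis Source VIS tibble.
#' @param size Number of VIS to draw (`<= nrow(vis)`).
#' @param seed Integer seed; fixed seed gives an identical sample.
#' @return Sorted VIS tibble of `size` rows.
#' @export
subsample_vis <- function(vis, size, seed = 1) {
  if (size > nrow(vis)) abort("subsample size exceeds dataset size")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  keep <- sort(sample.int(nrow(vis), size))
  vis[keep, , drop = FALSE]
}

#' Size-invariance study of hot-spot detection
#'
#' Reproduces the subsampling experiment that motivates binned hot-spot
#' definitions: from a source dataset, draw `replicates` subsamples without
#' replacement at each size, run each detection method, and record the
#' percentage of VIS falling in hot-spots. Per method, the median percentage
#' at each size is tested for a monotone relationship with size by a
#' Spearman correlation test; a size-invariant method should show no
#' significant trend while the CIS density rule shows a strong positive one.
#'
#' BCP cells for sizes below 300 VIS are marked inapplicable per the
#' method-selection rules.
#'
#' @param vis Source VIS tibble.
#' @param partition Bin tibble for the z-threshold/BCP methods.
#' @param threshold `threshold_spec` applied to z-scores and BCP posterior
#'   means (calibrate with [get_threshold()] on an acute-style reference).
#' @param sizes Subsample sizes (default the canonical 200-2000 grid).
#' @param replicates Subsamples per size (default 10).
#' @param methods Subset of `c("cis", "zthreshold", "bcp")`.
#' @param seed Master seed; per-(size, replicate) streams are derived from
#'   it, so studies are reproducible cell by cell.
#' @param bcp_iterations Gibbs sweeps for BCP runs inside the study.
#' @param cis_rule_set CIS rules for the `"cis"` method.
#' @return List with `results` (tibble: method, size, replicate,
#'   pct_vis_in_hotspots, n_hotspots) and `spearman` (tibble per method:
#'   rho and p-value over the per-size medians).
#' @export
size_invariance_study <- function(vis, partition, threshold,
                                  sizes = c(200, 300, 400, 500, 600, 800,
                                            1000, 1200, 1400, 1600, 1800, 2000),
                                  replicates = 10,
                                  methods = c("cis", "zthreshold", "bcp"),
                                  seed = 1, bcp_iterations = 600,
                                  cis_rule_set = cis_rules()) {
  if (max(sizes) > nrow(vis)) abort("max(sizes) exceeds the source dataset")
  if (replicates < 2) abort("need at least 2 replicates")
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- tidyr::expand_grid(size = sizes, replicate = seq_len(replicates))
  cells <- purrr::pmap(grid, function(size, replicate) {
    cell_seed <- (seed * 1000L + size %/% 10L + replicate * 7919L) %% 2147483647L
    sub <- subsample_vis(vis, size, seed = cell_seed)
    prof <- add_zscores(bin_counts(sub, partition))
    purrr::map(setNames(methods, methods), function(m) {
      if (m == "cis") {
        hs <- cis_scan(sub, cis_rule_set)
      } else if (m == "zthreshold") {
        hb <- call_hotbins(prof, threshold, score = "zscore")
        hs <- suppressWarnings(refine_hotspots(hb, sub, partition))
      } else {
        if (size < 300)
          return(tibble::tibble(size = size, replicate = replicate,
                                method = m, pct_vis_in_hotspots = NA_real_,
                                n_hotspots = NA_integer_,
                                applicable = FALSE))
        fit <- bcp_fit(prof, iterations = bcp_iterations, seed = cell_seed)
        hb <- bcp_hotbins(fit, threshold)
        hs <- suppressWarnings(refine_hotspots(hb, sub, partition,
                                               method = "bcp"))
      }
      tibble::tibble(size = size, replicate = replicate, method = m,
                     pct_vis_in_hotspots = sum(hs$pct_vis),
                     n_hotspots = nrow(hs), applicable = TRUE)
    })
  })
  results <- dplyr::bind_rows(purrr::flatten(cells))
  medians <- results |>
    dplyr::filter(.data$applicable) |>
    dplyr::group_by(.data$method, .data$size) |>
    dplyr::summarise(median_pct = median(.data$pct_vis_in_hotspots),
                     .groups = "drop")
  spearman <- medians |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(test = list(suppressWarnings(
      cor.test(.data$size, .data$median_pct, method = "spearman"))),
      .groups = "drop") |>
    dplyr::mutate(rho = purrr::map_dbl(.data$test, ~ unname(.x$estimate)),
                  p_value = purrr::map_dbl(.data$test, "p.value"),
                  significant = .data$p_value < 0.05) |>
    dplyr::select(-"test")
  list(results = results, medians = medians, spearman = spearman,
       seed = seed, sizes = sizes, replicates = replicates)
}
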