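#' Dataset-level clustering metrics
#'
#' Two summary statistics of how clustered a VIS dataset is across the
#' genome: the "maximum %", `100 * max(z) / total VIS` (values above 8
#' indicate a high degree of clustering), and the BCP cluster score
#' `1 - P_bar`, one minus the mean posterior change probability (values
#' above 0.98 indicate a high degree of clustering).
#'
#' @param profile Bin profile with `count` and `zscore` columns.
#' @param bcp Optional `bcp_fit` for the same profile; when absent the BCP
#'   score is `NA`.
#' @return One-row tibble: `n_vis`, `max_percent`, `bcp_score`,
#'   `clustered_by_max`, `clustered_by_bcp`.
#' @export
cluster_metrics <- function(profile, bcp = NULL) {
  stopifnot(all(c("count", "zscore") %in% names(profile)))
  total <- sum(profile$count)
  if (total == 0) abort("empty dataset")
  max_percent <- 100 * max(profile$zscore) / total
  bcp_score <- if (is.null(bcp)) NA_real_ else 1 - bcp$p_bar
  tibble::tibble(n_vis = total, max_percent = max_percent,
                 bcp_score = bcp_score,
                 clustered_by_max = max_percent > 8,
                 clustered_by_bcp = !is.na(bcp_score) & bcp_score > 0.98)
}

#' Cross-tabulate hot-bins of two datasets
#'
#' Builds the 2x2 hot-bin contingency table between two datasets analysed on
#' the same genome partition: bins hot in both, hot in A only, hot in B
#' only, hot in neither. Hot-bins, rather than hot-spots, are used so that
#' conservation testing controls for hot-spot size.
#'
#' @param bins_a,bins_b Hot-bin index vectors on a shared partition.
#' @param n Total number of bins in the partition (3091 for hg18 Mb bins).
#' @return One-row tibble: `a_and_b`, `a_only`, `b_only`, `neither`, `n`.
#' @export
hotbin_overlap <- function(bins_a, bins_b, n) {
  bins_a <- unique(as.integer(bins_a)); bins_b <- unique(as.integer(bins_b))
  if (length(c(bins_a, bins_b)) && max(c(bins_a, bins_b, 0)) > n)
    abort("hot-bin index exceeds the number of bins")
  if (any(c(bins_a, bins_b) < 1)) abort("hot-bin indices must be >= 1")
  ab <- length(intersect(bins_a, bins_b))
  tibble::tibble(a_and_b = ab,
                 a_only = length(bins_a) - ab,
                 b_only = length(bins_b) - ab,
                 neither = n - length(union(bins_a, bins_b)),
                 n = as.integer(n))
}

#' Fisher's exact test of a hot-bin overlap table
#'
#' Two-sided exact test of association for the 2x2 hot-bin table, with the
#' two-sided p-value defined as the sum of hypergeometric point
#' probabilities not exceeding that of the observed table (the convention
#' under which the published worked examples print 6.6e-5 and 0.007).
#'
#' @param table One-row tibble from [hotbin_overlap()], or a numeric vector
#'   `c(a_and_b, a_only, b_only, neither)`.
#' @return The two-sided p-value.
#' @export
fisher_overlap <- function(table) {
  v <- if (is.data.frame(table))
    c(table$a_and_b, table$a_only, table$b_only, table$neither)
  else as.numeric(table)[1:4]
  if (any(v < 0)) abort("table cells must be non-negative")
  if (sum(v) == 0) abort("all-zero table")
  m <- matrix(v, nrow = 2, byrow = TRUE)
  fisher.test(m)$p.value
}

#' Pairwise hot-bin conservation report
#'
#' For every pair of datasets, cross-tabulates hot-bins over the shared
#' partition and computes the two-sided Fisher exact p-value, annotated for
#' significance at a conservative threshold (default 0.007, the benchmark
#' p-value of an acute-infection versus post-transplant comparison with a
#' single overlapping hot-bin).
#'
#' @param hotbin_sets Named list of hot-bin index vectors, one per dataset,
#'   all on the same partition.
#' @param n Total bin count of the shared partition.
#' @param alpha Significance annotation threshold (default 0.007).
#' @param methods Optional character vector recording, per dataset, the
#'   method that produced its hot-bins.
#' @return Tibble with one row per dataset pair: names, table cells,
#'   `p_value`, `significant`, and the recorded methods.
#' @export
conservation_report <- function(hotbin_sets, n, alpha = 0.007,
                                methods = NULL) {
  if (length(hotbin_sets) < 2) abort("need at least 2 datasets")
  nm <- names(hotbin_sets) %||% paste0("dataset", seq_along(hotbin_sets))
  if (is.null(names(hotbin_sets))) names(hotbin_sets) <- nm
  if (!is.null(methods)) methods <- setNames(methods, nm)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  dplyr::bind_rows(purrr::map(pairs, function(pr) {
    tab <- hotbin_overlap(hotbin_sets[[pr[1]]], hotbin_sets[[pr[2]]], n)
    p <- fisher_overlap(tab)
    dplyr::bind_cols(
      tibble::tibble(a = pr[1], b = pr[2]),
      tab,
      tibble::tibble(p_value = p, significant = p <= alpha,
                     method_a = if (is.null(methods)) NA_character_ else methods[[pr[1]]],
                     method_b = if (is.null(methods)) NA_character_ else methods[[pr[2]]])
    )
  }))
}
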