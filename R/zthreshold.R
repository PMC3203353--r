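#' Calibrate a hot-bin threshold from a reference profile
#'
#' Returns the given percentile of a reference dataset's per-bin scores,
#' following the convention that a suitable hot-bin threshold should call few
#' to no hot-bins in an acute-infection (pre-transplant) reference dataset.
#' The shipped default threshold of 422 is the 99.92 percentile of the
#' z-scores of a 922-VIS lentiviral acute-infection reference over the 3091
#' hg18 Mb bins; the analogous rate-scale default is 0.006.
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), recorded in the returned object so calibrated
#' thresholds are reproducible.
#'
#' @param reference_profile Bin profile with the requested score column.
#' @param percentile Percentile in (0, 100); default 99.92.
#' @param score Which score to calibrate on: `"zscore"` or `"rate"`.
#' @return A `threshold_spec` list with elements `value`, `percentile`,
#'   `score`, `source` and `quantile_type`.
#' @export
get_threshold <- function(reference_profile, percentile = 99.92,
                          score = c("zscore", "rate")) {
  score <- match.arg(score)
  if (!score %in% names(reference_profile))
    abort(paste0("reference profile lacks a '", score, "' column"))
  if (percentile <= 0 || percentile >= 100 + 1e-9)
    abort("percentile must lie in (0, 100]")
  x <- reference_profile[[score]]
  if (all(x == x[1])) abort("degenerate reference: zero variance")
  value <- unname(quantile(x, probs = percentile / 100, type = 7))
  threshold_spec(value, percentile = percentile, score = score,
                 source = "calibrated-from-reference")
}

#' Construct a fixed hot-bin threshold
#'
#' @param value Threshold on the score scale (default 422, the shipped
#'   z-score threshold).
#' @param percentile Percentile the value corresponds to, if known.
#' @param score Score the threshold applies to.
#' @param source `"fixed"` or `"calibrated-from-reference"`.
#' @return A `threshold_spec` list.
#' @export
threshold_spec <- function(value = 422, percentile = 99.92,
                           score = "zscore", source = "fixed") {
  if (!is.finite(value)) abort("threshold value must be finite")
  structure(list(value = value, percentile = percentile, score = score,
                 source = source, quantile_type = 7L),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %s > %g (%s; %.4g percentile)\n",
              x$score, x$value, x$source, x$percentile))
  invisible(x)
}

#' Call hot-bins by thresholding a per-bin score
#'
#' Returns the genome-wide indices of bins whose score strictly exceeds the
#' threshold; bins exactly at the threshold are excluded (and reported with a
#' message when present).
#'
#' @param profile Bin profile containing the requested score column
#'   (`zscore`, `rate`, or `post_mean` after [bcp_fit()] augmentation).
#' @param threshold A `threshold_spec` or a bare number.
#' @param score Score column to threshold; defaults to the threshold's own
#'   score.
#' @return Sorted integer vector of hot-bin indices.
#' @export
call_hotbins <- function(profile, threshold = threshold_spec(), score = NULL) {
  if (!inherits(threshold, "threshold_spec"))
    threshold <- threshold_spec(threshold, percentile = NA_real_,
                                score = score %||% "zscore")
  score <- score %||% threshold$score
  if (!score %in% names(profile))
    abort(paste0("profile lacks a '", score, "' column"))
  x <- profile[[score]]
  ties <- sum(x == threshold$value)
  if (ties > 0)
    message(ties, " bin(s) exactly at the threshold excluded (strict '>')")
  sort(profile$bin[x > threshold$value])
}

#' Refine hot-bins into hot-spots with VIS-based boundaries
#'
#' Groups maximal runs of consecutive hot-bins on the same chromosome into
#' one hot-spot each, then moves each external boundary to the VIS closest to
#' that bin edge. The nearest VIS may lie inside or outside the hot-bin run
#' (so hot-spots can extend past a bin edge); when two VIS are equidistant
#' from an edge the interior one is taken. A hot-bin run on a chromosome with
#' no VIS keeps its bin-edge boundaries, with a warning.
#'
#' @param hotbins Sorted hot-bin indices from [call_hotbins()] or
#'   [bcp_hotbins()].
#' @param vis VIS tibble of the same dataset.
#' @param partition Bin tibble the indices refer to.
#' @param method Method label stored in the result (`"zthreshold"` by
#'   default; [bcp_hotbins()] callers pass `"bcp"`).
#' @return Hot-spot tibble (see [cis_scan()] for columns).
#' @export
refine_hotspots <- function(hotbins, vis, partition, method = "zthreshold") {
  if (length(hotbins) == 0) return(hotspot_tibble())
  hotbins <- sort(unique(as.integer(hotbins)))
  if (any(hotbins < 1 | hotbins > nrow(partition)))
    abort("hot-bin index outside the partition")
  bins <- partition[match(hotbins, partition$bin), ]
  run_id <- cumsum(c(1, diff(hotbins) != 1 |
                       bins$chrom[-1] != bins$chrom[-nrow(bins)]))
  regions <- dplyr::bind_rows(purrr::map(split(bins, run_id), function(b) {
    ch <- b$chrom[1]
    left_edge <- min(b$start) + 1 # first base covered by the run (1-based)
    right_edge <- max(b$end)
    p <- vis$pos[vis$chrom == ch]
    if (length(p) == 0) {
      warn(paste0("hot-bin run on ", ch,
                  " has no VIS on that chromosome; using bin edges"))
      return(tibble::tibble(chrom = ch, start = left_edge, end = right_edge))
    }
    start <- nearest_vis(p, left_edge, prefer = "right")
    end <- nearest_vis(p, right_edge, prefer = "left")
    if (start > end) { # degenerate: no VIS inside, nearest collapses
      warn(paste0("hot-bin run on ", ch,
                  " contains no VIS; using bin edges"))
      return(tibble::tibble(chrom = ch, start = left_edge, end = right_edge))
    }
    tibble::tibble(chrom = ch, start = start, end = end)
  }))
  hs <- hotspot_stats(regions, vis, method = method)
  dplyr::arrange(hs, match(.data$chrom, unique(partition$chrom)), .data$start)
}

# Position among sorted-or-not VIS positions p closest to edge; ties go to
# the side named by `prefer` (the interior of the hot-bin run).
nearest_vis <- function(p, edge, prefer) {
  d <- abs(p - edge)
  cand <- which(d == min(d))
  if (length(cand) > 1) {
    side <- if (prefer == "right") p[cand] >= edge else p[cand] <= edge
    if (any(side)) cand <- cand[side]
  }
  p[cand[1]]
}
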