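#' Merge hot-spot sets from shifted genome partitions
#'
#' Hot-spot results can depend on where the bin grid falls, so detection may
#' be run on several shifted partitions of the same genome and the results
#' merged into one comprehensive hot-spot set: intervals overlapping by at
#' least 1 bp (configurable) are unioned, and the statistics of each merged
#' hot-spot are recomputed from the dataset's VIS within the union (never
#' averaged from the parents). Provenance lists the contributing shifts.
#'
#' @param results List of hot-spot tibbles for the same dataset, one per
#'   partition shift. Names (or the `shifts` argument) label provenance.
#' @param vis The dataset's VIS tibble, used to recompute statistics.
#' @param shifts Optional numeric vector of shift values, one per result.
#' @param min_overlap Minimum overlap in bp for two hot-spots to be unioned
#'   (default 1).
#' @return Merged hot-spot tibble with a `shifts` provenance column.
#' @export
merge_hotspots <- function(results, vis, shifts = NULL, min_overlap = 1) {
  stopifnot(is.list(results), length(results) >= 1)
  labels <- as.character(shifts %||% names(results) %||%
                           (seq_along(results) - 1))
  all_hs <- dplyr::bind_rows(purrr::map2(results, labels, function(hs, lab) {
    if (nrow(hs) == 0) return(NULL)
    dplyr::mutate(hs[, c("chrom", "start", "end")], shift = lab)
  }))
  if (is.null(all_hs) || nrow(all_hs) == 0) {
    out <- hotspot_tibble()
    out$shifts <- character()
    return(out)
  }
  gr <- GenomicRanges::GRanges(all_hs$chrom,
                               IRanges::IRanges(all_hs$start, all_hs$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1 - min_overlap)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  prov <- split(all_hs$shift[S4Vectors::queryHits(hit)],
                S4Vectors::subjectHits(hit))
  regions <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged))
  out <- hotspot_stats(regions, vis, method = "merged")
  out$shifts <- unname(purrr::map_chr(
    prov[as.character(seq_len(nrow(regions)))],
    ~ paste(sort(unique(.x)), collapse = ",")))
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Match hot-spots between two result sets
#'
#' A match is a pair of hot-spots (one from each set) overlapping by at
#' least 1 bp. Reports the pairing, the match count, and the correspondence
#' ratio (matches over the size of the reference set `a`).
#'
#' @param a,b Hot-spot tibbles on the same genome.
#' @return List with `pairs` (tibble of matched index pairs), `n_matches`
#'   (number of hot-spots of `a` matched in `b`), and `correspondence`
#'   (`n_matches / nrow(a)`).
#' @export
match_hotspots <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(list(pairs = tibble::tibble(a = integer(), b = integer()),
                n_matches = 0L,
                correspondence = if (nrow(a) == 0) NA_real_ else 0))
  hit <- GenomicRanges::findOverlaps(hotspot_granges(a), hotspot_granges(b))
  pairs <- tibble::tibble(a = S4Vectors::queryHits(hit),
                          b = S4Vectors::subjectHits(hit))
  n_matches <- length(unique(pairs$a))
  list(pairs = pairs, n_matches = n_matches,
       correspondence = n_matches / nrow(a))
}
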