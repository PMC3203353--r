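#' CIS density rules
#'
#' A common insertion site (CIS) rule is a window width in base pairs and a
#' minimum VIS count: a region qualifies when some window of that width
#' contains at least that many VIS. The default rule set is the conventional
#' definition of at least 3 VIS within 50 kb or at least 4 VIS within 100 kb;
#' a region qualifying under either rule is a CIS hot-spot.
#'
#' @param window Integer vector of window widths (bp).
#' @param min_count Integer vector (same length) of minimum VIS counts.
#' @return A tibble with columns `window`, `min_count`.
#' @export
cis_rules <- function(window = c(50000, 100000), min_count = c(3, 4)) {
  stopifnot(length(window) == length(min_count))
  if (any(window <= 0)) abort("CIS window widths must be positive")
  if (any(min_count < 2)) abort("CIS min_count must be >= 2")
  tibble::tibble(window = as.numeric(window), min_count = as.integer(min_count))
}

#' Detect CIS hot-spots by sliding-window density
#'
#' Implements the conventional CIS definition: slide a window of `window` bp
#' along each chromosome in 1 bp steps and call every window containing at
#' least `min_count` VIS. This is computed equivalently (and in O(m) time) by
#' noting that such a window exists iff `min_count` consecutive sorted VIS
#' span less than `window` bp. Qualifying VIS runs from all rules are pooled
#' and overlapping or VIS-sharing runs are merged into maximal disjoint
#' hot-spots whose boundaries are the outermost member VIS.
#'
#' @param vis Sorted VIS tibble (see [validate_vis()]).
#' @param rules Rule tibble from [cis_rules()].
#' @return A hot-spot tibble with columns `chrom`, `start`, `end` (1-based,
#'   both VIS positions), `n_vis`, `pct_vis`, `size_mb`, `pct_density`,
#'   `method` (`"cis"`). Zero rows when no region qualifies.
#' @export
cis_scan <- function(vis, rules = cis_rules()) {
  total <- nrow(vis)
  empty <- hotspot_tibble()
  if (total == 0) return(empty)
  runs <- dplyr::bind_rows(purrr::map(unique(vis$chrom), function(ch) {
    p <- sort(vis$pos[vis$chrom == ch])
    iv <- dplyr::bind_rows(purrr::pmap(rules, function(window, min_count) {
      m <- length(p)
      if (m < min_count) return(NULL)
      i <- seq_len(m - min_count + 1)
      ok <- (p[i + min_count - 1] - p[i]) < window
      if (!any(ok)) return(NULL)
      tibble::tibble(start = p[i[ok]], end = p[i[ok] + min_count - 1])
    }))
    if (is.null(iv) || nrow(iv) == 0) return(NULL)
    iv <- dplyr::arrange(iv, .data$start, .data$end)
    merged <- merge_intervals(iv$start, iv$end)
    tibble::tibble(chrom = ch, start = merged$start, end = merged$end)
  }))
  if (nrow(runs) == 0) return(empty)
  hotspot_stats(runs, vis, method = "cis")
}

# Union of intervals that overlap or share an endpoint.
merge_intervals <- function(start, end) {
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  out_s <- start[1]; out_e <- end[1]
  for (k in seq_along(start)[-1]) {
    if (start[k] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], end[k])
    } else {
      out_s <- c(out_s, start[k]); out_e <- c(out_e, end[k])
    }
  }
  list(start = out_s, end = out_e)
}

hotspot_tibble <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 n_vis = integer(), pct_vis = numeric(), size_mb = numeric(),
                 pct_density = numeric(), method = character())
}

# Fill per-hot-spot statistics from the member VIS of each interval.
hotspot_stats <- function(regions, vis, method) {
  total <- nrow(vis)
  res <- purrr::pmap(regions, function(chrom, start, end, ...) {
    inside <- vis$pos[vis$chrom == chrom & vis$pos >= start & vis$pos <= end]
    n <- length(inside)
    size_mb <- (end - start) / 1e6
    pct <- 100 * n / total
    tibble::tibble(chrom = chrom, start = start, end = end, n_vis = n,
                   pct_vis = pct, size_mb = size_mb,
                   pct_density = ifelse(size_mb > 0, pct / size_mb, NA_real_))
  })
  out <- dplyr::bind_rows(res)
  out$method <- method
  out
}

#' List the member VIS of each hot-spot
#'
#' @param hotspots Hot-spot tibble.
#' @param vis VIS tibble.
#' @return A tibble with one row per (hot-spot, VIS) pair: `hotspot`,
#'   `chrom`, `pos`.
#' @export
hotspot_members <- function(hotspots, vis) {
  dplyr::bind_rows(purrr::imap(split(hotspots, seq_len(nrow(hotspots))),
    function(h, i) {
      inside <- vis[vis$chrom == h$chrom & vis$pos >= h$start &
                      vis$pos <= h$end, c("chrom", "pos")]
      if (nrow(inside) == 0) return(NULL)
      dplyr::mutate(inside, hotspot = as.integer(i), .before = 1)
    }))
}
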