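#' Read a genomic-feature track
#'
#' Reads a BED-like file (chrom, start, end, optional name) into a feature
#' track tibble. Starts are taken as 0-based half-open BED coordinates.
#'
#' @param path Path to the BED/TSV file.
#' @param name Track name (defaults to the file name).
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, sorted.
#' @export
read_track <- function(path, name = NULL) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) abort("feature track needs >= 3 columns (chrom, start, end)")
  out <- tibble::tibble(chrom = as.character(df[[1]]),
                        start = as.numeric(df[[2]]),
                        end = as.numeric(df[[3]]),
                        name = if (ncol(df) >= 4) as.character(df[[4]])
                               else paste0("feature", seq_len(nrow(df))))
  attr(out, "track_name") <- name %||% sub("\\.[^.]*$", "", basename(path))
  dplyr::arrange(out, .data$chrom, .data$start)
}

track_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(track$start + 1, pmax(track$end,
                                                                track$start + 1)))
}

hotspot_granges <- function(hotspots) {
  GenomicRanges::GRanges(hotspots$chrom,
                         IRanges::IRanges(hotspots$start, hotspots$end))
}

#' Per-hot-spot feature densities
#'
#' Counts, for each hot-spot, the features of a track overlapping it by at
#' least 1 bp (each feature counted once per hot-spot) and divides by the
#' hot-spot size in Mb.
#'
#' @param hotspots Hot-spot tibble.
#' @param track Feature track tibble (BED-like, 0-based starts).
#' @return `hotspots` with `n_features` and `feature_density` (features/Mb)
#'   columns added.
#' @export
feature_density <- function(hotspots, track) {
  if (any(hotspots$size_mb <= 0)) abort("zero-size hot-spot")
  if (nrow(hotspots) == 0)
    return(dplyr::mutate(hotspots, n_features = integer(),
                         feature_density = numeric()))
  counts <- if (nrow(track) == 0) integer(nrow(hotspots)) else
    GenomicRanges::countOverlaps(hotspot_granges(hotspots),
                                 track_granges(track))
  dplyr::mutate(hotspots, n_features = as.integer(counts),
                feature_density = counts / .data$size_mb)
}

#' Genome-wide per-bin feature densities and their median
#'
#' Computes the feature count per Mb for every bin of a genome partition —
#' the genome-wide density distribution against which hot-spot densities are
#' compared — and its median over all bins.
#'
#' @param track Feature track tibble.
#' @param partition Bin tibble from [partition_genome()].
#' @return List with `per_bin` (partition plus `n_features`, `density`) and
#'   `median` (genome median density, features/Mb).
#' @export
genome_density_profile <- function(track, partition) {
  gr_bins <- GenomicRanges::GRanges(
    partition$chrom, IRanges::IRanges(partition$start + 1, partition$end))
  counts <- if (nrow(track) == 0) integer(nrow(partition)) else
    GenomicRanges::countOverlaps(gr_bins, track_granges(track))
  per_bin <- dplyr::mutate(partition, n_features = as.integer(counts),
                           density = counts / ((.data$end - .data$start) / 1e6))
  list(per_bin = per_bin, median = median(per_bin$density))
}

#' Compare hot-spot feature densities to the genome
#'
#' Two-sample Wilcoxon rank-sum test (normal approximation with continuity
#' correction) of the hot-spot per-Mb feature densities against the
#' genome-wide per-bin density distribution, flagged for significance at the
#' Bonferroni-corrected level 0.0025 (20 tests: 5 dataset comparisons by 4
#' genomic features in the reference analysis design).
#'
#' @param hotspot_densities Numeric vector of per-hot-spot densities
#'   (features/Mb), e.g. the `feature_density` column of [feature_density()].
#' @param genome_bin_densities Numeric vector of per-bin genome densities,
#'   from [genome_density_profile()].
#' @param alpha Bonferroni-corrected significance level (default 0.0025).
#' @return One-row tibble: `n_hotspots`, `hotspot_median`, `genome_median`,
#'   `wilcoxon_p`, `significant`, `low_power` (fewer than 3 hot-spots).
#' @export
compare_to_genome <- function(hotspot_densities, genome_bin_densities,
                              alpha = 0.0025) {
  if (length(hotspot_densities) < 1 || length(genome_bin_densities) < 1)
    abort("empty density inputs")
  wt <- suppressWarnings(
    wilcox.test(hotspot_densities, genome_bin_densities,
                correct = TRUE, exact = FALSE))
  tibble::tibble(n_hotspots = length(hotspot_densities),
                 hotspot_median = median(hotspot_densities),
                 genome_median = median(genome_bin_densities),
                 wilcoxon_p = wt$p.value,
                 significant = wt$p.value < alpha,
                 low_power = length(hotspot_densities) < 3)
}

#' Percentage of cancer-related genes among hot-spot genes
#'
#' Divides the number of cancer-related genes located in hot-spots by the
#' total number of genes located in hot-spots (controlling for gene-density
#' differences), and tests enrichment against the genome-wide cancer/other
#' gene split with a two-sided Fisher exact test.
#'
#' @param hotspot_genes Character vector of gene identifiers found in
#'   hot-spots (e.g. names of genes overlapping hot-spot intervals).
#' @param cancer_genes Character vector of cancer-related gene identifiers.
#' @param genome_genes Character vector of all gene identifiers genome-wide.
#' @return One-row tibble: `n_genes`, `n_cancer`, `pct_cancer` (`NA` when no
#'   genes lie in hot-spots), `fisher_p`.
#' @export
cancer_gene_pct <- function(hotspot_genes, cancer_genes, genome_genes) {
  n <- length(hotspot_genes)
  n_cancer <- sum(hotspot_genes %in% cancer_genes)
  if (n == 0)
    return(tibble::tibble(n_genes = 0L, n_cancer = 0L,
                          pct_cancer = NA_real_, fisher_p = NA_real_))
  out_genes <- setdiff(genome_genes, hotspot_genes)
  out_cancer <- sum(out_genes %in% cancer_genes)
  tab <- matrix(c(n_cancer, n - n_cancer,
                  out_cancer, length(out_genes) - out_cancer), nrow = 2,
                byrow = TRUE)
  tibble::tibble(n_genes = as.integer(n), n_cancer = as.integer(n_cancer),
                 pct_cancer = 100 * n_cancer / n,
                 fisher_p = fisher.test(tab)$p.value)
}

#' Genes overlapping hot-spots
#'
#' @param hotspots Hot-spot tibble.
#' @param gene_track Feature track of genes with a `name` column.
#' @return Character vector of unique gene names overlapping any hot-spot.
#' @export
hotspot_genes <- function(hotspots, gene_track) {
  if (nrow(hotspots) == 0 || nrow(gene_track) == 0) return(character())
  hits <- GenomicRanges::findOverlaps(track_granges(gene_track),
                                      hotspot_granges(hotspots))
  unique(gene_track$name[S4Vectors::queryHits(hits)])
}
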