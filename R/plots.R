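#' Assign display colour classes to VIS from z-score quantiles
#'
#' Classifies each VIS for plotting: VIS outside hot-spots are `"grey"`;
#' VIS inside hot-spots are coloured by the z-score of their bin relative to
#' the dataset's non-zero z-score distribution (bins with positive scores):
#' at or below the 85th percentile light blue, (85, 95] dark blue,
#' (95, 97.5] purple, (97.5, 99] pink, above the 99th red. Ties at a class
#' edge fall in the lower class.
#'
#' @param vis VIS tibble.
#' @param profile Bin profile with `zscore`.
#' @param hotspots Hot-spot tibble (possibly empty).
#' @param partition Bin tibble matching `profile`.
#' @return `vis` with columns `bin`, `zscore`, `in_hotspot`, `colour_class`
#'   (ordered factor grey < lightblue < darkblue < purple < pink < red).
#' @export
vis_colour_classes <- function(vis, profile, hotspots, partition) {
  counted <- bin_counts(vis[, c("chrom", "pos")], partition)
  idx <- rep(NA_integer_, nrow(vis))
  for (ch in unique(vis$chrom)) {
    rows <- which(partition$chrom == ch)
    sel <- vis$chrom == ch
    idx[sel] <- rows[findInterval(vis$pos[sel] - 1, partition$start[rows])]
  }
  z <- profile$zscore[idx]
  in_hs <- rep(FALSE, nrow(vis))
  for (k in seq_len(nrow(hotspots))) {
    in_hs <- in_hs | (vis$chrom == hotspots$chrom[k] &
                        vis$pos >= hotspots$start[k] &
                        vis$pos <= hotspots$end[k])
  }
  pos_z <- profile$zscore[profile$zscore > 0]
  qs <- quantile(pos_z, c(.85, .95, .975, .99), type = 7)
  lv <- c("grey", "lightblue", "darkblue", "purple", "pink", "red")
  cls <- rep("grey", nrow(vis))
  hot <- which(in_hs)
  # ties at a class edge fall in the lower class (strict '>' between classes)
  cls[hot] <- lv[-1][findInterval(z[hot], qs, left.open = TRUE) + 1]
  dplyr::mutate(vis, bin = profile$bin[idx], zscore = z, in_hotspot = in_hs,
                colour_class = factor(cls, levels = lv, ordered = TRUE))
}

vis_palette <- c(grey = "grey60", lightblue = "#9ecae1", darkblue = "#2171b5",
                 purple = "#6a51a3", pink = "#f768a1", red = "#cb181d")

genome_mb_offsets <- function(chrom_sizes) {
  off <- cumsum(c(0, head(chrom_sizes$length, -1))) / 1e6
  setNames(off, chrom_sizes$chrom)
}

#' Genome-wide stripchart of VIS and hot-spots
#'
#' One horizontal strip per dataset, VIS plotted at their strung-together
#' genomic position in Mb and coloured by hot-spot z-score class (see
#' [vis_colour_classes()]).
#'
#' @param classified Named list of classified VIS tibbles (one per dataset)
#'   from [vis_colour_classes()], or a single tibble.
#' @param chrom_sizes Chromosome-sizes tibble (for chromosome offsets).
#' @return A ggplot object.
#' @export
plot_genome_stripchart <- function(classified, chrom_sizes) {
  if (is.data.frame(classified)) classified <- list(dataset = classified)
  off <- genome_mb_offsets(chrom_sizes)
  df <- dplyr::bind_rows(purrr::imap(classified, function(v, nm)
    dplyr::mutate(v, dataset = nm, genome_mb = .data$pos / 1e6 +
                    off[.data$chrom])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_mb, y = .data$dataset,
                                   colour = .data$colour_class)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::scale_colour_manual(values = vis_palette, drop = FALSE) +
    ggplot2::labs(x = "Genome position (Mb)", y = NULL,
                  colour = "z-score class") +
    ggplot2::theme_minimal()
}

#' Single-chromosome stripchart of VIS and hot-spots
#'
#' @inheritParams plot_genome_stripchart
#' @param chrom Chromosome to display.
#' @return A ggplot object.
#' @export
plot_chromosome_stripchart <- function(classified, chrom) {
  if (is.data.frame(classified)) classified <- list(dataset = classified)
  df <- dplyr::bind_rows(purrr::imap(classified, function(v, nm)
    dplyr::mutate(v, dataset = nm)))
  if (!chrom %in% df$chrom) abort(paste0("unknown chromosome: ", chrom))
  df <- dplyr::filter(df, .data$chrom == !!chrom)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$dataset,
                                   colour = .data$colour_class)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::scale_colour_manual(values = vis_palette, drop = FALSE) +
    ggplot2::labs(x = paste0(chrom, " position (Mb)"), y = NULL,
                  colour = "z-score class") +
    ggplot2::theme_minimal()
}

#' Per-bin barplot of VIS rates for one chromosome
#'
#' Bars show the bin rate (VIS per bin divided by the dataset total), which
#' unlike the z-score is non-negative; hot-spot bins are coloured by their
#' z-score class, other bins grey.
#'
#' @param profile Bin profile with `count` and `zscore`.
#' @param chrom Chromosome to display.
#' @param hotbins Hot-bin indices (coloured).
#' @return A ggplot object.
#' @export
plot_bin_barplot <- function(profile, chrom, hotbins = integer()) {
  if (!chrom %in% profile$chrom) abort(paste0("unknown chromosome: ", chrom))
  total <- sum(profile$count)
  pos_z <- profile$zscore[profile$zscore > 0]
  qs <- quantile(pos_z, c(.85, .95, .975, .99), type = 7)
  lv <- c("grey", "lightblue", "darkblue", "purple", "pink", "red")
  df <- dplyr::filter(profile, .data$chrom == !!chrom)
  cls <- rep("grey", nrow(df))
  hot <- df$bin %in% hotbins
  cls[hot] <- lv[-1][findInterval(df$zscore[hot], qs, left.open = TRUE) + 1]
  df$colour_class <- factor(cls, levels = lv, ordered = TRUE)
  df$rate <- df$count / total
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$rate,
                                   fill = .data$colour_class)) +
    ggplot2::geom_col(width = (df$end - df$start) / 1e6) +
    ggplot2::scale_fill_manual(values = vis_palette, drop = FALSE) +
    ggplot2::labs(x = paste0(chrom, " position (Mb)"),
                  y = "Bin rate (VIS per bin / total VIS)",
                  fill = "z-score class") +
    ggplot2::theme_minimal()
}

#' @rdname bcp_fit
#' @param object A `bcp_fit` object (for `autoplot`).
#' @export
autoplot.bcp_fit <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("zscore", "post_mean"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Genome bin", y = "z-score scale",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
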