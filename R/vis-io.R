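#' Read a VIS coordinate file
#'
#' Reads a tab- or whitespace-delimited file of viral integration sites with
#' at least two columns: chromosome and 1-based insertion position. A third
#' column, if present, is kept as `label`; a `strand` column is carried
#' through but never used by any hot-spot definition. An optional header line
#' is detected when the second field of the first line is not an integer.
#'
#' Records are validated against `chrom_sizes`: unknown chromosomes or
#' positions outside `[1, length]` raise an error naming the offending line
#' numbers. Records are returned sorted by (chromosome order, position);
#' duplicated positions are allowed but reported with a warning, mirroring
#' the convention that published datasets contain unique VIS.
#'
#' @param path Path to the VIS file.
#' @param chrom_sizes Chromosome-sizes tibble (`chrom`, `length`).
#' @param name Dataset name; defaults to the file name without extension.
#' @return A sorted, validated VIS tibble with columns `chrom`, `pos` and
#'   optionally `label`/`strand`.
#' @export
read_vis <- function(path, chrom_sizes, name = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read VIS file: ", path))
  raw <- tryCatch(
    read.table(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE, fill = FALSE),
    error = function(e) abort(paste0("no parseable records in ", path))
  )
  if (nrow(raw) == 0) abort(paste0("no parseable records in ", path))
  has_header <- is.na(suppressWarnings(as.numeric(raw[1, 2])))
  line_offset <- 0L
  if (has_header) {
    hdr <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    names(raw)[seq_along(hdr)] <- tolower(hdr)
    line_offset <- 1L
    if (nrow(raw) == 0) abort(paste0("no parseable records in ", path))
  } else {
    nm <- c("chrom", "pos", "label", "strand")
    names(raw) <- nm[seq_len(min(ncol(raw), 4))]
  }
  if (!all(c("chrom", "pos") %in% names(raw)))
    names(raw)[1:2] <- c("chrom", "pos")
  pos_num <- suppressWarnings(as.numeric(raw$pos))
  bad_pos <- which(!is.finite(pos_num) | pos_num != floor(pos_num))
  if (length(bad_pos))
    abort(paste0("non-integer position on line(s): ",
                 paste(bad_pos + line_offset, collapse = ", ")))
  vis <- tibble::tibble(chrom = as.character(raw$chrom), pos = pos_num)
  if ("label" %in% names(raw)) vis$label <- as.character(raw$label)
  if ("strand" %in% names(raw)) vis$strand <- as.character(raw$strand)
  validate_vis(vis, chrom_sizes, line_offset = line_offset,
               source = path, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Validate and sort a VIS tibble against a genome
#'
#' @param vis Tibble with columns `chrom`, `pos` (1-based).
#' @param chrom_sizes Chromosome-sizes tibble.
#' @param line_offset,source Internal, used for error messages from [read_vis()].
#' @param name Optional dataset name stored as the `"vis_name"` attribute.
#' @return The VIS tibble sorted by (chromosome order, position).
#' @export
validate_vis <- function(vis, chrom_sizes, line_offset = 0L, source = "input",
                         name = NULL) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  stopifnot(all(c("chrom", "pos") %in% names(vis)))
  vis <- tibble::as_tibble(vis)
  idx <- match(vis$chrom, chrom_sizes$chrom)
  bad_chr <- which(is.na(idx))
  if (length(bad_chr))
    abort(paste0("unknown chromosome '", vis$chrom[bad_chr[1]], "' in ", source,
                 " on line(s): ",
                 paste(bad_chr + line_offset, collapse = ", ")))
  len <- chrom_sizes$length[idx]
  oob <- which(vis$pos < 1 | vis$pos > len)
  if (length(oob))
    abort(paste0("position out of chromosome bounds in ", source,
                 " on line(s): ", paste(oob + line_offset, collapse = ", ")))
  ord <- order(idx, vis$pos)
  vis <- vis[ord, , drop = FALSE]
  dup <- duplicated(vis[, c("chrom", "pos")])
  if (any(dup))
    warn(paste0(sum(dup), " duplicated VIS position(s) in ", source,
                " (counted separately)"))
  attr(vis, "vis_name") <- name
  vis
}

#' Write hot-spots as BED and as a summary-statistics table
#'
#' The BED file uses 0-based half-open coordinates. The stats TSV mirrors the
#' published hot-spot tables: chromosome, location in Mb (3 decimals), number
#' of VIS with its percentage of the dataset, size in Mb, and % density
#' (percent VIS per Mb).
#'
#' @param hotspots Hot-spot tibble as returned by [cis_scan()],
#'   [refine_hotspots()] or [merge_hotspots()].
#' @param bed_path,stats_path Output paths; either may be `NULL` to skip.
#' @return `hotspots`, invisibly.
#' @export
write_hotspots <- function(hotspots, bed_path = NULL, stats_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = hotspots$chrom,
                      start = format(hotspots$start - 1, scientific = FALSE, trim = TRUE),
                      end = format(hotspots$end, scientific = FALSE, trim = TRUE),
                      name = paste0(hotspots$method, "_hotspot_",
                                    seq_len(nrow(hotspots))))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(stats_path)) {
    stats <- data.frame(
      Chr = hotspots$chrom,
      Location_Mb = sprintf("%.3f-%.3f", hotspots$start / 1e6,
                            hotspots$end / 1e6),
      VIS = sprintf("%d (%.2f%%)", hotspots$n_vis, hotspots$pct_vis),
      Size_Mb = round(hotspots$size_mb, 3),
      Pct_Density = round(hotspots$pct_density, 2),
      Method = hotspots$method
    )
    write.table(stats, stats_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(hotspots)
}
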