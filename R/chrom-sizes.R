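#' Chromosome sizes of the human hg18 assembly
#'
#' Lengths of the 24 nuclear chromosomes (chr1-chr22, chrX, chrY) of the
#' UCSC hg18 (NCBI36) human assembly, excluding random/haplotype contigs.
#' Partitioning this genome into 1 Mb bins (ceiling division per chromosome)
#' yields 3091 bins, the bin total used throughout genome-wide hot-spot
#' analyses of human VIS datasets.
#'
#' @return A tibble with columns `chrom` (character, in karyotype order) and
#'   `length` (integer base pairs). The row order fixes the order in which
#'   chromosomes are strung together into one genomic bin sequence.
#' @examples
#' sum(ceiling(hg18_chrom_sizes()$length / 1e6)) # 3091
#' @export
hg18_chrom_sizes <- function() {
  tibble::tibble(
    chrom = c(paste0("chr", 1:22), "chrX", "chrY"),
    length = c(
      247249719L, 242951149L, 199501827L, 191273063L, 180857866L,
      170899992L, 158821424L, 146274826L, 140273252L, 135374737L,
      134452384L, 132349534L, 114142980L, 106368585L, 100338915L,
      88827254L, 78774742L, 76117153L, 63811651L, 62435964L,
      46944323L, 49691432L, 154913754L, 57772954L
    )
  )
}

#' Read a chromosome-sizes table
#'
#' Reads a UCSC chromInfo-style whitespace-delimited file with at least two
#' columns: chromosome name and length in base pairs. Row order is preserved
#' and defines the strung-together genome order.
#'
#' @param path Path to a two-column text file (no header, or a header line
#'   starting with `#`).
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("chromosome-sizes file needs >= 2 columns (chrom, length)")
  out <- tibble::tibble(chrom = as.character(df[[1]]),
                        length = as.numeric(df[[2]]))
  validate_chrom_sizes(out)
}

validate_chrom_sizes <- function(chrom_sizes) {
  stopifnot(is.data.frame(chrom_sizes),
            all(c("chrom", "length") %in% names(chrom_sizes)))
  if (anyDuplicated(chrom_sizes$chrom))
    abort("duplicated chromosome names in chromosome-sizes table")
  if (any(!is.finite(chrom_sizes$length)) || any(chrom_sizes$length <= 0))
    abort("chromosome lengths must be positive finite numbers")
  tibble::as_tibble(chrom_sizes)
}

# Toy genome helper used in examples/vignettes: k chromosomes of equal length.
#' Build a small uniform genome for simulations and examples
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of every chromosome, in base pairs.
#' @return A chromosome-sizes tibble (`chrom`, `length`).
#' @export
toy_genome <- function(n_chrom = 6, chrom_length = 5e7) {
  tibble::tibble(chrom = paste0("chr", seq_len(n_chrom)),
                 length = as.integer(chrom_length))
}
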