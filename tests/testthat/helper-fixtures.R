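# Shared fixtures: small genomes and synthetic datasets built in code.

tiny_genome <- function(n_chrom = 2, chrom_length = 1e7) {
  tibble::tibble(chrom = paste0("chr", seq_len(n_chrom)),
                 length = as.integer(chrom_length))
}

# Mixed fixture used across detector tests: uniform background plus three
# planted single-bin clusters on a 6 x 50 Mb genome (300 one-Mb bins).
mixed_fixture <- function(seed = 101, n_background = 900,
                          cluster_n = c(30, 30, 30)) {
  genome <- vishotspot::toy_genome(6, 5e7)
  clusters <- tibble::tibble(
    chrom = c("chr1", "chr3", "chr5"),
    center = c(10.5e6, 20.5e6, 30.5e6),
    width = c(6e5, 6e5, 6e5),
    n_vis = cluster_n)
  vis <- vishotspot::generate_synthetic_vis(genome, n_background, clusters,
                                            seed = seed)
  list(genome = genome, clusters = clusters, vis = vis,
       partition = vishotspot::partition_genome(genome))
}

write_vis_file <- function(vis, path = tempfile(fileext = ".tsv")) {
  write.table(vis[, c("chrom", "pos")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}
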