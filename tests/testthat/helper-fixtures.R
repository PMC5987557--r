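# fixture builders shared across test files

make_methylome <- function(start, meth, unmeth, chrom = "chr1", strand = "+",
                           context = "CG", id = "s") {
  methylome(tibble::tibble(chrom = chrom, start = as.integer(start),
                           strand = strand, context = context,
                           meth = as.integer(meth),
                           unmeth = as.integer(unmeth)),
            sample_id = id)
}

# one transcript as a gene-model tibble
make_gene <- function(gene = "G1", tx = "G1.1", chrom = "chr1", strand = "+",
                      tx_start = 1000L, tx_end = 3000L,
                      cds_start = tx_start + 200L, cds_end = tx_end - 200L,
                      exon_starts = c(tx_start, tx_end - 1000L),
                      exon_ends = c(tx_start + 500L, tx_end)) {
  tibble::tibble(gene_name = gene, transcript_id = tx, chrom = chrom,
                 strand = strand, tx_start = tx_start, tx_end = tx_end,
                 cds_start = cds_start, cds_end = cds_end,
                 exon_starts = list(as.integer(exon_starts)),
                 exon_ends = list(as.integer(exon_ends)))
}

# a tested-window row in the scan_windows layout
make_dmw <- function(chrom = "chr1", start = 0L, n = 5L, delta = 0.3,
                     p = 0.005, width = 100L) {
  l2 <- rep(0.2, n)
  l1 <- l2 + delta
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + width), n_cpgs = as.integer(n),
                 mean_s1 = mean(l1), mean_s2 = mean(l2), delta = delta,
                 p_value = p,
                 positions = list(as.integer(start + seq_len(n))),
                 levels_s1 = list(l1), levels_s2 = list(l2))
}

small_chrom_sizes <- function(len = 10000L, chroms = "chr1") {
  tibble::tibble(chrom = chroms, length = as.integer(len))
}
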