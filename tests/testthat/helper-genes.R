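# shared fixture builders

# build a gene-model tibble from exon coding lengths (translation order),
# on either strand, with fixed 100-bp introns
gene_from_lengths <- function(gene_id, lens, strand = "+", chrom = "chr1") {
  lens_gen <- if (strand == "+") lens else rev(lens)
  starts <- integer(length(lens_gen))
  ends <- integer(length(lens_gen))
  p <- 1L
  for (e in seq_along(lens_gen)) {
    starts[e] <- p
    ends[e] <- p + lens_gen[e] - 1L
    p <- ends[e] + 101L
  }
  tibble::tibble(gene_id = gene_id, chromosome = chrom, strand = strand,
                 start = starts, end = ends)
}
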