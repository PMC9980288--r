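# Fixtures are built in code; no binary or stored data.

# Short-hand mutation record constructor.
rec <- function(contig, position, ref, alt, sample_id = "S1",
                alt_depth = 20L, total_depth = 50L) {
  mutation_records(sample_id, contig, position, ref, alt, alt_depth,
                   total_depth)
}

# Random genome with reproducible content.
random_genome <- function(n_contigs = 1L, len = 2000L, seed = 1L,
                          comp = c(0.25, 0.25, 0.25, 0.25)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_contigs), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob = comp),
          collapse = ""), "")
  names(seqs) <- paste0("c", seq_len(n_contigs))
  genome_sequence(seqs)
}

# Write a VCF from raw body lines with a standard single-sample header.
write_test_vcf <- function(body, path, sample = "TUMOR") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# Reverse-complement a whole single-contig genome together with its records
# (for strand-symmetry properties).
flip_genome_and_records <- function(genome, records) {
  stopifnot(length(genome) == 1L)
  L <- nchar(genome[[1L]])
  g2 <- genome_sequence(stats::setNames(revcomp(unclass(genome)[[1L]]),
                                        names(genome)))
  r2 <- records
  r2$position <- L - records$position + 1L
  r2$ref_allele <- chartr("ACGT", "TGCA", records$ref_allele)
  r2$alt_allele <- chartr("ACGT", "TGCA", records$alt_allele)
  list(genome = g2, records = r2)
}
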