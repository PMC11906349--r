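# Shared fixture builders. Everything is generated in code at test time.

small_locus <- function(seed = 11L, n = 400L, m = 300L,
                        window_length = 40000L, ...) {
  gene_span <- min(8000L, window_length %/% 8L)
  simulate_locus(locus_config(n_samples = n, n_variants = m,
                              window_length = window_length,
                              gene_span = gene_span,
                              proximal_flank = min(5000L,
                                                   window_length %/% 8L),
                              seed = seed, ...))
}

# A hand-built single-transcript gene model on [s, e) with one exon.
toy_gene <- function(s = 2000000L, span = 10000L, chrom = "chr1") {
  e <- s + span
  gene_model(
    gene_id = "G", chrom = chrom, strand = "+",
    transcripts = list(list(
      transcript_id = "T", start = s, end = e,
      exons = data.frame(start = s, end = e),
      utr5 = data.frame(start = s, end = s + 100L),
      utr3 = data.frame(start = e - 100L, end = e))))
}

# Independent Hardy-Weinberg dosage matrix with given allele frequencies.
hwe_genotypes <- function(n, freqs, seed = 1L) {
  set.seed(seed)
  G <- vapply(freqs, function(f) rbinom(n, 2L, f), numeric(n))
  colnames(G) <- paste0("v", seq_along(freqs))
  G
}

# Dosage column with an exact number of heterozygous carriers.
carrier_column <- function(n, carriers, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- numeric(n)
  g[sample.int(n, carriers)] <- 1
  g
}

# Minimal variant table for dosage matrices built by hand.
toy_variant_table <- function(G, pos = NULL,
                              classification = "intergenic_regulatory") {
  s <- rarecis:::allele_summary(G)
  data.frame(vid = colnames(G), chrom = "chr1",
             pos = pos %||% seq_len(ncol(G)) * 10L,
             mac = s$mac, maf = s$maf,
             classification = rep_len(classification, ncol(G)),
             annotated_gene = NA_character_,
             consequence = "intergenic_variant",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
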