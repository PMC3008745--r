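# Hand-built fixtures shared across test files.

# One pileup row with sensible defaults; counts are overridden per test.
pileup_row <- function(chrom = "chrT", pos = 1L, ref = "A", alt = "G",
                       ref_fwd = 5L, ref_rev = 5L, alt_fwd = 0L,
                       alt_rev = 0L, max_alt_quality = 0,
                       homopolymer_len = 1L) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             ref_fwd = ref_fwd, ref_rev = ref_rev, alt_fwd = alt_fwd,
             alt_rev = alt_rev, max_alt_quality = max_alt_quality,
             homopolymer_len = homopolymer_len, stringsAsFactors = FALSE)
}

# A fully hand-specified two-transcript gene on a 140 bp contig "chrT".
# Layout (1-based, plus strand):
#   1-10    intergenic
#   11-20   5' UTR of transcript t1
#   21-40   CDS part 1 of t1: ATG TGG GGA GCT GAT AAA CA-
#   41-80   intron (GT ... AG)
#   81-111  CDS part 2 of t1: -T then 9x GGT, stop TAA at 109-111
#   112-114 3' UTR of t1
#   115-123 ORF of transcript t2: ATG GCT TAA  (t1 3' UTR)
#   124-140 3' UTR of both
make_test_genome <- function() {
  seq <- paste0(
    "ACGTACGTAC",                          # 1-10
    "TTTTTTTTTT",                          # 11-20
    "ATGTGGGGAGCTGATAAACA",                # 21-40
    "GT", strrep("C", 36), "AG",           # 41-80 intron
    "T", strrep("GGT", 9), "TAA",          # 81-111
    "CCC",                                 # 112-114
    "ATGGCTTAA",                           # 115-123
    strrep("C", 17))                       # 124-140
  stopifnot(nchar(seq) == 140L)
  reference <- Biostrings::DNAStringSet(c(chrT = seq))
  exons <- data.frame(start = c(11L, 81L), end = c(40L, 140L))
  transcripts <- list(
    t1 = list(gene_id = "geneT", transcript_id = "t1", strand = "+",
              chrom = "chrT", exons = exons,
              cds = data.frame(start = c(21L, 81L), end = c(40L, 111L))),
    t2 = list(gene_id = "geneT", transcript_id = "t2", strand = "+",
              chrom = "chrT", exons = exons,
              cds = data.frame(start = 115L, end = 123L)))
  list(reference = reference, transcripts = transcripts, length = 140L)
}

# The same gene mirrored onto the minus strand of a reverse-complemented
# contig: position p maps to 141 - p.
make_test_genome_minus <- function() {
  g <- make_test_genome()
  seq_rc <- as.character(
    Biostrings::reverseComplement(g$reference[[1]]))
  mirror <- function(d) {
    out <- data.frame(start = 141L - d$end, end = 141L - d$start)
    out[order(out$start), , drop = FALSE]
  }
  transcripts <- lapply(g$transcripts, function(tx) {
    tx$strand <- "-"
    tx$exons <- mirror(tx$exons)
    tx$cds <- mirror(tx$cds)
    tx
  })
  list(reference = Biostrings::DNAStringSet(c(chrT = seq_rc)),
       transcripts = transcripts, length = 140L)
}

variant_df <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
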