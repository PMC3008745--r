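#' Annotate variants against all overlapping transcript models
#'
#' Maps each substitution onto every transcript model that overlaps it and
#' classifies the coding consequence; loci under several transcripts yield
#' several annotations (a variant can change an amino acid in one transcript
#' and sit in the UTR of another), and variants under no transcript yield a
#' single intergenic record. Codon extraction is strand-aware: on the minus
#' strand codons are read from the reverse complement. The protein position
#' is the codon number, `ceiling(CDS offset / 3)`. Splice sites are the
#' `splice_window` intronic bases flanking each exon (2 by default).
#'
#' @param variants data frame with chrom, pos, ref, alt. The ref base must
#'   match the reference at pos — a mismatch is a hard error naming the site.
#' @param transcripts transcript models: the `transcripts` element of a
#'   [simulate_gene_models()] genome, or the result of [read_gene_models()].
#'   A `sim_genome` may be passed directly (its reference is then used).
#' @param reference a [Biostrings::DNAStringSet] holding the contigs named
#'   in the models; ignored when `transcripts` is a `sim_genome`.
#' @param splice_window intronic bases flanking each exon classified as
#'   splice_site.
#' @return data frame with one row per (variant, overlapping transcript):
#'   chrom, pos, ref, alt, gene_id, transcript_id, consequence, and for
#'   coding consequences ref_codon, alt_codon, ref_aa, alt_aa, protein_pos.
#' @export
annotate_variants <- function(variants, transcripts, reference = NULL,
                              splice_window = 2L) {
  if (inherits(transcripts, "sim_genome")) {
    reference <- transcripts$reference
    transcripts <- transcripts$transcripts
  }
  stopifnot(is.data.frame(variants), is.list(transcripts))
  if (is.null(reference))
    stop("a reference sequence is required")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants need columns: ", paste(need, collapse = ", "))
  if (!nrow(variants))
    return(empty_annotation())

  ref_chars <- lapply(stats::setNames(names(reference), names(reference)),
                      function(nm) strsplit(as.character(reference[[nm]]),
                                            "")[[1]])
  # reference consistency check up front
  for (i in seq_len(nrow(variants))) {
    chars <- ref_chars[[variants$chrom[i]]]
    if (is.null(chars) || variants$pos[i] > length(chars))
      stop("variant outside the reference: ",
           variants$chrom[i], ":", variants$pos[i])
    base <- chars[variants$pos[i]]
    if (base != variants$ref[i])
      stop(sprintf("reference mismatch at %s:%d (have %s, variant says %s)",
                   variants$chrom[i], variants$pos[i], base,
                   variants$ref[i]))
  }

  tx_info <- lapply(transcripts, prepare_transcript, ref_chars = ref_chars)
  tx_gr <- GenomicRanges::GRanges(
    seqnames = vapply(tx_info, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(tx_info, `[[`, numeric(1), "span_start"),
      end = vapply(tx_info, `[[`, numeric(1), "span_end")))
  var_gr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(var_gr, tx_gr)

  rows <- list()
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    i <- qh[k]
    rows[[length(rows) + 1L]] <- annotate_one(
      variants[i, , drop = FALSE], tx_info[[sh[k]]], splice_window,
      ref_chars)
  }
  no_hit <- setdiff(seq_len(nrow(variants)), unique(qh))
  for (i in no_hit) {
    r <- empty_annotation()[0, ]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = variants$chrom[i], pos = variants$pos[i],
      ref = variants$ref[i], alt = variants$alt[i],
      gene_id = NA_character_, transcript_id = NA_character_,
      consequence = "intergenic", ref_codon = NA_character_,
      alt_codon = NA_character_, ref_aa = NA_character_,
      alt_aa = NA_character_, protein_pos = NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$transcript_id,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_annotation <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), gene_id = character(0),
             transcript_id = character(0), consequence = character(0),
             ref_codon = character(0), alt_codon = character(0),
             ref_aa = character(0), alt_aa = character(0),
             protein_pos = integer(0), stringsAsFactors = FALSE)
}

# Precompute per-transcript lookup structures: exon table, spliced exonic
# positions in transcript (5'->3') order, CDS positions in the same order.
prepare_transcript <- function(tx, ref_chars) {
  exons <- tx$exons[order(tx$exons$start), , drop = FALSE]
  chrom <- if (!is.null(tx$chrom)) tx$chrom else names(ref_chars)[1]
  exon_pos <- unlist(lapply(seq_len(nrow(exons)),
                            function(r) exons$start[r]:exons$end[r]))
  cds <- tx$cds
  cds_pos <- if (nrow(cds))
    unlist(lapply(seq_len(nrow(cds)), function(r) cds$start[r]:cds$end[r]))
  else integer(0)
  if (identical(tx$strand, "-")) {
    exon_pos <- rev(exon_pos)
    cds_pos <- rev(cds_pos)
  }
  list(chrom = chrom, strand = tx$strand, gene_id = tx$gene_id,
       transcript_id = tx$transcript_id, exons = exons,
       exon_pos = exon_pos, cds_pos = cds_pos,
       span_start = min(exons$start), span_end = max(exons$end))
}

annotate_one <- function(v, tx, splice_window, ref_chars) {
  pos <- v$pos
  base_row <- data.frame(
    chrom = v$chrom, pos = pos, ref = v$ref, alt = v$alt,
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    consequence = NA_character_, ref_codon = NA_character_,
    alt_codon = NA_character_, ref_aa = NA_character_,
    alt_aa = NA_character_, protein_pos = NA_integer_,
    stringsAsFactors = FALSE)
  in_exon <- any(tx$exons$start <= pos & pos <= tx$exons$end)
  if (!in_exon) {
    near <- any((pos >= tx$exons$start - splice_window &
                   pos < tx$exons$start) |
                (pos > tx$exons$end &
                   pos <= tx$exons$end + splice_window))
    base_row$consequence <- if (near) "splice_site" else "intronic"
    return(base_row)
  }
  ci <- match(pos, tx$cds_pos)
  if (is.na(ci)) {
    # exonic non-coding: before the CDS in transcript orientation = 5' UTR
    mi <- match(pos, tx$exon_pos)
    first_cds_mi <- match(tx$cds_pos[1L], tx$exon_pos)
    base_row$consequence <- if (!length(tx$cds_pos) || mi < first_cds_mi)
      "utr5" else "utr3"
    return(base_row)
  }
  codon_number <- (ci - 1L) %/% 3L + 1L
  off <- (ci - 1L) %% 3L + 1L
  codon_gpos <- tx$cds_pos[(codon_number - 1L) * 3L + 1:3]
  chars <- ref_chars[[tx$chrom]]
  codon_bases <- chars[codon_gpos]
  alt_base <- v$alt
  if (identical(tx$strand, "-")) {
    codon_bases <- unname(COMPLEMENT[codon_bases])
    alt_base <- COMPLEMENT[[alt_base]]
  }
  ref_codon <- paste(codon_bases, collapse = "")
  alt_bases <- codon_bases
  alt_bases[off] <- alt_base
  alt_codon <- paste(alt_bases, collapse = "")
  ref_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(ref_codon), no.init.codon = TRUE))
  alt_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(alt_codon), no.init.codon = TRUE))
  consequence <- if (ref_aa == "*" && alt_aa != "*") "stop_lost"
    else if (alt_aa == "*" && ref_aa != "*") "nonsense"
    else if (codon_number == 1L && alt_codon != "ATG") "start_lost"
    else if (ref_aa == alt_aa) "synonymous"
    else "missense"
  base_row$consequence <- consequence
  base_row$ref_codon <- ref_codon
  base_row$alt_codon <- alt_codon
  base_row$ref_aa <- ref_aa
  base_row$alt_aa <- alt_aa
  base_row$protein_pos <- codon_number
  base_row
}

#' Flag variants falling inside miRNA intervals
#'
#' @param variants data frame with chrom and pos.
#' @param mirna_intervals data frame with chrom, start, end (1-based,
#'   inclusive); may be empty.
#' @return logical vector, one flag per variant.
#' @export
classify_mirna <- function(variants, mirna_intervals) {
  stopifnot(is.data.frame(variants))
  if (is.null(mirna_intervals) || !nrow(mirna_intervals))
    return(rep(FALSE, nrow(variants)))
  mi_gr <- GenomicRanges::GRanges(
    seqnames = mirna_intervals$chrom,
    ranges = IRanges::IRanges(start = mirna_intervals$start,
                              end = mirna_intervals$end))
  var_gr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L))
  GenomicRanges::countOverlaps(var_gr, mi_gr) > 0L
}
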