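#' Tab-separated interchange helpers
#'
#' All tabular artifacts (pileups, truth, side tables, reports) travel as
#' plain TSV with a header and no quoting.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_tsv_file` returns a data frame; writers return the path,
#'   invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_tsv_file
#' @export
write_pileup <- function(x, path) {
  check_pileup(x)
  write_tsv_file(x[, PILEUP_COLUMNS], path)
}

#' @rdname write_tsv_file
#' @export
read_pileup <- function(path) {
  check_pileup(read_tsv_file(path))
}

#' Write calls as a minimal VCF v4.2 subset
#'
#' One record per call with CHROM, POS, ID ".", REF, ALT, QUAL ".",
#' FILTER ".", and INFO keys DP (coverage), AD (variant reads), RULE
#' (evidence branch) and, when a `status` column is present, SS in
#' SOMATIC / GERMLINE / UNDET.
#'
#' @param calls data frame from [call_variants()] or [classify_somatic()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total coverage\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
    "##INFO=<ID=RULE,Number=1,Type=String,Description=\"Evidence rule (strand|quality)\">",
    "##INFO=<ID=SS,Number=1,Type=String,Description=\"Somatic status (SOMATIC|GERMLINE|UNDET)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    info <- sprintf("DP=%d;AD=%d", calls$coverage, calls$alt_reads)
    if (!is.null(calls$rule))
      info <- paste0(info, ";RULE=", calls$rule)
    if (!is.null(calls$status)) {
      ss <- c(somatic = "SOMATIC", germline = "GERMLINE",
              undetermined = "UNDET")[calls$status]
      info <- paste0(info, ";SS=", ss)
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                       calls$chrom, calls$pos, calls$ref, calls$alt, info),
               con)
  }
  invisible(path)
}

#' Write / read the simulated genome
#'
#' The reference goes out as FASTA (via Biostrings) and the gene models as a
#' GFF3 subset with gene, mRNA, exon, CDS and miRNA features (via
#' rtracklayer). `read_gene_models` reconstructs the transcript structures
#' used by [annotate_variants()] from such a GFF3 file.
#'
#' @param genome a `sim_genome` from [simulate_gene_models()].
#' @param path output/input path.
#' @return writers return the path invisibly; `read_gene_models` returns a
#'   list of transcript models (exons, CDS, strand, ids, chrom).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$reference, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
write_gene_models_gff3 <- function(genome, path) {
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$seqid,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$type
  S4Vectors::mcols(gr)$ID <- f$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(f$Parent), NA_character_,
                                        f$Parent)
  # CDS phase: bases to skip before the first complete codon of each chunk
  phase <- rep(NA_integer_, nrow(f))
  for (tx in unique(f$transcript_id[f$type == "CDS"])) {
    rows <- which(f$type == "CDS" & f$transcript_id == tx)
    rows <- rows[order(f$start[rows],
                       decreasing = identical(f$strand[rows][1], "-"))]
    lens <- f$end[rows] - f$start[rows] + 1L
    before <- c(0L, cumsum(lens)[-length(lens)])
    phase[rows] <- (3L - before %% 3L) %% 3L
  }
  S4Vectors::mcols(gr)$phase <- phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(mrna))) {
    tx_id <- mrna$ID[i]
    ex <- df[df$type == "exon" & df$Parent == tx_id, , drop = FALSE]
    cd <- df[df$type == "CDS" & df$Parent == tx_id, , drop = FALSE]
    out[[tx_id]] <- list(
      gene_id = mrna$Parent[i], transcript_id = tx_id,
      strand = as.character(mrna$strand[i]),
      chrom = as.character(mrna$seqnames[i]),
      exons = ex[order(ex$start), c("start", "end"), drop = FALSE],
      cds = cd[order(cd$start), c("start", "end"), drop = FALSE])
  }
  out
}

#' Write CNV segments as BED
#'
#' 0-based half-open intervals; the BED name column carries the state and
#' the score column the mean centered log2 ratio.
#'
#' @param segments segment table from [call_states()].
#' @param path output path.
#' @param bin_size bin width in bp used to convert bin indices to
#'   coordinates.
#' @return the path, invisibly.
#' @export
write_segments_bed <- function(segments, path, bin_size) {
  if (!nrow(segments)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(
      start = (segments$start_bin - 1L) * bin_size + 1L,
      end = segments$end_bin * bin_size))
  S4Vectors::mcols(gr)$name <- segments$state
  S4Vectors::mcols(gr)$score <- segments$mean_ratio
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
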