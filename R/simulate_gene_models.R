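#' Simulate a reference sequence with transcript models
#'
#' Builds a small single-contig genome containing `n_genes` non-overlapping
#' genes separated by intergenic spacers. Every transcript has exons and a
#' CDS that starts with ATG, ends with a stop codon, contains no internal
#' stop, and has length divisible by 3; introns carry canonical GT..AG
#' dinucleotides; strands alternate so both orientations are exercised. One
#' locus carries two transcripts that disagree — the second transcript's CDS
#' is a small open reading frame inside the first transcript's 3' UTR, so
#' the same base is CDS in one transcript and UTR in the other. Two miRNA
#' intervals are planted in intergenic spacers.
#'
#' The returned object keeps, besides the reference and the feature table, a
#' per-base bookkeeping map (region class, codon, in-codon offset, strand per
#' overlapping transcript) from which [simulate_pair()] derives truth
#' consequence classes by direct codon arithmetic — an accounting path
#' independent of the sequence-extraction path used by [annotate_variants()].
#'
#' @param config a [simulation_config()]; uses `n_genes` and `seed`.
#' @return an object of class `sim_genome`: list with `reference`
#'   (a [Biostrings::DNAStringSet] of one contig), `features` (GFF3-style
#'   data frame: gene/mRNA/exon/CDS/miRNA rows), `transcripts` (per-transcript
#'   exon and CDS genomic intervals), `mirna` (interval data frame),
#'   `gene_map`, `map` (per-base truth bookkeeping), `length`, `seqname`.
#' @examples
#' genome <- simulate_gene_models(simulation_config(n_genes = 4, seed = 7))
#' subset(genome$features, type == "gene")
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream(config$seed, 3L), simulate_gene_models_impl(config))
}

SENSE_CODONS <- {
  all_codons <- as.vector(outer(
    as.vector(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0)),
    c("T", "C", "A", "G"),
    function(ab, c) paste0(substr(ab, 1, 1), substr(ab, 2, 2), c)))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_bases <- function(n) paste(sample(BASES, n, replace = TRUE),
                                  collapse = "")

# Random CDS: ATG + sense codons + stop. `plant_atg_at` optionally forces a
# Met codon at that codon index (for the shared-exon second transcript).
random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

simulate_gene_models_impl <- function(config) {
  n_genes <- config$n_genes
  dual_gene <- if (n_genes >= 2L) 2L else 1L
  pieces <- character(0)
  map_rows <- list()        # per-gene local maps, later shifted to genomic
  features <- list()
  transcripts <- list()
  gene_spans <- list()
  offset <- 0L
  seqname <- "sim1"

  spacer0 <- 150L + sample.int(100L, 1L)
  pieces <- c(pieces, random_bases(spacer0))
  offset <- offset + spacer0

  mirna <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = character(0))

  for (g in seq_len(n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("gene_%04d", g)
    gm <- build_gene(gene_id, strand, dual = (g == dual_gene))
    glen <- nchar(gm$local_seq)
    if (strand == "+") {
      pieces <- c(pieces, gm$local_seq)
      to_genomic <- function(l) offset + l
    } else {
      pieces <- c(pieces, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gm$local_seq))))
      to_genomic <- function(l) offset + (glen - l + 1L)
    }
    # per-base map in genomic coordinates
    lm <- gm$map
    lm$gpos <- to_genomic(lm$lpos)
    map_rows[[g]] <- lm
    gene_spans[[g]] <- data.frame(gene_id = gene_id,
                                  start = offset + 1L, end = offset + glen)
    # features: local intervals -> genomic (flip for minus strand)
    fx <- gm$features
    gstart <- pmin(to_genomic(fx$lstart), to_genomic(fx$lend))
    gend <- pmax(to_genomic(fx$lstart), to_genomic(fx$lend))
    fx$start <- gstart; fx$end <- gend
    fx$strand <- strand
    fx$seqid <- seqname
    features[[g]] <- fx[, c("seqid", "type", "start", "end", "strand",
                            "ID", "Parent", "gene_id", "transcript_id")]
    for (tx in gm$tx_ids) {
      ex <- fx[fx$type == "exon" & fx$transcript_id == tx, c("start", "end")]
      cd <- fx[fx$type == "CDS" & fx$transcript_id == tx, c("start", "end")]
      transcripts[[tx]] <- list(
        gene_id = gene_id, transcript_id = tx, strand = strand,
        exons = ex[order(ex$start), , drop = FALSE],
        cds = cd[order(cd$start), , drop = FALSE])
    }
    offset <- offset + glen

    spacer <- 150L + sample.int(100L, 1L)
    sp_seq <- random_bases(spacer)
    # plant a miRNA hairpin interval inside the first two spacers
    if (g <= 2L) {
      mi_start <- offset + 60L
      mi_end <- mi_start + 21L
      mirna <- rbind(mirna, data.frame(
        chrom = seqname, start = mi_start, end = mi_end,
        id = sprintf("mir_%02d", g)))
    }
    pieces <- c(pieces, sp_seq)
    offset <- offset + spacer
  }

  genome_seq <- paste(pieces, collapse = "")
  glen_total <- nchar(genome_seq)

  # assemble the per-base truth map
  map <- list(
    region1 = rep("intergenic", glen_total),
    codon1 = rep(NA_character_, glen_total),
    off1 = rep(NA_integer_, glen_total),
    cdspos1 = rep(NA_integer_, glen_total),
    strand1 = rep(NA_character_, glen_total),
    region2 = rep(NA_character_, glen_total),
    codon2 = rep(NA_character_, glen_total),
    off2 = rep(NA_integer_, glen_total),
    cdspos2 = rep(NA_integer_, glen_total),
    strand2 = rep(NA_character_, glen_total)
  )
  gene_map <- rep(NA_character_, glen_total)
  for (g in seq_len(n_genes)) {
    lm <- map_rows[[g]]
    i <- lm$gpos
    map$region1[i] <- lm$region1
    map$codon1[i] <- lm$codon1
    map$off1[i] <- lm$off1
    map$cdspos1[i] <- lm$cdspos1
    map$strand1[i] <- lm$strand1
    map$region2[i] <- lm$region2
    map$codon2[i] <- lm$codon2
    map$off2[i] <- lm$off2
    map$cdspos2[i] <- lm$cdspos2
    map$strand2[i] <- lm$strand2
    sp <- gene_spans[[g]]
    gene_map[sp$start:sp$end] <- sp$gene_id
  }
  for (k in seq_len(nrow(mirna)))
    map$region1[mirna$start[k]:mirna$end[k]] <- "mirna"

  features_df <- do.call(rbind, features)
  mi_feat <- data.frame(seqid = seqname, type = "miRNA",
                        start = mirna$start, end = mirna$end, strand = "+",
                        ID = mirna$id, Parent = NA_character_,
                        gene_id = NA_character_,
                        transcript_id = NA_character_)
  features_df <- rbind(features_df, mi_feat)
  rownames(features_df) <- NULL

  structure(list(
    reference = Biostrings::DNAStringSet(stats::setNames(genome_seq, seqname)),
    features = features_df,
    transcripts = transcripts,
    mirna = mirna,
    gene_map = gene_map,
    map = map,
    length = glen_total,
    seqname = seqname
  ), class = "sim_genome")
}

# Construct one gene on a local, transcript-oriented axis (1 = 5' end of the
# primary transcript). Returns the local sequence, per-base map rows, and
# feature intervals in local coordinates.
build_gene <- function(gene_id, strand, dual = FALSE) {
  utr5_len <- sample(30:60, 1L)
  n_codons <- sample(40:80, 1L)
  cds <- random_cds(n_codons)
  cds_len <- nchar(cds)
  if (dual) {
    # 3' UTR carries a small independent ORF: transcript B's CDS
    orf_codons <- sample(12:20, 1L)
    orf <- random_cds(orf_codons)
    pre <- sample(5:12, 1L); post <- sample(25:45, 1L)
    utr3 <- paste0(random_bases(pre), orf, random_bases(post))
    orf_lstart <- utr5_len + cds_len + pre + 1L
    orf_llen <- nchar(orf)
  } else {
    utr3 <- random_bases(sample(40:80, 1L))
  }
  utr3_len <- nchar(utr3)
  mrna <- paste0(random_bases(utr5_len), cds, utr3)
  mrna_len <- nchar(mrna)

  # split the mRNA into exons with 1-2 introns
  n_introns <- sample(1:2, 1L)
  splits <- sort(sample(20:(mrna_len - 20L), n_introns))
  while (n_introns == 2L && diff(splits) < 25L)
    splits <- sort(sample(20:(mrna_len - 20L), n_introns))
  exon_bounds <- cbind(c(1L, splits + 1L), c(splits, mrna_len))

  # build local gene sequence: exons interleaved with GT..AG introns;
  # record, for every local base, its mRNA index (NA inside introns)
  seq_parts <- character(0)
  mrna_chars <- strsplit(mrna, "")[[1]]
  lpos_region <- character(0)
  lpos_mrna_index <- integer(0)
  for (e in seq_len(nrow(exon_bounds))) {
    a <- exon_bounds[e, 1L]; b <- exon_bounds[e, 2L]
    seq_parts <- c(seq_parts, paste(mrna_chars[a:b], collapse = ""))
    lpos_region <- c(lpos_region, rep("exon", b - a + 1L))
    lpos_mrna_index <- c(lpos_mrna_index, a:b)
    if (e < nrow(exon_bounds)) {
      ilen <- sample(30:50, 1L)
      intron <- paste0("GT", random_bases(ilen - 4L), "AG")
      seq_parts <- c(seq_parts, intron)
      ireg <- rep("intronic", ilen)
      ireg[c(1L, 2L, ilen - 1L, ilen)] <- "splice_site"
      lpos_region <- c(lpos_region, ireg)
      lpos_mrna_index <- c(lpos_mrna_index, rep(NA_integer_, ilen))
    }
  }
  local_seq <- paste(seq_parts, collapse = "")
  glen <- nchar(local_seq)

  # transcript A regions by mRNA index
  classify_A <- function(mi) {
    ifelse(is.na(mi), NA_character_,
           ifelse(mi <= utr5_len, "utr5",
                  ifelse(mi <= utr5_len + cds_len, "cds", "utr3")))
  }
  regA <- classify_A(lpos_mrna_index)
  region1 <- ifelse(lpos_region == "exon", regA, lpos_region)
  cdsposA <- ifelse(!is.na(regA) & regA == "cds",
                    lpos_mrna_index - utr5_len, NA_integer_)
  codon_index <- (cdsposA - 1L) %/% 3L
  off1 <- ifelse(is.na(cdsposA), NA_integer_, (cdsposA - 1L) %% 3L + 1L)
  codon1 <- rep(NA_character_, glen)
  in_cds <- which(!is.na(cdsposA))
  if (length(in_cds))
    codon1[in_cds] <- substr(rep(cds, length(in_cds)),
                             codon_index[in_cds] * 3L + 1L,
                             codon_index[in_cds] * 3L + 3L)
  strand1 <- rep(strand, glen)
  strand1[region1 %in% c(NA_character_)] <- NA_character_

  tx_a <- paste0(gene_id, ".t1")
  tx_ids <- tx_a

  region2 <- rep(NA_character_, glen)
  codon2 <- rep(NA_character_, glen)
  off2 <- rep(NA_integer_, glen)
  cdspos2 <- rep(NA_integer_, glen)
  strand2 <- rep(NA_character_, glen)
  if (dual) {
    # transcript B shares the exons; its CDS is the planted 3'-UTR ORF
    orf_lend <- orf_lstart + orf_llen - 1L
    mi <- lpos_mrna_index
    regB <- ifelse(is.na(mi), NA_character_,
                   ifelse(mi < orf_lstart, "utr5",
                          ifelse(mi <= orf_lend, "cds", "utr3")))
    region2 <- ifelse(lpos_region == "exon", regB, lpos_region)
    cdsposB <- ifelse(!is.na(regB) & regB == "cds",
                      mi - orf_lstart + 1L, NA_integer_)
    codon_iB <- (cdsposB - 1L) %/% 3L
    off2 <- ifelse(is.na(cdsposB), NA_integer_, (cdsposB - 1L) %% 3L + 1L)
    inB <- which(!is.na(cdsposB))
    if (length(inB))
      codon2[inB] <- substr(rep(orf, length(inB)),
                            codon_iB[inB] * 3L + 1L,
                            codon_iB[inB] * 3L + 3L)
    cdspos2 <- cdsposB
    strand2 <- ifelse(is.na(region2), NA_character_, strand)
    tx_b <- paste0(gene_id, ".t2")
    tx_ids <- c(tx_a, tx_b)
  }

  # feature intervals in local coordinates
  feats <- list()
  add_feat <- function(type, lstart, lend, id, parent, tx) {
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, lstart = lstart, lend = lend, ID = id, Parent = parent,
      gene_id = gene_id, transcript_id = tx, stringsAsFactors = FALSE)
  }
  add_feat("gene", 1L, glen, gene_id, NA_character_, NA_character_)
  local_of_mrna <- match(seq_len(mrna_len), lpos_mrna_index)
  runs_of <- function(mrna_lo, mrna_hi) {
    # contiguous local runs covering an mRNA interval (split at introns)
    lp <- local_of_mrna[mrna_lo:mrna_hi]
    brk <- c(TRUE, diff(lp) != 1L)
    grp <- cumsum(brk)
    do.call(rbind, lapply(split(lp, grp), function(v)
      data.frame(lstart = v[1L], lend = v[length(v)])))
  }
  for (t in seq_along(tx_ids)) {
    tx <- tx_ids[t]
    add_feat("mRNA", 1L, glen, tx, gene_id, tx)
    for (r in seq_len(nrow(exon_bounds)))
      add_feat("exon", local_of_mrna[exon_bounds[r, 1L]],
               local_of_mrna[exon_bounds[r, 2L]],
               sprintf("%s.exon%d", tx, r), tx, tx)
    cds_rng <- if (t == 1L) c(utr5_len + 1L, utr5_len + cds_len)
               else c(orf_lstart, orf_lend)
    cr <- runs_of(cds_rng[1L], cds_rng[2L])
    for (r in seq_len(nrow(cr)))
      add_feat("CDS", cr$lstart[r], cr$lend[r],
               sprintf("%s.cds%d", tx, r), tx, tx)
  }
  features <- do.call(rbind, feats)

  list(
    local_seq = local_seq,
    features = features,
    tx_ids = tx_ids,
    map = data.frame(
      lpos = seq_len(glen), region1 = region1, codon1 = codon1, off1 = off1,
      cdspos1 = cdsposA, strand1 = strand1, region2 = region2,
      codon2 = codon2, off2 = off2, cdspos2 = cdspos2, strand2 = strand2,
      stringsAsFactors = FALSE)
  )
}

# Severity ranking used wherever one consequence per variant is needed.
CONSEQUENCE_SEVERITY <- c(
  "nonsense", "start_lost", "stop_lost", "missense", "splice_site",
  "utr5", "utr3", "synonymous", "mirna", "intronic", "intergenic")

#' Pick the most severe consequence of a set
#'
#' Severity order (most to least): nonsense, start_lost, stop_lost, missense,
#' splice_site, 5' UTR, 3' UTR, synonymous, miRNA, intronic, intergenic.
#'
#' @param classes character vector of consequence classes.
#' @return the single most severe class.
#' @export
most_severe_consequence <- function(classes) {
  classes <- classes[!is.na(classes)]
  if (!length(classes)) return(NA_character_)
  CONSEQUENCE_SEVERITY[min(match(classes, CONSEQUENCE_SEVERITY))]
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Consequence of substituting `alt` at a CDS base described by the map slot.
codon_consequence <- function(codon, off, cdspos, strand, alt) {
  alt_t <- if (!is.na(strand) && strand == "-") COMPLEMENT[[alt]] else alt
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_t
  ref_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(codon), no.init.codon = TRUE))
  alt_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(alt_codon), no.init.codon = TRUE))
  if (ref_aa == "*" && alt_aa != "*") return("stop_lost")
  if (alt_aa == "*" && ref_aa != "*") return("nonsense")
  if (cdspos <= 3L && alt_codon != "ATG") return("start_lost")
  if (ref_aa == alt_aa) "synonymous" else "missense"
}

# Truth consequence from the generator's per-base bookkeeping: evaluate each
# overlapping transcript slot, then take the most severe class.
truth_consequence <- function(genome, pos, alt) {
  m <- genome$map
  vapply(seq_along(pos), function(i) {
    p <- pos[i]
    out <- character(0)
    for (slot in 1:2) {
      reg <- m[[paste0("region", slot)]][p]
      if (is.na(reg)) next
      if (reg == "cds") {
        out <- c(out, codon_consequence(
          m[[paste0("codon", slot)]][p], m[[paste0("off", slot)]][p],
          m[[paste0("cdspos", slot)]][p], m[[paste0("strand", slot)]][p],
          alt[i]))
      } else {
        out <- c(out, reg)
      }
    }
    if (!length(out)) "intergenic" else most_severe_consequence(out)
  }, character(1))
}
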