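#' Simulate a tumor/normal pileup pair with ground truth
#'
#' Draws per-site read evidence for a matched tumor/normal exome pair under
#' binomial read sampling. Coverage at each site is Poisson around the
#' configured mean; variant-supporting reads are binomial with allele
#' fraction 0.5 (heterozygous) or 1 (homozygous), scaled by `tumor_purity`
#' for somatic sites; reference reads are misread as the alternative base
#' with probability `error_rate`; read strands are assigned with probability
#' 0.5 each. Somatic substitutions are planted only on a germline-reference
#' background, so no site is both germline- and somatic-variant at the same
#' allele.
#'
#' When `genome` (from [simulate_gene_models()]) is supplied, sites are
#' sampled from the simulated reference and the truth consequence class is
#' derived from the generator's own per-base gene-model bookkeeping;
#' otherwise sites live on an abstract contig and consequence classes are
#' drawn from a fixed categorical distribution dominated by missense changes.
#'
#' @param config a [simulation_config()] object.
#' @param genome optional genome from [simulate_gene_models()].
#' @return a list with elements `tumor`, `normal` (pileup data frames with
#'   columns chrom, pos, ref, alt, ref_fwd, ref_rev, alt_fwd, alt_rev,
#'   max_alt_quality, homopolymer_len) and `truth` (one row per site:
#'   genotypes, `is_somatic`, `consequence_class`, gene id and the annotation
#'   truth flags `frequent`, `damaging`, `conserved`, `expressed`).
#' @examples
#' sim <- simulate_pair(simulation_config(n_sites = 500, somatic_rate = 0.01))
#' table(sim$truth$is_somatic)
#' @export
simulate_pair <- function(config, genome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(substream(config$seed, 1L), simulate_pair_impl(config, genome))
}

# Fixed categorical consequence distribution for abstract-contig mode;
# weighted towards missense as in exome substitution spectra.
CONSEQUENCE_CLASS_PROBS <- c(
  missense = 0.650, synonymous = 0.150, nonsense = 0.040,
  utr3 = 0.040, utr5 = 0.030, splice_site = 0.005,
  intronic = 0.045, intergenic = 0.030, mirna = 0.005,
  start_lost = 0.0025, stop_lost = 0.0025
)

BASES <- c("A", "C", "G", "T")

simulate_pair_impl <- function(config, genome) {
  n <- config$n_sites
  if (is.null(genome)) {
    chrom <- rep("sim1", n)
    pos <- seq_len(n)
    ref <- sample(BASES, n, replace = TRUE)
    gene_id <- sprintf("gene_%04d",
                       ((seq_len(n) - 1L) %/% config$gene_site_block) + 1L)
  } else {
    glen <- genome$length
    if (n > glen)
      stop("n_sites exceeds the simulated genome length")
    chrom <- rep(genome$seqname, n)
    pos <- sort(sample.int(glen, n))
    ref <- strsplit(as.character(
      Biostrings::subseq(genome$reference[[1]], 1, glen)), "")[[1]][pos]
    gene_id <- genome$gene_map[pos]
  }
  # alternative base differs from reference by construction
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
  names(alt) <- NULL

  u <- stats::runif(n)
  normal_genotype <- ifelse(u < config$heterozygosity_rate, "het",
                     ifelse(u < config$heterozygosity_rate + config$hom_alt_rate,
                            "alt-hom", "ref-hom"))
  is_somatic <- normal_genotype == "ref-hom" &
    stats::runif(n) < config$somatic_rate
  tumor_genotype <- ifelse(is_somatic, "het", normal_genotype)

  af_normal <- c("ref-hom" = 0, "het" = 0.5, "alt-hom" = 1)[normal_genotype]
  af_tumor <- af_normal
  af_tumor[is_somatic] <- 0.5 * config$tumor_purity

  tumor <- draw_pileup(chrom, pos, ref, alt, config$mean_coverage_tumor,
                       af_tumor, config)
  normal <- draw_pileup(chrom, pos, ref, alt, config$mean_coverage_normal,
                        af_normal, config)
  # the two samples share one locus, hence one homopolymer context
  normal$homopolymer_len <- tumor$homopolymer_len

  variant_site <- normal_genotype != "ref-hom" | is_somatic
  if (is.null(genome)) {
    consequence_class <- rep(NA_character_, n)
    consequence_class[variant_site] <- sample(
      names(CONSEQUENCE_CLASS_PROBS), sum(variant_site), replace = TRUE,
      prob = CONSEQUENCE_CLASS_PROBS)
  } else {
    consequence_class <- rep(NA_character_, n)
    idx <- which(variant_site)
    consequence_class[idx] <- truth_consequence(genome, pos[idx], alt[idx])
    gene_id[is.na(gene_id)] <- NA_character_
  }

  frequent <- variant_site & stats::runif(n) < config$frequent_fraction
  damaging <- variant_site & stats::runif(n) < config$damaging_fraction
  conserved <- variant_site & stats::runif(n) < config$conserved_fraction

  genes <- unique(gene_id[!is.na(gene_id)])
  gene_expressed <- stats::setNames(
    stats::runif(length(genes)) < config$expressed_fraction, genes)
  expressed <- ifelse(is.na(gene_id), FALSE, unname(gene_expressed[gene_id]))

  truth <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene_id = gene_id,
    normal_genotype = normal_genotype, tumor_genotype = tumor_genotype,
    is_somatic = is_somatic, consequence_class = consequence_class,
    frequent = frequent, damaging = damaging, conserved = conserved,
    expressed = expressed, stringsAsFactors = FALSE
  )
  list(tumor = tumor, normal = normal, truth = truth)
}

# Draw one sample's pileup rows given per-site true allele fractions.
draw_pileup <- function(chrom, pos, ref, alt, mean_coverage, af, config) {
  n <- length(pos)
  coverage <- stats::rpois(n, mean_coverage)
  true_alt <- stats::rbinom(n, coverage, af)
  err_alt <- stats::rbinom(n, coverage - true_alt, config$error_rate)
  alt_reads <- true_alt + err_alt
  ref_reads <- coverage - alt_reads
  alt_fwd <- stats::rbinom(n, alt_reads, 0.5)
  ref_fwd <- stats::rbinom(n, ref_reads, 0.5)
  # max of alt_reads draws from a two-point quality mixture: equals the high
  # value unless every supporting read drew the low one
  all_low <- stats::runif(n) < (1 - config$quality_p_high)^alt_reads
  max_alt_quality <- ifelse(alt_reads == 0L, 0,
                            ifelse(all_low, config$quality_low,
                                   config$quality_high))
  homopolymer_len <- 1L + stats::rgeom(n, config$homopolymer_p)
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    ref_fwd = ref_fwd, ref_rev = ref_reads - ref_fwd,
    alt_fwd = alt_fwd, alt_rev = alt_reads - alt_fwd,
    max_alt_quality = max_alt_quality,
    homopolymer_len = homopolymer_len,
    stringsAsFactors = FALSE
  )
}
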