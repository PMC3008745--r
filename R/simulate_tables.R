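#' Simulate annotation side-tables consistent with truth flags
#'
#' Produces the external evidence the prioritization cascade joins against:
#' a population allele-frequency table (common polymorphisms above 0.01 for
#' truth-frequent sites, plus rare sub-0.01 entries for a fifth of the
#' remaining variant sites), per-site damaging-prediction flags from two
#' simulated predictors, per-base conservation scores (background normal with
#' its 0.975 quantile at 2.0; truth-conserved variant sites drawn at or above
#' 2.0), a gene expression matrix, and gene-category / catalogue sets.
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [simulate_pair()].
#' @return list with elements `frequency` (chrom, pos, frequency), `damaging`
#'   (chrom, pos, damaging_polyphen, damaging_mutationtaster), `conservation`
#'   (chrom, pos, score; all sites), `expression` (gene + one column per
#'   sample), `categories` and `catalogues` (named lists of gene-id vectors).
#' @export
simulate_annotation_tables <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  with_seed(substream(config$seed, 2L),
            simulate_annotation_tables_impl(config, truth))
}

simulate_annotation_tables_impl <- function(config, truth) {
  if (nrow(truth) == 0L) {
    empty_sites <- data.frame(chrom = character(0), pos = integer(0))
    return(list(
      frequency = cbind(empty_sites, frequency = numeric(0)),
      damaging = cbind(empty_sites, damaging_polyphen = logical(0),
                       damaging_mutationtaster = logical(0)),
      conservation = cbind(empty_sites, score = numeric(0)),
      expression = data.frame(gene = character(0)),
      categories = list(repair = character(0), kinase = character(0),
                        receptor = character(0),
                        transmembrane_receptor = character(0)),
      catalogues = list(cancer_census = character(0),
                        prior_study = character(0))
    ))
  }
  variant <- truth$normal_genotype != "ref-hom" | truth$is_somatic

  # population frequency: common entries for truth-frequent sites, rare
  # (<0.01) entries for a random fifth of the other variant sites
  freq_common <- truth[variant & truth$frequent, c("chrom", "pos")]
  if (nrow(freq_common))
    freq_common$frequency <- stats::runif(nrow(freq_common), 0.011, 0.5)
  rare_pool <- truth[variant & !truth$frequent, c("chrom", "pos")]
  rare_pick <- rare_pool[stats::runif(nrow(rare_pool)) < 0.2, , drop = FALSE]
  if (nrow(rare_pick))
    rare_pick$frequency <- stats::runif(nrow(rare_pick), 0, 0.009)
  frequency <- rbind(
    if (nrow(freq_common)) freq_common else NULL,
    if (nrow(rare_pick)) rare_pick else NULL)
  if (is.null(frequency))
    frequency <- data.frame(chrom = character(0), pos = integer(0),
                            frequency = numeric(0))
  frequency <- frequency[order(frequency$chrom, frequency$pos), ,
                         drop = FALSE]
  rownames(frequency) <- NULL

  # damaging flags: truth-damaging sites get at least one of two predictors
  dm <- truth[variant, c("chrom", "pos")]
  dtruth <- truth$damaging[variant]
  pattern <- sample(c("A", "B", "AB"), nrow(dm), replace = TRUE,
                    prob = c(0.3, 0.3, 0.4))
  dm$damaging_polyphen <- dtruth & pattern %in% c("A", "AB")
  dm$damaging_mutationtaster <- dtruth & pattern %in% c("B", "AB")
  rownames(dm) <- NULL

  # conservation: background scores whose 0.975 quantile sits at 2.0;
  # variant-site scores overridden to match the truth conserved flag
  sd_bg <- 2 / stats::qnorm(0.975)
  cons <- data.frame(chrom = truth$chrom, pos = truth$pos,
                     score = stats::rnorm(nrow(truth), 0, sd_bg))
  vc <- which(variant & truth$conserved)
  vn <- which(variant & !truth$conserved)
  cons$score[vc] <- stats::runif(length(vc), 2.0, 4.0)
  cons$score[vn] <- stats::runif(length(vn), -2.0, 1.95)

  # expression: per-gene means separated around a nominal threshold of 10
  genes <- unique(truth$gene_id[!is.na(truth$gene_id)])
  gene_expressed <- vapply(genes, function(g)
    any(truth$expressed[truth$gene_id == g], na.rm = TRUE), logical(1))
  mean_expr <- ifelse(gene_expressed,
                      10 * (1 + stats::rexp(length(genes), 2)),
                      stats::runif(length(genes), 1, 9.5))
  ns <- config$n_expression_samples
  expr <- matrix(stats::rnorm(length(genes) * ns, mean_expr, 0.5),
                 nrow = length(genes))
  expression <- data.frame(gene = genes, expr)
  names(expression)[-1L] <- sprintf("sample_%d", seq_len(ns))
  rownames(expression) <- NULL

  categories <- list(
    repair = genes[stats::runif(length(genes)) < 0.08],
    kinase = genes[stats::runif(length(genes)) < 0.08],
    receptor = genes[stats::runif(length(genes)) < 0.08],
    transmembrane_receptor = genes[stats::runif(length(genes)) < 0.05])
  catalogues <- list(
    cancer_census = genes[stats::runif(length(genes)) < 0.39],
    prior_study = genes[stats::runif(length(genes)) < 0.2])

  list(frequency = frequency, damaging = dm, conservation = cons,
       expression = expression, categories = categories,
       catalogues = catalogues)
}

#' Simulate binned read counts with planted copy-number segments
#'
#' Normal-tissue counts are Poisson around `cnv_base_rate`; tumor counts are
#' Poisson with the rate multiplied by `2^log2_effect` inside each planted
#' segment. Overlapping planted segments are rejected at config validation.
#'
#' @param config a [simulation_config()]; uses `bin_count`, `bin_size`,
#'   `cnv_base_rate`, `planted_segments`, `seed`.
#' @return list with `counts` (chrom, bin, bin_start, tumor_count,
#'   normal_count) and `truth_segments` (start, end, log2_effect).
#' @export
simulate_cnv_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(substream(config$seed, 4L), {
    nb <- config$bin_count
    rate <- rep(config$cnv_base_rate, nb)
    tumor_rate <- rate
    for (seg in config$planted_segments)
      tumor_rate[seg$start:seg$end] <-
        tumor_rate[seg$start:seg$end] * 2^seg$log2_effect
    counts <- data.frame(
      chrom = "sim1",
      bin = seq_len(nb),
      bin_start = (seq_len(nb) - 1L) * config$bin_size,
      tumor_count = stats::rpois(nb, tumor_rate),
      normal_count = stats::rpois(nb, rate))
    truth_segments <- if (length(config$planted_segments)) {
      do.call(rbind, lapply(config$planted_segments, function(s)
        data.frame(start = s$start, end = s$end,
                   log2_effect = s$log2_effect)))
    } else {
      data.frame(start = integer(0), end = integer(0),
                 log2_effect = numeric(0))
    }
    list(counts = counts, truth_segments = truth_segments)
  })
}

#' Simulate array-style genotype calls from truth
#'
#' Emulates a genotyping-array side-channel used as the concordance
#' standard: genotypes are copied from the truth table's normal genotypes
#' (optionally perturbed at `error_rate`) and each position receives a
#' quality p-value drawn from Beta(1, 19), so most, but not all, positions
#' pass the p < 0.1 eligibility filter.
#'
#' @param truth truth table from [simulate_pair()].
#' @param seed RNG seed.
#' @param error_rate probability an array genotype is perturbed to a
#'   different state.
#' @return data frame: chrom, pos, genotype, quality_p.
#' @export
simulate_array_genotypes <- function(truth, seed = 1L, error_rate = 0) {
  stopifnot(is.data.frame(truth))
  with_seed(substream(seed, 5L), {
    gt <- truth$normal_genotype
    if (error_rate > 0) {
      flip <- stats::runif(nrow(truth)) < error_rate
      states <- c("ref-hom", "het", "alt-hom")
      gt[flip] <- vapply(gt[flip], function(g)
        sample(setdiff(states, g), 1L), character(1))
    }
    data.frame(chrom = truth$chrom, pos = truth$pos, genotype = gt,
               quality_p = stats::rbeta(nrow(truth), 1, 19))
  })
}
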