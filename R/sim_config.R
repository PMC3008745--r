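#' Simulation configuration for tumor/normal exome emulation
#'
#' Builds the parameter object consumed by every generator in the package
#' ([simulate_pair()], [simulate_annotation_tables()], [simulate_gene_models()],
#' [simulate_cnv_counts()]). Defaults emulate a paired exome study design:
#' per-site coverage is Poisson around the configured means, germline
#' heterozygous variants occur at `heterozygosity_rate`, somatic substitutions
#' are planted at `somatic_rate` on a germline-reference background, and tumor
#' reads are drawn from the tumor genome with probability `tumor_purity`
#' (default 0.8, the dissection target of >80% tumor cell content).
#'
#' @param n_sites number of simulated exome positions.
#' @param mean_coverage_tumor,mean_coverage_normal mean read depth per site;
#'   depth is drawn per site as Poisson around these means.
#' @param error_rate probability that a reference-supporting read is misread
#'   as the site's alternative base.
#' @param heterozygosity_rate probability a site carries a germline
#'   heterozygous variant.
#' @param hom_alt_rate probability a site is germline homozygous for the
#'   alternative base (array-SNP-like genotype spectra need all three states).
#' @param somatic_rate per-site probability of a somatic substitution; see
#'   [msi_config()] / [mss_config()] for the hypermutated / stable presets.
#' @param tumor_purity fraction of tumor-sample reads originating from tumor
#'   cells; the expected somatic allele fraction is `0.5 * tumor_purity`.
#' @param damaging_fraction probability a somatic variant is flagged damaging
#'   by at least one of the two simulated predictors.
#' @param conserved_fraction probability a variant site is highly conserved
#'   (score at or above 2.0, the 0.975 quantile of the background).
#' @param expressed_fraction fraction of genes whose mean expression lies at
#'   or above the generator's expression threshold. The default 0.75 matches
#'   the pipeline's first-quartile rule, so truth flags and the filter agree.
#' @param frequent_fraction probability a germline variant is a common
#'   polymorphism (population frequency above 0.01).
#' @param quality_low,quality_high,quality_p_high two-point per-read quality
#'   mixture; `max_alt_quality` is the maximum over variant-supporting reads.
#' @param homopolymer_p geometric tail parameter for simulated homopolymer
#'   run lengths (P(length >= 5) ~ 0.05 at the default).
#' @param n_genes,gene_site_block gene models to simulate and how many
#'   consecutive sites map to the same gene in abstract (genome-free) mode.
#' @param n_expression_samples columns of the simulated expression matrix.
#' @param bin_count,bin_size,cnv_base_rate read-depth CNV grid: number of
#'   bins, bin width in bp (50 kb default), and the expected normal-tissue
#'   read count per bin.
#' @param planted_segments list of `list(start, end, log2_effect)` copy-number
#'   segments (bin indices, inclusive) planted in the tumor counts.
#' @param seed integer RNG seed; identical configs give byte-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- simulation_config(n_sites = 1000, seed = 1)
#' sim <- simulate_pair(cfg)
#' head(sim$tumor)
#' @export
simulation_config <- function(n_sites = 10000,
                              mean_coverage_tumor = 20,
                              mean_coverage_normal = 20,
                              error_rate = 0.001,
                              heterozygosity_rate = 0.001,
                              hom_alt_rate = 0,
                              somatic_rate = 1e-4,
                              tumor_purity = 0.8,
                              damaging_fraction = 0.5,
                              conserved_fraction = 0.5,
                              expressed_fraction = 0.75,
                              frequent_fraction = 0.3,
                              quality_low = 15,
                              quality_high = 35,
                              quality_p_high = 0.9,
                              homopolymer_p = 0.53,
                              n_genes = 12,
                              gene_site_block = 50,
                              n_expression_samples = 4,
                              bin_count = 200,
                              bin_size = 50000,
                              cnv_base_rate = 500,
                              planted_segments = list(),
                              seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites),
    mean_coverage_tumor = mean_coverage_tumor,
    mean_coverage_normal = mean_coverage_normal,
    error_rate = error_rate,
    heterozygosity_rate = heterozygosity_rate,
    hom_alt_rate = hom_alt_rate,
    somatic_rate = somatic_rate,
    tumor_purity = tumor_purity,
    damaging_fraction = damaging_fraction,
    conserved_fraction = conserved_fraction,
    expressed_fraction = expressed_fraction,
    frequent_fraction = frequent_fraction,
    quality_low = quality_low,
    quality_high = quality_high,
    quality_p_high = quality_p_high,
    homopolymer_p = homopolymer_p,
    n_genes = as.integer(n_genes),
    gene_site_block = as.integer(gene_site_block),
    n_expression_samples = as.integer(n_expression_samples),
    bin_count = as.integer(bin_count),
    bin_size = as.integer(bin_size),
    cnv_base_rate = cnv_base_rate,
    planted_segments = planted_segments,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c("error_rate", "heterozygosity_rate", "hom_alt_rate",
             "somatic_rate", "tumor_purity", "damaging_fraction",
             "conserved_fraction", "expressed_fraction", "frequent_fraction",
             "quality_p_high", "homopolymer_p")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a probability in [0, 1]", p))
  }
  if (cfg$heterozygosity_rate + cfg$hom_alt_rate > 1)
    stop("heterozygosity_rate + hom_alt_rate must not exceed 1")
  pos <- c("n_sites", "bin_count", "bin_size", "n_genes",
           "gene_site_block", "n_expression_samples")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("config field '%s' must be a positive count", p))
  }
  nonneg <- c("mean_coverage_tumor", "mean_coverage_normal", "cnv_base_rate",
              "quality_low", "quality_high")
  for (p in nonneg) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("config field '%s' must be finite and non-negative", p))
  }
  for (seg in cfg$planted_segments) {
    if (!all(c("start", "end", "log2_effect") %in% names(seg)))
      stop("planted segments need fields start, end, log2_effect")
    if (seg$start < 1 || seg$end > cfg$bin_count || seg$start > seg$end)
      stop("planted segment outside the bin grid")
  }
  if (length(cfg$planted_segments) > 1L) {
    ord <- order(vapply(cfg$planted_segments, `[[`, numeric(1), "start"))
    segs <- cfg$planted_segments[ord]
    for (i in seq_len(length(segs) - 1L)) {
      if (segs[[i + 1L]]$start <= segs[[i]]$end)
        stop("planted segments overlap")
    }
  }
  invisible(cfg)
}

#' Microsatellite-phenotype presets
#'
#' `msi_config()` emulates a hypermutated mismatch-repair-deficient tumor
#' (somatic rate 8e-4 per site); `mss_config()` a microsatellite-stable tumor
#' (1e-4). The 8:1 rate ratio mirrors the fold difference in non-synonymous
#' somatic mutation counts between the two phenotypes.
#'
#' @param ... overrides passed to [simulation_config()].
#' @return a `sim_config`.
#' @export
msi_config <- function(...) {
  args <- list(...)
  defaults <- list(somatic_rate = 8e-4)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

#' @rdname msi_config
#' @export
mss_config <- function(...) {
  args <- list(...)
  defaults <- list(somatic_rate = 1e-4)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a sub-stream seed (kept below 2^31) so each generator has its own
# reproducible stream regardless of call order.
substream <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483629L
}
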