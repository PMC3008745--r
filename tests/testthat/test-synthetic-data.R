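test_that("config validation rejects out-of-range values", {
  expect_error(simulation_config(error_rate = 1.5), "probability")
  expect_error(simulation_config(n_sites = 0), "positive")
  expect_error(simulation_config(mean_coverage_tumor = NaN), "finite")
  expect_error(simulation_config(
    bin_count = 50,
    planted_segments = list(list(start = 1, end = 10, log2_effect = 1),
                            list(start = 5, end = 20, log2_effect = 1))),
    "overlap")
})

test_that("zero somatic rate yields no somatic truth records", {
  sim <- simulate_pair(simulation_config(n_sites = 2000, somatic_rate = 0,
                                         seed = 3))
  expect_equal(sum(sim$truth$is_somatic), 0L)
})

test_that("same config and seed reproduce pileups byte for byte", {
  cfg <- simulation_config(n_sites = 1000, heterozygosity_rate = 0.02,
                           somatic_rate = 0.01, seed = 9)
  s1 <- simulate_pair(cfg)
  s2 <- simulate_pair(cfg)
  expect_identical(s1, s2)
  c1 <- simulate_cnv_counts(simulation_config(bin_count = 100, seed = 9))
  c2 <- simulate_cnv_counts(simulation_config(bin_count = 100, seed = 9))
  expect_identical(c1, c2)
})

test_that("het-site count matches the binomial sampling model", {
  n <- 100000
  rate <- 0.001
  sim <- simulate_pair(simulation_config(
    n_sites = n, mean_coverage_normal = 20, heterozygosity_rate = rate,
    somatic_rate = 0, seed = 17))
  observed <- sum(sim$truth$normal_genotype == "het")
  expect_lt(abs(observed - n * rate), 4 * sqrt(n * rate * (1 - rate)))
})

test_that("het-site allele fractions concentrate at one half", {
  sim <- simulate_pair(simulation_config(
    n_sites = 20000, mean_coverage_normal = 60,
    heterozygosity_rate = 0.05, somatic_rate = 0, error_rate = 0,
    seed = 23))
  het <- sim$truth$normal_genotype == "het"
  p <- sim$normal[het, ]
  alt <- p$alt_fwd + p$alt_rev
  cov <- alt + p$ref_fwd + p$ref_rev
  total_alt <- sum(alt); total_cov <- sum(cov)
  # pooled fraction within 4 SD of the binomial expectation 0.5
  expect_lt(abs(total_alt - 0.5 * total_cov), 4 * sqrt(total_cov * 0.25))
})

test_that("truth never marks a site both germline and somatic", {
  sim <- simulate_pair(simulation_config(
    n_sites = 20000, heterozygosity_rate = 0.2, somatic_rate = 0.05,
    seed = 29))
  som <- sim$truth[sim$truth$is_somatic, ]
  expect_true(all(som$normal_genotype == "ref-hom"))
  expect_true(all(som$tumor_genotype != som$normal_genotype))
})

test_that("annotation tables agree with truth flags", {
  cfg <- simulation_config(n_sites = 5000, heterozygosity_rate = 0.05,
                           somatic_rate = 0.02, damaging_fraction = 1,
                           seed = 37)
  sim <- simulate_pair(cfg)
  tabs <- simulate_annotation_tables(cfg, sim$truth)
  truth <- sim$truth
  variant <- truth$normal_genotype != "ref-hom" | truth$is_somatic

  # set equality: table entries above 0.01 == truth frequent flags
  common <- tabs$frequency[tabs$frequency$frequency > 0.01, ]
  expect_setequal(paste(common$chrom, common$pos),
                  paste(truth$chrom[variant & truth$frequent],
                        truth$pos[variant & truth$frequent]))

  # damaging saturation: every truth-somatic site carries >= 1 flag
  som_key <- paste(truth$chrom[truth$is_somatic], truth$pos[truth$is_somatic])
  dm <- tabs$damaging
  dm_key <- paste(dm$chrom, dm$pos)
  hit <- dm$damaging_polyphen | dm$damaging_mutationtaster
  expect_true(all(som_key %in% dm_key[hit]))

  # conserved truth flags match scores at the 2.0 cutoff
  cons <- tabs$conservation
  idx <- match(paste(truth$chrom[variant], truth$pos[variant]),
               paste(cons$chrom, cons$pos))
  expect_equal(cons$score[idx] >= 2.0, truth$conserved[variant])

  # expression matrix covers every gene with >= 2 samples
  expect_true(all(unique(truth$gene_id) %in% tabs$expression$gene))
  expect_gte(ncol(tabs$expression) - 1L, 2L)
})

test_that("empty truth yields empty annotation tables", {
  cfg <- simulation_config(n_sites = 10, seed = 1)
  tabs <- simulate_annotation_tables(cfg, data.frame())
  expect_equal(nrow(tabs$frequency), 0L)
  expect_equal(nrow(tabs$damaging), 0L)
  expect_equal(nrow(tabs$expression), 0L)
})

test_that("simulated gene models satisfy their structural contract", {
  cfg <- simulation_config(n_genes = 8, seed = 13)
  g <- simulate_gene_models(cfg)
  genes <- g$features[g$features$type == "gene", ]
  # genes do not overlap
  ord <- order(genes$start)
  expect_true(all(genes$start[ord][-1] > genes$end[ord][-nrow(genes)]))

  for (tx in g$transcripts) {
    cds <- tx$cds
    widths <- cds$end - cds$start + 1L
    expect_equal(sum(widths) %% 3L, 0L)
    # spliced CDS starts with ATG, ends with a stop, no internal stop
    chars <- strsplit(as.character(g$reference[[1]]), "")[[1]]
    pos <- unlist(lapply(seq_len(nrow(cds)),
                         function(r) cds$start[r]:cds$end[r]))
    if (tx$strand == "-") pos <- rev(pos)
    bases <- chars[pos]
    if (tx$strand == "-")
      bases <- unname(c(A = "T", C = "G", G = "C", T = "A")[bases])
    cds_seq <- Biostrings::DNAString(paste(bases, collapse = ""))
    aa <- as.character(Biostrings::translate(cds_seq))
    expect_equal(substr(as.character(cds_seq), 1, 3), "ATG")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }

  # the dual locus has two transcripts over the same bases
  tx_per_gene <- table(vapply(g$transcripts, `[[`, character(1), "gene_id"))
  dual <- names(tx_per_gene)[tx_per_gene == 2L]
  expect_length(dual, 1L)
  pair <- Filter(function(t) t$gene_id == dual, g$transcripts)
  shared <- intersect(
    unlist(Map(`:`, pair[[1]]$exons$start, pair[[1]]$exons$end)),
    unlist(Map(`:`, pair[[2]]$exons$start, pair[[2]]$exons$end)))
  expect_gt(length(shared), 0L)
})

test_that("planted CNV segments shift tumor counts by the right factor", {
  cfg0 <- simulation_config(bin_count = 400, cnv_base_rate = 800, seed = 7)
  c0 <- simulate_cnv_counts(cfg0)
  lr <- log2(c0$counts$tumor_count / c0$counts$normal_count)
  # no planted segment: mean log2 ratio within 4 SD of zero
  expect_lt(abs(mean(lr)), 4 * sd(lr) / sqrt(length(lr)))

  cfg1 <- simulation_config(
    bin_count = 400, cnv_base_rate = 800,
    planted_segments = list(list(start = 100, end = 119, log2_effect = 1)),
    seed = 7)
  c1 <- simulate_cnv_counts(cfg1)
  inside <- 100:119
  ratio <- sum(c1$counts$tumor_count[inside]) /
    sum(c1$counts$normal_count[inside])
  expect_lt(abs(ratio - 2), 0.25)
})
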