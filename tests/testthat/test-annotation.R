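test_that("coding consequences follow the genetic code", {
  g <- make_test_genome()
  # TGG -> CGG: Trp -> Arg missense at codon 2
  out <- annotate_variants(variant_df("chrT", 24L, "T", "C"),
                           g$transcripts, g$reference)
  t1 <- out[out$transcript_id == "t1", ]
  expect_equal(t1$consequence, "missense")
  expect_equal(t1$ref_aa, "W")
  expect_equal(t1$alt_aa, "R")
  expect_equal(t1$protein_pos, 2L)

  # GGA -> GGG: third-position wobble, synonymous
  out <- annotate_variants(variant_df("chrT", 29L, "A", "G"),
                           g$transcripts, g$reference)
  expect_equal(out$consequence[out$transcript_id == "t1"], "synonymous")

  # stop codon TAA -> CAA: stop lost
  out <- annotate_variants(variant_df("chrT", 109L, "T", "C"),
                           g$transcripts, g$reference)
  expect_equal(out$consequence[out$transcript_id == "t1"], "stop_lost")

  # start codon ATG -> GTG: start lost
  out <- annotate_variants(variant_df("chrT", 21L, "A", "G"),
                           g$transcripts, g$reference)
  expect_equal(out$consequence[out$transcript_id == "t1"], "start_lost")

  # TGG -> TGA: nonsense
  out <- annotate_variants(variant_df("chrT", 26L, "G", "A"),
                           g$transcripts, g$reference)
  expect_equal(out$consequence[out$transcript_id == "t1"], "nonsense")
})

test_that("a variant can be coding in one transcript and UTR in another", {
  g <- make_test_genome()
  # inside t2's ORF (GCT codon) but in t1's 3' UTR
  out <- annotate_variants(variant_df("chrT", 118L, "G", "C"),
                           g$transcripts, g$reference)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$consequence, c("missense", "utr3"))
  expect_equal(out$consequence[out$transcript_id == "t2"], "missense")
})

test_that("splice, intron, UTR and intergenic regions are recognized", {
  g <- make_test_genome()
  ann <- function(pos, ref) {
    out <- annotate_variants(variant_df("chrT", pos, ref,
                                        setdiff(c("A","C","G","T"), ref)[1]),
                             g$transcripts, g$reference)
    out$consequence[is.na(out$transcript_id) | out$transcript_id == "t1"][1]
  }
  expect_equal(ann(41L, "G"), "splice_site")   # first intronic base
  expect_equal(ann(42L, "T"), "splice_site")
  expect_equal(ann(60L, "C"), "intronic")
  expect_equal(ann(79L, "A"), "splice_site")
  expect_equal(ann(15L, "T"), "utr5")
  expect_equal(ann(113L, "C"), "utr3")
  expect_equal(ann(5L, "A"), "intergenic")
})

test_that("mirrored minus-strand gene gives identical protein outcomes", {
  gp <- make_test_genome()
  gm <- make_test_genome_minus()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cases <- list(c(24L, "T", "C"), c(29L, "A", "G"), c(26L, "G", "A"),
                c(109L, "T", "C"))
  for (cs in cases) {
    pos <- as.integer(cs[1])
    out_p <- annotate_variants(variant_df("chrT", pos, cs[2], cs[3]),
                               gp$transcripts, gp$reference)
    out_m <- annotate_variants(
      variant_df("chrT", 141L - pos, comp[[cs[2]]], comp[[cs[3]]]),
      gm$transcripts, gm$reference)
    p1 <- out_p[out_p$transcript_id == "t1", ]
    m1 <- out_m[out_m$transcript_id == "t1", ]
    expect_equal(m1$consequence, p1$consequence)
    expect_equal(m1$ref_aa, p1$ref_aa)
    expect_equal(m1$alt_aa, p1$alt_aa)
    expect_equal(m1$protein_pos, p1$protein_pos)
  }
})

test_that("reference mismatches are hard errors naming the site", {
  g <- make_test_genome()
  expect_error(annotate_variants(variant_df("chrT", 24L, "G", "C"),
                                 g$transcripts, g$reference),
               "chrT:24")
})

test_that("annotation agrees with the generator's independent truth path", {
  cfg <- simulation_config(n_sites = 1200, n_genes = 10,
                           heterozygosity_rate = 0.1, somatic_rate = 0.05,
                           seed = 19)
  genome <- simulate_gene_models(cfg)
  sim <- simulate_pair(cfg, genome)
  vs <- sim$truth[sim$truth$is_somatic |
                    sim$truth$normal_genotype != "ref-hom", ]
  ann <- annotate_variants(vs[, c("chrom", "pos", "ref", "alt")], genome)
  red <- somaticExome:::reduce_to_most_severe(ann)
  red$consequence[classify_mirna(red, genome$mirna) &
                    red$consequence == "intergenic"] <- "mirna"
  m <- merge(red, vs[, c("chrom", "pos", "consequence_class")],
             by = c("chrom", "pos"))
  expect_equal(m$consequence, m$consequence_class)
})

test_that("miRNA intervals flag positions and tolerate empty tables", {
  mi <- data.frame(chrom = "chrT", start = 10L, end = 31L)
  v <- variant_df("chrT", c(5L, 10L, 31L, 32L), "A", "G")
  expect_equal(classify_mirna(v, mi), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(classify_mirna(v, mi[0, ]), rep(FALSE, 4L))
})

test_that("severity ordering picks the documented winner", {
  expect_equal(most_severe_consequence(c("synonymous", "utr3")), "utr3")
  expect_equal(most_severe_consequence(c("missense", "splice_site")),
               "missense")
  expect_equal(most_severe_consequence(c("intergenic")), "intergenic")
  expect_true(is.na(most_severe_consequence(character(0))))
})
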