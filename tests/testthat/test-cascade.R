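# ten hand-built somatic variants with fully known annotations
cascade_fixture <- function() {
  v <- data.frame(
    chrom = "chrT", pos = 1:10, ref = "A", alt = "G",
    gene_id = sprintf("g%02d", c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9)),
    consequence = c("missense", "synonymous", "missense", "nonsense",
                    "missense", "utr3", "missense", "splice_site",
                    "missense", "missense"),
    status = "somatic", stringsAsFactors = FALSE)
  tables <- list(
    frequency = data.frame(chrom = "chrT", pos = c(1L, 5L, 9L),
                           frequency = c(0.02, 0.005, 0.30)),
    damaging = data.frame(
      chrom = "chrT", pos = c(3L, 4L, 5L, 7L, 8L),
      damaging_polyphen = c(TRUE, TRUE, TRUE, FALSE, FALSE),
      damaging_mutationtaster = c(TRUE, FALSE, FALSE, TRUE, FALSE)),
    conservation = data.frame(chrom = "chrT", pos = c(3L, 4L, 5L, 7L),
                              score = c(2.0, 1.99, 3.5, 2.7)),
    expression = data.frame(gene = sprintf("g%02d", 1:9),
                            sample_1 = c(9, 1, 12, 14, 2, 2, 13, 2, 2),
                            sample_2 = c(11, 1, 12, 14, 2, 2, 13, 2, 2)),
    categories = list(repair = "g02", kinase = c("g03", "g06"),
                      receptor = "g04", transmembrane_receptor = character(0)),
    catalogues = list(cancer_census = "g03", prior_study = "g07"))
  list(variants = v, tables = tables)
}

test_that("frequency filter keeps unreported and rare variants", {
  fx <- cascade_fixture()
  out <- filter_frequency(fx$variants, fx$tables$frequency)
  expect_false(1L %in% out$pos)   # 0.02  -> removed
  expect_true(5L %in% out$pos)    # 0.005 -> kept
  expect_true(2L %in% out$pos)    # absent -> kept
})

test_that("functional filter honours any/all predictor modes", {
  fx <- cascade_fixture()
  any_out <- filter_functional(fx$variants, fx$tables$damaging, "any")
  expect_setequal(any_out$pos, c(3L, 4L, 5L, 7L))
  all_out <- filter_functional(fx$variants, fx$tables$damaging, "all")
  expect_setequal(all_out$pos, 3L)
  expect_false(8L %in% any_out$pos)  # flagged by neither
})

test_that("conservation threshold is the 0.975 linear-interpolation quantile", {
  expect_equal(conservation_threshold(1:1000), 975.025)
  expect_equal(conservation_threshold(rep(3.7, 50)), 3.7)
  expect_error(conservation_threshold(numeric(0)), "empty")
  # generator calibration: background 0.975 quantile sits at 2.0
  cfg <- simulation_config(n_sites = 40000, heterozygosity_rate = 0.001,
                           somatic_rate = 1e-4, seed = 47)
  sim <- simulate_pair(cfg)
  tabs <- simulate_annotation_tables(cfg, sim$truth)
  expect_lt(abs(conservation_threshold(tabs$conservation$score) - 2.0),
            0.05)
})

test_that("conservation filter is inclusive at 2.0 and fails closed", {
  fx <- cascade_fixture()
  expect_warning(
    out <- filter_conserved(fx$variants, fx$tables$conservation),
    "without a conservation score")
  expect_true(3L %in% out$pos)    # exactly 2.0 kept
  expect_false(4L %in% out$pos)   # 1.99 removed
  expect_false(1L %in% out$pos)   # missing score removed
})

test_that("expression filter thresholds at the first quartile, inclusively", {
  fx <- cascade_fixture()
  means <- rowMeans(fx$tables$expression[, -1])
  q1 <- unname(quantile(means, 0.25))
  out <- filter_expressed(fx$variants, fx$tables$expression)
  kept_genes <- unique(out$gene_id)
  expect_setequal(kept_genes,
                  fx$tables$expression$gene[means >= q1])
  # all genes equal -> everything kept
  eq <- data.frame(gene = c("a", "b"), s1 = c(5, 5), s2 = c(5, 5))
  v <- data.frame(gene_id = c("a", "b"), pos = 1:2)
  expect_equal(nrow(filter_expressed(v, eq)), 2L)
  # missing gene dropped with warning
  v2 <- data.frame(gene_id = "zz", pos = 1L)
  expect_warning(out2 <- filter_expressed(v2, eq), "absent")
  expect_equal(nrow(out2), 0L)
})

test_that("category flags reproduce set membership exactly", {
  fx <- cascade_fixture()
  out <- flag_categories(fx$variants, fx$tables$categories,
                         fx$tables$catalogues)
  for (nm in names(fx$tables$categories))
    expect_equal(out[[nm]],
                 fx$variants$gene_id %in% fx$tables$categories[[nm]])
  expect_equal(out$cancer_census, fx$variants$gene_id %in% "g03")
})

test_that("cascade stage counts equal brute-force set intersections", {
  fx <- cascade_fixture()
  v <- fx$variants
  # independent set algebra on the fixture
  nonsyn <- v$pos[v$consequence %in% c("missense", "nonsense", "start_lost",
                                       "stop_lost", "splice_site")]
  common <- fx$tables$frequency$pos[fx$tables$frequency$frequency >= 0.01]
  rare <- setdiff(nonsyn, common)
  dm <- fx$tables$damaging
  damaging <- intersect(rare, dm$pos[dm$damaging_polyphen |
                                       dm$damaging_mutationtaster])

  res <- run_cascade(v, fx$tables)
  expect_equal(res$stages$stage,
               c("somatic", "non_synonymous", "rare", "damaging"))
  expect_equal(res$stages$n,
               c(nrow(v), length(nonsyn), length(rare), length(damaging)))
  expect_setequal(res$variants$pos, damaging)
  # counts never increase along the cascade
  expect_true(all(diff(res$stages$n) <= 0))
})

test_that("extended cascade narrows through conservation and expression", {
  fx <- cascade_fixture()
  res <- suppressWarnings(run_cascade(fx$variants, fx$tables,
                                      extended = TRUE))
  expect_equal(res$stages$stage,
               c("somatic", "non_synonymous", "rare", "damaging",
                 "conserved", "expressed", "categorized"))
  expect_true(all(diff(res$stages$n) <= 0))
  # hand-traced survivors: pos 5 (g04, receptor) and pos 7 (g06, kinase);
  # pos 3 falls to the expression stage (its gene g02 sits below Q1) and
  # pos 4 to conservation (score 1.99)
  expect_setequal(res$variants$pos, c(5L, 7L))
  expect_true(res$variants$receptor[res$variants$pos == 5L])
  expect_true(res$variants$kinase[res$variants$pos == 7L])
})

test_that("cascade output is invariant to input order", {
  fx <- cascade_fixture()
  res1 <- run_cascade(fx$variants, fx$tables)
  perm <- fx$variants[sample(nrow(fx$variants)), ]
  res2 <- run_cascade(perm, fx$tables)
  expect_equal(res1$stages, res2$stages)
  expect_setequal(res1$variants$pos, res2$variants$pos)
})

test_that("empty input gives all-zero stage counts", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$variants[0, ], fx$tables)
  expect_true(all(res$stages$n == 0L))
  expect_equal(nrow(res$variants), 0L)
})
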