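make_call <- function(pos, coverage, alt_reads) {
  data.frame(chrom = "chrT", pos = pos, ref = "A", alt = "G",
             coverage = coverage, alt_reads = alt_reads,
             vaf = alt_reads / coverage, rule = "strand",
             stringsAsFactors = FALSE)
}

test_that("stringent tumor filter applies the 15% boundary inclusively", {
  calls <- rbind(make_call(1L, 40L, 4L),   # VAF 0.10 -> removed
                 make_call(2L, 40L, 6L),   # VAF 0.15 -> retained
                 make_call(3L, 40L, 20L))  # VAF 0.50 -> retained
  out <- filter_tumor_calls(calls)
  expect_equal(out$pos, c(2L, 3L))
  empty <- calls[0, ]
  expect_equal(nrow(filter_tumor_calls(empty)), 0L)
})

test_that("normal-tissue evidence classifies somatic vs germline", {
  tumor <- rbind(make_call(1L, 30L, 12L), make_call(2L, 30L, 12L),
                 make_call(3L, 30L, 12L), make_call(4L, 30L, 12L))
  normal <- rbind(
    pileup_row(pos = 1L, ref_fwd = 2L, ref_rev = 2L),                 # cov 4
    pileup_row(pos = 2L, ref_fwd = 4L, ref_rev = 3L, alt_fwd = 1L),   # cov 8
    pileup_row(pos = 3L, ref_fwd = 13L, ref_rev = 12L))               # cov 25
  out <- classify_somatic(tumor, normal)
  expect_equal(out$status,
               c("undetermined", "germline", "somatic", "undetermined"))
  expect_equal(out$normal_coverage[4], 0L)   # absent site, coverage 0
})

test_that("classifier matches brute force over the normal-evidence grid", {
  grid <- expand.grid(cov = 0:10, alt = 0:3)
  grid <- grid[grid$alt <= grid$cov, ]
  tumor <- do.call(rbind, lapply(seq_len(nrow(grid)),
                                 function(i) make_call(i, 40L, 20L)))
  normal <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ref <- grid$cov[i] - grid$alt[i]
    pileup_row(pos = i, ref_fwd = ref %/% 2L, ref_rev = ref - ref %/% 2L,
               alt_fwd = grid$alt[i])
  }))
  out <- classify_somatic(tumor, normal)
  expected <- ifelse(grid$cov < 5L, "undetermined",
                     ifelse(grid$alt >= 1L, "germline", "somatic"))
  expect_equal(out$status, expected)
})

test_that("the three statuses always partition the input", {
  sim <- simulate_pair(simulation_config(
    n_sites = 4000, heterozygosity_rate = 0.05, somatic_rate = 0.01,
    seed = 31))
  stringent <- filter_tumor_calls(call_variants(sim$tumor))
  out <- classify_somatic(stringent, sim$normal)
  expect_equal(nrow(out), nrow(stringent))
  expect_equal(sum(table(factor(out$status,
                                c("somatic", "germline", "undetermined")))),
               nrow(stringent))
  expect_true(all(out$status %in% c("somatic", "germline", "undetermined")))
})

test_that("no true germline variant is labelled somatic without errors", {
  sim <- simulate_pair(simulation_config(
    n_sites = 5000, heterozygosity_rate = 0.10, somatic_rate = 0,
    error_rate = 0, mean_coverage_normal = 30, seed = 41))
  stringent <- filter_tumor_calls(call_variants(sim$tumor))
  out <- classify_somatic(stringent, sim$normal)
  germline_truth <- sim$truth$pos[sim$truth$normal_genotype != "ref-hom"]
  labelled_somatic <- out$pos[out$status == "somatic"]
  expect_length(intersect(labelled_somatic, germline_truth), 0L)
})

test_that("duplicate tumor sites are rejected", {
  tumor <- rbind(make_call(1L, 30L, 12L), make_call(1L, 30L, 12L))
  expect_error(classify_somatic(tumor, pileup_row(pos = 1L)), "duplicate")
})

test_that("benign-tissue miss probability follows the binomial zero class", {
  expect_equal(benign_false_negative_rate(5, 0.5), 0.03125)
  expect_lt(benign_false_negative_rate(5, 0.5), 0.10)
  expect_equal(benign_false_negative_rate(0, 0.3), 1.0)
  expect_equal(benign_false_negative_rate(1, 1.0), 0.0)
  expect_error(benign_false_negative_rate(-1, 0.5), "non-negative")
  expect_error(benign_false_negative_rate(5, 1.5), "\\[0, 1\\]")
})

test_that("8:1 somatic-rate presets are recovered in labelled counts", {
  classify_run <- function(cfg) {
    sim <- simulate_pair(cfg)
    out <- classify_somatic(filter_tumor_calls(call_variants(sim$tumor)),
                            sim$normal)
    sum(out$status == "somatic")
  }
  s_msi <- classify_run(msi_config(n_sites = 150000, seed = 51))
  s_mss <- classify_run(mss_config(n_sites = 150000, seed = 52))
  n <- s_msi + s_mss
  # observed MSI share within the binomial 95% interval implied by 8:1
  ci <- qbinom(c(0.025, 0.975), n, 8 / 9)
  expect_gte(s_msi, ci[1])
  expect_lte(s_msi, ci[2])
})
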