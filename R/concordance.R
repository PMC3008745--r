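GENOTYPE_STATES <- c("ref-hom", "het", "alt-hom")

#' Call diploid genotypes from pileup allele fractions
#'
#' A simple fraction-threshold caller used for the array comparison: the
#' variant allele fraction below `lower` gives ref-hom, above `upper` gives
#' alt-hom, anything between gives het. Zero-coverage sites get NA.
#'
#' @param pileups pileup data frame.
#' @param lower,upper allele-fraction thresholds (defaults 0.15 / 0.85).
#' @return data frame: chrom, pos, coverage, vaf, genotype.
#' @export
call_genotypes <- function(pileups, lower = 0.15, upper = 0.85) {
  check_pileup(pileups)
  stopifnot(lower < upper)
  coverage <- pileups$ref_fwd + pileups$ref_rev +
    pileups$alt_fwd + pileups$alt_rev
  alt_reads <- pileups$alt_fwd + pileups$alt_rev
  vaf <- ifelse(coverage > 0, alt_reads / coverage, NA_real_)
  genotype <- ifelse(is.na(vaf), NA_character_,
                     ifelse(vaf < lower, "ref-hom",
                            ifelse(vaf > upper, "alt-hom", "het")))
  data.frame(chrom = pileups$chrom, pos = pileups$pos,
             coverage = coverage, vaf = vaf, genotype = genotype,
             stringsAsFactors = FALSE)
}

check_genotype_coding <- function(gt, what) {
  bad <- !is.na(gt) & !gt %in% GENOTYPE_STATES
  if (any(bad))
    stop(what, " genotypes use unknown coding: ",
         paste(utils::head(unique(gt[bad]), 3L), collapse = ", "))
  invisible(gt)
}

#' Compare sequencing genotypes against array-style truth
#'
#' Restricts the comparison to positions where the array quality p-value is
#' strictly below `max_array_p` (default 0.1) and the sequencing coverage
#' strictly exceeds `min_cov` (default 3), treats the array genotypes as
#' the standard, and reports the confusion matrix, the false-positive rate
#' (array-reference positions where sequencing calls a variant), the
#' false-negative rate (array-variant positions where sequencing calls
#' reference), diploid accuracy (concordant fraction), and haploid
#' concordance (heterozygous calls recoded as homozygous non-reference on
#' both sides before comparing).
#'
#' @param seq data frame from [call_genotypes()] (chrom, pos, coverage,
#'   genotype).
#' @param array data frame with chrom, pos, genotype, quality_p (see
#'   [simulate_array_genotypes()]).
#' @param min_cov sequencing coverage must strictly exceed this.
#' @param max_array_p array p-value must be strictly below this.
#' @return a `concordance_report` list: n_compared, accuracy, fp_rate,
#'   fn_rate, haploid_concordance, confusion (array x sequencing table),
#'   coverage_breakdown.
#' @export
compare_genotypes <- function(seq, array, min_cov = 3L, max_array_p = 0.1) {
  stopifnot(is.data.frame(seq), is.data.frame(array))
  check_genotype_coding(seq$genotype, "sequencing")
  check_genotype_coding(array$genotype, "array")
  idx <- match(paste(seq$chrom, seq$pos), paste(array$chrom, array$pos))
  eligible <- !is.na(idx) & seq$coverage > min_cov &
    !is.na(seq$genotype) &
    array$quality_p[idx] < max_array_p & !is.na(array$genotype[idx])
  s <- factor(seq$genotype[eligible], levels = GENOTYPE_STATES)
  a <- factor(array$genotype[idx][eligible], levels = GENOTYPE_STATES)
  confusion <- table(array = a, sequencing = s)

  n <- length(s)
  acc <- if (n) mean(s == a) else NA_real_
  array_ref <- a == "ref-hom"
  fp <- if (any(array_ref)) mean(s[array_ref] != "ref-hom") else NA_real_
  fn <- if (any(!array_ref)) mean(s[!array_ref] == "ref-hom") else NA_real_
  hap_s <- ifelse(s == "het", "alt-hom", as.character(s))
  hap_a <- ifelse(a == "het", "alt-hom", as.character(a))
  hap <- if (n) mean(hap_s == hap_a) else NA_real_

  cov <- seq$coverage[eligible]
  breaks <- sort(unique(c(min_cov, 5, 10, 20, Inf)))
  breaks <- breaks[breaks >= min_cov]
  strata <- cut(cov, breaks = breaks)
  breakdown <- if (n) {
    data.frame(
      coverage = levels(strata),
      n = as.integer(table(strata)),
      accuracy = as.numeric(tapply(s == a, strata, mean)))
  } else {
    data.frame(coverage = character(0), n = integer(0),
               accuracy = numeric(0))
  }

  structure(list(n_compared = n, accuracy = acc, fp_rate = fp,
                 fn_rate = fn, haploid_concordance = hap,
                 confusion = confusion, coverage_breakdown = breakdown),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Genotype concordance vs array standard\n")
  cat(sprintf("  positions compared : %d\n", x$n_compared))
  cat(sprintf("  diploid accuracy   : %.4f\n", x$accuracy))
  cat(sprintf("  haploid concordance: %.4f\n", x$haploid_concordance))
  cat(sprintf("  false positive rate: %.4f\n", x$fp_rate))
  cat(sprintf("  false negative rate: %.4f\n", x$fn_rate))
  invisible(x)
}

#' Concordance as a function of the coverage filter
#'
#' Recomputes the comparison at each minimum-coverage value of a strictly
#' increasing grid.
#'
#' @param seq,array,max_array_p as in [compare_genotypes()].
#' @param grid strictly increasing integer vector of minimum coverages.
#' @return data frame: min_coverage, n_compared, accuracy, fp_rate,
#'   fn_rate, haploid_concordance.
#' @export
concordance_vs_coverage <- function(seq, array, grid, max_array_p = 0.1) {
  if (!length(grid))
    return(data.frame(min_coverage = integer(0), n_compared = integer(0),
                      accuracy = numeric(0), fp_rate = numeric(0),
                      fn_rate = numeric(0),
                      haploid_concordance = numeric(0)))
  if (any(diff(grid) <= 0)) stop("coverage grid must be strictly increasing")
  rows <- lapply(grid, function(mc) {
    r <- compare_genotypes(seq, array, min_cov = mc,
                           max_array_p = max_array_p)
    data.frame(min_coverage = mc, n_compared = r$n_compared,
               accuracy = r$accuracy, fp_rate = r$fp_rate,
               fn_rate = r$fn_rate,
               haploid_concordance = r$haploid_concordance)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
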