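#' Parameters of the bimodal somatic/germline strategy
#'
#' Two stringencies: tumor variants must reach a variant allele fraction of
#' at least `tumor_min_vaf` (default 15% of all reads at the position), while
#' the matched normal is screened permissively — any normal coverage of at
#' least `normal_min_coverage` (default 5) with more than
#' `normal_max_variant_reads` (default 0, i.e. a single variant read)
#' classifies the variant as germline. Below the normal coverage cutoff no
#' conclusion is drawn. This asymmetry keeps the false negative rate for
#' germline variants in the normal tissue under 10% at the 5x cutoff
#' (see [benign_false_negative_rate()]) while minimizing false somatic calls.
#'
#' @param tumor_min_vaf minimum tumor variant allele fraction, inclusive.
#' @param normal_min_coverage normal-tissue coverage below which the status
#'   is undetermined.
#' @param normal_max_variant_reads maximum normal variant reads compatible
#'   with a somatic label.
#' @return a `bimodal_params` list.
#' @export
bimodal_params <- function(tumor_min_vaf = 0.15,
                           normal_min_coverage = 5L,
                           normal_max_variant_reads = 0L) {
  if (!(tumor_min_vaf > 0 && tumor_min_vaf <= 1))
    stop("tumor_min_vaf must lie in (0, 1]")
  if (normal_min_coverage < 1)
    stop("normal_min_coverage must be at least 1")
  structure(list(tumor_min_vaf = tumor_min_vaf,
                 normal_min_coverage = normal_min_coverage,
                 normal_max_variant_reads = normal_max_variant_reads),
            class = "bimodal_params")
}

#' Stringent tumor-variant filter
#'
#' Retains calls whose variant allele fraction is at least
#' `params$tumor_min_vaf` (boundary inclusive). Input order is preserved.
#'
#' @param calls variant calls from [call_variants()].
#' @param params a [bimodal_params()] object.
#' @return the retained subset of `calls`.
#' @export
filter_tumor_calls <- function(calls, params = bimodal_params()) {
  stopifnot(is.data.frame(calls), inherits(params, "bimodal_params"))
  if (!nrow(calls)) return(calls)
  out <- calls[calls$vaf >= params$tumor_min_vaf, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify tumor variants as somatic, germline, or undetermined
#'
#' For each stringently called tumor variant, inspects the matched-normal
#' pileup at the same site: normal coverage below the cutoff gives
#' `undetermined` (no conclusion is drawn), at least one normal variant read
#' above the cutoff gives `germline`, and zero normal variant reads at
#' adequate coverage gives `somatic`. Sites absent from the normal pileup
#' are treated as coverage zero, hence undetermined — never somatic. The
#' three statuses partition the input.
#'
#' @param tumor_variants calls surviving [filter_tumor_calls()]; duplicate
#'   (chrom, pos) entries are rejected.
#' @param normal_pileups the matched normal pileup table.
#' @param params a [bimodal_params()] object.
#' @return data frame with the tumor evidence plus `normal_coverage`,
#'   `normal_alt_reads` and `status` in
#'   `c("somatic", "germline", "undetermined")`.
#' @export
classify_somatic <- function(tumor_variants, normal_pileups,
                             params = bimodal_params()) {
  stopifnot(is.data.frame(tumor_variants), inherits(params, "bimodal_params"))
  check_pileup(normal_pileups)
  key_t <- paste(tumor_variants$chrom, tumor_variants$pos)
  if (anyDuplicated(key_t))
    stop("duplicate site ids in tumor variants: ",
         paste(utils::head(key_t[duplicated(key_t)], 5L), collapse = ", "))
  key_n <- paste(normal_pileups$chrom, normal_pileups$pos)
  idx <- match(key_t, key_n)
  normal_coverage <- ifelse(is.na(idx), 0L,
                            normal_pileups$ref_fwd[idx] +
                              normal_pileups$ref_rev[idx] +
                              normal_pileups$alt_fwd[idx] +
                              normal_pileups$alt_rev[idx])
  normal_alt_reads <- ifelse(is.na(idx), 0L,
                             normal_pileups$alt_fwd[idx] +
                               normal_pileups$alt_rev[idx])
  status <- ifelse(normal_coverage < params$normal_min_coverage,
                   "undetermined",
                   ifelse(normal_alt_reads > params$normal_max_variant_reads,
                          "germline", "somatic"))
  out <- tumor_variants
  out$normal_coverage <- normal_coverage
  out$normal_alt_reads <- normal_alt_reads
  out$status <- status
  rownames(out) <- NULL
  out
}

#' Miss probability for a germline variant in normal tissue
#'
#' Closed-form chance that a true germline variant with the given allele
#' fraction shows zero supporting reads at the given coverage — the binomial
#' zero-class `(1 - allele_fraction)^coverage`. At the 5x normal coverage
#' cutoff and allele fraction 0.5 this is 0.03125, inside the 10% false
#' negative budget the cutoff was chosen for.
#'
#' @param coverage non-negative read depth (vectorized).
#' @param allele_fraction variant allele fraction in `[0, 1]` (vectorized).
#' @return miss probability in `[0, 1]`.
#' @examples
#' benign_false_negative_rate(5, 0.5)   # 0.03125
#' @export
benign_false_negative_rate <- function(coverage, allele_fraction) {
  if (any(coverage < 0)) stop("coverage must be non-negative")
  if (any(allele_fraction < 0 | allele_fraction > 1))
    stop("allele_fraction must lie in [0, 1]")
  (1 - allele_fraction)^coverage
}
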