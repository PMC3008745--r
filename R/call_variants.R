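#' High-confidence caller parameters
#'
#' Evidence rules for calling a substitution from a per-site pileup. A site
#' is called when its total coverage strictly exceeds `min_coverage` and
#' either the strand-count rule fires (at least `min_variant_reads`
#' variant-supporting reads with both a forward and a reverse read among
#' them) or the quality rule fires (best variant-supporting quality strictly
#' over `quality_threshold`, raised to `homopolymer_quality_threshold` when
#' a homopolymer of `homopolymer_min_len` or more bases is involved).
#'
#' @param min_variant_reads strand-count rule read minimum (default 3).
#' @param require_both_strands require forward and reverse support for the
#'   strand-count rule.
#' @param quality_threshold phred-like quality the best variant read must
#'   strictly exceed (default 20).
#' @param homopolymer_quality_threshold raised threshold near homopolymers
#'   (default 30).
#' @param homopolymer_min_len homopolymer length at which the raised
#'   threshold applies (default 5).
#' @param min_coverage coverage must strictly exceed this (default 10).
#' @param quality_min_variant_reads variant reads required by the quality
#'   rule; the rule text leaves this open, at least one read is required by
#'   default.
#' @return a `caller_params` list.
#' @export
caller_params <- function(min_variant_reads = 3L,
                          require_both_strands = TRUE,
                          quality_threshold = 20,
                          homopolymer_quality_threshold = 30,
                          homopolymer_min_len = 5L,
                          min_coverage = 10L,
                          quality_min_variant_reads = 1L) {
  p <- list(min_variant_reads = min_variant_reads,
            require_both_strands = isTRUE(require_both_strands),
            quality_threshold = quality_threshold,
            homopolymer_quality_threshold = homopolymer_quality_threshold,
            homopolymer_min_len = homopolymer_min_len,
            min_coverage = min_coverage,
            quality_min_variant_reads = quality_min_variant_reads)
  num <- vapply(p[setdiff(names(p), "require_both_strands")], is.numeric,
                logical(1))
  if (!all(num) ||
      any(unlist(p[setdiff(names(p), "require_both_strands")]) <= 0))
    stop("caller thresholds must be positive numbers")
  class(p) <- "caller_params"
  p
}

PILEUP_COLUMNS <- c("chrom", "pos", "ref", "alt", "ref_fwd", "ref_rev",
                    "alt_fwd", "alt_rev", "max_alt_quality",
                    "homopolymer_len")

check_pileup <- function(pileups) {
  missing <- setdiff(PILEUP_COLUMNS, names(pileups))
  if (length(missing))
    stop("pileup table lacks columns: ", paste(missing, collapse = ", "))
  invisible(pileups)
}

#' Call high-confidence substitution variants from a pileup
#'
#' Applies the two-branch evidence rule described in [caller_params()] to
#' each pileup row. Records failing basic sanity (negative read counts, or
#' alt equal to ref) are dropped with a warning naming the offending sites.
#' Output rows are ordered by (chrom, pos) and record which rule fired: the
#' strand-count branch takes precedence in `rule` when both hold.
#'
#' @param pileups pileup data frame (columns as written by
#'   [simulate_pair()] / [read_pileup()]).
#' @param params a [caller_params()] object.
#' @return data frame of calls: chrom, pos, ref, alt, coverage, alt_reads,
#'   vaf (variant allele fraction), rule ("strand" or "quality").
#' @examples
#' p <- data.frame(chrom = "sim1", pos = 1, ref = "A", alt = "G",
#'                 ref_fwd = 5, ref_rev = 4, alt_fwd = 2, alt_rev = 1,
#'                 max_alt_quality = 15, homopolymer_len = 1)
#' call_variants(p)
#' @export
call_variants <- function(pileups, params = caller_params()) {
  check_pileup(pileups)
  stopifnot(inherits(params, "caller_params"))
  counts <- c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")
  bad <- Reduce(`|`, lapply(pileups[counts], function(x) x < 0)) |
    pileups$ref == pileups$alt | pileups$pos < 1
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed pileup record(s): ",
            paste(utils::head(paste0(pileups$chrom[bad], ":",
                                     pileups$pos[bad]), 5L),
                  collapse = ", "))
    pileups <- pileups[!bad, , drop = FALSE]
  }
  coverage <- pileups$ref_fwd + pileups$ref_rev +
    pileups$alt_fwd + pileups$alt_rev
  alt_reads <- pileups$alt_fwd + pileups$alt_rev

  strand_ok <- !params$require_both_strands |
    (pileups$alt_fwd >= 1L & pileups$alt_rev >= 1L)
  strand_rule <- alt_reads >= params$min_variant_reads & strand_ok
  qthr <- ifelse(pileups$homopolymer_len >= params$homopolymer_min_len,
                 params$homopolymer_quality_threshold,
                 params$quality_threshold)
  quality_rule <- pileups$max_alt_quality > qthr &
    alt_reads >= params$quality_min_variant_reads
  called <- coverage > params$min_coverage & (strand_rule | quality_rule)

  out <- data.frame(
    chrom = pileups$chrom, pos = pileups$pos,
    ref = pileups$ref, alt = pileups$alt,
    coverage = coverage, alt_reads = alt_reads,
    vaf = ifelse(coverage > 0, alt_reads / coverage, 0),
    rule = ifelse(strand_rule, "strand", "quality"),
    stringsAsFactors = FALSE)[called, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
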