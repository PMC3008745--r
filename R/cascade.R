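#' Population-frequency filter
#'
#' Removes variants that are common polymorphisms: a variant is kept when it
#' is absent from the frequency table (not previously reported) or its
#' population frequency is below `threshold` (default 0.01, the minor allele
#' frequency / average heterozygosity cutoff).
#'
#' @param variants data frame with chrom and pos.
#' @param frequency_table data frame with chrom, pos, frequency.
#' @param threshold exclusive frequency cutoff in (0, 1).
#' @return the surviving subset of `variants`.
#' @export
filter_frequency <- function(variants, frequency_table, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  if (!nrow(variants)) return(variants)
  idx <- match(paste(variants$chrom, variants$pos),
               paste(frequency_table$chrom, frequency_table$pos))
  freq <- frequency_table$frequency[idx]
  keep <- is.na(freq) | freq < threshold
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Functional-impairment filter
#'
#' Keeps variants predicted damaging. With `mode = "any"` (default) one of
#' the two predictors suffices ("at least one potentially destructive"
#' reading); with `mode = "all"` both must agree.
#'
#' @param variants data frame with chrom and pos.
#' @param flags data frame with chrom, pos, damaging_polyphen,
#'   damaging_mutationtaster; variants absent from it count as not damaging.
#' @param mode "any" or "all".
#' @return the surviving subset of `variants`.
#' @export
filter_functional <- function(variants, flags, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (!nrow(variants)) return(variants)
  idx <- match(paste(variants$chrom, variants$pos),
               paste(flags$chrom, flags$pos))
  a <- !is.na(idx) & flags$damaging_polyphen[idx] %in% TRUE
  b <- !is.na(idx) & flags$damaging_mutationtaster[idx] %in% TRUE
  keep <- if (mode == "any") a | b else a & b
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical conservation-score threshold
#'
#' The 0.975 quantile of a conservation-score collection, the point at which
#' a base counts as highly conserved (2.0 on a genome-wide phyloP-style
#' background). Uses the linear-interpolation quantile definition
#' (`stats::quantile` type 7).
#'
#' @param scores numeric vector, non-empty.
#' @param prob quantile level (default 0.975).
#' @return the score threshold.
#' @examples
#' conservation_threshold(1:1000)  # 975.025
#' @export
conservation_threshold <- function(scores, prob = 0.975) {
  if (!length(scores)) stop("cannot take a quantile of an empty score set")
  unname(stats::quantile(scores, prob, type = 7, names = FALSE))
}

#' Conservation filter
#'
#' Keeps variants whose per-base conservation score is greater than or equal
#' to `threshold` (inclusive). Variants with no score are dropped with a
#' warning (missing annotation fails closed).
#'
#' @param variants data frame with chrom and pos.
#' @param scores data frame with chrom, pos, score.
#' @param threshold inclusive score cutoff (default 2.0).
#' @return the surviving subset of `variants`.
#' @export
filter_conserved <- function(variants, scores, threshold = 2.0) {
  if (!nrow(variants)) return(variants)
  idx <- match(paste(variants$chrom, variants$pos),
               paste(scores$chrom, scores$pos))
  if (anyNA(idx))
    warning(sum(is.na(idx)),
            " variant(s) without a conservation score dropped")
  keep <- !is.na(idx) & scores$score[idx] >= threshold
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expression filter
#'
#' Computes genewise mean expression across all samples of the matrix, sets
#' the threshold at the first quartile of those means, and keeps variants in
#' genes whose mean is at or above it (inclusive). Variants whose gene is
#' absent from the matrix are dropped with a warning.
#'
#' @param variants data frame with a gene_id column.
#' @param expression data frame: `gene` column plus one numeric column per
#'   sample.
#' @return the surviving subset of `variants`.
#' @export
filter_expressed <- function(variants, expression) {
  if (!nrow(variants)) return(variants)
  if (ncol(expression) < 2L)
    stop("expression matrix needs at least one sample column")
  means <- rowMeans(expression[, -1L, drop = FALSE])
  q1 <- unname(stats::quantile(means, 0.25, type = 7, names = FALSE))
  expressed_genes <- expression$gene[means >= q1]
  idx <- match(variants$gene_id, expression$gene)
  if (anyNA(idx))
    warning(sum(is.na(idx)),
            " variant(s) in genes absent from the expression matrix dropped")
  keep <- variants$gene_id %in% expressed_genes
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach gene-category and catalogue flags
#'
#' Pure flag attachment (no filtering): marks each variant's gene for
#' membership in the repair / kinase / receptor / transmembrane-receptor
#' category sets and the cancer-census / prior-study catalogues.
#'
#' @param variants data frame with a gene_id column.
#' @param categories named list of gene-id vectors (repair, kinase,
#'   receptor, transmembrane_receptor).
#' @param catalogues named list of gene-id vectors (cancer_census,
#'   prior_study).
#' @return `variants` with one logical column per set.
#' @export
flag_categories <- function(variants, categories, catalogues = list()) {
  for (nm in names(categories))
    variants[[nm]] <- variants$gene_id %in% categories[[nm]]
  for (nm in names(catalogues))
    variants[[nm]] <- variants$gene_id %in% catalogues[[nm]]
  variants
}

#' Run the somatic-variant prioritization cascade
#'
#' Applies, in order: the consequence-severity gate (protein-affecting
#' classes), the population-frequency filter, and the
#' functional-impairment filter; with `extended = TRUE` the conservation,
#' expression and category stages also act as filters (reproducing the
#' successive narrowing reading of the workflow), otherwise they are
#' attached as reporting annotations only. Surviving counts are recorded at
#' every stage and are non-increasing by construction.
#'
#' @param variants labelled-somatic records carrying `gene_id` and a
#'   most-severe `consequence` column.
#' @param tables side tables as produced by [simulate_annotation_tables()]:
#'   list with frequency, damaging, conservation, expression, categories,
#'   catalogues.
#' @param frequency_threshold passed to [filter_frequency()].
#' @param functional_mode passed to [filter_functional()].
#' @param conservation_cutoff passed to [filter_conserved()].
#' @param nonsyn_classes consequence classes passing the severity gate.
#' @param extended make conservation / expression / category stages filters.
#' @return a `cascade_result`: list with `stages` (stage, n), `variants`
#'   (final set with category flags and reporting columns), `gene_rollup`.
#' @export
run_cascade <- function(variants, tables,
                        frequency_threshold = 0.01,
                        functional_mode = "any",
                        conservation_cutoff = 2.0,
                        nonsyn_classes = c("missense", "nonsense",
                                           "start_lost", "stop_lost",
                                           "splice_site"),
                        extended = FALSE) {
  stopifnot(is.data.frame(variants), is.list(tables))
  stages <- list()
  note <- function(name, df) {
    stages[[length(stages) + 1L]] <<- data.frame(stage = name, n = nrow(df))
    df
  }
  cur <- note("somatic", variants)
  keep <- nrow(cur) > 0 & cur$consequence %in% nonsyn_classes
  cur <- note("non_synonymous", cur[keep, , drop = FALSE])
  cur <- note("rare", filter_frequency(cur, tables$frequency,
                                       frequency_threshold))
  cur <- note("damaging", filter_functional(cur, tables$damaging,
                                            functional_mode))
  if (extended) {
    cur <- note("conserved",
                filter_conserved(cur, tables$conservation,
                                 conservation_cutoff))
    cur <- note("expressed", filter_expressed(cur, tables$expression))
    flagged <- flag_categories(cur, tables$categories, tables$catalogues)
    in_cat <- Reduce(`|`, lapply(names(tables$categories),
                                 function(nm) flagged[[nm]]),
                     rep(FALSE, nrow(flagged)))
    cur <- note("categorized", cur[in_cat, , drop = FALSE])
  }
  # reporting annotations on the final set
  final <- flag_categories(cur, tables$categories, tables$catalogues)
  if (nrow(final)) {
    ci <- match(paste(final$chrom, final$pos),
                paste(tables$conservation$chrom, tables$conservation$pos))
    final$conservation_score <- tables$conservation$score[ci]
    if (ncol(tables$expression) >= 2L) {
      means <- rowMeans(tables$expression[, -1L, drop = FALSE])
      final$mean_expression <-
        means[match(final$gene_id, tables$expression$gene)]
    } else {
      final$mean_expression <- NA_real_
    }
  }
  rownames(final) <- NULL

  rollup <- if (nrow(final)) {
    agg <- stats::aggregate(list(n_variants = final$pos),
                            by = list(gene_id = final$gene_id), FUN = length)
    for (nm in c(names(tables$categories), names(tables$catalogues)))
      agg[[nm]] <- agg$gene_id %in% c(tables$categories[[nm]],
                                      tables$catalogues[[nm]])
    agg
  } else {
    data.frame(gene_id = character(0), n_variants = integer(0))
  }

  structure(list(stages = do.call(rbind, stages), variants = final,
                 gene_rollup = rollup),
            class = "cascade_result")
}
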