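#' Mutation-burden fold ratio
#'
#' @param count_a,count_b mutation counts; `count_b` must be positive.
#' @return `count_a / count_b`.
#' @examples
#' fold_ratio(532, 65)  # 8.18..., i.e. about 8-fold
#' @export
fold_ratio <- function(count_a, count_b) {
  if (any(count_b <= 0)) stop("denominator count must be positive")
  count_a / count_b
}

# Reduce per-transcript annotations to one row per variant carrying the
# most severe consequence (ties broken by transcript id order).
reduce_to_most_severe <- function(ann) {
  if (!nrow(ann)) {
    out <- ann
    return(out)
  }
  key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
  sev <- match(ann$consequence, CONSEQUENCE_SEVERITY)
  ord <- order(key, sev, ann$transcript_id, na.last = TRUE)
  ann <- ann[ord, , drop = FALSE]
  out <- ann[!duplicated(paste(ann$chrom, ann$pos, ann$ref, ann$alt)), ,
             drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a pipeline run across patients
#'
#' Aggregates per-patient labelled-somatic counts (total and
#' non-synonymous), consequence-class fractions over labelled-somatic
#' variants (most severe consequence per variant; fractions sum to 1),
#' cascade stage counts, the CNV segment count, and the matrix of pairwise
#' mutation-burden fold ratios.
#'
#' @param patient_results named list; each element needs `somatic` (records
#'   from [classify_somatic()]), `annotated` (one row per somatic variant
#'   with a `consequence` column) and `cascade` (a `cascade_result`).
#' @param cnv_segments optional segment table from [call_states()].
#' @param nonsyn_classes consequence classes counted as non-synonymous.
#' @return a `run_summary` list.
#' @export
summarize_run <- function(patient_results, cnv_segments = NULL,
                          nonsyn_classes = c("missense", "nonsense",
                                             "start_lost", "stop_lost",
                                             "splice_site")) {
  need <- c("somatic", "annotated", "cascade")
  for (nm in names(patient_results)) {
    missing <- setdiff(need, names(patient_results[[nm]]))
    if (length(missing))
      stop("patient '", nm, "' lacks stage output(s): ",
           paste(missing, collapse = ", "))
  }
  per_patient <- do.call(rbind, lapply(names(patient_results), function(nm) {
    r <- patient_results[[nm]]
    lab <- r$somatic[r$somatic$status == "somatic", , drop = FALSE]
    data.frame(patient = nm,
               n_somatic = nrow(lab),
               n_nonsyn = sum(r$annotated$consequence %in% nonsyn_classes),
               stringsAsFactors = FALSE)
  }))
  fractions <- lapply(patient_results, function(r) {
    cls <- r$annotated$consequence
    if (!length(cls)) return(stats::setNames(numeric(0), character(0)))
    tab <- table(factor(cls, levels = CONSEQUENCE_SEVERITY))
    as.list(tab[tab > 0] / sum(tab))
  })
  stage_counts <- lapply(patient_results, function(r) {
    stats::setNames(as.list(r$cascade$stages$n), r$cascade$stages$stage)
  })
  counts <- stats::setNames(per_patient$n_nonsyn, per_patient$patient)
  fold <- outer(counts, pmax(counts, 1L), "/")
  dimnames(fold) <- list(per_patient$patient, per_patient$patient)
  structure(list(
    per_patient = per_patient,
    consequence_fractions = fractions,
    cascade_stage_counts = stage_counts,
    n_cnv_segments = if (is.null(cnv_segments)) NA_integer_
                     else nrow(cnv_segments),
    fold_ratio_matrix = fold), class = "run_summary")
}

#' Default end-to-end pipeline configuration
#'
#' Two simulated patients (MSI-like hypermutated, MSS-like) on a shared
#' simulated genome, one CNV profile with a planted single-copy gain, and a
#' concordance comparison on the normal tissue of each patient.
#'
#' @return a nested configuration list accepted by [run_all()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    n_sites = 30000L,
    n_genes = 80L,
    heterozygosity_rate = 0.001,
    error_rate = 0.001,
    extended_cascade = FALSE,
    patients = list(
      msi_patient = list(preset = "msi"),
      mss_patient = list(preset = "mss")),
    cnv = list(bin_count = 200L, bin_size = 50000L,
               planted_segments = list(
                 list(start = 100L, end = 119L, log2_effect = 1))),
    concordance = list(grid = c(3L, 5L, 10L))
  )
}

PIPELINE_STAGES <- c("simulate", "call", "classify", "annotate",
                     "prioritize", "cnv", "concord", "report")

#' Run the whole pipeline and write its artifact directory
#'
#' Executes simulate, call, classify, annotate, prioritize, cnv, concord
#' and report for every configured patient, writing pileups and truth as
#' TSV, calls and somatic records as VCF subset plus TSV twin, the genome as
#' FASTA/GFF3, CNV segments as BED, and the reports and manifest as JSON.
#' All randomness derives from the configured seed, so rerunning with the
#' same configuration reproduces every artifact byte for byte.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file holding one.
#' @param out_dir artifact directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return invisibly, a list with the in-memory results (`genome`,
#'   `patients`, `cnv`, `summary`, `manifest`).
#' @export
run_all <- function(config = default_pipeline_config(), out_dir,
                    seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  # two-level merge; second-level values (including unnamed lists such as
  # planted_segments) replace the default wholesale
  base <- default_pipeline_config()
  for (nm in names(config)) {
    if (nm != "patients" && is.list(base[[nm]]) &&
        !is.null(names(base[[nm]])) && is.list(config[[nm]])) {
      for (k in names(config[[nm]]))
        base[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  if (!is.null(seed)) base$seed <- as.integer(seed)
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genome_cfg <- simulation_config(n_genes = base$n_genes,
                                  seed = substream(base$seed, 30L))
  genome <- simulate_gene_models(genome_cfg)
  write_genome_fasta(genome, file.path(out_dir, "reference.fasta"))
  write_gene_models_gff3(genome, file.path(out_dir, "gene_models.gff3"))

  preset_fn <- list(msi = msi_config, mss = mss_config)
  patients <- list()
  pnames <- names(base$patients)
  for (i in seq_along(pnames)) {
    nm <- pnames[i]
    spec <- base$patients[[nm]]
    preset <- spec$preset
    if (is.null(preset_fn[[preset]]))
      stop("stage simulate failed for patient '", nm,
           "': unknown preset '", preset, "'")
    overrides <- spec[setdiff(names(spec), "preset")]
    cfg <- do.call(preset_fn[[preset]], c(list(
      n_sites = base$n_sites,
      heterozygosity_rate = base$heterozygosity_rate,
      error_rate = base$error_rate,
      seed = substream(base$seed, 40L + i)), overrides))

    pdir <- file.path(out_dir, nm)
    dir.create(pdir, showWarnings = FALSE)
    sim <- simulate_pair(cfg, genome)
    write_pileup(sim$tumor, file.path(pdir, "tumor_pileup.tsv"))
    write_pileup(sim$normal, file.path(pdir, "normal_pileup.tsv"))
    write_tsv_file(sim$truth, file.path(pdir, "truth.tsv"))

    calls <- call_variants(sim$tumor)
    write_variant_vcf(calls, file.path(pdir, "tumor_calls.vcf"))
    write_tsv_file(calls, file.path(pdir, "tumor_calls.tsv"))

    stringent <- filter_tumor_calls(calls)
    som <- classify_somatic(stringent, sim$normal)
    write_variant_vcf(som, file.path(pdir, "somatic_status.vcf"))
    write_tsv_file(som, file.path(pdir, "somatic_status.tsv"))

    somatic <- som[som$status == "somatic", , drop = FALSE]
    ann_all <- annotate_variants(
      somatic[, c("chrom", "pos", "ref", "alt")], genome)
    ann <- reduce_to_most_severe(ann_all)
    in_mirna <- classify_mirna(ann, genome$mirna)
    ann$consequence[in_mirna & ann$consequence == "intergenic"] <- "mirna"
    write_tsv_file(ann_all, file.path(pdir, "annotation_by_transcript.tsv"))
    write_tsv_file(ann, file.path(pdir, "annotation_most_severe.tsv"))

    tables <- simulate_annotation_tables(cfg, sim$truth)
    cascade_input <- ann
    cascade_input$status <- rep("somatic", nrow(cascade_input))
    cascade <- run_cascade(cascade_input, tables,
                           extended = isTRUE(base$extended_cascade))
    write_tsv_file(cascade$variants, file.path(pdir, "prioritized.tsv"))
    jsonlite::write_json(
      stats::setNames(as.list(cascade$stages$n), cascade$stages$stage),
      file.path(pdir, "cascade_counts.json"), auto_unbox = TRUE,
      digits = NA)

    genotypes <- call_genotypes(sim$normal)
    array <- simulate_array_genotypes(sim$truth,
                                      seed = substream(base$seed, 60L + i))
    conc <- compare_genotypes(genotypes, array)
    conc_grid <- concordance_vs_coverage(genotypes, array,
                                         base$concordance$grid)
    jsonlite::write_json(
      list(n_compared = conc$n_compared, accuracy = conc$accuracy,
           fp_rate = conc$fp_rate, fn_rate = conc$fn_rate,
           haploid_concordance = conc$haploid_concordance,
           by_min_coverage = conc_grid),
      file.path(pdir, "concordance.json"), auto_unbox = TRUE, digits = NA)

    patients[[nm]] <- list(config = cfg, sim = sim, calls = calls,
                           somatic = som, annotated = ann,
                           cascade = cascade, concordance = conc)
  }

  cnv_cfg <- simulation_config(
    bin_count = base$cnv$bin_count, bin_size = base$cnv$bin_size,
    planted_segments = base$cnv$planted_segments,
    seed = substream(base$seed, 50L))
  cnv_sim <- simulate_cnv_counts(cnv_cfg)
  write_tsv_file(cnv_sim$counts, file.path(out_dir, "cnv_counts.tsv"))
  cnv <- with_seed(substream(base$seed, 51L), detect_cnv(cnv_sim$counts))
  write_segments_bed(cnv$segments, file.path(out_dir, "cnv_segments.bed"),
                     base$cnv$bin_size)

  summary <- summarize_run(patients, cnv$segments)
  jsonlite::write_json(
    list(per_patient = summary$per_patient,
         consequence_fractions = summary$consequence_fractions,
         cascade_stage_counts = summary$cascade_stage_counts,
         n_cnv_segments = summary$n_cnv_segments,
         fold_ratio_matrix = as.data.frame(summary$fold_ratio_matrix)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    tool = "somaticExome",
    version = as.character(utils::packageVersion("somaticExome")),
    seed = base$seed,
    stages = PIPELINE_STAGES,
    parameters = base[setdiff(names(base), "patients")],
    patients = pnames)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(genome = genome, patients = patients, cnv = cnv,
                 summary = summary, manifest = manifest))
}
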