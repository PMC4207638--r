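#' Default pipeline configuration
#'
#' A small fully-simulated configuration: toy three-chromosome genome,
#' default probe tiers, a mixed blood/hair cohort of four samples from two
#' breeds, study-condition truth parameters and the standard calling
#' thresholds (|log2| > 0.5 over >= 5 probes, homozygosity at |mean| > 2).
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @return a config list accepted by \code{\link{run_pipeline}}.
#' @export
default_pipeline_config <- function(outdir, seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    genome = list(preset = "toy"),
    probes = list(spacing_default = 7500, spacing_subtelomere = 4000,
                  spacing_chrY = 20000, subtelomere_window = 1e6,
                  jitter_fraction = 0.3),
    samples = data.frame(
      sample_id = c("E1", "E2", "F1", "F2"),
      breed = c("Exmoor Pony", "Exmoor Pony", "Friesian", "Friesian"),
      tissue = c("blood", "hair", "blood", "blood"),
      sex = c("F", "F", "M", "F"),
      reference_id = c("Twilight", "Twilight", "Bravo", "Twilight"),
      stringsAsFactors = FALSE),
    sim = list(mean_cnvs_per_sample = 8, size_range = c(5e4, 5e5)),
    calling = list(log2_threshold = 0.5, min_probes = 5, hom_threshold = 2.0),
    genes = NULL,
    studies = NULL)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the CNV discovery pipeline
#'
#' Executes simulate (when no hybridization files are configured) -> qc ->
#' call -> merge -> annotate -> stats, and integrate when multiple study
#' CNVR sets are configured.  All tables are written under
#' \code{config$outdir} together with a run log recording the package
#' version, seed and parameters; given a fixed config and seed the output
#' bundle is byte-identical across runs.
#'
#' @param config a config list (see \code{\link{default_pipeline_config}})
#'   or the path of a YAML file readable by
#'   \code{\link{read_pipeline_config}}.
#' @return invisibly, a list with the in-memory objects (genome, probe_map,
#'   truth, hybridizations, qc, calls, cnvrs, chrom_summary, summary,
#'   composite) and \code{outdir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- config$outdir %||% stop("config needs an 'outdir'")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "hybridizations"), showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  genome <- pipeline_stage("genome", {
    g <- config$genome %||% list(preset = "toy")
    if (!is.null(g$chrom_sizes)) read_chrom_sizes(g$chrom_sizes)
    else if (!is.null(g$preset)) build_genome(preset = g$preset)
    else build_genome(spec = as.data.frame(g$spec))
  })
  write_chrom_sizes(genome, file.path(outdir, "chrom_sizes.tsv"))

  probe_map <- pipeline_stage("probe_map", {
    p <- config$probes %||% list()
    design_probe_map(
      genome,
      spacing = list(default = p$spacing_default %||% 7500,
                     subtelomere = p$spacing_subtelomere %||% 4000,
                     chrY = p$spacing_chrY %||% 20000),
      subtelomere_window = p$subtelomere_window %||% 1e6,
      jitter_fraction = p$jitter_fraction %||% 0.3,
      seed = derive_seed(seed, 9999L))
  })
  write_probe_map(probe_map, file.path(outdir, "probe_map.tsv"))

  samples <- pipeline_stage("samples", {
    s <- config$samples
    if (is.character(s)) utils::read.delim(s, stringsAsFactors = FALSE)
    else as.data.frame(s, stringsAsFactors = FALSE)
  })
  write_tsv(samples, file.path(outdir, "samples.tsv"))

  sim <- pipeline_stage("simulate", {
    params <- do.call(truth_params, config$sim %||% list())
    simulate_cohort(genome, probe_map, samples, params, seed = seed)
  })
  write_bed(sim$truth, file.path(outdir, "truth.bed"),
            name = sim$truth$sample_id,
            extra = data.frame(copy_state = sim$truth$copy_state))
  for (s in names(sim$hybridizations))
    write_log2_table(sim$hybridizations[[s]], probe_map,
                     file.path(outdir, "hybridizations",
                               paste0(s, ".tsv")))

  qc <- pipeline_stage("qc", {
    do.call(rbind, lapply(sim$hybridizations, function(h)
      quality_report(h, probe_map)))
  })
  write_tsv(as.data.frame(qc), file.path(outdir, "qc.tsv"))

  cparams <- pipeline_stage("calling_params",
                            do.call(calling_params, config$calling %||%
                                      list()))
  calls <- pipeline_stage("call", {
    cl <- do.call(rbind, lapply(sim$hybridizations, function(h)
      as.data.frame(call_cnvs(h, probe_map, cparams))))
    rownames(cl) <- NULL
    class(cl) <- c("cnv_calls", "data.frame")
    cl
  })
  write_calls(calls, file.path(outdir, "calls.tsv"))
  if (nrow(calls))
    write_bed(calls, file.path(outdir, "calls.bed"), name = calls$sample_id,
              extra = data.frame(direction = calls$direction))
  else write_bed(calls[0, ], file.path(outdir, "calls.bed"))

  breed_map <- stats::setNames(as.character(samples$breed),
                               as.character(samples$sample_id))
  cnvrs <- pipeline_stage("merge", consolidate_calls(calls, breed_map))

  cnvrs <- pipeline_stage("annotate", {
    x <- if (!is.null(config$genes))
      annotate_genic(cnvrs, read_gene_annotation(config$genes)) else cnvrs
    flag_subtelomeric(x, genome,
                      window = (config$probes$subtelomere_window %||% 1e6))
  })
  write_tsv(as.data.frame(cnvrs), file.path(outdir, "cnvrs.tsv"))
  if (nrow(cnvrs))
    write_bed(cnvrs, file.path(outdir, "cnvrs.bed"), name = cnvrs$state)
  else write_bed(cnvrs[0, ], file.path(outdir, "cnvrs.bed"))

  chrom_summary <- pipeline_stage("stats",
                                  chromosome_enrichment(cnvrs, genome))
  write_tsv(chrom_summary, file.path(outdir, "chrom_summary.tsv"))
  summ <- pipeline_stage("stats", {
    if (nrow(calls)) cohort_summary(calls, cnvrs, genome) else NULL
  })
  if (!is.null(summ)) {
    flat <- summ[!vapply(summ, is.object, logical(1))]
    scalars <- flat[vapply(flat, function(x)
      is.numeric(x) && length(x) == 1, logical(1))]
    write_tsv(data.frame(statistic = names(scalars),
                         value = unlist(scalars)),
              file.path(outdir, "cohort_summary.tsv"))
    write_tsv(summ$per_sample, file.path(outdir, "per_sample_counts.tsv"))
  }

  composite <- NULL
  if (!is.null(config$studies) && length(config$studies) >= 1) {
    composite <- pipeline_stage("integrate", {
      studies <- lapply(config$studies, function(st) {
        # read_bed converts half-open BED to the internal 1-based form;
        # the declared convention applies to plain tables only
        if (grepl("\\.bed$", st$path)) {
          rec <- read_bed(st$path)
          conv <- "one_based_inclusive"
        } else {
          rec <- utils::read.delim(st$path, stringsAsFactors = FALSE)
          conv <- st$convention %||% "one_based_inclusive"
        }
        normalize_records(rec, convention = conv, genome,
                          study_id = st$study_id)
      })
      this_study <- if (nrow(cnvrs))
        normalize_records(cnvrs[, c("chrom", "start", "end")],
                          "one_based_inclusive", genome,
                          study_id = "this_study") else NULL
      integrate_studies(c(list(this_study)[!is.null(this_study)], studies))
    })
    write_tsv(as.data.frame(composite), file.path(outdir, "composite.tsv"))
    acct <- novelty_accounting(composite)
    write_tsv(acct$per_study, file.path(outdir, "study_accounting.tsv"))
  }

  pipeline_stage("log", {
    lines <- c("equicnv run log",
               paste0("package_version: ",
                      as.character(utils::packageVersion("equicnv"))),
               paste0("seed: ", seed),
               paste0("genome: ", paste(genome$chrom, genome$length,
                                        sep = "=", collapse = " ")),
               paste0("n_probes: ", nrow(probe_map)),
               paste0("n_samples: ", nrow(samples)),
               paste0("calling: log2_threshold=", cparams$log2_threshold,
                      " min_probes=", cparams$min_probes,
                      " hom_threshold=", cparams$hom_threshold),
               paste0("sim: ", paste(names(config$sim %||% list()),
                                     vapply(config$sim %||% list(),
                                            function(x)
                                              paste(x, collapse = ":"),
                                            character(1)),
                                     sep = "=", collapse = " ")),
               paste0("n_calls: ", nrow(calls)),
               paste0("n_cnvrs: ", nrow(cnvrs)))
    writeLines(lines, file.path(outdir, "run_log.txt"))
  })

  invisible(list(outdir = outdir, genome = genome, probe_map = probe_map,
                 truth = sim$truth, hybridizations = sim$hybridizations,
                 qc = qc, calls = calls, cnvrs = cnvrs,
                 chrom_summary = chrom_summary, summary = summ,
                 composite = composite))
}
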