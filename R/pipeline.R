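pipeline_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

write_manifest <- function(out_dir, stage, params, inputs = character()) {
  checksums <- purrr::map_chr(inputs, function(p) {
    as.character(tools::md5sum(p))
  })
  manifest <- list(
    package = "intronarray",
    version = as.character(utils::packageVersion("intronarray")),
    stage = stage,
    parameters = params,
    input_checksums = if (length(inputs)) as.list(setNames(checksums, basename(inputs))) else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
}

#' Generate a complete synthetic data set on disk
#'
#' Runs the synthetic-data generator end to end: annotation, genome-wide
#' probe tiling, feature map, true abundances, probe intensities, ground
#' truth and a qPCR plate, all written under `out_dir` together with a
#' manifest echoing the seed and parameters.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param probe_length,step Tiling parameters (defaults 25 and 20).
#' @param min_core_probes Intron eligibility threshold (default 4).
#' @return Invisibly, a named list of the objects written (annotation,
#'   probes, feature map, abundances, intensities, truth, qpcr plate).
#' @export
run_simulate <- function(config, out_dir, probe_length = 25L, step = 20L,
                         min_core_probes = 4L) {
  if (!inherits(config, "simulation_config")) {
    stop_invalid("`config` must be a simulation_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log("simulate: annotation (%d genes)", config$n_genes)
  ann <- simulate_annotation(config$n_genes, config$seed)
  probes <- tile_probes(ann$chromosomes, probe_length, step)
  fmap <- build_feature_map(ann, probes, min_core_probes)
  pipeline_log("simulate: %d probes, %d eligible introns",
               nrow(probes), length(fmap$eligible_introns))
  ab <- simulate_abundances(config, ann, eligible = fmap$eligible_introns)
  x <- simulate_intensities(ab, fmap, probes, config)
  true_iv <- ab$truth$retention |>
    filter(.data$intron_id %in% ab$truth$candidate_introns)
  qpcr_truth <- c(intron_A = 2e4, exon_A = 8e4, myo1 = 5e4)
  plate <- simulate_qpcr(qpcr_truth, efficiency = 0.95,
                         seed = derive_seed(config$seed, 9L))

  write_annotation(ann, file.path(out_dir, "annotation.gff3"))
  write_probes(probes, file.path(out_dir, "probes.tsv"))
  write_feature_map(fmap, file.path(out_dir, "feature_map.tsv"))
  write_intensities(x, file.path(out_dir, "intensities.tsv"))
  write_qpcr_plate(plate, file.path(out_dir, "qpcr_plate.tsv"))
  truth_json <- list(
    affected_introns = ab$truth$affected_introns,
    fraction_affected_realized = ab$truth$fraction_affected_realized,
    candidate_introns = ab$truth$candidate_introns,
    retention = ab$truth$retention,
    qpcr_copies_per_ng = as.list(qpcr_truth),
    qpcr_efficiency = 0.95
  )
  jsonlite::write_json(truth_json, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_echo <- config[setdiff(names(config), "de_genes")]
  cfg_echo$rho_t <- as.list(config$rho_t)
  cfg_echo$rdna_precursor_fold <- as.list(config$rdna_precursor_fold)
  cfg_echo$n_samples <- nrow(ab$samples)
  cfg_echo$probe_length <- probe_length
  cfg_echo$step <- step
  cfg_echo$min_core_probes <- min_core_probes
  write_manifest(out_dir, "simulate", cfg_echo)
  pipeline_log("simulate: wrote %d files to %s", 7L, out_dir)
  invisible(list(annotation = ann, probes = probes, feature_map = fmap,
                 abundances = ab, intensities = x, plate = plate))
}

#' Run the microarray analysis pipeline
#'
#' Feature mapping, background correction, quantile normalization,
#' median-polish summarization, replicate QC, intron/exon retention ratios
#' with per-timepoint Mann-Whitney tests and fold-change exceedance
#' counts, and moderated-t differential expression — writing every table
#' plus a JSON summary and manifest to `out_dir`.
#'
#' @param annotation A [genome_annotation()] or path to a GFF3 file.
#' @param probes Probe tibble or path to a probe TSV.
#' @param intensities An [intensity_matrix()] or path to an intensity TSV
#'   (with its `.samples.tsv` sidecar).
#' @param out_dir Output directory.
#' @param ground_truth Optional path to a ground-truth JSON from
#'   [run_simulate()]; adds recovery metrics to the summary.
#' @param min_core_probes,percentile,floor,fc_threshold,alpha,d0,exact_limit
#'   Stage parameters (see the stage functions).
#' @return Invisibly, a list: `expression`, `retention`, `time_course`,
#'   `de`, `qc`, `summary`.
#' @export
run_analyze <- function(annotation, probes, intensities, out_dir,
                        ground_truth = NULL, min_core_probes = 4L,
                        percentile = 2, floor = 1.0, fc_threshold = 1.5,
                        alpha = 0.05, d0 = 3, exact_limit = 20L) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(probes)) probes <- read_probes(probes)
  if (is.character(intensities)) intensities <- read_intensities(intensities)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pipeline_log("analyze: mapping features")
  fmap <- build_feature_map(annotation, probes, min_core_probes)
  pipeline_log("analyze: preprocessing (%d probes x %d samples)",
               nrow(intensities$intensities), nrow(intensities$samples))
  qc <- replicate_correlation(intensities)
  corrected <- background_correct(intensities, percentile, floor)
  normalized <- quantile_normalize(corrected)
  expr <- summarize_features(normalized, fmap)
  pipeline_log("analyze: retention statistics")
  retention <- compute_ratios(expr, annotation, fmap)
  tc <- retention_time_course(retention, threshold = fc_threshold,
                              exact_limit = exact_limit)
  exon_tc <- exon_time_course(expr, exact_limit = exact_limit)
  t0 <- min(expr$samples$timepoint)
  de <- purrr::map_dfr(setdiff(sort(unique(expr$samples$timepoint)), t0),
                       function(tp) {
                         differential_expression(expr, tp, fc_threshold,
                                                 alpha, d0)
                       })

  write_expression(expr, file.path(out_dir, "expression.tsv"))
  readr::write_tsv(retention$ratios, file.path(out_dir, "retention_ratios.tsv"))
  readr::write_tsv(retention$summary, file.path(out_dir, "retention_summary.tsv"))
  readr::write_tsv(de, file.path(out_dir, "differential_expression.tsv"))
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  summary <- list(
    n_eligible_introns = length(fmap$eligible_introns),
    n_scored_introns = dplyr::n_distinct(retention$summary$intron_id),
    replicate_pearson_r = qc,
    intron_time_course = tc,
    exon_time_course = exon_tc
  )
  if (!is.null(ground_truth)) {
    truth <- jsonlite::read_json(ground_truth, simplifyVector = TRUE)
    est <- tc$fraction[tc$timepoint == max(tc$timepoint)]
    summary$recovery <- list(
      true_affected_fraction = truth$fraction_affected_realized,
      estimated_affected_fraction = est,
      absolute_error = abs(est - truth$fraction_affected_realized)
    )
  }
  jsonlite::write_json(summary, file.path(out_dir, "analysis_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  write_manifest(out_dir, "analyze",
                 list(min_core_probes = min_core_probes,
                      percentile = percentile, floor = floor,
                      fc_threshold = fc_threshold, alpha = alpha, d0 = d0,
                      exact_limit = exact_limit))
  pipeline_log("analyze: done (%d eligible introns)",
               length(fmap$eligible_introns))
  invisible(list(feature_map = fmap, expression = expr, retention = retention,
                 time_course = tc, exon_time_course = exon_tc, de = de,
                 qc = qc, summary = summary))
}

#' Exon-level distribution shifts over time
#'
#' Mann-Whitney comparison of summarized exon log2 levels at each timepoint
#' against baseline — the negative control mirroring the expectation that
#' exon levels (mature + pre-mRNA) stay flat when only splicing is
#' perturbed.
#'
#' @param expr An `expression_table`.
#' @param exact_limit Passed to [compare_distributions()].
#' @return Tibble: `timepoint`, `u_statistic`, `p_value`.
#' @export
exon_time_course <- function(expr, exact_limit = 20L) {
  samples <- expr$samples
  tab <- filter(expr$expression, .data$kind == "exon")
  m <- as.matrix(tab[, samples$sample_id, drop = FALSE])
  by_tp <- purrr::map(split(samples$sample_id, samples$timepoint),
                      function(ids) rowMeans(m[, ids, drop = FALSE]))
  tps <- as.numeric(names(by_tp))
  t0 <- min(tps)
  purrr::map_dfr(setdiff(sort(tps), t0), function(tp) {
    cmp <- compare_distributions(by_tp[[as.character(tp)]],
                                 by_tp[[as.character(t0)]],
                                 exact_limit = exact_limit)
    tibble(timepoint = tp, u_statistic = cmp$u_statistic,
           p_value = cmp$p_value)
  })
}

#' Run the qPCR analysis
#'
#' Standard curves per target from the plate's dilution series, no-RT
#' control checks, and (when a calibrator is supplied) absolute copies per
#' ng at the reference input amount; results written as tables plus a JSON
#' summary and manifest.
#'
#' @param plate Plate tibble or path to a plate TSV.
#' @param out_dir Output directory.
#' @param calibrator Optional named list per target: each a list with
#'   `copies` and `cq` enabling absolute quantification.
#' @param reference_input_ng Input amount at which copies per ng are
#'   reported (default 50).
#' @return Invisibly, a list: `curves` (glance tibble), `no_rt`,
#'   `absolute` (or `NULL`).
#' @export
run_qpcr <- function(plate, out_dir, calibrator = NULL,
                     reference_input_ng = 50) {
  if (is.character(plate)) plate <- read_qpcr_plate(plate)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log("qpcr: fitting standard curves")
  curves <- plate_standard_curves(plate)
  curve_tab <- purrr::map_dfr(curves, function(cv) {
    bind_cols(tibble(target = cv$target), glance(cv))
  })
  no_rt <- check_no_rt(plate)
  absolute <- NULL
  if (!is.null(calibrator)) {
    agg <- aggregate_triplicates(plate) |>
      filter(.data$input_ng == reference_input_ng)
    absolute <- purrr::map_dfr(intersect(names(calibrator), agg$target),
                               function(tg) {
      row <- agg[agg$target == tg, ]
      tibble(target = tg, input_ng = reference_input_ng,
             copies_per_ng = absolute_quantify(row$mean_cq, curves[[tg]],
                                               reference_input_ng,
                                               calibrator[[tg]]))
    })
  }
  readr::write_tsv(curve_tab, file.path(out_dir, "standard_curves.tsv"))
  readr::write_tsv(no_rt, file.path(out_dir, "no_rt_controls.tsv"))
  if (!is.null(absolute)) {
    readr::write_tsv(absolute, file.path(out_dir, "absolute_quantification.tsv"))
  }
  jsonlite::write_json(
    list(curves = curve_tab,
         no_rt_contaminated = sum(no_rt$contaminated),
         absolute = absolute),
    file.path(out_dir, "qpcr_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null",
    pretty = TRUE
  )
  write_manifest(out_dir, "qpcr",
                 list(reference_input_ng = reference_input_ng,
                      has_calibrator = !is.null(calibrator)))
  pipeline_log("qpcr: %d curve(s) fitted", nrow(curve_tab))
  invisible(list(curves = curve_tab, curve_objects = curves, no_rt = no_rt,
                 absolute = absolute))
}
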