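# One full array-analysis cycle on synthetic data, returning the headline
# statistics. Used by the acceptance-style simulation tests and kept free of
# file I/O for speed.
retention_cycle <- function(seed, fraction_affected = 0.30, n_genes = 200L,
                            with_exons = TRUE, ...) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes,
                           fraction_affected = fraction_affected, ...)
  ann <- simulate_annotation(cfg$n_genes, cfg$seed)
  probes <- tile_probes(ann$chromosomes)
  fmap <- build_feature_map(ann, probes)
  ab <- simulate_abundances(cfg, ann, eligible = fmap$eligible_introns)
  x <- simulate_intensities(ab, fmap, probes, cfg)
  y <- quantile_normalize(background_correct(x))
  expr <- suppressWarnings(summarize_features(y, fmap))
  retention <- compute_ratios(expr, ann, fmap)
  tc <- retention_time_course(retention)
  out <- list(
    config = cfg, annotation = ann, feature_map = fmap, truth = ab$truth,
    expr = expr, retention = retention, time_course = tc,
    p240 = tc$p_value[tc$timepoint == 240],
    fraction240 = tc$fraction[tc$timepoint == 240],
    true_fraction = ab$truth$fraction_affected_realized,
    qc = replicate_correlation(x)
  )
  if (with_exons) {
    etc <- exon_time_course(expr)
    out$exon_p240 <- etc$p_value[etc$timepoint == 240]
  }
  out
}
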