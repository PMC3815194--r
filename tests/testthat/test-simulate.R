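small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_genes = 12L, ...)
}

test_that("abundances follow the retention model by construction", {
  cfg <- small_config(fraction_affected = 0, rho0 = 0.25,
                      expression_log2_sd = 0)
  ann <- simulate_annotation(cfg$n_genes, cfg$seed, include_rdna = FALSE,
                             n_trna = 0L)
  ab <- simulate_abundances(cfg, ann)
  wide <- tidyr::pivot_wider(ab$abundances, names_from = sample_id,
                             values_from = abundance)
  t_g <- 2^cfg$expression_log2_mean
  introns <- wide[grepl("_i1$", wide$feature_id), ]
  exons <- wide[grepl("_e1$", wide$feature_id), ]
  expect_true(all(abs(as.matrix(introns[, -1]) - 0.25 * t_g) < 1e-9))
  expect_true(all(abs(as.matrix(exons[, -1]) - t_g) < 1e-9))
  # true intron/exon ratio equals rho for every gene and sample
  expect_true(all(abs(as.matrix(introns[, -1]) /
                        as.matrix(exons[, -1]) - 0.25) < 1e-12))
})

test_that("with fraction_affected = 0 every intron keeps a constant rho", {
  cfg <- small_config(fraction_affected = 0)
  ann <- simulate_annotation(cfg$n_genes, cfg$seed)
  ab <- simulate_abundances(cfg, ann)
  per_intron <- tapply(ab$truth$retention$rho, ab$truth$retention$intron_id,
                       function(x) diff(range(x)))
  expect_true(all(per_intron == 0))
  expect_equal(ab$truth$affected_introns, character(0))
})

test_that("de_genes double the exon output at the stated timepoint only", {
  de <- tibble::tibble(feature_id = "gene001", timepoint = 240, log2_fc = 1)
  cfg <- small_config(de_genes = de, fraction_affected = 0)
  ann <- simulate_annotation(cfg$n_genes, cfg$seed)
  ab <- simulate_abundances(cfg, ann)
  wide <- tidyr::pivot_wider(ab$abundances, names_from = sample_id,
                             values_from = abundance)
  e1 <- wide[wide$feature_id == "gene001_e1", ]
  expect_equal(e1$t240_r1, 2 * e1$t0_r1)
  e2 <- wide[wide$feature_id == "gene002_e1", ]
  expect_equal(e2$t240_r1, e2$t0_r1)
})

test_that("rho_t for a timepoint not in the design is rejected", {
  expect_error(
    simulation_config(seed = 1, rho_t = c(`0` = 0.1, `999` = 0.5)),
    class = "intronarray_invalid_input"
  )
})

test_that("noiseless intensities equal abundances exactly", {
  cfg <- small_config(noise_log_sd = 0, affinity_log_sd = 0,
                      background_mean = 0, gain = 1)
  ann <- simulate_annotation(cfg$n_genes, cfg$seed)
  probes <- tile_probes(ann$chromosomes)
  fmap <- build_feature_map(ann, probes)
  ab <- simulate_abundances(cfg, ann)
  x <- simulate_intensities(ab, fmap, probes, cfg)
  m <- as.matrix(x$intensities[, -1])
  rownames(m) <- x$intensities$probe_id
  # pick an intron probe and compare to the intron's abundance
  asg <- fmap$assignments[fmap$assignments$kind == "intron", ][1, ]
  ab_val <- ab$abundances$abundance[
    ab$abundances$feature_id == asg$feature_id &
      ab$abundances$sample_id == "t0_r1"]
  expect_equal(unname(m[asg$probe_id, "t0_r1"]), ab_val)

  # doubling the gain doubles the (background-free) intensity
  cfg2 <- small_config(noise_log_sd = 0, affinity_log_sd = 0,
                       background_mean = 0, gain = 2)
  x2 <- simulate_intensities(ab, fmap, probes, cfg2)
  m2 <- as.matrix(x2$intensities[, -1])
  keep <- m > 0
  expect_true(all(abs(m2[keep] / m[keep] - 2) < 1e-12))
})

test_that("equal seeds give identical data, different seeds differ", {
  cfg <- small_config(seed = 11)
  ann <- simulate_annotation(cfg$n_genes, 11)
  probes <- tile_probes(ann$chromosomes)
  fmap <- build_feature_map(ann, probes)
  a1 <- simulate_abundances(cfg, ann)
  a2 <- simulate_abundances(cfg, ann)
  expect_identical(a1, a2)
  x1 <- simulate_intensities(a1, fmap, probes, cfg)
  x2 <- simulate_intensities(a2, fmap, probes, cfg)
  expect_identical(x1, x2)
  cfg3 <- small_config(seed = 12)
  a3 <- simulate_abundances(cfg3, ann)
  expect_false(identical(a1$truth$total_levels, a3$truth$total_levels))
})

test_that("rDNA spacers track the precursor pool while mature regions stay flat", {
  cfg <- small_config(fraction_affected = 0)
  ann <- simulate_annotation(cfg$n_genes, cfg$seed, include_rdna = TRUE)
  ab <- simulate_abundances(cfg, ann)
  wide <- tidyr::pivot_wider(ab$abundances, names_from = sample_id,
                             values_from = abundance)
  its2 <- wide[wide$feature_id == "rDNA_ITS2", ]
  s18 <- wide[wide$feature_id == "rDNA_18S", ]
  expect_equal(its2$t240_r1 / its2$t0_r1, 1.65, tolerance = 1e-12)
  # mature pool dominates: 18S changes far less than the spacer
  expect_lt(s18$t240_r1 / s18$t0_r1, 1.05)
})

test_that("qPCR Cq values follow the efficiency model", {
  # perfect doubling: 4-fold more input lowers Cq by exactly 2
  plate <- simulate_qpcr(c(tgt = 1e5), efficiency = 1,
                         dilution_series = c(50, 12.5), cq_noise_sd = 0,
                         seed = 3, replicates = 1, include_no_rt = FALSE)
  expect_equal(plate$cq[2] - plate$cq[1], 2, tolerance = 1e-12)

  # 2-fold at E = 1: one cycle
  plate2 <- simulate_qpcr(c(tgt = 1e5), efficiency = 1,
                          dilution_series = c(50, 25), cq_noise_sd = 0,
                          seed = 3, replicates = 1, include_no_rt = FALSE)
  expect_equal(plate2$cq[2] - plate2$cq[1], 1, tolerance = 1e-12)

  # E = 0.9, 16-fold: delta Cq = log(16)/log(1.9)
  plate3 <- simulate_qpcr(c(tgt = 1e5), efficiency = 0.9,
                          dilution_series = c(16, 1), cq_noise_sd = 0,
                          seed = 3, replicates = 1, include_no_rt = FALSE)
  expect_equal(plate3$cq[2] - plate3$cq[1], log(16) / log(1.9),
               tolerance = 1e-9)
  expect_equal(log(16) / log(1.9), 4.320, tolerance = 5e-4)

  expect_error(simulate_qpcr(c(t = 1e4), efficiency = 0.9,
                             dilution_series = c(-1, 5), seed = 1),
               class = "intronarray_invalid_input")
  expect_error(simulate_qpcr(c(t = -3), efficiency = 0.9, seed = 1),
               class = "intronarray_invalid_input")
})
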