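test_that("standard curves recover slope and efficiency from dilution series", {
  # perfect doubling: +2 cycles per 4-fold dilution
  sc <- fit_standard_curve(four_fold_series(2))
  expect_equal(sc$slope, -2 / log10(4), tolerance = 1e-9)
  expect_equal(sc$efficiency, 1.0, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1.0, tolerance = 1e-9)

  # +2.152 per 4-fold step: E about 0.905
  sc2 <- fit_standard_curve(four_fold_series(2.152))
  expect_equal(sc2$slope, -2.152 / log10(4), tolerance = 1e-6)
  expect_equal(sc2$slope, -3.574, tolerance = 1e-3)
  expect_equal(sc2$efficiency, 10^(1 / 3.574) - 1, tolerance = 1e-3)
  expect_equal(sc2$efficiency, 0.905, tolerance = 1e-3)

  expect_error(fit_standard_curve(four_fold_series(-2)), "slope")
  expect_error(fit_standard_curve(four_fold_series(2)[1:2, ]),
               class = "intronarray_invalid_input")
})

test_that("tidy and glance expose the curve fit", {
  sc <- fit_standard_curve(four_fold_series(2.1), target = "tgt")
  td <- tidy(sc)
  expect_equal(nrow(td), 2L)
  gl <- glance(sc)
  expect_equal(gl$efficiency, sc$efficiency)
  expect_equal(gl$n_points, 5L)
})

test_that("absolute quantification scales by (1+E)^deltaCq against the calibrator", {
  sc <- fit_standard_curve(four_fold_series(2))  # E = 1
  cal <- list(copies = 1e6, cq = 20)
  # same Cq, same input: the calibrator value per ng
  expect_equal(absolute_quantify(20, sc, input_ng = 1, cal), 1e6)
  # one cycle lower at E = 1: twice the copies
  expect_equal(absolute_quantify(19, sc, input_ng = 1, cal), 2e6)
  # E = 0.9, 3 cycles lower: 1.9^3
  sc9 <- fit_standard_curve(four_fold_series(log(4) / log(1.9)))
  expect_equal(sc9$efficiency, 0.9, tolerance = 1e-9)
  expect_equal(absolute_quantify(17, sc9, input_ng = 1, cal) / 1e6,
               1.9^3, tolerance = 1e-6)
  expect_equal(1.9^3, 6.859, tolerance = 1e-12)

  expect_error(absolute_quantify(20, sc, input_ng = 1, calibrator = NULL),
               "relative_quantify")
})

test_that("intron/exon copy ratios and their t test behave", {
  base <- tibble::tibble(
    condition = rep(c("t0", "t240"), each = 3),
    replicate = rep(1:3, 2),
    intron_copies = c(100, 110, 90, 100, 110, 90),
    exon_copies = c(400, 440, 360, 400, 440, 360)
  )
  out <- intron_exon_copy_ratio(base)
  expect_equal(out$by_condition$mean_ratio, c(0.25, 0.25))
  expect_equal(out$fold_change, 1)
  expect_equal(out$t_statistic, 0)
  expect_equal(out$p_value, 1)

  shifted <- base
  shifted$intron_copies[4:6] <- c(400, 420, 380)
  out2 <- intron_exon_copy_ratio(shifted)
  expect_gt(out2$fold_change, 3)
  expect_lt(out2$p_value, 0.05)

  bad <- base
  bad$exon_copies[1] <- 0
  expect_error(intron_exon_copy_ratio(bad),
               class = "intronarray_invalid_input")
})

test_that("relative quantification follows the efficiency-corrected model", {
  # equal Cq, equal input
  expect_equal(relative_quantify(20, 20, efficiency = 1), 1)
  # E = 1, treated two cycles lower
  expect_equal(relative_quantify(22, 20, efficiency = 1), 4)
  # input normalization
  expect_equal(relative_quantify(20, 20, efficiency = 1,
                                 input_control = 2, input_treated = 1), 2)
  # Pfaffl reference mode: E_t = 0.95, dCq_t = -2 (treated lower), ref flat
  fc <- relative_quantify(20, 22, efficiency = 0.95,
                          reference = list(cq_control = 25, cq_treated = 25,
                                           efficiency = 1))
  expect_equal(fc, 1.95^-2)
  fc2 <- relative_quantify(22, 20, efficiency = 0.95,
                           reference = list(cq_control = 25, cq_treated = 25,
                                            efficiency = 1))
  expect_equal(fc2, 1.95^2)
  expect_equal(1.95^2, 3.8025)

  expect_error(relative_quantify(20, 19, efficiency = 1,
                                 reference = list(cq_control = 1)),
               class = "intronarray_invalid_input")
})

test_that("simulated dilution series round-trip through curve fitting", {
  # noiseless perfect doubling returns E = 1 exactly
  plate <- simulate_qpcr(c(tgt = 1e5), efficiency = 1, cq_noise_sd = 0,
                         seed = 2, include_no_rt = FALSE)
  sc <- fit_standard_curve(
    dplyr::select(aggregate_triplicates(plate), input_ng, cq = mean_cq))
  expect_equal(sc$efficiency, 1.0, tolerance = 1e-9)

  # relative quantification is invariant to the per-target constant C_ref
  p1 <- simulate_qpcr(c(a = 1e5), efficiency = 0.9, cq_noise_sd = 0,
                      seed = 5, c_ref = 40, include_no_rt = FALSE)
  p2 <- simulate_qpcr(c(a = 4e5), efficiency = 0.9, cq_noise_sd = 0,
                      seed = 5, c_ref = 33, include_no_rt = FALSE)
  dcq_40 <- function(pl) pl$cq[pl$dilution_step == 0][1]
  fc_40 <- relative_quantify(dcq_40(p1), dcq_40(p2) + (40 - 33),
                             efficiency = 0.9)
  expect_equal(fc_40, 4, tolerance = 1e-9)
})

test_that("triplicate aggregation flags outlier wells without removing them", {
  plate <- tibble::tibble(
    well = paste0("W", 1:4),
    target = "t", sample = "s", input_ng = 50, dilution_step = 0L,
    cq = c(20.0, 20.1, 21.5, NA), no_rt = c(FALSE, FALSE, FALSE, TRUE)
  )
  agg <- aggregate_triplicates(plate)
  expect_equal(agg$n_wells, 3L)
  expect_equal(agg$n_outliers, 1L)
  expect_equal(agg$mean_cq, mean(c(20.0, 20.1, 21.5)))
})

test_that("no-RT controls are screened for contamination", {
  plate <- tibble::tibble(
    well = c("W1", "W2", "W3"),
    target = "t", sample = "s", input_ng = 50, dilution_step = 0L,
    cq = c(20, NA, 30), no_rt = c(FALSE, TRUE, TRUE)
  )
  chk <- check_no_rt(plate)
  expect_equal(chk$contaminated, c(FALSE, TRUE))
})
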