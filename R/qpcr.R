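#' Read / write a qPCR plate table
#'
#' Tab-separated columns: `well`, `target`, `sample`, `input_ng`,
#' `dilution_step`, `cq` (empty for non-amplified wells), `no_rt`.
#'
#' @param path File path.
#' @export
read_qpcr_plate <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    well = readr::col_character(), target = readr::col_character(),
    sample = readr::col_character(), input_ng = readr::col_double(),
    dilution_step = readr::col_integer(), cq = readr::col_double(),
    no_rt = readr::col_logical()
  ))
}

#' @rdname read_qpcr_plate
#' @param plate Plate tibble.
#' @export
write_qpcr_plate <- function(plate, path) {
  readr::write_tsv(plate, path)
  invisible(path)
}

#' Average triplicate wells
#'
#' Arithmetic mean Cq per (target, sample, input amount); wells more than
#' `outlier_cycles` from their triplicate median are flagged (never
#' removed). No-RT control wells are excluded from averaging.
#'
#' @param plate A plate tibble (see [read_qpcr_plate()]).
#' @param outlier_cycles Flagging distance in cycles (default 0.5).
#' @return Tibble: `target`, `sample`, `input_ng`, `dilution_step`,
#'   `mean_cq`, `n_wells`, `n_outliers`.
#' @export
aggregate_triplicates <- function(plate, outlier_cycles = 0.5) {
  plate |>
    filter(!.data$no_rt, !is.na(.data$cq)) |>
    group_by(.data$target, .data$sample, .data$input_ng,
             .data$dilution_step) |>
    summarise(
      mean_cq = mean(.data$cq),
      n_wells = n(),
      n_outliers = sum(abs(.data$cq - median(.data$cq)) > outlier_cycles),
      .groups = "drop"
    )
}

#' Check no-RT controls
#'
#' No-reverse-transcriptase wells must not amplify: a recorded Cq at or
#' below `cutoff` indicates DNA contamination.
#'
#' @param plate A plate tibble.
#' @param cutoff Cq above which a signal is treated as non-amplification
#'   (default 35).
#' @return Tibble of no-RT wells with a `contaminated` flag.
#' @export
check_no_rt <- function(plate, cutoff = 35) {
  plate |>
    filter(.data$no_rt) |>
    mutate(contaminated = !is.na(.data$cq) & .data$cq <= cutoff) |>
    select("well", "target", "sample", "cq", "contaminated")
}

#' Fit a dilution-series standard curve
#'
#' Least-squares fit of `Cq = intercept + slope * log10(input)` over a
#' dilution series; the amplification efficiency follows from the slope as
#' `E = 10^(-1/slope) - 1` (a perfect-doubling assay gives slope
#' -1/log10(2) per 10-fold, i.e. about -3.32, and E = 1).
#'
#' @param points Tibble with `input_ng` and `cq` (mean Cq per input), e.g.
#'   from [aggregate_triplicates()]; a `mean_cq` column is accepted.
#' @param target Optional target label stored on the result.
#' @return A `standard_curve` object: `target`, `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n_points`, and the underlying `points`.
#'   Efficiencies above 1 (possible under measurement noise) are flagged
#'   with a warning above 1.1.
#' @export
fit_standard_curve <- function(points, target = NA_character_) {
  points <- as_tibble(points)
  if ("mean_cq" %in% names(points) && !"cq" %in% names(points)) {
    points <- rename(points, cq = "mean_cq")
  }
  if (!all(c("input_ng", "cq") %in% names(points))) {
    stop_invalid("`points` needs columns `input_ng` and `cq`")
  }
  points <- filter(points, !is.na(.data$cq))
  if (length(unique(points$input_ng)) < 3L) {
    stop_invalid("standard curve needs >= 3 distinct input amounts")
  }
  if (any(points$input_ng <= 0)) stop_invalid("input amounts must be > 0")
  fit <- lm(cq ~ log10(input_ng), data = points)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    stop_invalid("no amplification trend: slope %.3f is not negative", slope)
  }
  efficiency <- 10^(-1 / slope) - 1
  if (efficiency > 1.1) {
    warn(sprintf("standard curve efficiency %.3f exceeds 1.1; check the series",
                 efficiency))
  }
  # noiseless series fit exactly; summary.lm warns about perfect fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(target = target, slope = slope,
         intercept = unname(coef(fit)[1L]), efficiency = efficiency,
         r_squared = r2, n_points = nrow(points), points = points,
         fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve%s> slope %.3f, E = %.3f, r^2 = %.4f (%d points)\n",
              if (is.na(x$target)) "" else paste0(" ", x$target),
              x$slope, x$efficiency, x$r_squared, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return [tidy()]: one row per coefficient (`term`, `estimate`,
#'   `std.error`); [glance()]: one row with `slope`, `intercept`,
#'   `efficiency`, `r.squared`, `n_points`.
#' @export
tidy.standard_curve <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1L], std.error = sm[, 2L])
}

#' @rdname tidy.standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, r.squared = x$r_squared,
         n_points = x$n_points)
}

#' Absolute quantification against a calibrator
#'
#' Converts a Cq into copies per ng of input using the curve's efficiency
#' and a calibrator of known copy number:
#' `copies_per_ng = calibrator_copies * (1+E)^(Cq_cal - Cq) / input_ng`.
#'
#' @param cq Observed Cq (vectorized).
#' @param curve A `standard_curve` (supplies the efficiency).
#' @param input_ng Input amount of the measured reaction, in ng.
#' @param calibrator List with `copies` (absolute copies in the calibrator
#'   reaction) and `cq` (its Cq). Without it absolute mode is impossible —
#'   use [relative_quantify()] instead.
#' @return Copies per ng (numeric).
#' @export
absolute_quantify <- function(cq, curve, input_ng, calibrator) {
  if (missing(calibrator) || is.null(calibrator) ||
      !all(c("copies", "cq") %in% names(calibrator))) {
    stop_invalid(paste0(
      "absolute quantification needs a calibrator (list with `copies` and ",
      "`cq`); without one, use relative_quantify()"))
  }
  if (any(input_ng <= 0)) stop_invalid("input_ng must be > 0")
  if (calibrator$copies <= 0) stop_invalid("calibrator copies must be > 0")
  e <- curve$efficiency
  calibrator$copies * (1 + e)^(calibrator$cq - cq) / input_ng
}

#' Normalized intron/exon copy ratio with a t test
#'
#' Per replicate, the ratio of intron to exon absolute copies; conditions
#' are compared with a two-sample two-tailed Student's t test on the
#' replicate ratios, and the effect is reported as the treated/control
#' fold change of mean ratios.
#'
#' @param measurements Tibble with columns `condition`, `replicate`,
#'   `intron_copies`, `exon_copies`; exactly two conditions, at least two
#'   replicates each. The first condition level (factor order or order of
#'   appearance) is the control.
#' @return List with `by_condition` (tibble `condition`, `mean_ratio`,
#'   `sd_ratio`, `n`), `fold_change`, `t_statistic`, `p_value`.
#' @export
intron_exon_copy_ratio <- function(measurements) {
  measurements <- as_tibble(measurements)
  needed <- c("condition", "replicate", "intron_copies", "exon_copies")
  if (!all(needed %in% names(measurements))) {
    stop_invalid("`measurements` needs columns: %s", paste(needed, collapse = ", "))
  }
  if (any(measurements$exon_copies <= 0)) {
    stop_invalid("exon copies must be > 0 to form a ratio")
  }
  conds <- unique(as.character(measurements$condition))
  if (length(conds) != 2L) stop_invalid("exactly two conditions required")
  measurements <- mutate(measurements,
                         ratio = .data$intron_copies / .data$exon_copies)
  by_cond <- measurements |>
    group_by(condition = as.character(.data$condition)) |>
    summarise(mean_ratio = mean(.data$ratio), sd_ratio = stats::sd(.data$ratio),
              n = n(), .groups = "drop")
  if (any(by_cond$n < 2L)) stop_invalid(">= 2 replicates per condition required")
  a <- measurements$ratio[measurements$condition == conds[1L]]
  b <- measurements$ratio[measurements$condition == conds[2L]]
  if (stats::var(a) + stats::var(b) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(b, a, var.equal = TRUE)
  }
  list(
    by_condition = by_cond[match(conds, by_cond$condition), ],
    fold_change = mean(b) / mean(a),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value
  )
}

#' Efficiency-corrected relative quantification
#'
#' Input-normalized mode: fold change
#' `FC = (1+E)^(Cq_control - Cq_treated) * input_control / input_treated`,
#' i.e. abundance relative to the amount of starting material. Reference-
#' gene mode (Pfaffl): the target ratio divided by the reference-gene
#' ratio, each efficiency-corrected.
#'
#' @param cq_control,cq_treated Target Cq in the two conditions.
#' @param efficiency Target amplification efficiency in (0, 1.1].
#' @param input_control,input_treated Input amounts (default 1, equal).
#' @param reference Optional list for reference-gene normalization:
#'   `cq_control`, `cq_treated`, `efficiency`.
#' @return Fold change (treated over control), numeric.
#' @export
relative_quantify <- function(cq_control, cq_treated, efficiency,
                              input_control = 1, input_treated = 1,
                              reference = NULL) {
  assert_scalar_number(efficiency, "efficiency", min = 1e-9, max = 1.1)
  fc <- (1 + efficiency)^(cq_control - cq_treated) *
    (input_control / input_treated)
  if (!is.null(reference)) {
    if (!all(c("cq_control", "cq_treated", "efficiency") %in% names(reference))) {
      stop_invalid("reference mode needs `cq_control`, `cq_treated` and `efficiency` for the reference gene")
    }
    ref_fc <- (1 + reference$efficiency)^(reference$cq_control -
                                            reference$cq_treated)
    fc <- fc / ref_fc
  }
  fc
}

#' Per-target standard curves from a plate
#'
#' Convenience wrapper: triplicates are averaged and one curve fitted per
#' (target, sample) dilution series. Multi-copy tRNA targets sharing a
#' `copy_group` should be encoded as one pooled target, mirroring assays
#' whose amplicons are a mixture over identical gene copies.
#'
#' @param plate A plate tibble.
#' @return Named list of `standard_curve` objects (by target).
#' @export
plate_standard_curves <- function(plate) {
  agg <- aggregate_triplicates(plate)
  curves <- purrr::map(split(agg, agg$target), function(d) {
    fit_standard_curve(select(d, "input_ng", cq = "mean_cq"),
                       target = d$target[1L])
  })
  curves
}
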