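#' Per-intron intron/exon retention ratios
#'
#' For every eligible intron, the per-sample ratio of the intron's linear
#' expression level to the geometric mean of its two flanking exons'
#' levels — an estimate of pre-mRNA / (mRNA + pre-mRNA), the unspliced
#' fraction. Replicates are averaged per timepoint on the linear scale and
#' fold changes taken against the earliest timepoint.
#'
#' @param expr An `expression_table` from [summarize_features()].
#' @param annotation The [genome_annotation()].
#' @param feature_map The `feature_map`; only `eligible_introns` are scored.
#' @param pool_replicates Keep per-sample ratios un-averaged in the summary
#'   (each replicate contributes its own observation) instead of averaging
#'   replicates per timepoint (default `FALSE`).
#' @return A `retention_table`: list with `ratios` (long tibble `intron_id`,
#'   `sample_id`, `timepoint`, `replicate`, `ratio`) and `summary` (tibble
#'   `intron_id`, `timepoint`, `mean_ratio`, `fold_change`).
#' @export
compute_ratios <- function(expr, annotation, feature_map,
                           pool_replicates = FALSE) {
  flanks <- intron_flanks(annotation)
  flanks <- flanks[flanks$intron_id %in% feature_map$eligible_introns, ]
  m <- expression_matrix(expr)
  have <- function(ids) ids %in% rownames(m)
  ok <- have(flanks$intron_id) & have(flanks$exon_left) & have(flanks$exon_right)
  if (any(!ok)) {
    warn(sprintf("compute_ratios: %d intron(s) dropped (missing intron or flanking-exon expression)",
                 sum(!ok)))
    flanks <- flanks[ok, ]
  }
  if (nrow(flanks) == 0L) {
    stop_invalid("no eligible introns with complete flanking-exon expression")
  }
  intron_log2 <- m[flanks$intron_id, , drop = FALSE]
  flank_log2 <- (m[flanks$exon_left, , drop = FALSE] +
                 m[flanks$exon_right, , drop = FALSE]) / 2
  ratio_mat <- 2^(intron_log2 - flank_log2)
  rownames(ratio_mat) <- flanks$intron_id
  ratios <- as_tibble(ratio_mat, rownames = "intron_id") |>
    tidyr::pivot_longer(-"intron_id", names_to = "sample_id",
                        values_to = "ratio") |>
    left_join(expr$samples, by = "sample_id")
  t0 <- min(expr$samples$timepoint)
  summary <- ratios |>
    group_by(.data$intron_id, .data$timepoint) |>
    summarise(mean_ratio = mean(.data$ratio), .groups = "drop_last") |>
    mutate(fold_change = .data$mean_ratio /
             .data$mean_ratio[.data$timepoint == t0]) |>
    ungroup()
  structure(
    list(ratios = ratios, summary = summary,
         pool_replicates = pool_replicates, baseline = t0),
    class = "retention_table"
  )
}

#' @export
print.retention_table <- function(x, ...) {
  cat(sprintf("<retention_table> %d introns x %d timepoints (baseline t%g)\n",
              dplyr::n_distinct(x$summary$intron_id),
              dplyr::n_distinct(x$summary$timepoint), x$baseline))
  invisible(x)
}

retention_values <- function(retention, timepoint) {
  if (isTRUE(retention$pool_replicates)) {
    retention$ratios$ratio[retention$ratios$timepoint == timepoint]
  } else {
    retention$summary$mean_ratio[retention$summary$timepoint == timepoint]
  }
}

#' Mann-Whitney comparison of two ratio distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The p value is exact
#' when the combined sample size is at most `exact_limit` and no ties are
#' present, otherwise the tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param ratios_a,ratios_b Numeric vectors (non-empty).
#' @param exact_limit Combined-size cutoff for the exact distribution
#'   (default 20).
#' @return One-row tibble: `u_statistic`, `p_value`, `n_a`, `n_b`, `exact`.
#' @export
compare_distributions <- function(ratios_a, ratios_b, exact_limit = 20L) {
  if (!length(ratios_a) || !length(ratios_b)) {
    stop_invalid("both samples must be non-empty")
  }
  ties <- anyDuplicated(c(ratios_a, ratios_b)) > 0L
  exact <- (length(ratios_a) + length(ratios_b)) <= exact_limit && !ties
  res <- wilcox.test(ratios_a, ratios_b, alternative = "two.sided",
                     exact = exact, correct = TRUE)
  tibble(u_statistic = unname(res$statistic), p_value = res$p.value,
         n_a = length(ratios_a), n_b = length(ratios_b), exact = exact)
}

#' Count introns exceeding a retention fold change
#'
#' @param retention A `retention_table`.
#' @param timepoint Timepoint (minutes) to evaluate.
#' @param threshold Fold-change threshold; introns counted when strictly
#'   above it (default 1.5).
#' @return One-row tibble: `timepoint`, `threshold`, `n_exceeding`,
#'   `n_total`, `fraction`.
#' @export
count_fold_change_exceedance <- function(retention, timepoint,
                                         threshold = 1.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_invalid("`threshold` must be a positive number")
  }
  fc <- retention$summary |>
    filter(.data$timepoint == !!timepoint)
  if (nrow(fc) == 0L) stop_invalid("timepoint %s not present", timepoint)
  tibble(
    timepoint = timepoint, threshold = threshold,
    n_exceeding = sum(fc$fold_change > threshold),
    n_total = nrow(fc),
    fraction = sum(fc$fold_change > threshold) / nrow(fc)
  )
}

#' Moderated-t differential expression against baseline
#'
#' Compares each feature's log2 level at `timepoint` with the earliest
#' timepoint using a two-sample t statistic whose pooled variance is shrunk
#' toward the across-feature mean residual variance `s0^2` with prior
#' weight `d0`: `s_mod^2 = (d0 * s0^2 + d * s^2) / (d0 + d)` with `d`
#' residual degrees of freedom, and p values from a t distribution on
#' `d0 + d` degrees of freedom. `d0 = 0` recovers the ordinary pooled t
#' test. Features are selected when the fold change exceeds `fc_threshold`
#' and the raw p value is below `alpha`; Benjamini-Hochberg adjusted values
#' are reported alongside.
#'
#' @param expr An `expression_table`.
#' @param timepoint Timepoint to contrast with baseline.
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param alpha Raw-p selection level (default 0.05).
#' @param d0 Prior degrees of freedom of the variance shrinkage (default 3).
#' @param kinds Feature kinds to test (default all present).
#' @return Tibble: `feature_id`, `kind`, `timepoint`, `log2_fc`,
#'   `t_statistic`, `df`, `p_value`, `p_adjusted`, `selected`.
#' @export
differential_expression <- function(expr, timepoint, fc_threshold = 1.5,
                                    alpha = 0.05, d0 = 3, kinds = NULL) {
  assert_scalar_number(d0, "d0", min = 0)
  samples <- expr$samples
  t0 <- min(samples$timepoint)
  s_base <- samples$sample_id[samples$timepoint == t0]
  s_trt <- samples$sample_id[samples$timepoint == timepoint]
  if (length(s_base) < 2L || length(s_trt) < 2L) {
    stop_invalid("need >= 2 replicates per group (baseline t%g: %d, t%s: %d)",
                 t0, length(s_base), timepoint, length(s_trt))
  }
  tab <- expr$expression
  if (!is.null(kinds)) tab <- filter(tab, .data$kind %in% kinds)
  m <- as.matrix(tab[, samples$sample_id, drop = FALSE])
  b <- m[, s_base, drop = FALSE]
  w <- m[, s_trt, drop = FALSE]
  n1 <- ncol(b); n2 <- ncol(w)
  d <- n1 + n2 - 2L
  fc <- rowMeans(w) - rowMeans(b)
  ss <- rowSums((b - rowMeans(b))^2) + rowSums((w - rowMeans(w))^2)
  s2 <- ss / d
  s0_sq <- mean(s2)
  s2_mod <- (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, fc / se, 0)
  df <- d0 + d
  p <- 2 * pt(-abs(tstat), df = df)
  padj <- bh_adjust(p)
  tibble(
    feature_id = tab$feature_id, kind = tab$kind, timepoint = timepoint,
    log2_fc = unname(fc), t_statistic = unname(tstat), df = df,
    p_value = unname(p), p_adjusted = padj,
    selected = 2^abs(unname(fc)) > fc_threshold & unname(p) < alpha
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: p values are sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1, and returned in
#' the original order.
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop_invalid("p values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Time-course retention summary
#'
#' Per-timepoint Mann-Whitney comparison of the intron/exon ratio
#' distribution with baseline, plus fold-change exceedance counts — the
#' machine-readable analogue of a ratio box-plot panel and its
#' "fraction above 1.5-fold" statement.
#'
#' @param retention A `retention_table`.
#' @param threshold Fold-change threshold (default 1.5).
#' @param exact_limit Passed to [compare_distributions()].
#' @return Tibble keyed by timepoint with `u_statistic`, `p_value`,
#'   `n_exceeding`, `n_total`, `fraction`.
#' @export
retention_time_course <- function(retention, threshold = 1.5,
                                  exact_limit = 20L) {
  tps <- sort(unique(retention$summary$timepoint))
  base <- retention_values(retention, retention$baseline)
  purrr::map_dfr(setdiff(tps, retention$baseline), function(tp) {
    cmp <- compare_distributions(retention_values(retention, tp), base,
                                 exact_limit = exact_limit)
    exc <- count_fold_change_exceedance(retention, tp, threshold)
    bind_cols(tibble(timepoint = tp),
              select(cmp, "u_statistic", "p_value"),
              select(exc, "n_exceeding", "n_total", "fraction"))
  })
}
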