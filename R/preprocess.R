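#' Probe intensity matrix with sample metadata
#'
#' @param intensities A numeric matrix (probes x samples, positive values,
#'   dimnames set) or a wide tibble with `probe_id` plus one column per
#'   sample.
#' @param samples Tibble with `sample_id`, `timepoint`, `replicate`;
#'   `sample_id` must match the intensity columns.
#' @return An `intensity_matrix` object: list with `intensities` (wide
#'   tibble, `probe_id` first) and `samples`.
#' @export
intensity_matrix <- function(intensities, samples) {
  samples <- as_tibble(samples)
  if (is.matrix(intensities)) {
    intensities <- bind_cols(tibble(probe_id = rownames(intensities)),
                             as_tibble(intensities))
  }
  intensities <- as_tibble(intensities)
  if (!"probe_id" %in% names(intensities)) {
    stop_invalid("`intensities` needs a `probe_id` column")
  }
  missing_cols <- setdiff(samples$sample_id, names(intensities))
  if (length(missing_cols)) {
    stop_invalid("intensity columns missing for sample(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  vals <- as.matrix(intensities[, samples$sample_id, drop = FALSE])
  if (anyNA(vals)) stop_invalid("intensities contain missing values")
  if (any(vals < 0)) stop_invalid("intensities must be non-negative")
  structure(
    list(
      intensities = select(intensities, "probe_id", all_of(samples$sample_id)),
      samples = samples
    ),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d probes x %d samples\n",
              nrow(x$intensities), nrow(x$samples)))
  invisible(x)
}

as_matrix <- function(x) {
  m <- as.matrix(x$intensities[, x$samples$sample_id, drop = FALSE])
  rownames(m) <- x$intensities$probe_id
  m
}

#' Per-array percentile background correction
#'
#' Subtracts, from each array, that array's `percentile` intensity value
#' and clamps the result at `floor` so downstream log transforms stay
#' defined. A simple, fully specified stand-in for convolution-model
#' background correction: downstream statistics depend only on relative
#' levels.
#'
#' @param x An [intensity_matrix()].
#' @param percentile Percentile (0-100, default 2) estimating the
#'   array-specific background.
#' @param floor Lower clamp after subtraction (default 1).
#' @return A background-corrected `intensity_matrix`.
#' @export
background_correct <- function(x, percentile = 2, floor = 1.0) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile < 0 || percentile >= 100) {
    stop_invalid("`percentile` must lie in [0, 100)")
  }
  m <- as_matrix(x)
  bg <- apply(m, 2L, quantile, probs = percentile / 100)
  m <- pmax(sweep(m, 2L, bg, `-`), floor)
  intensity_matrix(m, x$samples)
}

#' Quantile normalization
#'
#' Forces every array onto the common distribution given by the across-array
#' mean of order statistics; ranks within each array are preserved and ties
#' share the mean of their would-be values. Applying it twice is the same as
#' applying it once.
#'
#' @param x An [intensity_matrix()].
#' @return A normalized `intensity_matrix`.
#' @export
quantile_normalize <- function(x) {
  m <- as_matrix(x)
  if (ncol(m) > 1L) {
    m2 <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(m2) <- dimnames(m)
    m <- m2
  }
  intensity_matrix(m, x$samples)
}

#' Two-way median polish
#'
#' Fits `value ~ overall + row + column + residual` by alternately sweeping
#' row and column medians (rows first) until the largest absolute sweep
#' falls below `tol` or `max_iter` is reached.
#'
#' @param mat Numeric matrix.
#' @param tol Convergence tolerance on the largest absolute median sweep
#'   (default 1e-10, effectively full convergence; sweeps decay
#'   geometrically so this rarely needs more than a few dozen iterations).
#' @param max_iter Maximum sweep iterations (default 50).
#' @return List with `overall`, `row`, `col`, `residuals`, `iterations`,
#'   `converged`.
#' @export
median_polish <- function(mat, tol = 1e-10, max_iter = 50L) {
  z <- as.matrix(mat)
  fit <- .median_polish_cpp(z, tol, as.integer(max_iter))
  dimnames(fit$residuals) <- dimnames(z)
  names(fit$row) <- rownames(z)
  names(fit$col) <- colnames(z)
  fit
}

#' Summarize probe intensities into per-feature expression
#'
#' For each feature with assigned core probes, fits the additive model
#' `log2 intensity ~ probe effect + sample effect` by [median_polish()] and
#' reports `overall + sample effect` as the feature's log2 expression per
#' sample. Single-probe features pass through as that probe's log2 values.
#' Features with no assigned probes are dropped with a warning.
#'
#' @param x A background-corrected, normalized [intensity_matrix()].
#' @param feature_map A `feature_map` from [build_feature_map()].
#' @param tol,max_iter Median-polish controls (see [median_polish()]).
#' @return An `expression_table`: list with `expression` (wide tibble
#'   `feature_id`, `kind`, `n_core_probes`, then one log2 column per
#'   sample) and `samples`.
#' @export
summarize_features <- function(x, feature_map, tol = 1e-10, max_iter = 50L) {
  m <- log2(as_matrix(x))
  asg <- feature_map$assignments |>
    filter(.data$probe_id %in% rownames(m))
  counts <- feature_map$n_core_probes
  n_zero <- sum(counts$n_core_probes == 0L)
  if (n_zero > 0L) {
    warn(sprintf("summarize_features: %d feature(s) with no core probes dropped",
                 n_zero))
  }
  probe_idx <- match(asg$probe_id, rownames(m))
  split_probes <- split(probe_idx, asg$feature_id)
  feature_ids <- names(split_probes)
  effects <- vapply(split_probes, function(idx) {
    sub <- m[idx, , drop = FALSE]
    if (nrow(sub) == 1L) {
      as.numeric(sub)
    } else {
      fit <- .median_polish_cpp(sub, tol, as.integer(max_iter))
      fit$overall + fit$col
    }
  }, numeric(ncol(m)))
  expr <- t(effects)
  colnames(expr) <- colnames(m)
  meta <- counts[match(feature_ids, counts$feature_id), ]
  expression <- bind_cols(
    tibble(feature_id = feature_ids, kind = meta$kind,
           n_core_probes = meta$n_core_probes),
    as_tibble(expr)
  )
  structure(list(expression = expression, samples = x$samples),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d features x %d samples (log2)\n",
              nrow(x$expression), nrow(x$samples)))
  invisible(x)
}

expression_matrix <- function(expr) {
  m <- as.matrix(expr$expression[, expr$samples$sample_id, drop = FALSE])
  rownames(m) <- expr$expression$feature_id
  m
}

#' Replicate agreement per timepoint
#'
#' Pearson correlation of log2 probe intensities between the two replicate
#' arrays of each timepoint, the standard duplicate-quality check for
#' tiling hybridizations.
#'
#' @param x An [intensity_matrix()].
#' @return Tibble with `timepoint`, `pearson_r`.
#' @export
replicate_correlation <- function(x) {
  m <- log2(as_matrix(x))
  samples <- x$samples
  purrr::map_dfr(split(samples, samples$timepoint), function(grp) {
    if (nrow(grp) != 2L) {
      stop_invalid("timepoint %g does not have exactly two replicates",
                   grp$timepoint[1L])
    }
    tibble(timepoint = grp$timepoint[1L],
           pearson_r = cor(m[, grp$sample_id[1L]], m[, grp$sample_id[2L]]))
  }) |>
    arrange(.data$timepoint)
}

# ---- I/O -------------------------------------------------------------------

#' Read / write an intensity matrix
#'
#' The matrix is a tab-separated probes x samples table; sample metadata
#' travels in a `<path>.samples.tsv` sidecar (`sample_id`, `timepoint`,
#' `replicate`).
#'
#' @param x An [intensity_matrix()].
#' @param path File path for the matrix.
#' @export
write_intensities <- function(x, path) {
  readr::write_tsv(x$intensities, path)
  readr::write_tsv(x$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  intens <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()
  ))
  samples <- readr::read_tsv(paste0(path, ".samples.tsv"),
                             col_types = readr::cols(
                               sample_id = readr::col_character(),
                               timepoint = readr::col_double(),
                               replicate = readr::col_integer()
                             ))
  intensity_matrix(intens, samples)
}

#' Write / read an expression table
#'
#' Tab-separated features x samples (log2 values) with `kind` and
#' `n_core_probes` columns and a `<path>.samples.tsv` sidecar.
#'
#' @param expr An `expression_table`.
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr$expression, path)
  readr::write_tsv(expr$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), kind = readr::col_character(),
    n_core_probes = readr::col_integer(), .default = readr::col_double()
  ))
  samples <- readr::read_tsv(paste0(path, ".samples.tsv"),
                             col_types = readr::cols(
                               sample_id = readr::col_character(),
                               timepoint = readr::col_double(),
                               replicate = readr::col_integer()
                             ))
  structure(list(expression = tab, samples = samples),
            class = "expression_table")
}
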