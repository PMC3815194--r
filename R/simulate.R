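#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. The defaults emulate the study design the package targets: a
#' splicing-inhibition time course at 0/15/60/240 minutes with two
#' biological replicates, constant total transcript levels, and a
#' time-increasing retention fraction for the affected introns.
#'
#' @param seed Integer seed; mandatory, drives every random draw.
#' @param timepoints Minutes of drug exposure (default `c(0, 15, 60, 240)`).
#' @param replicates Biological replicates per timepoint (default 2).
#' @param n_genes Number of protein-coding genes to simulate (default 200).
#' @param fraction_affected Proportion of eligible introns whose retention
#'   increases with time (default 0.30).
#' @param rho0 Baseline retention fraction of unaffected introns
#'   (default 0.10).
#' @param rho_t Named numeric: retention fraction per timepoint for affected
#'   introns (default ramps 0.10 to 0.30 at 240 min).
#' @param expression_log2_mean,expression_log2_sd Log2-scale mean and sd of
#'   the per-gene total transcript abundance (defaults 8 and 1.5).
#' @param affinity_log_sd Natural-log sd of per-probe affinities, shared
#'   across samples (default 0.25).
#' @param noise_log_sd Natural-log sd of the multiplicative per-measurement
#'   noise (default 0.15, giving duplicate-array Pearson correlations
#'   around 0.97-0.99 on log2 intensities).
#' @param background_mean Mean of the per-array additive background level
#'   (lognormal across arrays; 0 disables background; default 20).
#' @param background_log_sd Natural-log sd of the per-measurement scatter
#'   around each array's background level (default 0.2).
#' @param gain Linear scale factor from abundance to intensity (default 1).
#' @param de_genes Optional tibble (`feature_id`, `timepoint`, `log2_fc`)
#'   of induced genes, e.g. tRNA genes or drug-response genes.
#' @param rdna_precursor_fold Named numeric: fold change of the rRNA
#'   precursor pool per timepoint (default ramps to 1.65 at 240 min,
#'   emulating spacer accumulation under defective rRNA processing).
#' @param rdna_precursor_base,rdna_mature_base Baseline abundance of the
#'   rRNA precursor and mature pools (defaults 50 and 1000).
#'
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              timepoints = c(0, 15, 60, 240),
                              replicates = 2L,
                              n_genes = 200L,
                              fraction_affected = 0.30,
                              rho0 = 0.10,
                              rho_t = c(`0` = 0.10, `15` = 0.13,
                                        `60` = 0.18, `240` = 0.30),
                              expression_log2_mean = 8,
                              expression_log2_sd = 1.5,
                              affinity_log_sd = 0.25,
                              noise_log_sd = 0.15,
                              background_mean = 20,
                              background_log_sd = 0.2,
                              gain = 1,
                              de_genes = NULL,
                              rdna_precursor_fold = c(`0` = 1, `15` = 1.1,
                                                      `60` = 1.3, `240` = 1.65),
                              rdna_precursor_base = 50,
                              rdna_mature_base = 1000) {
  if (missing(seed)) stop_invalid("`seed` is mandatory")
  assert_scalar_number(seed, "seed")
  assert_scalar_number(replicates, "replicates", min = 1)
  assert_scalar_number(n_genes, "n_genes", min = 1)
  assert_scalar_number(fraction_affected, "fraction_affected", min = 0, max = 1)
  assert_scalar_number(rho0, "rho0", min = 0, max = 1 - 1e-12)
  if (any(rho_t < 0 | rho_t >= 1)) stop_invalid("`rho_t` values must lie in [0, 1)")
  if (is.null(names(rho_t)) || any(!names(rho_t) %in% as.character(timepoints))) {
    stop_invalid("`rho_t` must be named by timepoints present in `timepoints`")
  }
  if (any(!names(rdna_precursor_fold) %in% as.character(timepoints))) {
    stop_invalid("`rdna_precursor_fold` names must be timepoints")
  }
  for (nm in c("expression_log2_sd", "affinity_log_sd", "noise_log_sd",
               "background_log_sd")) {
    assert_scalar_number(get(nm), nm, min = 0)
  }
  assert_scalar_number(background_mean, "background_mean", min = 0)
  assert_scalar_number(gain, "gain", min = 0)
  if (!is.null(de_genes)) {
    de_genes <- as_tibble(de_genes)
    if (!all(c("feature_id", "timepoint", "log2_fc") %in% names(de_genes))) {
      stop_invalid("`de_genes` needs columns feature_id, timepoint, log2_fc")
    }
    if (any(!de_genes$timepoint %in% timepoints)) {
      stop_invalid("`de_genes` refers to a timepoint absent from `timepoints`")
    }
  }
  structure(
    list(
      seed = as.integer(seed), timepoints = as.numeric(timepoints),
      replicates = as.integer(replicates), n_genes = as.integer(n_genes),
      fraction_affected = fraction_affected, rho0 = rho0, rho_t = rho_t,
      expression_log2_mean = expression_log2_mean,
      expression_log2_sd = expression_log2_sd,
      affinity_log_sd = affinity_log_sd, noise_log_sd = noise_log_sd,
      background_mean = background_mean,
      background_log_sd = background_log_sd,
      gain = gain, de_genes = de_genes,
      rdna_precursor_fold = rdna_precursor_fold,
      rdna_precursor_base = rdna_precursor_base,
      rdna_mature_base = rdna_mature_base
    ),
    class = "simulation_config"
  )
}

#' Sample metadata implied by a simulation config
#'
#' @param config A [simulation_config()].
#' @return Tibble with `sample_id`, `timepoint`, `replicate`.
#' @export
sample_sheet <- function(config) {
  tidyr::expand_grid(timepoint = config$timepoints,
                     replicate = seq_len(config$replicates)) |>
    mutate(sample_id = sprintf("t%g_r%d", .data$timepoint, .data$replicate)) |>
    select("sample_id", "timepoint", "replicate")
}

#' Generate a compact synthetic genome annotation
#'
#' Lays out `n_genes` single-intron protein-coding genes (exon-intron-exon,
#' contiguous), a handful of tRNA genes (some intron-containing, one
#' multi-copy pair sharing a `copy_group`), and one rDNA unit with
#' 18S/ITS1/5.8S/ITS2/28S segments, all on one chromosome with random
#' strands. Intron lengths are drawn uniformly between `intron_min` and
#' `intron_max`; under genome-wide 25-mer tiling at 20 bp most, but not
#' all, introns reach the four core probes needed for eligibility, as in
#' real tiling-array data.
#'
#' @param n_genes Number of protein-coding genes.
#' @param seed Integer seed.
#' @param exon_length Exon segment length in bp (default 1200).
#' @param intron_min,intron_max Intron length range in bp (default 40-150,
#'   bracketing the ~81 nt genome-wide average of fission-yeast introns).
#' @param gap Intergenic gap in bp (default 600).
#' @param n_trna Number of tRNA genes (default 6; every second one carries a
#'   short 20 bp intron, and the last two copies share a `copy_group`).
#' @param include_rdna Include the rDNA unit (default `TRUE`).
#' @return A [genome_annotation()].
#' @export
simulate_annotation <- function(n_genes, seed, exon_length = 1200L,
                                intron_min = 40L, intron_max = 150L,
                                gap = 600L, n_trna = 6L, include_rdna = TRUE) {
  assert_scalar_number(n_genes, "n_genes", min = 1)
  with_seed(derive_seed(seed, 1L), {
    intron_len <- sample(seq.int(intron_min, intron_max), n_genes, replace = TRUE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    pos <- 0L
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", i)
      e1 <- c(pos, pos + exon_length)
      iv <- c(e1[2L], e1[2L] + intron_len[i])
      e2 <- c(iv[2L], iv[2L] + exon_length)
      rows[[i]] <- tibble(
        feature_id = c(gid, paste0(gid, "_e1"), paste0(gid, "_i1"),
                       paste0(gid, "_e2")),
        kind = c("gene", "exon", "intron", "exon"),
        start = c(e1[1L], e1[1L], iv[1L], e2[1L]),
        end = c(e2[2L], e1[2L], iv[2L], e2[2L]),
        strand = strands[i],
        parent = c(NA_character_, gid, gid, gid),
        copy_group = NA_character_
      )
      pos <- e2[2L] + gap
    }
    trna_rows <- vector("list", n_trna)
    for (j in seq_len(n_trna)) {
      tid <- sprintf("tRNA%02d", j)
      tlen <- 90L
      has_intron <- j %% 2L == 0L
      strand <- sample(c("+", "-"), 1L)
      # last two tRNAs are identical copies of one gene
      cg <- if (n_trna >= 2L && j >= n_trna - 1L) "tRNA_dup" else NA_character_
      trna <- tibble(
        feature_id = tid, kind = "tRNA", start = pos, end = pos + tlen,
        strand = strand, parent = NA_character_, copy_group = cg
      )
      if (has_intron) {
        trna <- bind_rows(trna, tibble(
          feature_id = paste0(tid, "_i"), kind = "tRNA_intron",
          start = pos + 35L, end = pos + 55L, strand = strand,
          parent = tid, copy_group = NA_character_
        ))
      }
      trna_rows[[j]] <- trna
      pos <- pos + tlen + gap
    }
    rdna <- NULL
    if (include_rdna) {
      seg_len <- c(rDNA_18S = 1800L, rDNA_ITS1 = 360L, rDNA_5.8S = 160L,
                   rDNA_ITS2 = 230L, rDNA_28S = 3400L)
      starts <- pos + c(0L, cumsum(seg_len)[-length(seg_len)])
      rdna <- tibble(
        feature_id = names(seg_len), kind = "rDNA_segment",
        start = starts, end = starts + seg_len, strand = "+",
        parent = NA_character_, copy_group = NA_character_
      )
      pos <- pos + sum(seg_len) + gap
    }
    features <- bind_rows(bind_rows(rows), bind_rows(trna_rows), rdna) |>
      mutate(chromosome = "chrI", .after = "kind")
    genome_annotation(
      chromosomes = tibble(chromosome = "chrI", length = pos + gap),
      features = features
    )
  })
}

rho_for <- function(config, affected, timepoint) {
  if (affected) {
    unname(config$rho_t[as.character(timepoint)])
  } else {
    config$rho0
  }
}

#' Simulate true feature abundances
#'
#' For each gene with total transcript level `T` (lognormal draw, constant
#' over time unless listed in `de_genes`), the pre-mRNA pool at time `t` is
#' `rho_t * T` and the mature pool `(1 - rho_t) * T`; intron abundance
#' equals the pre-mRNA pool while exon (and whole-gene) abundance equals
#' `pre + mature = T`, so exon levels stay constant while intron levels
#' track retention. rDNA spacer segments follow the precursor pool only;
#' mature segments follow precursor plus mature pools.
#'
#' @param config A [simulation_config()].
#' @param annotation A [genome_annotation()].
#' @param eligible Optional character vector of intron ids (e.g. from
#'   [build_feature_map()]); affected introns are drawn from this set when
#'   given, otherwise from all introns.
#' @return A list with `abundances` (long tibble `feature_id`, `sample_id`,
#'   `abundance`), `samples`, and `truth` (a `ground_truth` list: per-intron
#'   per-timepoint retention, the affected set, total levels, realized
#'   `de_genes`).
#' @export
simulate_abundances <- function(config, annotation, eligible = NULL) {
  feats <- annotation$features
  samples <- sample_sheet(config)
  rho_missing <- setdiff(as.character(config$timepoints), names(config$rho_t))
  if (length(rho_missing) && config$fraction_affected > 0) {
    stop_invalid("`rho_t` lacks timepoint(s): %s",
                 paste(rho_missing, collapse = ", "))
  }
  intron_ids <- feats$feature_id[feats$kind %in% c("intron", "tRNA_intron")]
  candidates <- if (is.null(eligible)) intron_ids else intersect(eligible, intron_ids)
  top_ids <- feats$feature_id[feats$kind %in% c("gene", "tRNA")]

  with_seed(derive_seed(config$seed, 2L), {
    n_aff <- round(config$fraction_affected * length(candidates))
    affected <- if (n_aff > 0) sample(candidates, n_aff) else character()
    total <- 2^rnorm(length(top_ids), config$expression_log2_mean,
                     config$expression_log2_sd)
    names(total) <- top_ids
  })

  de <- config$de_genes
  de_mult <- function(fid, tp) {
    if (is.null(de)) return(1)
    hit <- de$feature_id == fid & de$timepoint == tp
    if (any(hit)) 2^sum(de$log2_fc[hit]) else 1
  }

  parent_of <- setNames(feats$parent, feats$feature_id)
  kind_of <- setNames(feats$kind, feats$feature_id)
  owner <- function(fid) {
    k <- kind_of[[fid]]
    if (k %in% c("gene", "tRNA", "rDNA_segment")) fid else parent_of[[fid]]
  }

  pf <- config$rdna_precursor_fold
  precursor_at <- function(tp) {
    f <- pf[as.character(tp)]
    config$rdna_precursor_base * if (is.na(f)) 1 else unname(f)
  }

  grid <- tidyr::expand_grid(feature_id = feats$feature_id,
                             sample_id = samples$sample_id) |>
    left_join(samples, by = "sample_id")
  abundance <- purrr::pmap_dbl(grid, function(feature_id, sample_id,
                                              timepoint, replicate) {
    k <- kind_of[[feature_id]]
    if (k == "rDNA_segment") {
      p <- precursor_at(timepoint)
      if (grepl("ITS", feature_id)) p else p + config$rdna_mature_base
    } else {
      own <- owner(feature_id)
      t_tot <- total[[own]] * de_mult(own, timepoint)
      if (k %in% c("intron", "tRNA_intron")) {
        rho_for(config, feature_id %in% affected, timepoint) * t_tot
      } else {
        t_tot
      }
    }
  })
  abundances <- grid |>
    mutate(abundance = abundance) |>
    select("feature_id", "sample_id", "abundance")

  retention <- tidyr::expand_grid(intron_id = intron_ids,
                                  timepoint = config$timepoints) |>
    mutate(rho = purrr::map2_dbl(.data$intron_id, .data$timepoint,
                                 ~ rho_for(config, .x %in% affected, .y)))
  truth <- structure(
    list(
      retention = retention,
      affected_introns = sort(affected),
      total_levels = tibble(feature_id = top_ids, total = unname(total)),
      de_genes = de,
      fraction_affected_realized =
        if (length(candidates)) length(affected) / length(candidates) else 0,
      candidate_introns = candidates
    ),
    class = "ground_truth"
  )
  list(abundances = abundances, samples = samples, truth = truth)
}

#' Simulate probe-level hybridization intensities
#'
#' `intensity(p, s) = background(p, s) + gain * a_p * abundance(feature(p),
#' s) * exp(eps)` with per-probe affinity `a_p` lognormal (shared across
#' samples) and `eps ~ N(0, noise_log_sd^2)` independent per measurement.
#' The background is array-specific: one lognormal level per array (mean
#' `background_mean`), with per-measurement lognormal scatter around that
#' level. Probes mapping to no feature receive background only. Each probe
#' carries the signal of its most specific containing feature (intron
#' before exon before whole gene).
#'
#' @param abundances Output of [simulate_abundances()] (or its
#'   `$abundances` tibble plus a `samples` tibble).
#' @param feature_map A `feature_map` from [build_feature_map()].
#' @param probes Probe tibble from [tile_probes()].
#' @param config A [simulation_config()].
#' @param samples Sample sheet; defaults to the one in `abundances`.
#' @return An `intensity_matrix` object (see [intensity_matrix()]).
#' @export
simulate_intensities <- function(abundances, feature_map, probes, config,
                                 samples = NULL) {
  if (is.list(abundances) && !is.data.frame(abundances) &&
      all(c("abundances", "samples") %in% names(abundances))) {
    samples <- samples %||% abundances$samples
    abundances <- abundances$abundances
  }
  if (is.null(samples)) stop_invalid("`samples` sheet required")
  specificity <- c(intron = 1L, tRNA_intron = 1L, exon = 2L,
                   rDNA_segment = 2L, tRNA = 3L, gene = 4L)
  probe_feature <- feature_map$assignments |>
    mutate(rank = specificity[.data$kind]) |>
    arrange(.data$probe_id, .data$rank) |>
    distinct(.data$probe_id, .keep_all = TRUE) |>
    select("probe_id", "feature_id")
  n_probes <- nrow(probes)
  n_samples <- nrow(samples)
  abun_wide <- abundances |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "abundance")
  abun_mat <- as.matrix(abun_wide[, samples$sample_id, drop = FALSE])
  rownames(abun_mat) <- abun_wide$feature_id

  with_seed(derive_seed(config$seed, 3L), {
    affinity <- rlnorm(n_probes, meanlog = -config$affinity_log_sd^2 / 2,
                       sdlog = config$affinity_log_sd)
    background <- if (config$background_mean > 0) {
      # array-specific background level, then per-measurement scatter
      # around it, so background correction is array-specific and
      # unmapped probes still carry measurement noise
      level <- rlnorm(n_samples, meanlog = log(config$background_mean) - 0.2^2 / 2,
                      sdlog = 0.2)
      bsd <- config$background_log_sd %||% 0.2
      matrix(rlnorm(n_probes * n_samples,
                    meanlog = rep(log(level), each = n_probes) - bsd^2 / 2,
                    sdlog = bsd),
             n_probes, n_samples)
    } else {
      matrix(0, n_probes, n_samples)
    }
    eps <- if (config$noise_log_sd > 0) {
      matrix(rnorm(n_probes * n_samples, 0, config$noise_log_sd),
             n_probes, n_samples)
    } else {
      matrix(0, n_probes, n_samples)
    }
  })

  fid <- probe_feature$feature_id[match(probes$probe_id, probe_feature$probe_id)]
  signal <- matrix(0, n_probes, n_samples)
  mapped <- !is.na(fid)
  signal[mapped, ] <- abun_mat[fid[mapped], , drop = FALSE]
  inten <- config$gain * affinity * signal * exp(eps) + background
  dimnames(inten) <- list(probes$probe_id, samples$sample_id)
  intensity_matrix(inten, samples)
}

#' Simulate a qPCR plate
#'
#' Generates Cq values under a log-linear amplification model:
#' `Cq = C_ref - log(N0) / log(1 + E) + N(0, cq_noise_sd^2)` with
#' `N0 = copies_per_ng * input_ng`, one well per replicate per input
#' amount. No-RT control wells are emitted with no amplification (`NA` Cq).
#'
#' @param true_copies Named numeric vector, target id to true copies per ng,
#'   or a tibble (`target`, `sample`, `copies_per_ng`).
#' @param efficiency Named numeric of per-target amplification efficiencies
#'   in (0, 1], or a single value recycled to all targets.
#' @param dilution_series Input amounts in ng (default five 4-fold
#'   dilutions from 50 ng).
#' @param cq_noise_sd Sd of the Cq measurement noise (default 0.15).
#' @param seed Integer seed.
#' @param replicates Wells per condition (default 3, i.e. triplicates).
#' @param c_ref Per-target reference cycle constant (default 40).
#' @param include_no_rt Emit one no-RT control well per target/sample
#'   (default `TRUE`).
#' @return A tibble plate: `well`, `target`, `sample`, `input_ng`,
#'   `dilution_step`, `cq`, `no_rt`.
#' @export
simulate_qpcr <- function(true_copies, efficiency,
                          dilution_series = 50 / 4^(0:4),
                          cq_noise_sd = 0.15, seed, replicates = 3L,
                          c_ref = 40, include_no_rt = TRUE) {
  if (missing(seed)) stop_invalid("`seed` is mandatory")
  if (!is.data.frame(true_copies)) {
    true_copies <- tibble(target = names(true_copies), sample = "pool",
                          copies_per_ng = unname(true_copies))
  }
  if (any(true_copies$copies_per_ng <= 0)) stop_invalid("copies must be > 0")
  if (any(dilution_series <= 0)) stop_invalid("input amounts must be > 0")
  targets <- unique(true_copies$target)
  if (length(efficiency) == 1L && is.null(names(efficiency))) {
    efficiency <- setNames(rep(efficiency, length(targets)), targets)
  }
  if (any(!targets %in% names(efficiency))) {
    stop_invalid("efficiency missing for target(s): %s",
                 paste(setdiff(targets, names(efficiency)), collapse = ", "))
  }
  if (any(efficiency <= 0 | efficiency > 1)) {
    stop_invalid("efficiencies must lie in (0, 1]")
  }
  if (length(c_ref) == 1L && is.null(names(c_ref))) {
    c_ref <- setNames(rep(c_ref, length(targets)), targets)
  }
  grid <- tidyr::expand_grid(
    true_copies,
    tibble(input_ng = dilution_series,
           dilution_step = seq_along(dilution_series) - 1L),
    rep_well = seq_len(replicates)
  )
  with_seed(derive_seed(seed, 4L), {
    noise <- rnorm(nrow(grid), 0, cq_noise_sd)
  })
  e <- unname(efficiency[grid$target])
  cq <- unname(c_ref[grid$target]) -
    log(grid$copies_per_ng * grid$input_ng) / log(1 + e) + noise
  plate <- grid |>
    mutate(cq = cq, no_rt = FALSE) |>
    select("target", "sample", "input_ng", "dilution_step", "cq", "no_rt")
  if (include_no_rt) {
    nr <- distinct(true_copies, .data$target, .data$sample) |>
      mutate(input_ng = dilution_series[1L], dilution_step = 0L,
             cq = NA_real_, no_rt = TRUE)
    plate <- bind_rows(plate, nr)
  }
  plate |>
    mutate(well = sprintf("W%03d", row_number()), .before = 1L)
}
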