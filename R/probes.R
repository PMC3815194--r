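#' Tile probes across both strands of a genome
#'
#' Lays 25-mer probes at fixed intervals along each chromosome, on both
#' strands, mirroring a whole-genome strand-specific tiling array design.
#' Probe starts on each chromosome/strand are `0, step, 2*step, ...` for as
#' long as the probe fits (`start + probe_length <= chromosome length`).
#'
#' @param chromosome_lengths A data frame with columns `chromosome`,
#'   `length`, or a named numeric vector of lengths.
#' @param probe_length Probe length in bp (default 25).
#' @param step Tiling interval in bp (default 20).
#' @return A tibble of probes: `probe_id`, `chromosome`, `strand`, `start`
#'   (0-based), `length`. Probe ids encode chromosome, strand and start.
#' @examples
#' tile_probes(tibble::tibble(chromosome = "chrI", length = 65))
#' @export
tile_probes <- function(chromosome_lengths, probe_length = 25L, step = 20L) {
  if (!is.data.frame(chromosome_lengths)) {
    chromosome_lengths <- tibble(
      chromosome = names(chromosome_lengths),
      length = as.integer(chromosome_lengths)
    )
  }
  assert_scalar_number(probe_length, "probe_length", min = 1)
  assert_scalar_number(step, "step", min = 1)
  if (nrow(chromosome_lengths) == 0L) {
    return(tibble(probe_id = character(), chromosome = character(),
                  strand = character(), start = integer(), length = integer()))
  }
  if (any(chromosome_lengths$length < 0)) {
    stop_invalid("negative chromosome length")
  }
  probe_length <- as.integer(probe_length)
  step <- as.integer(step)
  per_chrom <- purrr::pmap(chromosome_lengths, function(chromosome, length, ...) {
    n <- max(0L, (as.integer(length) - probe_length) %/% step + 1L)
    if (n == 0L) return(NULL)
    starts <- (seq_len(n) - 1L) * step
    tibble(
      chromosome = chromosome,
      strand = rep(c("+", "-"), each = n),
      start = rep(starts, 2L),
      length = probe_length
    )
  })
  probes <- bind_rows(per_chrom)
  if (nrow(probes) == 0L) {
    return(tibble(probe_id = character(), chromosome = character(),
                  strand = character(), start = integer(), length = integer()))
  }
  probes |>
    mutate(probe_id = sprintf("%s:%s:%d", .data$chromosome,
                              ifelse(.data$strand == "+", "p", "m"),
                              .data$start)) |>
    select("probe_id", "chromosome", "strand", "start", "length")
}

#' Map features to their core probes
#'
#' A probe is a *core probe* of a feature when it lies on the same chromosome
#' and strand and its interval is fully contained in the feature interval.
#' Introns (including tRNA introns) with at least `min_core_probes` core
#' probes form the eligible set used by the retention analysis; the default
#' of 4 reflects the common requirement that an intronic region be delimited
#' by at least four probes to be measured reliably.
#'
#' @param annotation A [genome_annotation()].
#' @param probes A probe tibble from [tile_probes()].
#' @param min_core_probes Minimum core probes for an intron to be eligible
#'   (default 4).
#' @return A `feature_map` object: list with `assignments` (tibble
#'   `feature_id`, `kind`, `probe_id`, ordered by genomic position within
#'   feature), `n_core_probes` (tibble `feature_id`, `kind`,
#'   `n_core_probes`), `eligible_introns` (character vector) and
#'   `min_core_probes`.
#' @export
build_feature_map <- function(annotation, probes, min_core_probes = 4L) {
  assert_scalar_number(min_core_probes, "min_core_probes", min = 1)
  feats <- annotation$features
  unknown <- setdiff(unique(feats$chromosome), unique(c(probes$chromosome,
                                                        annotation$chromosomes$chromosome)))
  if (length(unknown)) {
    stop_invalid("feature chromosome(s) absent from probe namespace: %s",
                 paste(unknown, collapse = ", "))
  }
  if (nrow(probes)) {
    probe_gr <- GenomicRanges::GRanges(
      probes$chromosome,
      IRanges::IRanges(start = probes$start + 1L,
                       end = probes$start + probes$length),
      strand = probes$strand
    )
    feat_gr <- GenomicRanges::GRanges(
      feats$chromosome,
      IRanges::IRanges(start = feats$start + 1L, end = feats$end),
      strand = feats$strand
    )
    hits <- GenomicRanges::findOverlaps(probe_gr, feat_gr, type = "within",
                                        ignore.strand = FALSE)
    assignments <- tibble(
      feature_id = feats$feature_id[S4Vectors::subjectHits(hits)],
      kind = feats$kind[S4Vectors::subjectHits(hits)],
      probe_id = probes$probe_id[S4Vectors::queryHits(hits)],
      probe_start = probes$start[S4Vectors::queryHits(hits)]
    ) |>
      arrange(.data$feature_id, .data$probe_start) |>
      select(-"probe_start")
  } else {
    assignments <- tibble(feature_id = character(), kind = character(),
                          probe_id = character())
  }
  counts <- assignments |>
    dplyr::count(.data$feature_id, .data$kind, name = "n_core_probes")
  counts <- feats |>
    select("feature_id", "kind") |>
    left_join(counts, by = c("feature_id", "kind")) |>
    mutate(n_core_probes = as.integer(dplyr::coalesce(.data$n_core_probes, 0L)))
  eligible <- counts |>
    filter(.data$kind %in% c("intron", "tRNA_intron"),
           .data$n_core_probes >= min_core_probes) |>
    pull("feature_id")
  structure(
    list(
      assignments = assignments,
      n_core_probes = counts,
      eligible_introns = eligible,
      min_core_probes = as.integer(min_core_probes)
    ),
    class = "feature_map"
  )
}

#' @export
print.feature_map <- function(x, ...) {
  cat("<feature_map>\n")
  cat(sprintf("  %d probe assignments across %d features\n",
              nrow(x$assignments), nrow(x$n_core_probes)))
  cat(sprintf("  eligible introns (>= %d core probes): %d\n",
              x$min_core_probes, length(x$eligible_introns)))
  invisible(x)
}

#' Read / write a probe table
#'
#' Tab-separated columns: `probe_id`, `chromosome`, `strand`, `start`,
#' `length`.
#'
#' @param path File path.
#' @return [read_probes()] returns the probe tibble; [write_probes()]
#'   returns `path` invisibly.
#' @export
read_probes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chromosome = readr::col_character(),
    strand = readr::col_character(),
    start = readr::col_integer(),
    length = readr::col_integer()
  ))
}

#' @rdname read_probes
#' @param probes Probe tibble.
#' @export
write_probes <- function(probes, path) {
  readr::write_tsv(probes, path)
  invisible(path)
}

#' Write / read a feature map
#'
#' Serialized as a tab-separated table (`feature_id`, `kind`,
#' `n_core_probes`, comma-joined `probe_ids`, `eligible` flag) with the
#' `min_core_probes` threshold in a header comment.
#'
#' @param map A `feature_map`.
#' @param path File path.
#' @export
write_feature_map <- function(map, path) {
  joined <- map$assignments |>
    group_by(.data$feature_id) |>
    summarise(probe_ids = paste(.data$probe_id, collapse = ","))
  out <- map$n_core_probes |>
    left_join(joined, by = "feature_id") |>
    mutate(
      probe_ids = dplyr::coalesce(.data$probe_ids, ""),
      eligible = .data$feature_id %in% map$eligible_introns
    )
  writeLines(c(sprintf("# min_core_probes=%d", map$min_core_probes),
               paste(names(out), collapse = "\t")), path)
  readr::write_tsv(out, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' @rdname write_feature_map
#' @export
read_feature_map <- function(path) {
  first <- readLines(path, n = 1L)
  min_core <- as.integer(sub("# min_core_probes=", "", first, fixed = TRUE))
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    feature_id = readr::col_character(),
    kind = readr::col_character(),
    n_core_probes = readr::col_integer(),
    probe_ids = readr::col_character(),
    eligible = readr::col_logical()
  ))
  tab$probe_ids[is.na(tab$probe_ids)] <- ""
  with_probes <- tab[tab$probe_ids != "", ]
  assignments <- tibble(
    feature_id = rep(with_probes$feature_id,
                     lengths(strsplit(with_probes$probe_ids, ","))),
    kind = rep(with_probes$kind, lengths(strsplit(with_probes$probe_ids, ","))),
    probe_id = unlist(strsplit(with_probes$probe_ids, ","), use.names = FALSE)
  )
  structure(
    list(
      assignments = assignments,
      n_core_probes = select(tab, "feature_id", "kind", "n_core_probes"),
      eligible_introns = tab$feature_id[tab$eligible],
      min_core_probes = min_core
    ),
    class = "feature_map"
  )
}
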