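#' Genome annotation container
#'
#' Bundles chromosome lengths with a flat feature table describing genes,
#' their exon/intron segments, tRNA genes (optionally with a tRNA intron) and
#' rDNA precursor segments. Coordinates are 0-based half-open internally;
#' GFF3 files on disk use the conventional 1-based inclusive coordinates.
#'
#' @param chromosomes A data frame with columns `chromosome` and `length`
#'   (bp), one row per chromosome.
#' @param features A data frame with columns `feature_id`, `kind` (one of
#'   `gene`, `exon`, `intron`, `tRNA`, `tRNA_intron`, `rDNA_segment`),
#'   `chromosome`, `start`, `end` (0-based half-open), `strand` (`+`/`-`),
#'   and optionally `parent` and `copy_group`.
#' @param validate Check structural invariants (default `TRUE`).
#'
#' @details Validation enforces: every feature lies within its chromosome;
#'   exon and intron segments of a gene are non-overlapping, contiguous in
#'   genomic order and on the gene's strand; every intron of a
#'   protein-coding gene is flanked by exactly two exon segments; segment
#'   kinds carry a `parent`.
#'
#' @return An object of class `genome_annotation`: a list with tibbles
#'   `chromosomes` and `features`.
#' @export
genome_annotation <- function(chromosomes, features, validate = TRUE) {
  chromosomes <- as_tibble(chromosomes)
  features <- as_tibble(features)
  if (!all(c("chromosome", "length") %in% names(chromosomes))) {
    stop_invalid("`chromosomes` needs columns `chromosome` and `length`")
  }
  needed <- c("feature_id", "kind", "chromosome", "start", "end", "strand")
  if (!all(needed %in% names(features))) {
    stop_invalid(
      "`features` is missing columns: %s",
      paste(setdiff(needed, names(features)), collapse = ", ")
    )
  }
  if (!"parent" %in% names(features)) features$parent <- NA_character_
  if (!"copy_group" %in% names(features)) features$copy_group <- NA_character_
  features <- features |>
    mutate(
      feature_id = as.character(.data$feature_id),
      kind = as.character(.data$kind),
      chromosome = as.character(.data$chromosome),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      strand = as.character(.data$strand),
      parent = as.character(.data$parent),
      copy_group = as.character(.data$copy_group)
    )
  ann <- structure(
    list(
      chromosomes = mutate(chromosomes,
        chromosome = as.character(.data$chromosome),
        length = as.integer(.data$length)
      ),
      features = features
    ),
    class = "genome_annotation"
  )
  if (validate) validate_annotation(ann)
  ann
}

feature_kinds <- c("gene", "exon", "intron", "tRNA", "tRNA_intron", "rDNA_segment")
segment_kinds <- c("exon", "intron", "tRNA_intron")

#' Validate a genome annotation
#'
#' @param annotation A [genome_annotation()] object.
#' @return The annotation, invisibly; signals a validation error otherwise.
#' @export
validate_annotation <- function(annotation) {
  feats <- annotation$features
  chroms <- annotation$chromosomes
  if (anyDuplicated(chroms$chromosome)) {
    stop_validation("duplicated chromosome ids")
  }
  if (anyDuplicated(feats$feature_id)) {
    stop_validation(
      "duplicated feature ids: %s",
      paste(unique(feats$feature_id[duplicated(feats$feature_id)]), collapse = ", ")
    )
  }
  bad_kind <- setdiff(unique(feats$kind), feature_kinds)
  if (length(bad_kind)) {
    stop_validation("unknown feature kind(s): %s", paste(bad_kind, collapse = ", "))
  }
  if (!all(feats$strand %in% c("+", "-"))) {
    stop_validation("feature strand must be '+' or '-'")
  }
  if (any(feats$start >= feats$end)) {
    bad <- feats$feature_id[feats$start >= feats$end]
    stop_validation("feature(s) with start >= end: %s", paste(bad, collapse = ", "))
  }
  unknown_chrom <- setdiff(unique(feats$chromosome), chroms$chromosome)
  if (length(unknown_chrom)) {
    stop_validation("feature chromosome(s) not declared: %s",
                    paste(unknown_chrom, collapse = ", "))
  }
  lens <- setNames(chroms$length, chroms$chromosome)
  oob <- feats$start < 0L | feats$end > lens[feats$chromosome]
  if (any(oob)) {
    stop_validation("feature(s) outside chromosome bounds: %s",
                    paste(feats$feature_id[oob], collapse = ", "))
  }
  needs_parent <- feats$kind %in% segment_kinds
  if (any(needs_parent & is.na(feats$parent))) {
    stop_validation("segment feature(s) without parent: %s",
                    paste(feats$feature_id[needs_parent & is.na(feats$parent)],
                          collapse = ", "))
  }
  known <- setNames(seq_len(nrow(feats)), feats$feature_id)
  orphan <- !is.na(feats$parent) & !(feats$parent %in% feats$feature_id)
  if (any(orphan)) {
    stop_validation("parent id(s) not present: %s",
                    paste(unique(feats$parent[orphan]), collapse = ", "))
  }

  # Per-gene segment structure: non-overlapping, contiguous, strand-matched,
  # introns flanked by exactly two exons.
  segs <- feats[feats$kind %in% c("exon", "intron") & !is.na(feats$parent), ]
  if (nrow(segs)) {
    parent_strand <- setNames(feats$strand, feats$feature_id)
    if (any(segs$strand != parent_strand[segs$parent])) {
      stop_validation("exon/intron segment strand differs from its gene")
    }
    for (gene in unique(segs$parent)) {
      g <- segs[segs$parent == gene, ]
      g <- g[order(g$start), ]
      if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)])) {
        stop_validation("overlapping exon/intron segments in gene %s", gene)
      }
      if (nrow(g) > 1L && any(g$start[-1L] != g$end[-nrow(g)])) {
        stop_validation("non-contiguous exon/intron segments in gene %s", gene)
      }
      idx <- which(g$kind == "intron")
      flanked <- idx > 1L & idx < nrow(g) &
        g$kind[pmax(idx - 1L, 1L)] == "exon" &
        g$kind[pmin(idx + 1L, nrow(g))] == "exon"
      if (length(idx) && !all(flanked)) {
        stop_validation("intron(s) of gene %s lack two flanking exons", gene)
      }
    }
  }
  trna_introns <- feats[feats$kind == "tRNA_intron", ]
  if (nrow(trna_introns)) {
    par <- feats[match(trna_introns$parent, feats$feature_id), ]
    contained <- par$chromosome == trna_introns$chromosome &
      par$start <= trna_introns$start & par$end >= trna_introns$end
    if (!all(contained)) {
      stop_validation("tRNA intron(s) not contained in their parent tRNA")
    }
  }
  invisible(annotation)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>\n")
  cat(sprintf("  chromosomes: %d (total %s bp)\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ",")))
  tab <- table(x$features$kind)
  cat(sprintf("  features: %d (%s)\n", nrow(x$features),
              paste(sprintf("%s %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}

#' Flanking exons of each intron
#'
#' For each protein-coding gene intron, finds the exon segment immediately
#' upstream and downstream in genomic order.
#'
#' @param annotation A [genome_annotation()].
#' @return A tibble with columns `intron_id`, `gene`, `exon_left`,
#'   `exon_right` (genomic order, independent of strand).
#' @export
intron_flanks <- function(annotation) {
  feats <- annotation$features
  segs <- feats |>
    filter(.data$kind %in% c("exon", "intron"), !is.na(.data$parent)) |>
    arrange(.data$parent, .data$start)
  out <- segs |>
    group_by(.data$parent) |>
    mutate(
      prev_id = dplyr::lag(.data$feature_id),
      next_id = dplyr::lead(.data$feature_id),
      prev_kind = dplyr::lag(.data$kind),
      next_kind = dplyr::lead(.data$kind)
    ) |>
    ungroup() |>
    filter(.data$kind == "intron",
           .data$prev_kind == "exon", .data$next_kind == "exon")
  tibble(
    intron_id = out$feature_id,
    gene = out$parent,
    exon_left = out$prev_id,
    exon_right = out$next_id
  )
}

# ---- GFF3 I/O --------------------------------------------------------------

#' Read a genome annotation from GFF3
#'
#' Chromosome lengths come from `##sequence-region` pragmas; feature kinds
#' from the GFF3 `type` column; hierarchy from the `Parent` attribute;
#' optional `copy_group` attribute for multi-copy tRNA genes. 1-based
#' inclusive coordinates on disk are converted to 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @param validate Validate invariants after reading (default `TRUE`).
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, validate = TRUE) {
  lines <- readLines(path)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(sr)) {
    stop_invalid("GFF3 file has no ##sequence-region pragmas: %s", path)
  }
  parts <- strsplit(trimws(sr), "\\s+")
  chromosomes <- tibble(
    chromosome = vapply(parts, `[[`, "", 2L),
    length = as.integer(vapply(parts, `[[`, "", 4L))
  )
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p) {
      if (length(p)) as.character(p[[1L]]) else NA_character_
    }, character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  copy_group <- if ("copy_group" %in% names(md)) {
    as.character(md$copy_group)
  } else {
    rep(NA_character_, length(gr))
  }
  features <- tibble(
    feature_id = as.character(md$ID),
    kind = as.character(md$type),
    chromosome = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    parent = parent,
    copy_group = copy_group
  )
  genome_annotation(chromosomes, features, validate = validate)
}

#' Write a genome annotation to GFF3
#'
#' Emits `##sequence-region` pragmas for chromosome lengths and converts the
#' internal 0-based half-open coordinates to GFF3's 1-based inclusive ones.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  chroms <- annotation$chromosomes
  feats <- annotation$features
  header <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", chroms$chromosome, chroms$length)
  )
  attrs <- sprintf("ID=%s", feats$feature_id)
  has_parent <- !is.na(feats$parent)
  attrs[has_parent] <- sprintf("%s;Parent=%s", attrs[has_parent],
                               feats$parent[has_parent])
  has_cg <- !is.na(feats$copy_group)
  attrs[has_cg] <- sprintf("%s;copy_group=%s", attrs[has_cg],
                           feats$copy_group[has_cg])
  body <- sprintf("%s\tintronarray\t%s\t%d\t%d\t.\t%s\t.\t%s",
                  feats$chromosome, feats$kind, feats$start + 1L, feats$end,
                  feats$strand, attrs)
  writeLines(c(header, body), path)
  invisible(path)
}
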