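# Independent brute-force oracles, deliberately naive.

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(probes x features) containment scan
bf_feature_map <- function(annotation, probes) {
  feats <- annotation$features
  out <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    hit <- probes$chromosome == f$chromosome &
      probes$strand == f$strand &
      probes$start >= f$start &
      (probes$start + probes$length) <= f$end
    out[[f$feature_id]] <- sort(probes$probe_id[hit])
  }
  out
}

# exact two-sided Mann-Whitney p by enumerating every rank assignment
bf_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combos <- utils::combn(n, na)
  us <- apply(combos, 2L, function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
  center <- na * (n - na) / 2
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# literal step-up definition
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {
    i <- ord[r]
    vals <- vapply(seq(r, m), function(j) p[ord[j]] * m / j, numeric(1))
    adj[i] <- min(1, min(vals))
  }
  adj
}

# long-iteration median polish via the reference implementation
oracle_medpolish_col <- function(x) {
  fit <- stats::medpolish(x, eps = 1e-12, maxiter = 1000L, trace.iter = FALSE)
  fit$overall + fit$col
}

# tiny random annotation on 1-2 chromosomes, unconstrained feature kinds
# (standalone intervals only, so no structural invariants get in the way)
random_annotation <- function(seed, max_features = 50L) {
  set.seed(seed)
  n_chrom <- sample(1:2, 1L)
  chroms <- tibble::tibble(
    chromosome = paste0("c", seq_len(n_chrom)),
    length = sample(500:4000, n_chrom, replace = TRUE)
  )
  n_feat <- sample(5:max_features, 1L)
  chrom <- sample(chroms$chromosome, n_feat, replace = TRUE)
  len <- chroms$length[match(chrom, chroms$chromosome)]
  start <- vapply(len, function(l) sample(0:(l - 30L), 1L), integer(1))
  width <- vapply(len - start, function(w) sample(25:min(w, 400L), 1L), integer(1))
  feats <- tibble::tibble(
    feature_id = sprintf("f%02d", seq_len(n_feat)),
    kind = sample(c("gene", "rDNA_segment", "tRNA"), n_feat, replace = TRUE),
    chromosome = chrom,
    start = start,
    end = start + width,
    strand = sample(c("+", "-"), n_feat, replace = TRUE)
  )
  genome_annotation(chroms, feats, validate = FALSE)
}

# three-gene annotation with hand-placed coordinates, used across tests
tiny_annotation <- function() {
  genome_annotation(
    chromosomes = tibble::tibble(chromosome = "chrI", length = 3000L),
    features = tibble::tribble(
      ~feature_id, ~kind, ~chromosome, ~start, ~end, ~strand, ~parent,
      "g1", "gene", "chrI", 0L, 500L, "+", NA,
      "g1_e1", "exon", "chrI", 0L, 200L, "+", "g1",
      "g1_i1", "intron", "chrI", 200L, 330L, "+", "g1",
      "g1_e2", "exon", "chrI", 330L, 500L, "+", "g1",
      "g2", "gene", "chrI", 700L, 1200L, "-", NA,
      "g2_e1", "exon", "chrI", 700L, 900L, "-", "g2",
      "g2_i1", "intron", "chrI", 900L, 1000L, "-", "g2",
      "g2_e2", "exon", "chrI", 1000L, 1200L, "-", "g2",
      "t1", "tRNA", "chrI", 1500L, 1590L, "+", NA
    )
  )
}

# noiseless dilution-series fixture: Cq rises by cq_step per 4-fold dilution
four_fold_series <- function(cq_step, n = 5, top_cq = 18) {
  tibble::tibble(
    input_ng = 50 / 4^(seq_len(n) - 1),
    cq = top_cq + cq_step * (seq_len(n) - 1)
  )
}
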