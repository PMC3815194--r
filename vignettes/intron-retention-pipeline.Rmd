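---
title: "Quantifying intron retention from strand-specific tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention from strand-specific tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Drugs that interfere with RNA metabolism — the uracil analogue
5-fluorouracil (5FU) is the canonical example — can impair pre-mRNA
splicing genome-wide. On a strand-specific tiling microarray, a failure to
splice shows up as intronic probe signal rising relative to the flanking
exons: exon probes see mature mRNA *plus* pre-mRNA, while intron probes see
pre-mRNA only. The intron/exon signal ratio is therefore an estimate of the
unspliced fraction,

$$\rho \;=\; \frac{\text{pre-mRNA}}{\text{mRNA} + \text{pre-mRNA}},$$

and a time course of that ratio after drug exposure measures how fast
unspliced transcripts accumulate. `intronarray` implements this analysis
end to end for a fission-yeast-sized genome: probe tiling, feature mapping,
array preprocessing, ratio statistics, differential expression, and the
companion qPCR quantification used to validate individual transcripts. A
synthetic-data generator with known ground truth drives all testing.

## Probe tiling and the core-probe map

25-mer probes are tiled every 20 bp along both strands
(`tile_probes()`), mirroring a whole-genome strand-specific array. A probe
is a **core probe** of an annotated feature when it lies on the same strand
and is *fully contained* in the feature's interval. Containment is the
strictest unambiguous rule and makes the eligibility filter meaningful;
probes straddling a splice junction belong to neither segment. An intron
enters the analysis only when it has at least `min_core_probes = 4` core
probes — short introns (the genome-wide average in fission yeast is 81 nt)
frequently fail this filter, which is exactly why only a minority of
annotated introns are quantifiable on this platform.

Probe strand is stored as the annotation strand of the transcript the probe
detects; the physical oligo on the array is its reverse complement. One
convention, applied consistently, since labelling preserves the polarity of
the RNA.

Coordinates are 0-based half-open internally and 1-based inclusive in GFF3
files, converted only at the I/O boundary.

## Preprocessing

The expression pipeline follows the RMA recipe — background correction,
quantile normalization, median-polish summarization on log2 intensities —
with one deliberate simplification: instead of the exponential-signal /
normal-background convolution model, `background_correct()` subtracts each
array's 2nd-percentile intensity and clamps at 1. Every downstream
statistic in this package depends on relative levels only, and the
percentile rule is fully specified and directly testable.

`quantile_normalize()` maps every array onto the across-array mean of order
statistics (ties share the mean of their would-be values).
`summarize_features()` fits, per feature,

$$\log_2 I_{ps} = \mu + \alpha_p + \beta_s + \varepsilon_{ps}$$

by Tukey median polish (row sweeps first) and reports $\mu + \beta_s$ as
the feature's log2 level in sample $s$. Numerical choices: the sweep loop
stops when the largest absolute median sweep falls below `1e-10` (sweeps
decay geometrically, so this is effectively full convergence and is reached
well within the 50-iteration cap); features are summarized independently
per segment — each exon, each intron — rather than through a whole-gene
model, matching the segment-level qPCR validation design. Each segment is
small enough that the additive model is a good local description.

Replicate quality is reported as the Pearson correlation of log2 probe
intensities between the two replicate arrays of each timepoint, computed on
the raw (pre-normalization) intensities.

## Retention statistics

For each eligible intron, the per-sample ratio divides the intron's linear
level by the **geometric mean** of its two flanking exons (arithmetic mean
in log2) — the geometric mean is the natural combination on the log scale
where the summaries live. Replicate ratios are averaged per timepoint with
an **arithmetic mean on the linear scale** (the ratio is the quantity of
interest, so averaging happens on its own scale); a `pool_replicates` flag
keeps replicates as separate observations instead.

Distribution shifts against the untreated baseline use the two-sided
Mann-Whitney test: exact when the combined sample size is at most
`exact_limit = 20` and ties are absent, otherwise the tie-corrected normal
approximation with continuity correction. These switches are fixed for
reproducibility.

The "fraction above 1.5-fold" summary (`count_fold_change_exceedance()`)
counts introns whose timepoint-averaged ratio exceeds the baseline
strictly by more than the threshold, with the full scored-intron set as
denominator. On synthetic data this fraction doubles as an estimator of the
affected-intron fraction, because unaffected ratios concentrate near fold
1 while a retention shift from 0.10 to 0.30 lands far beyond 1.5.

Differential expression uses a moderated two-sample t: the pooled per-
feature variance $s^2$ (d residual df) is shrunk toward the across-feature
mean residual variance $s_0^2$ with a fixed prior weight $d_0 = 3$,

$$s^2_{\mathrm{mod}} = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},$$

and p values come from a t distribution on $d_0 + d$ df. The fully
empirical-Bayes estimation of $d_0$ (as limma does by marginal likelihood)
is intentionally out of scope; the fixed-prior form is completely specified,
testable, and reduces to the ordinary pooled t at $d_0 = 0$. Selection uses
the classic screen "fold change > 1.5 and raw P < 0.05" — the raw-P
convention matches how such gene lists are usually reported — while
Benjamini-Hochberg adjusted values are always computed alongside.

## The synthetic-data generator

`simulation_config()` fixes the study design: timepoints 0/15/60/240 min,
two biological replicates, 200 single-intron protein-coding genes, plus a
handful of tRNA genes (some intron-containing, one multi-copy pair) and one
rDNA unit. Ground truth:

* Each gene's total transcript level $T_g$ is drawn lognormally
  (log2 mean 8, sd 1.5) and **stays constant over time** — the drug
  perturbs processing, not transcription. Intron abundance is
  $\rho_{g,t} T_g$; exon (and whole-gene) abundance is $T_g$.
* A fraction (default 30%) of the *eligible* introns is "affected":
  their retention ramps $\rho = 0.10 \to 0.13 \to 0.18 \to 0.30$ across
  the time course; unaffected introns stay at $\rho_0 = 0.10$.
* The rRNA locus carries two pools: a precursor pool (spacer segments
  ITS1/ITS2 follow it alone) that ramps 1.65-fold by 240 min, and a much
  larger mature pool added to the 18S/5.8S/28S segments, so spacer
  accumulation is visible while mature rRNA stays flat.
* Probe intensities are
  $I_{ps} = B_{ps} + a_p \cdot \text{abundance} \cdot e^{\varepsilon}$,
  with per-probe affinities $a_p$ lognormal (log-sd 0.25, shared across
  samples), measurement noise $\varepsilon \sim N(0, 0.15^2)$, and an
  additive background with an array-specific lognormal level (mean 20)
  and per-measurement lognormal scatter (log-sd 0.2) around that level.
  The per-measurement scatter matters: a constant per-array background
  would make every unmapped probe identical within an array, which both
  inflates duplicate correlations artificially and creates a rank
  point-mass in quantile normalization.
* qPCR plates follow $C_q = C_{\mathrm{ref}} - \log N_0 / \log(1+E)$ with
  triplicate wells and Gaussian Cq noise.

With these defaults the duplicate-array Pearson correlations land around
0.98, comparable to what good tiling hybridizations achieve; no exact match
to any particular experiment is claimed.

### Array composition matters

One generator choice deserves emphasis. Quantile normalization forces all
arrays onto a common distribution, so probes whose true signal rises push
other probes' normalized values down by an amount proportional to the
*fraction of the array* they occupy. On a real whole-genome array the
affected intron probes are a vanishing fraction (~0.1%) and the effect is
negligible, but a toy genome made mostly of eligible introns concentrates
them to ~10% of probes and visibly depresses unaffected ratios. The default
geometry therefore uses realistic proportions — 1200 bp exon segments,
40-150 bp introns (bracketing the ~81 nt genome-wide average of
fission-yeast introns), 600 bp intergenic gaps — which dilutes affected
probes to ~0.3% of the array and keeps the normalization artifact to a few
percent. Even so, the artifact is intrinsic to quantile normalization
whenever a treatment moves a visible fraction of probes, and it is the
main reason a minority of simulated studies show only marginal
Mann-Whitney significance. Simulations that shrink the genome for speed
should keep these proportions.

### What the generator does not emulate

Sequence-dependent probe affinity (GC content), cross-hybridization,
scanner saturation, spatial array artifacts, and biological replicate
variation beyond measurement noise are all absent. Passing tests on this
generator therefore demonstrate that the *pipeline arithmetic* recovers a
known ground truth under a plausible noise model — not that the pipeline is
robust to every artifact of real hybridizations.

## qPCR quantification

Dilution-series standard curves are fitted by least squares,
$C_q = b + m \log_{10}(\text{input})$, and the amplification efficiency is
$E = 10^{-1/m} - 1$ (perfect doubling: $m \approx -3.32$, $E = 1$).
Triplicate wells are averaged; wells more than 0.5 cycles from their
triplicate median are flagged but never removed, and no-RT controls are
screened for amplification below Cq 35. Absolute copies per ng require an
explicit calibrator of known copy number — without one the package refuses
absolute mode and points to relative quantification, since a copy scale
cannot be conjured from Cq values alone. Relative quantification offers the
input-normalized form and the efficiency-corrected ratio-of-ratios (Pfaffl)
form against a reference gene. Multi-copy tRNA genes sharing a `copy_group`
are quantified as one pooled target, because amplicons from identical gene
copies are experimentally indistinguishable.

## Problem sizes used in the test suite

The simulation-based tests run the full design (200 genes, 8 arrays,
~62,000 probes) across 100 seeds for the retention and null checks, 10
seeds for differential-expression recovery, and 100 simulated plates for
qPCR recovery; the mapping, median-polish, Mann-Whitney and
Benjamini-Hochberg implementations are checked against brute-force oracles
on hundreds of random instances. These sizes give stable pass/fail
behaviour for the stochastic criteria while keeping a full run of the suite
in the tens of minutes.

## Known limitations

* The intron/exon ratio is a *relative* retention measure; absolute
  pre-mRNA fractions inherit any probe-affinity bias that median polish
  cannot remove with only two replicates.
* The percentile background correction under-corrects arrays whose
  background varies spatially; it is deliberately simpler than the RMA
  convolution model.
* The fixed-prior moderated t is conservative or liberal depending on how
  far the true variance distribution departs from a single shared scale;
  `d0` is exposed precisely so users can tune the shrinkage.
* Mann-Whitney on per-timepoint *averaged* ratios treats introns as
  exchangeable units and ignores pairing; it mirrors the classic
  distribution-comparison figure rather than a per-intron paired test.
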