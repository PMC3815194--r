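# intronarray

Transcriptome-wide **intron retention analysis for strand-specific tiling
microarrays**, with the companion qPCR quantification methods — built for
studies of drugs and mutants that disrupt pre-mRNA splicing (the motivating
case is 5-fluorouracil treatment of fission yeast, assayed on a
whole-genome 25-mer array tiled at 20 nt on both strands over a time
course).

On such an array, exon probes report mature mRNA *plus* pre-mRNA while
intron probes report pre-mRNA only, so the per-intron signal ratio

```
ratio = intron / geometric mean(flanking exons)  ~  pre-mRNA / (mRNA + pre-mRNA)
```

estimates the unspliced fraction of a transcript. The package implements
the full path from probe coordinates to that statistic and its time-course
tests:

* **Probe tiling and mapping** — `tile_probes()` lays 25-mers at 20 bp on
  both strands; `build_feature_map()` assigns *core probes* (fully
  contained, strand-matched) to every annotated feature and applies the
  eligibility filter: an intron is analysed only if delimited by at least
  4 core probes.
* **Preprocessing** — `background_correct()` (per-array percentile
  subtraction), `quantile_normalize()`, and `summarize_features()`
  (Tukey median polish of log2 probe intensities per feature, Rcpp inner
  loop), plus `replicate_correlation()` for duplicate-array QC.
* **Retention statistics** — `compute_ratios()`,
  `compare_distributions()` (two-sided Mann-Whitney, exact for small
  samples), `count_fold_change_exceedance()` (fraction of introns above a
  1.5-fold increase), `retention_time_course()`, and
  `differential_expression()` (moderated t with fixed-prior variance
  shrinkage, Benjamini-Hochberg adjustment via `bh_adjust()`).
* **qPCR quantification** — `fit_standard_curve()` (dilution series,
  `E = 10^(-1/slope) - 1`), `absolute_quantify()` (copies per ng against a
  calibrator), `intron_exon_copy_ratio()` (with Student's t test), and
  `relative_quantify()` (input-normalized or Pfaffl reference-gene form);
  broom-style `tidy()`/`glance()` and `autoplot()` for curve fits.
* **Synthetic data with ground truth** — `simulation_config()`,
  `simulate_annotation()`, `simulate_abundances()`,
  `simulate_intensities()`, `simulate_qpcr()` emulate the study design
  (4 timepoints x 2 replicates, constant totals, time-ramped retention,
  rRNA precursor accumulation) so every stage is testable against known
  truth.
* **Orchestration** — `run_simulate()`, `run_analyze()`, `run_qpcr()`
  write all tables, JSON summaries and a reproducibility manifest; a thin
  CLI lives at `inst/scripts/intronarray-cli.R`.

All user-facing functions take and return tibbles (or light S3 wrappers
around them) and compose with the pipe.

## Worked example

Simulate a complete study (200 genes, 30% of eligible introns ramping
their retention fraction from 0.10 to 0.30 over 240 min of treatment) and
analyse it:

```r
library(intronarray)

cfg <- simulation_config(seed = 42)
sim <- run_simulate(cfg, "sim")
res <- run_analyze("sim/annotation.gff3", "sim/probes.tsv",
                   "sim/intensities.tsv", "sim/out",
                   ground_truth = "sim/ground_truth.json")

res$qc
#> # A tibble: 4 x 2
#>   timepoint pearson_r
#>       <dbl>     <dbl>
#> 1         0     0.983
#> 2        15     0.984
#> 3        60     0.982
#> 4       240     0.986

res$time_course
#> # A tibble: 3 x 6
#>   timepoint u_statistic   p_value n_exceeding n_total fraction
#>       <dbl>       <dbl>     <dbl>       <int>   <int>    <dbl>
#> 1        15        6503 0.0245              2     105   0.0190
#> 2        60        6722 0.00603            20     105   0.190
#> 3       240        7372 0.0000242          33     105   0.314
```

Reading: duplicate arrays agree (Pearson r about 0.98 on log2 probe
signals); the intron/exon ratio distribution shifts progressively over the
time course (two-sided Mann-Whitney against the untreated baseline), with
31.4% of scored introns above a 1.5-fold retention increase at 240 min —
against a simulated truth of 30.5% affected introns
(`res$summary$recovery$absolute_error` is 0.0095). Exon-level
distributions show no significant shift (`res$exon_time_course`), ruling
out a transcription-rate explanation.

The qPCR side, from a simulated dilution-series plate:

```r
q <- run_qpcr("sim/qpcr_plate.tsv", "sim/qout")
q$curves
#> # A tibble: 3 x 7
#>   target     slope intercept efficiency r.squared n_points
#>   <chr>      <dbl>     <dbl>      <dbl>     <dbl>    <int>
#> 1 exon_A     -3.51      23.2      0.926     1.000        5
#> 2 intron_A   -3.47      25.3      0.943     1.000        5
#> 3 myo1       -3.43      23.8      0.955     0.999        5
```

Each target's amplification efficiency is recovered near the simulated
0.95 from five 4-fold dilutions in triplicate.

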