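# idrbench

Disorder-stratified benchmarking of variant effect predictors (VEPs).

About 30% of human protein residues lie in intrinsically disordered
regions (IDRs) — segments without stable tertiary structure, with weak
sequence conservation and low AlphaFold2 confidence. VEPs built on the
conservation-and-structure paradigm behave differently there, and a single
cohort-wide accuracy number hides it. `idrbench` implements the stratified
benchmark that exposes it:

* **Disorder calling** from per-residue score tracks in several dialects
  (probability-like predictors thresholded at 0.5 / 0.3 / 0.581, pLDDT at
  ≤ 70 read from the B-factor field of AlphaFold PDB files), with
  Savitzky–Golay smoothing (window 9, degree 3) where a tool calls for it.
* **IDR segmentation**: maximal runs of disordered residues, segments
  shorter than 10 residues dropped, survivors classified as N-terminal,
  C-terminal, between-domains, or IDP (fully disordered protein).
* **Variant annotation** with per-tool disorder context, plus the
  start-methionine special case: position-1 variants are split off and
  benchmarked separately, with the first-to-second-methionine distance as
  a rescue proxy.
* **VEP calling** at the authors' recommended cutoffs (REVEL/VEST4/
  VARITY_R/PolyPhen-2 at 0.5, MVP at 0.7, ESM1b at < −7.5, categorical
  AlphaMissense with its ambiguous class excluded) and complete-case
  filtering across the panel.
* **The stratified bootstrap**: sensitivity = TP/(TP+FN) and specificity =
  TN/(TN+FP) estimated on replicates drawn with replacement, an equal
  number from each stratum of (pathogenic, benign) × (disordered,
  ordered), summarised by medians and the gap median(spec) − median(sens)
  per VEP and disorder class. Rank-based (Mann–Whitney) ROC AUC, Pearson
  chi-square with adjusted standardized residuals, and exact/corrected
  Wilcoxon rank-sum tests round out the statistics.
* **A synthetic cohort generator** with known ground truth (latent
  disorder architectures observed through noisy per-tool channels,
  Gaussian class-conditional VEP scores with a disorder-dependent
  separation shrinkage), so the whole pipeline is testable offline and
  recovers its generating parameters.

## Worked example

```r
library(idrbench)

cfg <- synthetic_config(n_proteins = 1000L, seed = 1L)
cohort <- generate_cohort(cfg)

tools <- default_tool_configs()
masks <- lapply(names(tools), function(t)
  call_disorder(cohort$tracks[[t]], tools[[t]]))
names(masks) <- names(tools)
segments <- lapply(names(tools), function(t)
  classify_segments(segment_idrs(masks[[t]]), cohort$proteins))
names(segments) <- names(tools)

ann <- annotate_variants(cohort$variants, masks, segments, cohort$proteins)
round(100 * mean(ann$metapredict_disordered), 1)
#> [1] 31.2
round(100 * mean(ann$label[ann$metapredict_disordered] == "BENIGN"), 1)
#> [1] 83.3

main <- complete_case_filter(split_nmet(ann)$main, default_vep_panel())
bs <- stratified_bootstrap(main, default_vep_panel(), "metapredict",
                           n_reps = 200, per_stratum = 2000, seed = 18)
g <- gap_summary(bs)
subset(g, vep == "revel", c(disorder_class, median_sensitivity,
                            median_specificity, gap))
#>    disorder_class median_sensitivity median_specificity    gap
#> 9      DISORDERED            0.80875            0.93275  0.124
#> 10        ORDERED            0.93100            0.91400 -0.017
```

Read: 31% of variants fall at disordered positions and 83% of those are
benign; for the REVEL-like predictor the bootstrap medians show a
specificity-minus-sensitivity gap of +12 percentage points in disordered
regions versus −2 in ordered ones — the predictor over-calls benign
exactly where variants are hardest to classify. The numbers above are from
a run at the stated seeds; the `analysis/` drivers (`01_simulate.R` …
`06_stats.R`) run the same stages end to end and write their tables and
manifests under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R --seed 20260101
Rscript analysis/02_segment.R
Rscript analysis/03_annotate.R
Rscript analysis/04_benchmark.R
Rscript analysis/05_nmet.R
Rscript analysis/06_stats.R
```

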