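---
title: "Disorder-stratified benchmarking of variant effect predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disorder-stratified benchmarking of variant effect predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrbench)
```

## The problem

Variant effect predictors (VEPs) score missense variants for pathogenicity
and are benchmarked against curated clinical labels. Those benchmarks are
usually reported as single cohort-wide numbers, which hides a structural
feature of the proteome: roughly 30% of human protein residues lie in
intrinsically disordered regions (IDRs), where sequence conservation is
weak, AlphaFold2 confidence (pLDDT) is low, and the conservation-and-
structure paradigm that underlies most VEPs gives little signal. `idrbench`
implements the stratified benchmark that makes this visible: every variant
is annotated with its disorder context under several independent disorder
definitions, and sensitivity and specificity are estimated separately for
disordered and ordered variants with a balanced resampling design.

The pipeline has six stages, mirrored by the numbered drivers under
`analysis/`:

1. **simulate** — generate a synthetic cohort with known ground truth;
2. **segment** — per-residue disorder calls and classified IDR segments per
   tool;
3. **annotate** — join variants to their disorder context and start-Met
   attributes;
4. **benchmark** — complete-case filtering and the four-stratum bootstrap;
5. **nmet** — the start-methionine subset, benchmarked separately;
6. **stats** — chi-square association of IDR positional group with
   phenotype.

## Disorder calling and IDR segmentation

Each disorder tool produces a per-residue score on its own scale, and each
has a recommended threshold and direction: probability-like predictors
(AIUPred, metapredict) call a residue disordered when the score exceeds
0.5, flDPnn at or above 0.3, window-smoothed relative solvent accessibility
at or above 0.581, and pLDDT — an inverted scale, since low structural
confidence proxies disorder — at or below 70. Where a tool states its
threshold without strictness we use `>=` (`<=` for pLDDT); the comparisons
are configurable per tool in `tool_config()`.

For AIUPred and flDPnn the scores are smoothed before thresholding with a
Savitzky–Golay filter (window 9 residues, polynomial degree 3), the
standard least-squares polynomial smoother for per-residue tracks; the
other tools threshold raw scores, and smoothing can be switched per tool.
Edges are handled by evaluating the first/last full window's fitted
polynomial at the edge positions, so any polynomial signal of degree at
most 3 — constants and linear ramps included — passes through unchanged.
Tracks shorter than the window are returned unsmoothed.

Consecutive disordered residues are concatenated into IDR segments and
segments shorter than 10 residues are dropped. Retained segments are
classified by position: `NTERM` if the segment starts at residue 1, `CTERM`
if it ends at the last residue, `BETWEEN` otherwise, and `IDP` when a
single segment covers the whole protein (tested before the terminal labels,
so a fully disordered protein is never double-labelled). Because of the
10-residue filter the pipeline keeps two distinct notions — the per-residue
disordered flag and membership in a retained IDR — and annotates both;
`idr_containment_fraction()` measures how close to interchangeable they are
(a few percent of disordered residues fall outside retained IDRs at
realistic noise levels).

## Variant annotation and the start-methionine special case

Variants are joined to the masks and segments of every tool; the reference
amino acid is checked against the protein sequence. Variants at residue 1
with reference methionine are start-loss candidates with their own
biology — loss of the initiator can be rescued by re-initiation at a nearby
downstream AUG — so they are split off (`split_nmet()`) and benchmarked
separately, and the distance from the first methionine to the second
(`second_met_distance()`, defined as the second Met's 1-based position
minus one; proteins without a second Met are excluded rather than imputed)
is compared between pathogenic and benign hosts with a one-sided Wilcoxon
rank-sum test. As a yardstick for the observed excess of position-1
variants, `nmet_uniform_baseline()` gives the per-site percentage a uniform
distribution would produce — about 0.17% per site for the cohort median
length of 572 residues.

## VEP calls and the complete-case benchmark set

Continuous predictor scores are thresholded at the authors' recommended
cutoffs (0.5 for REVEL, VEST4, VARITY_R and the PolyPhen-2 HVAR
probability; 0.7 for MVP; −7.5 for ESM1b, whose low scores mean
pathogenic). Boundary convention: a score exactly at a `>=`-oriented
cutoff is pathogenic; ESM1b uses a strict `<`. Categorical predictors
(AlphaMissense-style) map their labels directly and their ambiguous
category is excluded from confusion counts. To keep the panel comparable,
the benchmark runs on the complete-case set — variants with a prediction
from every VEP; by default an ambiguous category still counts as "a
prediction exists" (the stricter reading is available via
`ambiguous_as_missing = TRUE`), and any VEP missing more than half its
predictions is flagged for exclusion from the panel.

## The four-stratum bootstrap

The cohort is unbalanced in both label and disorder, so plug-in metrics
from different strata are not comparable. Metrics are therefore estimated
on bootstrap samples drawn with replacement, an equal number from each of
the four strata (pathogenic/benign × disordered/ordered); per replicate,
sensitivity and specificity are computed per VEP within the disordered and
ordered halves of the pooled sample. Each stratum carries a single label,
so per-class sensitivity depends only on the pathogenic stratum of that
class and the "pooled then split" and "per-stratum" readings coincide.
Distributions are summarised by their medians and by the gap
`median(specificity) − median(sensitivity)`; positive gaps mean the
predictor over-calls benign in that class. The reference design is 200
replicates of 12,540 per stratum (a pooled sample of 50,160, the scale of
the clinical cohort); the analysis drivers and tests run 200 × 2,000,
which leaves the Monte-Carlo error of the medians far below the effects of
interest while keeping a full run in seconds. Randomness follows one root
seed from which per-replicate child seeds are drawn, so results do not
depend on execution order. ROC AUC is provided as the rank-based
Mann–Whitney estimator with midranks (equivalent to the conventional
trapezoidal ROC area), computed on the full set rather than on replicates.

## Association tests

The IDR positional-group analysis uses the Pearson chi-square test of
independence (no continuity correction; the tables are larger than 2×2)
with *adjusted* standardized residuals,
`(O − E) / sqrt(E (1 − row prop)(1 − col prop))`, the form whose cells are
approximately standard normal under independence. The Wilcoxon rank-sum
test uses the exact enumeration distribution when `n·m ≤ 400` and the data
are tie-free, and the tie-corrected normal approximation with continuity
correction otherwise — the clinical-scale comparisons (hundreds of
pathogenic hosts vs a few dozen benign) always fall in the approximation
regime.

## The synthetic cohort generator

The generator exists so that every stage can be tested end-to-end with no
external data and with known ground truth. It emulates the statistical
structure of the published clinical cohort, not its sequences:

* **Proteins** — log-normal lengths with median 572 residues (log-sd 0.65,
  a typical spread for curated human proteins), sequences starting with M.
* **Disorder architecture** — one latent ground-truth architecture per
  protein: each terminus begins/ends with a disordered run with
  probability 0.45 (length 10–35% of the protein), one internal linker
  with probability 0.5 (5–30%), and 2% of proteins fully disordered.
  These geometry choices were fixed once so the expected disordered
  residue fraction equals the 0.30 target.
* **Score tracks** — every tool observes the same latent architecture
  through its own channel: the latent state places the score a margin of
  0.25 (25 pLDDT units) on the correct side of the tool's threshold, plus
  AR(1) Gaussian noise (sd 0.12, autocorrelation length 10 residues). With
  the noise at 0 every mask reproduces the latent architecture exactly;
  channels are positively correlated after orientation alignment, giving
  the multi-tool agreement tables non-trivial structure.
* **Variants** — Poisson(8) per protein, positions uniform over residues
  2..L; benign with probability 0.85 at disordered positions and 0.53 at
  ordered ones (the latter chosen so the cohort is ~37% pathogenic overall
  and 10–15% of pathogenic variants fall in IDRs). Start-Met hosts are
  pre-assigned so that position-1 variants make up 0.85% of the cohort and
  are 93% pathogenic; pathogenic hosts have their second methionine
  shifted 20 residues further away (baseline distances geometric with rate
  1/20), so the second-Met comparison has signal.
* **VEP scores** — Gaussian class-conditionals per VEP on its native
  scale, with the recommended cutoff between the class means and
  closed-form expected sensitivity/specificity (`expected_metrics()`).
  Disorder weakens the predictors through a single shrinkage parameter:
  at disordered positions the pathogenic mean moves toward the benign side
  by `shrinkage × (μ_p − μ_b)` and the benign mean by 0.3 × that amount in
  the same direction. A symmetric pull of both means toward their midpoint
  would lower sensitivity *and* specificity in IDRs, which is not what the
  stratified benchmark of real predictors shows — they over-call benign in
  disordered regions, i.e. lower sensitivity but *higher* specificity — so
  the shift is deliberately oriented. Setting the shrinkage to 0 makes the
  disordered and ordered score distributions identical (an exact null for
  testing); any positive value produces strictly smaller class separation
  and a strictly larger specificity-minus-sensitivity gap in the
  disordered class. The default 0.25 places the disordered-class gap
  around +10 to +20 percentage points, the magnitude seen with real
  predictors. Scores are missing completely at random per VEP (2%; 5% for
  one panel member to exercise the missingness report).

What the generator does **not** emulate: real amino-acid substitution
preferences, transcript-level effects, correlated missingness, the
enrichment of particular phenotypes in particular IDR positional groups
(labels depend on the latent state only, so the group × phenotype
chi-square is null on synthetic data and the machinery, not an effect, is
what gets exercised), and any dependence between VEPs beyond the shared
label and disorder state. Tests passing on synthetic data therefore
validate the pipeline's arithmetic and contracts, not the biological
claims themselves.

## Numerical choices and degenerate inputs

* Metrics with zero denominators are `NA`, never 0 or 1 by convention.
* `roc_auc` with a single class is `NA`; all-tied scores give 0.5.
* Savitzky–Golay on tracks shorter than the window returns them unsmoothed;
  even windows and degree ≥ window are errors.
* Segmentation of an all-ordered mask returns a zero-row table; the
  containment fraction of a mask with no disordered residue is `NaN`.
* The bootstrap refuses to run if any of the four strata is empty (the
  error names the stratum) or if start-Met variants are still present
  (overridable).
* pLDDT extraction requires a CA atom per residue and rejects overlapping
  fragment models that disagree on a residue's value; agreement is
  deduplicated silently, since long proteins are distributed as
  overlapping fragments.
* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical cohorts, bootstrap draws and output files.

## Problem sizes

The shipped analyses and tests use 1,000-protein cohorts (~8,000 variants)
and 200 × 2,000 bootstraps: large enough that the realized cohort rates sit
within ±3 percentage points of their targets and the closed-form per-VEP
metrics are recovered within three Monte-Carlo standard errors, small
enough that the full suite runs in about a minute. The per-stratum count
is a free parameter; the reference value of 12,540 is used where the
pooled-sample scale itself is the quantity of interest.

## Known limitations

* The disorder-tool thresholds are treated as exact constants; no
  per-protein calibration is attempted.
* The complete-case rule discards variants rather than imputing scores, so
  panels with very different coverage shrink the benchmark set
  multiplicatively.
* Bootstrap confidence summaries are replicate quantiles only; no
  bias-corrected intervals.
* The annotation join is per-protein-position; multi-transcript proteins
  must be resolved upstream.
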