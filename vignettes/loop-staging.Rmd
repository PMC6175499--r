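---
title: "Staging inflammation and resolution with gene-pair loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging inflammation and resolution with gene-pair loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopstage)
library(dplyr)
```

## The model

A resilient immune response is a perturbation that resolves: transcripts are
induced, peak, and return to baseline. When gene *A* induces gene *B* and
*B* in turn suppresses *A* (IL1A/TNIP3-style feedback), their time courses
rise and fall roughly a quarter period apart. Plotted against each other,
two such series trace a loop through the (A, B) expression plane, and a
sample's angular position on that loop encodes how far along the
inflammation → resolution trajectory it sits. `loopstage` automates three
things: *finding* candidate phase-shifted pairs, *scoring* how faithfully
each loop's angle tracks time, and *using* a loop as a map to stage new
samples.

The method makes few assumptions, but they matter:

* the cohort shares a time grid covering induction **and** resolution — a
  grid that stops at the peak cannot close the loop;
* series are comparable on a log2 scale after rescaling to each
  individual's time-0 baseline;
* a quarter-period shift is the geometry of interest: exactly 90° of phase
  gives a circle, smaller or larger shifts give flatter ellipses that are
  harder to read as a clock.

## Pipeline and the parameters that matter

**Imputation.** A missing (individual, time) sample is filled with the
per-gene median of the individuals observed at that time. Imputation runs
before baseline centring because the time-0 value being subtracted may
itself need imputing.

**Composite profile.** Per gene, the median across individuals at each time
point, centred to time 0. Below six time points the package warns (two
variables out of phase need at least four samples to be resolved; six is
the working minimum used when selecting datasets) but proceeds.

**Dynamic filter** (`top_fraction`, default 0.005; `dispersion_statistic`,
default `"stdev"`). Genes are ranked by the population standard deviation of
the centred composite series and the top `ceiling(top_fraction * n_genes)`
kept. The ceiling convention reproduces the familiar whole-transcriptome
counts (95 of 18859, 91 of 18197); floor or round would give 94/90. Whether
dispersion should be computed on centred or raw values is not fixed by any
convention; we centre first, which makes the statistic a deviation from
baseline, and expose `"range"` as the alternative statistic.

**SAX** (`alphabet_size`, default 4; `word_length`, default one symbol per
time point). Each filtered series is z-normalised (population sd) and each
value mapped to the equiprobable standard-normal region it falls in,
lower-inclusive, so 0 maps to the third of four symbols. Four symbols is a
deliberate compromise for the short series this method targets (T ≈ 7–9):
a binary alphabet cannot distinguish rise from peak, while eight or more
symbols make every word unique and matching brittle. Piecewise aggregate
approximation is available behind `word_length` for longer series but is
off by default — with nine samples there is nothing worth compressing.

**Search patterns** (`shift_symbols`, default `floor(T/4)`). The quarter
period on the symbol scale; flooring maps a 9-point series to a 2-symbol
shift. The shift is a *right* shift with leading wildcards and truncation,
not a rotation: a sampled time course is not periodic, and wrap-around
would fabricate a return-to-start the data cannot support. Consequently
only the `T - shift` non-wildcard positions are compared.

**Matching** (`max_distance`, default 0). "Most closely matched" is
operationalised as Hamming distance over the compared positions, with exact
match as default. Matching is directional — the lead gene's shifted pattern
is tested against the lag gene's word, encoding "lead peaks first" — and
every ordered pair is scanned, so a gene may appear in several candidates.
Equal-distance candidates are ordered lexicographically for determinism.

**Polar geometry** (`grid_resolution`, default 101). Both genes' coordinates
are normalised to the unit range (so neither scale dominates), then a
101 × 101 grid of candidate centres over the bounding box is scanned for the
centre minimising the population variance of radii, with one ×10-finer
refinement pass around the winner and ties broken toward the smallest
(x, y). Angles are measured counterclockwise with 0° at the centroid of the
baseline samples. Angles are unwrapped rank by rank: each sample takes the
360°-branch nearest above (previous rank mean − 180°), which both detects
genuine seam crossings and keeps together samples jittered across the seam
within one rank; baseline angles are read in (−180°, 180°]. The correlation
of unwrapped angle with time is computed on the *rank* scale because the
sampling grids of real studies are grossly uneven (0–4 h densely, then 14,
24, 48 h) — raw hours would let the last point dominate the fit.

**Staging** (`k = 3`, Euclidean). Prediction happens in the raw two-gene
plane, not in polar coordinates — the polar transform is a quality score
and a visualisation, the classifier sees the coordinates directly. Vote
ties go to the tied label whose nearest representative is closest (the
nearest neighbour's label whenever that label is among the tied winners,
extended deterministically when it is not); distance ties resolve by
training-input order. Time labels can be collapsed through a stage map;
`stage_map_vaccination()` encodes the 0–28 day convention (3 → early,
7 → middle, 10 → late, 0/14/28 → base, day 60 excluded via
`excluded_times`) under which baseline days are interchangeable.

**Null comparison.** `random_pair_null()` scores every candidate pair and a
seeded sample of non-candidate pairs on the same holdout split and compares
the two accuracy distributions with a two-sample KS test (`stats::ks.test`,
asymptotic p by default, exact behind a flag). The distance between these
distributions — not any single pair's accuracy — is the evidence that loop
structure carries temporal information.

## What the synthetic generator emulates — and what it does not

`simulate_loops()` reproduces the *structure* of a self-resolving cohort:
multiple individuals on a shared, uneven 9-point 0–48 h grid; a large
static background; planted pairs whose pulses rise from baseline, peak and
return, the lag partner delayed by `round(0.25 T)` samples; per-individual
additive offsets; i.i.d. Gaussian noise; optional missing samples. Defaults
are fixed once to the cohort scale of the motivating data: 12 individuals,
500 background genes, 3 planted pairs, amplitude 2 log2 units
(a four-fold induction, typical for a strongly induced cytokine), noise sd
0.2 (one tenth of amplitude), individual offset sd 0.1, background sd 0.05.

Two design choices deserve explanation:

* **Pulses live on the time-rank axis**, not raw hours, so the planted lag
  is a whole number of samples and aligns with SAX's one-symbol-per-point
  words. This mirrors the ordinal-scale treatment used throughout.
* **Pulses are raised-cosine windows with compact support**, zero outside
  their rise-peak-fall interval, with support placed so the lag partner
  still fits inside the grid. The lead and lag series then contain exactly
  the same multiset of values, z-normalise identically, and at zero noise
  the lag word is an exact shifted copy of the lead word — recovery at
  `max_distance = 0` is guaranteed by construction, which is what makes the
  zero-noise recall invariant a meaningful regression test. Pulse
  peak/width variants are restricted to the widest admissible windows:
  narrow pulses leave long zero plateaus whose z-scores sit almost exactly
  on a quartile breakpoint, and their symbols flip under the slightest
  noise. With more planted pairs than admissible wide shapes, shapes repeat
  across pairs; repeated-shape genes from different pairs are then
  genuinely phase-shifted and legitimately enter the candidate list, which
  is why `score_recovery()` reports recall and precision separately.

What the generator does **not** emulate: probe-level effects, batch
effects, heteroscedastic microarray noise, amplitude variation between
individuals beyond an additive offset, or biological asynchrony (individuals
traversing the loop at different speeds). Passing tests on synthetic data
therefore demonstrate algorithmic correctness — the pipeline finds what it
is defined to find — not that any particular real cohort contains loops.

## Numerical choices and degenerate inputs

* Medians use the standard sample convention (mean of the two central
  values for even counts); standard deviations and radius variances use the
  population convention (irrelevant to argmins/rankings, fixed for
  reproducibility).
* Constant series cannot be z-normalised and raise an error rather than
  silently producing a degenerate word.
* Fewer than three points, identical points, or collinear points (detected
  by the smallest singular value of the centred coordinates) have no
  radius-variance centre and raise errors.
* A sample falling exactly on the fitted centre has no angle; it keeps
  radius 0, inherits the previous time point's angle, and triggers a
  warning.
* Probes mapping to more than one gene are rejected (the probe → gene map
  is treated as single-valued); unmapped probes are dropped and counted in
  a message.
* Ties everywhere — filter cutoffs, grid centres, votes, distances — break
  deterministically (lexicographic symbol, smallest coordinate, nearest
  representative, input order), so identical inputs and seeds give
  byte-identical outputs.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
deliberately moderate scale — cohorts of 4–12 individuals, 9 time points,
up to 500 background genes, 200 classifier oracle instances, 50-pair null
draws — sizes at which every quantity is recomputed from scratch in seconds
while still exercising whole-transcriptome gene counts (18859/18197) where
the arithmetic, not the data volume, is what is being checked.

## Known limitations

* A loop is only a clock where the trajectory is close to one traversal;
  oscillating systems (cell cycle, circadian) would alias.
* Time points at which the pair has returned to baseline are geometrically
  indistinguishable from time 0 — on the synthetic grid, 48 h coincides
  with 0 h in the pair plane. Stage maps that declare such times
  interchangeable (or `excluded_times`) are the honest way to score them.
* With `max_distance = 0` the matcher is conservative: composite-level
  noise that flips a single symbol near a breakpoint hides a true pair.
  Raising `max_distance` trades recall for false candidates; the null
  comparison quantifies whether the trade was worth it.
* The unwrap rule assumes the loop advances monotonically with rank on
  average; a trajectory that genuinely doubles back more than 180° within
  one rank step would be misread.
* Angle–time correlation uses ranks; it measures monotone association with
  sampling order, not calendar speed.
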