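---
title: "Prioritized single-cell proteomics: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritized single-cell proteomics: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(priomics)
```

This vignette is the package's own account of the science it implements:
the acquisition model and its assumptions, the statistical procedures, the
parameters that matter, what the synthetic generators do and do not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## 1. The acquisition model

A data-dependent LC-MS run is modeled as a sequence of duty cycles of
fixed length `cycle_time_s`. Each cycle spends `survey_cost_s` on a survey
(MS1) scan and fills the remainder with MS2 scans, each costing its
allotted maximum fill time plus a fixed per-scan overhead
`ms2_overhead_s`. This is a deliberate simplification of a real Orbitrap:
actual instruments stop accumulating ions when an AGC target is reached,
so expensive scans are often cheaper than their allotment. The fixed-cost
model preserves everything that matters for *scheduling behavior* — which
precursors are chosen when time is limiting — which is the quantity this
package exists to study; absolute scan counts should not be read as
instrument predictions.

**Elution and detection.** Every ground-truth peptide elutes as a Gaussian
of width `peak_sigma` (minutes) around a drift-shifted apex. An
inclusion-list entry is detected in a survey at time *t* when *t* lies
within `rt_tolerance_min` of its offset-corrected predicted apex and its
instantaneous intensity is at or above `noise_floor`. Both gates use
closed-form expressions, so detection boundaries are exactly testable.

**Real-time RT alignment.** The vendor's real-time aligner is proprietary
in detail; the package uses a sliding-window median of (observed −
predicted) apex times over the most recent `calib_window` observations
(default 20). A median is robust to the occasional mis-assigned
calibration peptide and tracks slow linear drift to within a fraction of
the RT tolerance; both properties are covered by tests. Every entry —
including calibration-only entries with `ms2_enabled = FALSE` —
contributes one observation the first time a survey detects it at or past
its true apex.

**Selection.** In prioritized mode, detected, non-excluded, MS2-enabled
entries are ordered by current priority (descending), then intensity
(descending), then m/z (ascending), and packed greedily first-fit into the
remaining budget. Two details were open and are fixed here for
reproducibility: the intensity/m-z tie-break (a deterministic total order
is required for replayable logs), and *continue-past-misfit* greedy
packing rather than stop-at-first-misfit, which keeps duty cycles full —
the stated purpose of the base tier in multi-tier lists. In topN mode the
ordering is intensity alone, each scan costs `default_fill_ms`, and at
most `topn_n` entries are taken; topN competes over the same inclusion
entries so that the two modes are directly comparable (and provably
fragment identical sets when the budget is unconstrained).

**Priority dynamics.** After each fragmentation within the RT tolerance of
the entry's *true* apex, the entry's stored priority is decremented by
one, floored at zero; an out-of-tolerance fragmentation (possible when the
offset estimate is poor) leaves it unchanged. Priorities are monotone
within a run and reset between runs — whether the real scheduler ever
re-increments is not documented anywhere we could verify, and monotone
decrement is the conservative reading. Fragmented entries enter dynamic
exclusion for `dyn_exclusion_s` (default 30 s; standard DDA hygiene,
configurable because it is not part of the prioritization logic proper).

**Identification.** An MS2 event counts as identified when sampled ions
(instantaneous intensity × fill time in ms) reach `id_threshold_ions`.
This deterministic threshold captures the mechanism longer fill times are
for — more ion copies per spectrum — without simulating spectra, and it
makes identification rates a smooth function of the fill-time policy.

The scheduler itself is fully deterministic; the only randomness in a
simulated experiment lives in the generator (drift, intensities), so a
single integer seed reproduces a run byte for byte.

## 2. Inclusion-list construction

`build_tiers()` evaluates tier specifications from highest priority
downward; each tier draws only from peptides not yet assigned, so tiers
are disjoint by construction and lower tiers exclude higher-tier members.
The rule vocabulary mirrors standard practice: PEP ceilings ("spectral
confidence" is read as PEP, lower = more confident), PIF floors, top-k
peptides per protein ranked by PEP ascending (intensity as tie-break),
run-identification-frequency windows (counting *runs* with at least one
passing PSM, not PSMs — apply `add_run_fractions()` before condensing
charge states, or the run evidence is lost), seeded random subsampling,
and a size cap keeping the most confident peptides. Peptides identified
but assigned to no tier stay on the list as calibration-only entries.

The decoy FDR threshold is the largest PEP cutoff at which the decoy
fraction among retained entries meets the target; an exhaustive-scan
oracle verifies both the guarantee and maximality in the tests.
Contaminants and decoys are removed before any tiering.

**Fill times.** Under the tertile policy, boundaries are computed across
the *full* supplied intensity pool (all filtered PSMs of the calibration
run, not the tier), and high-priority entries receive 1000/750/500 ms for
bottom/middle/top tertile; everything else gets 500 ms. Rank-balanced bins
(sizes differing by at most one) with boundary ties going to the
lower-intensity bin make the assignment deterministic; an alternative
900/750/600 grading exists in practice and can be passed via
`tertile_fill_ms`.

## 3. Single-cell quantification

`qc_cells()` computes, per cell and per protein with ≥2 observed peptides,
the CV (sd/mean) of peptide relative abundances, aggregates protein CVs
per cell, and removes cells above the threshold (default 0.4). The
aggregator defaults to the mean with the median available — the two
appear interchangeably in the field's descriptions of this filter, so the
choice is surfaced as an argument rather than hidden. Control channels are
reported but never enter the filtered matrix or downstream statistics.

`normalize_and_aggregate()` runs a fixed chain: optional reference-channel
division, column (cell) median normalization over observed entries, row
(precursor) mean normalization, log2, median aggregation to proteins.
Missingness propagates; imputation and batch correction are identity
hooks (`impute =`, `batch_correct =`) for pipelines that bring their own.
The cells-then-features order of `missingness_filter()` (strict 99%
threshold) is likewise fixed and documented because the source
descriptions leave it open.

One property worth stating precisely: the column/row normalization is
exactly idempotent on matrices with multiplicative per-cell and
per-peptide effects (the structure it is designed to remove — a rank-one
pattern on the raw scale), and only approximately so on arbitrary
matrices. The tests assert idempotence on the product-structured class;
on general complete matrices a second pass still moves entries by several
percent, which is a property of this normalization family, not a bug.

## 4. The statistics

**Intensity-binned null differential test.** Replicate injections of one
sample give per-precursor log2 fold changes whose spread shrinks with
intensity. `fit_null_model()` bins shared precursors into 15 equal-count
bins by the pair's average intensity and stores each bin's mean and s.d.;
`differential_proteins()` z-scores condition fold changes through their
bin and Welch-tests each protein's z's against a seeded draw of 10,000
standard-normal values, then applies BH. Choices made where the procedure
description was open: z-conversion uses bin mean/s.d. (not an empirical
quantile map); bin assignment of new pairs uses breaks at midpoints
between adjacent training bins, clamped to the outer bins; the protein
fold change is the median of its precursor fold changes; the t-test is
Welch (unequal variance); a single-precursor protein, which has no
within-group variance, is scored by the empirical two-sided tail
probability of its z in the same null draw and flagged. Exactly
proportional replicates produce zero-dispersion bins and are refused by
default (`zero_sd_action = "error"`) because every downstream z would be
infinite; `"allow"` exists for inspecting bin means.

**PSEA on PC loadings.** Member loadings vs. all non-member loadings,
two-tailed Wilcoxon rank-sum, eligibility filters ≥5 present, ≥10%
present, <200 entries, BH, filtered at 5% FDR. The per-set "z score" is
the standardization of per-set median loadings across tested sets — the
reference population was unstated, and across-sets standardization is the
reading that makes the column comparable within one results table. Null
calibration was measured directly: on uniformly shuffled loadings the
zero-discovery rate is at the nominal 95% for medium-size sets (the
BH/Simes identity makes it exactly 1−α under the global null) and
measurably above it for small (5–8 member) sets, where the
continuity-corrected rank-sum approximation is conservative; the
acceptance suite exercises the small-set regime typical of size-filtered
annotation databases.

**Marker permutation test.** The statistic is the median Pearson
correlation of a target with panel A minus its median correlation with
panel B. The null permutes protein-column labels (the literal reading of
the procedure it reimplements); permuting cells is available via
`scheme = "cells"` as the more common alternative. p is the fraction of
permutations with `|null| ≥ |observed|`; BH across targets; a p of
exactly zero gets the q floor 1e-5. The Monte-Carlo p agrees with
exhaustive enumeration on a 6-column instance within sampling error.

**Spike-in regression.** Per experiment and precursor, intensities are
divided by the median of the 1× anchor samples; charge states collapse by
median per sequence; pooled log2 normalized intensities are regressed on
log2 relative level through the origin. With a single predictor and no
intercept, partial least squares and ordinary least squares coincide (the
one-component weight is proportional to X'y, and projecting back yields
the OLS slope); the package fits `lm(y ~ 0 + x)` and a test verifies the
equivalence numerically. R² is reported against the through-origin total
sum of squares.

## 5. What the synthetic generators emulate — and what they don't

The generators exist so every routine has a ground truth. They emulate
the *statistical structure* of the real inputs: log-normal precursor
intensities, Gaussian elution with per-run drift, decoy PEPs
stochastically larger than target PEPs (so a 1% FDR cut is informative),
carrier/reference channels at ~200×/~5× the mean single-cell signal,
protein modules with a planted within-module correlation, multiplicative
log-normal reporter noise (cells share per-protein signal across
peptides; control columns are pure peptide-level noise, so the CV filter
separates them), completely-at-random missingness, and replicate noise
whose log2 s.d. falls with intensity percentile.

They deliberately do not emulate: chromatographic co-elution and
interference (no isolation-window purity model), spectra and search-engine
behavior, AGC dynamics, isobaric interference, structured (MNAR)
missingness, or batch effects. Passing tests therefore demonstrate that
the algorithms implement their rules correctly and hold their nominal
error rates under the stated generative model — not that any particular
real experiment will reach a given completeness or identification rate.

All generators take a mandatory seed; `sub_seed()` derives component
seeds from one integer so an entire fixture tree is named by a single
number.

## 6. Numerical choices and degenerate inputs

- Detection boundaries use `≤` on both the RT window and the noise floor.
- Equal-count binning (null model, tertiles) assigns ranks so bin sizes
  differ by at most one, extra members to the lower bins; boundary ties
  fall to the lower bin.
- A negative MS2 budget, an empty inclusion list, an empty calibration
  set, and a zero-length gradient all return well-defined empty results.
- Rates over empty tiers are `NA`, never 0.
- `percent_gain()` refuses a non-positive baseline; the gain is undefined.
- Unknown inclusion ids are reported as undetectable in an attribute
  rather than silently dropped — they signal a list/fixture mismatch.

## 7. Simulation scales

The test suite and `scripts/acceptance.R` use sizes chosen to make the
properties they probe visible while keeping a full run in minutes on one
CPU: the scheduler contrast uses 1,500 entries (3 tiers × 500) over a
15-min gradient with 2-s cycles, where the per-cycle MS2 budget covers
roughly half the detected load — dense enough that priority matters,
which a 60-min gradient at the same list size is not; budget conservation
is audited over 10,000 cycles; the differential null is checked over 200
simulations of 300 precursors/60 proteins; PSEA calibration over 100
shuffles of 20 sets; spike-in recovery over 200 repeats of 8 experiments.

## 8. Known limitations

- The fixed-cost duty cycle ignores AGC early-exit, so absolute
  throughput is approximate; tier *orderings* are the reliable output.
- The identification model is a sharp ion-count threshold; real
  identification probability is sigmoidal in ion count and
  sequence-dependent.
- The RT aligner estimates a global offset; real drift can be locally
  nonlinear within a window.
- `marker_permutation_test()` recomputes nothing about cell structure
  under the protein-label scheme; with few columns the null support is
  discrete, and exhaustive enumeration is preferable below ~8 columns.
- The CLI's TSV formats are deliberately minimal (a column-mapped reader
  adapts other headers); vendor raw files and search-engine outputs are
  out of scope.
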