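---
title: "Predicting Cas13 guide knockdown efficacy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Cas13 guide knockdown efficacy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas13design)
```

## The problem and the model

Cas13 degrades RNA transcripts that base-pair with the 28-nt spacer of
its guide, but measured knockdown varies widely between spacers against
the same target. `cas13design` treats guide design as a four-class
classification problem: normalized residual expression of the target
(0 = fully depleted, 1 = unchanged) is binned into quartiles, and a
classifier maps guide features to the quartile class. The working
assumptions are:

- knockdown efficacy is predictable from the spacer sequence, the
  position of its target window on the transcript, the protein occupancy
  of that window, and the redundancy of the target sequence in the
  transcriptome;
- replicates of one guide share all of those features exactly, so any
  disagreement between replicate labels is irreducible measurement noise;
- expression values arrive already normalized to [0, 1] by the data
  provider; the package never renormalizes them.

## Coordinate and orientation conventions

All coordinates are 0-based half-open in transcript space; there are no
genomic (chromosomal) coordinates anywhere. macs2 `.xls` peak input is
converted on read by decrementing its 1-based inclusive start. A single
internal convention removes any chance of off-by-one drift between the
parser, the feature extractor and the exporters.

The stored spacer is the reverse complement of the transcript window it
hybridizes with; searching operates on the target-side (window) sequence,
so hit positions index transcript windows. The convention lives in one
function (`guide_target_seq()`) and can be flipped there; because the
map is a bijection, it does not change what any classifier can learn.
Spacer positions are stored 0-based from the 5' end; figures and reports
that speak of "position 8" in 1-based terms should add one.

Only the sense strand is searched — transcripts are single-stranded RNA,
and an antisense match is not a Cas13 target. Mismatch tolerance is plain
Hamming distance (no indels), with a maximum budget of 3, the most the
Cas13 system tolerates. `N` bases are allowed in transcripts, but any
28-nt window containing one is excluded from enumeration: an undefined
base cannot parameterize one-hot sequence features.

## The mismatch search

The transcriptome search uses pigeonhole seeding: the 28-nt target
sequence is split into `max_mismatches + 1` equal-length exact seed
blocks (7-mers at the default budget of 3); if a window matches within
budget, at least one block must match exactly. Candidate windows are
located through a hash index of all transcript k-mers and verified by a
full Hamming comparison. The method is exact — the test suite proves it
equivalent to a brute-force scan over every window at every budget in
0..3 — and self-contained. Multiple matching windows within one
transcript count as separate hits; the per-guide hit count is the
multi-target feature.

## Features

- Positional k-mer indicators, `kmer|k|KMER|pos`: one-hot per
  (k, position), not counts — the unit of the per-position composition
  analyses is "which k-mer sits at this position", and the indicators at
  each (k, position) sum to exactly 1 over the `4^k` siblings.
- Composition `comp|A..T`: percent of the spacer, summing to 100.
- `relpos`: `(target_start + 14) / transcript_length`, in [0, 1];
  transcript ends are typically structured, making mid-transcript
  windows more accessible.
- `occ_overlap`: percent of the 28-nt window covered by the union of
  occupancy peaks — peaks are unioned first so the value cannot depend on
  how one occupied region was split into peak calls. A transcript with no
  occupancy data gets 0 with a warning rather than an error: occupancy
  maps are cell-line-dependent and sparse.
- `n_hits`: transcriptome-wide hit count at the configured budget
  (≥ 1 for any guide enumerated from the searched transcriptome).

The full pre-selection space has 2215 columns. The published-style
feature count (112) is a property of one particular training table; the
package keeps the space configurable and ships the full space plus the
selection ladder instead of hard-coding a list.

## The selection ladder

Five candidate k-mer lists are produced:

1. `pval` — univariate simple-regression F-test per feature
   (`F = r²(n−2)/(1−r²)`, df (1, n−2)), keep p < 0.05 strictly; a
   constant feature gets p = 1, and an underflowing p-value is reported
   as the smallest positive double. No multiple-testing correction by
   default, matching the raw-0.05 convention of the source protocol; a
   BH option exists but is off.
2. `z2`, `z3` — standardize `s = −log₁₀ p` over the significant subset
   and keep `z > 2` (or 3) strictly. Applying the Z rungs to the
   significant subset is what makes the lists nest
   (`pval ⊇ z2 ⊇ z3`); applied to an arbitrary p-value map the nesting
   would not be guaranteed. The log base is cosmetic (it rescales all
   z-scores identically); base 10 is fixed for reproducibility.
3. `gini_dt`, `gini_rf` — mean-decrease-in-Gini importances from a
   Gini decision tree / random forest, normalized to sum to 1 over the
   full space; unused features get 0. The list size is user-set
   (`top_n`, default 20) because no canonical size exists; with the
   seven non-k-mer features appended, `top_n` can be chosen to pin the
   final space to any published count.

Diagnostics, not filters: per-position chi-squared
over/under-representation (uniform `1/4^k` null by default — the natural
null for per-position counting; a global-composition background null is
available) and per-position Kruskal–Wallis tests of expression grouped by
the nucleotide at that position (all-tied data defines H = 0; a single
group is flagged not-applicable). Whether the original protocol used the
Kruskal–Wallis positions as a filter or only descriptively is ambiguous;
this package reports them and filters on the regression p-values only.

## Classes, boundaries and ties

Quartile binning assigns boundary values upward (0.25 → class 1,
0.5 → class 2, 0.75 → class 3) and caps 1.0 into class 3, so the four
bins partition [0, 1] exactly. Interval notation like "0–0.25, 0.25–0.5"
is inherently ambiguous at the boundaries; one convention is chosen,
documented and tested. In ranked prediction output, confidence ties are
broken by ascending target start, making output order deterministic.

Confidence is the model's class-membership score: the training-class
fraction in the reached leaf for a decision tree, vote fractions for the
forest and for kNN, and probability estimates for the SVCs. No
calibration is applied.

## Noise-normalized evaluation

Each guide contributes one training row per replicate — identical
features, possibly different labels. This duplication is deliberate: it
is exactly what makes the noise ceiling bind. The ceiling counts, over
unordered pairs of distinct rows with identical feature vectors, the
fraction with disagreeing labels, and

`max_nn = 1 − conflicting/total`, `acc_nn = acc / max_nn`.

The denominator is the set of identical-feature pairs (replicate pairs of
the same guide), not all pairs — the all-pairs reading would drive
`max_nn` to ≈ 1 always and make the normalization vacuous. When no
identical-feature pairs exist, `max_nn = 1` by convention (no noise is
measurable) and the result is flagged. Because the ceiling is a pairwise
bound while a classifier is scored per row, `acc_nn` can exceed 1 on a
2-vs-1 conflicted triple; values slightly above 1 mean the model is at
the ceiling.

Two schemes are implemented:

- **3-fold replicate-wise**: each fold trains on two replicates and
  tests on the held-out third, averaged over the three rotations. The
  source description of this scheme is self-contradictory about which
  side is train and which test; train-on-two/test-on-one is the chosen
  reading, stated here and isolated in one code path.
- **5-fold random**: per repeat, one random 80/20 split of all rows
  (the literal reading of "80% training / 20% testing"), averaged over
  `repeats` (default 100). True rotating folds would be a small variant;
  the one-draw-per-repeat form is implemented.

Per-class one-vs-all AUCs use midrank (Mann–Whitney) counting on the
pooled out-of-fold score matrix — pooling is an interpretation choice,
made because it uses every held-out score exactly once. kNN and
random-forest cells of the benchmark grid sweep k ∈ 1..15 and
trees ∈ {10, 20, …, 100} and report the per-fold-best parameter averaged
across folds; the swept ranges bracket typical best values and are
configurable. Ablation runs `repeats` full-feature evaluations as
background, then `repeats` more per removed feature; note that mutually
redundant features (e.g. the four sibling indicators at one position)
ablate to ≈ 0 individually even when the position as a whole is the
signal.

RNG discipline: every model fit takes an explicit seed, and
`cross_validate()` pre-draws all fold assignments and per-fold fit seeds
before any fitting, so a fit's internal seeding cannot couple successive
splits.

## The fixture generator

`fixture_config()` + `make_guide_dataset()` emulate the study conditions:
a small transcriptome (default 6 transcripts, 300–800 nt, GC 0.5), all or
a sampled subset of candidate guides, exactly 3 replicates per guide, and
occupancy peaks emitted in both BED and macs2-xls dialects. The planted
efficacy rule is compositional — a nucleotide-at-one-position term
(default position 8, mirroring where the real data shows positional
structure), a mid-transcript accessibility term on relative position
0.3–0.7 (the region where efficient guides concentrate in real
predictions), and an occupancy penalty — so each feature family can be
validated in isolation. Replicate noise is Gaussian with sd 0.05 by
default (clipped to [0, 1]); alternatively a target replicate-pair
quartile-disagreement rate can be requested, and the noise sd is solved
for analytically from the normal CDF rather than by simulation, keeping
the calibration deterministic. The emulated disagreement scale (~25%)
matches the replicate discordance reported for the source data.

What the generator does **not** emulate: real HEK293 expression
distributions, RNA secondary structure, sequence composition biases of
real transcriptomes, or correlated (non-Gaussian) replicate error.
Passing the planted-signal tests therefore shows the pipeline recovers
signal of the kinds it models, not that real Cas13 data carries that
signal.

## Problem sizes used by the shipped checks

The test suite runs on transcriptomes up to ~10 kb with brute-force
oracle comparisons, statistical-oracle loops of 100 random instances, a
planted-signal dataset of ~350 guides × 3 replicates, and a 100-repeat
null calibration on 400 rows. `scripts/acceptance.R` regenerates a
555-guide × 3-replicate dataset — matching the size of the published
training set — and reports cross-validated accuracies, the noise ceiling,
per-class AUCs and the null calibration, all recomputed from scratch from
the `--seed` argument. These sizes were chosen so every check completes
in minutes on a single CPU while leaving the statistical conclusions
stable.

## Known limitations

- No RNA secondary-structure features; target-side accessibility enters
  only through occupancy peaks.
- Hamming-only off-target counting; a bulged (indel) near-match is
  invisible to the search.
- The published 112-feature configuration can be reproduced only with
  the original training table, which ships with the source publication,
  not with this package.
- Raw-p feature filtering (no FDR) is faithful to the source protocol
  but anticonservative; the BH option is available when faithfulness is
  not required.
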