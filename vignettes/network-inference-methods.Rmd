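---
title: "Methods: hub-TF network inference from ChIP peaks, motifs and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub-TF network inference from ChIP peaks, motifs and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eranet)
```

## The model

The package implements a hierarchical view of transcriptional
regulation around a ChIP-profiled factor (the motivating case is ERα
in estrogen-stimulated breast cancer cells). A small set of *hub*
transcription factors — those whose motifs are enriched among the
strongest factor-bound peaks — is taken as the upper tier; the lower
tier is every *target* TF gene that is (a) bound by the factor within
a wide window, (b) bound by Pol-II within a narrow window (evidence of
active transcription machinery), and (c) differentially expressed
after stimulation. A directed edge hub → target is proposed whenever
the hub's motif occurs in a factor peak assigned to the target gene,
and the edge is kept only if a sequence-shuffling test rates the
occurrence as arrangement-specific rather than a side effect of base
composition.

The underlying assumptions are worth stating plainly: binding within
100 kb of a gene is treated as potentially regulatory (long-range
enhancer-promoter contact), Pol-II within 10 kb as evidence the gene
is transcriptionally engaged, and a motif occurrence inside a bound
peak as evidence the hub co-binds there. None of these is validated
biochemically by the pipeline; the permutation test controls only for
composition, not for chromatin context or binding competition.

## Scoring

A PWM over `n` columns is built from `m` aligned sites. Per-column
frequencies are either raw counts over `m` or, for small site sets,
pseudocounted as `f = (count + m/4) / (m + m)`, which bounds every
frequency inside (0, 1) and keeps all log-odds weights finite. Weights
are `w(i, j) = log2(f(i, j) / p(i))` with the human-like background
`p(A) = p(T) = 0.30`, `p(C) = p(G) = 0.20` (configurable through
`background_model()`).

For a window of length `n`, the raw score `S_seq` sums the matched
weights and is min–max normalized by the column-wise extremes, so the
per-column argmax ("consensus") window scores exactly 1 and the argmin
window exactly 0. The *core score* slides the contiguous core columns
`k1..k2` along the window, normalizes each placement by the core-only
extremes, and takes the maximum: a core score of 1 means some
placement matches the core's best bases perfectly. Note the asymmetry:
the consensus window always has core score 1, but the anti-consensus
window does not generally have core score 0, because the maximum runs
over all placements.

A scan hit requires core score ≥ 1 **and** PWM score ≥ 0.95 — the
stringent setting used throughout; since comparisons are inclusive,
core threshold 1 demands a perfect core match. Both strands are
scanned by default (ChIP peaks are unstranded); `strands = "forward"`
reproduces a literal single-strand reading. Windows containing `N`
are skipped entirely.

When the core span is not supplied, the package picks the
`core_length = 5` consecutive columns with maximal summed relative
entropy against the background, leftmost on ties. This stands in for
an upstream motif-discovery tool that would normally report the core;
it is a package decision, exposed through `build_pwm(core = ...)`.

## Region taxonomy and windows

Peaks are standardized to 500 bp, centred on the summit when present
and otherwise on the interval midpoint, shifted (not truncated) at
chromosome start so the width is preserved. All coordinates are
0-based half-open; the anchor for every localization decision is the
peak midpoint, which makes the ten region categories a true partition
— each peak gets exactly one label per nearest gene.

The sub-boundaries around the TSS (±200 bp TSS band, 2 kb core bands,
10 kb proximal, 100 kb distal, desert beyond) are package defaults
exposed in `region_schema()`; the 2 kb promoter, 10 kb proximal,
100 kb distal and desert limits follow the source analysis, while the
200 bp band and the exact 3′ mirror are package choices, since the
original sub-region limits are not printed in text form. Strand
matters: "upstream" always means 5′ of the TSS on the gene's strand.

Gene assignment is many-to-many by design: a midpoint inside two
genes' windows is assigned to both, since the network layer operates
per gene and single-nearest-gene assignment would silently drop
regulatory candidates.

## The permutation test

Each candidate edge is backed by one or more (peak, hit) pairs. For
each hit-bearing peak the sequence is shuffled `n_shuffles = 1000`
times — a uniform character permutation, preserving composition but
not dinucleotide structure — and rescanned with the same thresholds.
The reported ratio counts shuffles with at least one hit (the
per-shuffle hit counts are kept as a diagnostic attribute, since
"times hit" could also be read per occurrence). An edge is retained
when at least one supporting peak has ratio ≤ 0.2; requiring all
peaks to pass is available as `edge_support = "all"`.

Determinism: every (hub, peak) pair derives its own substream seed
from the master seed, so networks are reproducible bit-for-bit and
independent of iteration order; the caller's RNG state is restored
after every internal draw.

## The simulator and what passing tests mean

`simulate_regulatory_study()` generates the conditions the pipeline
assumes: one chromosome with 200 non-overlapping genes 350 kb apart
(far enough that 100 kb windows never overlap neighbours), 30 genes
labelled TFs, half the genes dual-bound, factor peaks at scripted
strand-aware offsets (−50 kb … +50 kb from the TSS), Pol-II peaks
within 2 kb of the TSS, a 0/3/6/12 h expression series with a ±2-unit
effect on 60% of genes plus N(0, 0.25) noise, and three hub PWMs.
Hub motifs are planted at PWM score ≥ 0.97 (core forced to consensus)
into the factor peaks of 30% of eligible targets per hub, at
non-overlapping offsets so instances never destroy one another.

The default hub motifs are 12 bp, built from 12 sites at 95%
per-position consensus fidelity. That choice is load-bearing: a hit
requires an exact core match plus PWM score ≥ 0.95, and with these
matrices that effectively demands the full consensus, whose chance
probability in 500 bp of i.i.d. background is about
`2 * 490 * prod(p(base))` ≈ 1e-4 per peak — low enough that exact
edge recovery is the expected outcome of a run. Softer matrices (say
10 bp at 85% fidelity) admit chance matches at the per-mille level per
peak, and since such matches are arrangement-specific the permutation
test rightly keeps them: exact recovery would then fail for reasons
that are a property of the fixture, not of the code. The simulator is
deliberately clean in other ways too: i.i.d. background (no repeats,
no CpG structure, no composition gradients), exactly one peak per
bound gene, and noise-free binding classes. Passing the recovery
tests therefore demonstrates the pipeline's correctness and
calibration on its own assumptions, not robustness to real ChIP
artefacts.

Expression is called by the sign rule, so measurement noise makes
every gene nominally "up" or "down"; planted effects (2 units against
0.35 sd of the difference) essentially never flip sign. This mirrors
the thresholdless design of the original time-series rule, and it is
why the simulator's planted *direction*, not the mere existence of a
call, is what recovery tests check on target nodes.

## Numerical choices and degenerate inputs

* Min–max normalized scores within 1e-12 of 0 or 1 are snapped to the
  exact bound, so a perfect core match scores exactly 1 regardless of
  floating-point summation order; the inclusive core threshold relies
  on this.
* A constant weight matrix (`S_max == S_min`) scores 1 by convention,
  keeping the consensus identity true.
* Sites containing `N` are rejected (frequencies must be unambiguous);
  genome/peak sequences may contain `N`, and windows touching one are
  skipped rather than scored.
* Zero within-group variance in the Welch call is treated as p = 0
  when the means differ and "no call" when they are equal; exact
  zero expression differences are "no call" rather than forced into a
  direction.
* Fold changes are computed on linear-scale means by default
  (`log_scale = TRUE` switches to log2 intensities), as the original
  rule does not state the scale.
* Ties everywhere are broken deterministically: top-peak selection by
  (chrom, start), nearest-gene by distance then lexicographic id,
  core auto-selection leftmost.

## Problem sizes used in the tests

The committed tests run the full pipeline at the default study size
(200 genes, 1000 shuffles) over 20 seeds for recovery and 20 seeds for
the zero-plant control, the scanner–oracle comparison on 50 random
matrix/sequence pairs (sequences up to a few hundred bp), and the
permutation oracle at 1000 shuffles over 10 seeds — sizes chosen so
the whole suite completes in a few minutes while keeping every
stochastic acceptance band meaningful.

## Known limitations

* The shuffle preserves mononucleotide composition only; a
  dinucleotide-preserving shuffle would be stricter for CpG-rich
  peaks.
* The region taxonomy's sub-2 kb boundaries are package conventions;
  analyses sensitive to them should set `region_schema()` explicitly.
* Hubs enter the network only through their motifs: hub nodes carry no
  binding or expression evidence of their own unless they also appear
  as targets.
* The comparison report's "common target percentage" uses the smaller
  target set as denominator; other conventions (union, fixed
  reference) change the number and should be computed from the
  returned sets if needed.
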