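---
title: "Methods: difference-table encoding and the chi-square decision table"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: difference-table encoding and the chi-square decision table}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
model and its assumptions, the parameters that matter, the numerical
choices made where the procedure left room, and what the synthetic
benchmark does and does not demonstrate.

## The prediction problem

Given a protein, every lysine is a candidate succinylation site. The
method works entirely on a fixed-length residue window around the
candidate K (offsets −25…+25; the K itself at offset 0) and on counts of
residues per offset in a labelled training set. Its two assumptions are
(i) that class information is carried by position-specific residue
preferences in a limited window plus coarse compositional context, and
(ii) that training labels are trustworthy but heavily imbalanced
(≈ 1:10 positives to negatives), so the classifier must be cost-aware
rather than rebalanced by sampling.

## Window construction

Fragments shorter than the full window are completed by reflecting
residues across the central K (offset −i takes the residue at +i and vice
versa). The procedure is iterated to a fixed point; if a protein is so
short that positions remain open on both sides, the filled core — by then
a palindrome around K — is mirrored outward again until the window is
full. This extension of the reflect rule is the package's own choice for
an input class the base rule cannot complete; it preserves the
reflection identity `residues[-i] == residues[+i]` for every filled pair,
which is also the property the test suite asserts. Proteins with fewer
than two residues besides the K are rejected: there is nothing to
reflect.

## Table compression and its gate

All discretization in the package is one primitive: greedily merge the
pair of columns of a 2×m class-by-status table whose merged table keeps
the chi-square statistic highest, accept the merge only if a local 2×2
chi-square test on the merged pair is non-significant, stop at the first
rejected merge. The local test keeps a merge only when the two columns
are statistically indistinguishable, so compression stops exactly where
the data resist coarsening.

Numerical choices:

* **α (gate level), default 0.05, shared package-wide.** The procedure's
  sources leave the level unspecified; 0.05 is the conventional choice
  and it is exposed everywhere (`alpha =`) for sensitivity analysis.
  Larger α makes the gate harder to pass and therefore merges *less*.
* **No continuity correction** in the local 2×2 test, keeping the gate on
  the same statistic family as the merge ranking.
* **Zero-count columns merge first**: their local test is defined as
  p = 1, so empty statuses can never block compression. Because merging a
  zero column never lowers the table chi-square, the greedy ranking
  absorbs such columns before any informative merge is attempted.
* **Ties** in the merge ranking go to the first pair in status order
  (determinism); the comparison uses an absolute 10⁻⁹ slack so that
  floating-point noise cannot reorder structurally tied candidates.
* Residue tables merge any pair (*unordered* mode); numeric features
  merge neighbours only (*adjacent* mode), so bins remain intervals.

## Key positions, difference table, features

Per offset, the compressed table's chi-square measures how strongly that
offset separates the classes; offsets strictly above the mean are key
positions. The mean-threshold rule adapts to the signal actually present
rather than fixing a count. Two consequences worth knowing: with a few
very strong offsets the mean is dragged up and weak-but-real offsets can
drop out; with no signal at all the "key" set is whatever noise exceeds
its own mean — the end-to-end tests therefore always plant signal when
they assert recovery.

The Δχ² score of residue *j* at key position *i* is computed from the
*uncompressed* 2×20 table by incrementing the positive (then the
negative) cell for residue *j* and re-deriving every dependent marginal
(class total, column total, grand total) before evaluating the
statistic; compression enters selection only. Positive scores mean the
residue's presence at that offset argues for the positive class; the
score matrix is frozen at fit time and test fragments are encoded by pure
lookup.

Compositional features are proportions, not counts: 20 residue
frequencies normalized by window length and 210 unordered adjacent-pair
frequencies normalized by window length − 1. Proportions keep features
comparable across window sizes and are the standard composition
convention; each block sums to 1 by construction.

## The dependence measure

Feature selection needs one measure that is comparable between
feature-response relevance and feature-feature redundancy. The package
uses a maximal-information-coefficient variant in which grid growth is
terminated by local chi-square tests rather than by a maximal grid size:
one axis is split into equal-frequency bins, the other starts as a
single bin and gains a boundary only while the 2×k table of the two
newborn bins against the fixed axis is significant at α. The score is
mutual information normalized by the smaller marginal partition entropy,
maximized over fixed-axis bin counts and (for non-binary pairs) over
which axis grows. Internals left open by the measure's contract were
resolved as follows:

* **Fixed axis at two equal-frequency bins by default** (a median split;
  binary responses use their two values). This reproduces the measure's
  documented behaviour on independent data — terminal grids of 2×2 or
  2×3 and a small false-association background (mean ≈ 0.06–0.09 at
  n = 100) — while a noiseless functional relation still reaches 1
  through growth of the other axis.
* **Entropy normalization** instead of log₂(min grid size): identical on
  balanced grids, but it keeps the self-score at exactly 1 when tied
  values force unbalanced bins — a contract point the grid-size
  normalization cannot meet.
* **Minimum child share of 10%** for a new bin, the usual guard in
  maximally-selected chi-square procedures: near-edge cuts otherwise
  pair small statistics with small normalizers and inflate the
  independence background.
* All partitioning is on distinct values in rank order, so the score is
  invariant under strictly monotone transforms and deterministic.

The measure is pluggable in `select_features()`: anything mapping
independence towards 0, noiseless dependence to 1, and itself to 1 can
substitute.

## Redundancy-shared forward selection

A set E is scored by Σᵢ rel(i) ⁄ Σⱼ∈E red(i,j); the self term red(i,i)=1
makes the denominator safe and means an exact duplicate contributes
nothing (two copies each at half weight). Candidates are introduced
greedily while the total strictly increases; the forced variant
additionally stops at ≤ 1% relative gain, evaluated against the score
after the previous accepted introduction. The forced list is by
construction a prefix of the natural one. Ties between candidates go to
the lower column index. Pairwise redundancies are computed lazily and
cached, since only candidate-versus-introduced pairs are ever needed.

## The decision table

Retained features are discretized once, globally (adjacent mode, floor of
two bins). The first introduced feature maximizes gain ratio among
features with at-or-above-average information gain ("at or above" so a
pool of equal gains is never empty). Each further feature is recompressed
*within every current rule cell*; cells where it collapses to one bin are
left alone, so rules have variable length. Leaf-wise gain and intrinsic
value are aggregated sample-weighted over the cells a feature can split;
a pure cell always collapses, which is the natural stopping behaviour.
Growth stops when no feature can split any cell.

Balancing multiplies each rule's negative count by θ = n⁺/n⁻, making the
weighted negative row sum to the positive total. The decision statistic
is the chi-square of the *full* balanced 2×R table, evaluated once with
the matched rule's positive count incremented and once with its weighted
negative count incremented; the sample is positive iff the positive
increment wins strictly. Ties go to the negative class — the conservative
call under 1:10 imbalance. Because the decision depends only on the
matched rule, per-rule decisions are precomputed at fit time. Boundary
bins extend to ±∞, so any feature value routes to exactly one rule;
an unmatched sample (impossible through the stored discretizations, but
guarded) is predicted negative and logged. Weighted counts are kept at
full precision; two-decimal rounding is display-only.

## Evaluation indices

MCC is reported alongside sensitivity and specificity but is sensitive to
the class ratio of the evaluation set; Q9 is the ratio-independent
complement. A zero factor in the MCC denominator yields MCC = 0 by
convention (the sources are silent), and the two one-class branches of q⁹
are implemented as defined. Reported tables round half-away-from-zero to
three decimals.

## The synthetic benchmark

The generator emulates the *structure* of curated succinylation
benchmarks: 51-mers centred on K, 1:10 imbalance by default, and planted
class-dependent residue preferences at chosen offsets with a configurable
total-variation distance between the class distributions (default 0.5 at
offsets −2 and +1, uniform background). With a uniform background and
effect ≤ 0.5 the positive class shifts mass onto a ten-residue subset;
larger effects concentrate on fewer residues so the requested distance
stays attainable. What it does *not* emulate: real motif biology,
homology structure between fragments, non-uniform residue usage, or
label noise. Passing the end-to-end tests therefore demonstrates that the
pipeline recovers planted positional signal under realistic imbalance —
not that it attains any particular accuracy on real proteomes.

Problem sizes used by the suite and the acceptance script — recovery at
2000/20,000 fragments, end-to-end training at 300/3,000 with a held-out
150/1,500 split, dependence-measure background over 200 replicates of
n = 100 — were chosen as the smallest sizes at which the planted effects
are comfortably identifiable; all randomness flows from a single seed.

## Known limitations

* The mean-threshold key-position rule has no false-positive control;
  spurious key offsets at small n are expected and tolerated downstream
  (they enter as weak features and are usually dropped by selection).
* The dependence measure's greedy, gated grid growth is a heuristic; its
  score between two continuous variables can sit slightly below an
  exhaustive-MIC value, and symmetry holds only to heuristic tolerance
  (asserted ≤ 0.02).
* Rule tables generalize only through their interval extension; a test
  sample combining bins never seen jointly in training is still routed
  (rules are exhaustive) but its rule's counts may rest on few samples.
* Hard labels only: the decision table produces no calibrated scores.
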