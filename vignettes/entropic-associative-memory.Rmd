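---
title: "Entropic associative memory: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic associative memory: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eamem)
```

## The model

A conventional memory stores functions: each address holds one value.
The registers implemented here store *relations*: each feature argument may
be related to any subset of its `2^m` quantized levels. An associative
memory register (AMR) for a class is the boolean table accumulated by
OR-ing in (abstracting) the quantized representation of every registered
instance. Three operations exhaust the computing model:

- `abstraction(r_f, r_a)` — cell-wise disjunction (the write),
- `containment(r_a, r_f, relax)` — cell-wise material implication (the
  recognition test): a cue fails a column when it holds a level the register
  has never seen there; at `relax = k` up to `k` failing columns are
  tolerated,
- `reduction(f_a, r_f, policy, relax)` — the read: for a contained cue,
  one level per column is selected from the register's marked set, centred
  on the cue.

Because a register is the disjunction of its inputs, it contains not only
the registered instances but every *constituent function* formable by mixing
their levels column-wise. This is the source of both generalization (cues
never registered can be recognized) and confusion (false positives when the
level sets of different classes overlap). The computational entropy

```
e(r) = (1/n) * sum_i log2(mu_i)
```

(`mu_i` = marked levels in column `i`; empty columns contribute 0, so
partial functions have zero entropy) measures that indeterminacy. It is the
system's operating parameter: the experiments sweep it through the
quantization depth `m` and through the amount of registered data.

Two structural facts anchor the test suite. First, a registered instance is
always recognized by its own register (`η(f, λ(r, f))` holds for any `f`,
`r`), and further registration can never revoke an acceptance — recognition
is monotone under abstraction. Second, at `m = 0` every register has a
single row, every fully assigned cue is accepted by every non-empty
register, and entropy is exactly zero; over a balanced 10-class test set the
mean per-register precision is forced to 10% and recall to 100%,
independent of the data. The acceptance script recomputes this degenerate
quadruple end-to-end.

## Kernel choices

**Triangular reduction kernel.** Retrieval under the `triangular` policy
needs a discrete distribution over a column's marked set `S_i`, "centred"
on the cue level `c`. We use weights `w(v) = d_max + 1 - |v - c|` for
`v ∈ S_i`, with `d_max = max_{v ∈ S_i} |v - c|`. This has the properties a
retrieval kernel needs: strictly positive weight on every candidate (any
constituent value remains reachable), a unique peak at the cue when the cue
level is marked, and exact degeneration to the identity when `|S_i| = 1`.
It is also well defined when the marked set is non-contiguous, which
interval-based triangular sampling is not.

**Centring an unassigned cue.** When the cue leaves a column unassigned but
the column has marked levels, both policies centre on the lower median of
the marked set (an element of the set, so the identity policy stays inside
it). This keeps identity and triangular retrieval consistent on partial
cues and makes a fully unassigned cue retrieve a central constituent
function rather than an arbitrary one.

**Identity policy off the support.** Under relaxed containment a cue may be
accepted while holding an unmarked level in a failing column; the identity
policy then snaps to the nearest marked level (ties toward the lower
level). The retrieved function is therefore always contained in the source
relation — an invariant the tests enforce for both policies.

**Relaxation is a count.** The tolerated failures are an absolute number of
columns; percentage inputs are converted by flooring
(`relax_from_percent()`), and counts print as percentages of the feature
set via `relax_as_percent()` (1, 2, 3 of 64 → 1.6, 3.1, 4.7). Relaxation is
a bank-level setting applied uniformly by recognition and retrieval, and
reduction samples failing and passing columns identically — the model gives
no reason to treat them differently.

**Randomness.** Each `reduction_policy` carries a private RNG stream seeded
at construction; successive reductions advance it and the global RNG state
is never touched. All other stochastic steps (corpus generation, partition
shuffles, occlusion) derive from explicit seeds in their configuration, so
every metrics row is reproducible bit for bit.

## Quantization

The quantizer is equal-width per feature: ranges are the observed per-feature
minimum and maximum on the training split, then frozen for registration and
test. Equal-width (rather than quantile) binning keeps the digital/real
conversion affine and order-preserving, so `v1 ≤ v2` implies
`level(v1) ≤ level(v2)` and dequantization is simply the bin midpoint.
Out-of-range test values are clipped into the extreme bins rather than
rejected, because corrupted or occluded cues must still reach the bus;
missing features stay unassigned and impose no containment constraint
(consistent with zero-entropy partial functions). The round trip
`dequantize(quantize(v))` errs by at most one bin width, and midpoints
re-quantize to their own bins — both tested as properties.

## Memory protocols

Registration addresses exactly one register; the label is an explicit
argument, i.e. the attention mechanism that selects the target is assumed
external. Recognition activates the whole bank and costs exactly one
containment evaluation per register — rejection is `O(bank size)`, with no
iterative settling; an internal counter verifies this in the tests.
Retrieval selects, among accepting registers, the one with minimal entropy,
breaking ties by bank order: a deterministic rule chosen for testability,
given that at coarse granularities the minimal-entropy choice is not
expected to beat a uniform random pick (which remains available behind
`selection = "random"` in the granularity sweep). Rejection is a value
carrying the recognition report, never an exception.

Banks persist to JSON with the quantizer ranges written at 17 significant
digits (bit-exact for IEEE doubles) and each table as `2^m` rows of 0/1
integers; loading validates geometry and names the offending register on
mismatch.

## The synthetic generator

The corpus generator stands in for a trained convolutional encoder mapping
handwritten digits to 64 real latent features. It draws one mean vector per
class (coordinates from a centred normal scaled so that the expected
per-feature separation between two class means is
`class_separation × within_spread`) and adds independent Gaussian
within-class noise. Defaults, fixed once:

- `n_classes = 10`, `n_features = 64` — the digit-memory geometry;
- `class_separation = 6`, `within_spread = 1` — a well-separated regime in
  which, at `m = 5`, the quantized level sets of different classes are
  mostly disjoint and per-register precision is essentially 1;
- `fractions = 0.57/0.33/0.10` — the train/rem/test staging: the training
  split exists to fit the quantizer (the stand-in for encoder training),
  the rem split fills the registers, the test split is evaluated;
- `n_instances = 4000` (400 per class, giving 132 rem instances per class).
  The fill-fraction sweep goes down to 1% of the rem split, so each class
  needs at least 100 rem instances for the 1%, 2% and 4% fills to register
  different numbers of instances; 400 per class is the smallest round size
  with headroom, and it keeps the full experiment battery under ten
  seconds.

Partitioning is class-stratified with largest-remainder apportionment
(every per-class split size within one instance of its exact share);
rotating the fold index shifts a fixed seeded per-class shuffle, giving a
10-fold-style rotation of which block lands in each split.

What the generator does *not* emulate: feature covariance (noise is
independent per feature — the minimal structure the memory assumes),
multimodal within-class structure (e.g. handwriting styles), and the heavy
clustering/saturation of real encoder activations. The last difference
matters when reading the curves: with 64 independent Gaussian features, the
probability that a cue passes all columns decays roughly like a per-feature
coverage probability to the 64th power, so recall falls off at coarser `m`
than with encoder features, and the "operational" granularity of the
synthetic system sits near `m = 2..4` rather than `m = 5`. The harness
still uses the economical `64 × 32` geometry for the fill, similarity and
occlusion experiments, whose qualitative behaviour (entropy up, recall up,
precision high, similarity down) is what the tests assert; none of the
published point values are targets here, because they depend on a specific
image corpus and trained encoder.

## Occlusion

Occlusion is emulated in feature space, the pixel pathway being out of
scope. Two modes bracket what an encoder might do with occluded pixels:
`missing` (the information is absent: features become unassigned, imposing
no containment constraint) and `background` (the information is corrupted:
features are replaced by draws from the pooled all-class marginal). A fully
missing cue is vacuously accepted by every register — forced by the
containment semantics — which is why the occlusion experiment defaults to
`background`. Patterns mirror the two published settings at feature level:
`prefix` (the first half of the features, analogous to an opaque rectangle
over the top half) and `bars` (alternating 4-wide feature blocks).

A consequence worth stating plainly: under `background` corruption of half
the features, each corrupted feature independently lands in a register's
level set with small probability, so at `m = 5` essentially every cue is
rejected at relaxations 0–3 and the occlusion metrics sit at the
all-rejected convention (precision flagged 1, recall 0). The monotone
relations — accepted-cue sets grow with `relax`, hence recall is
non-decreasing, by set inclusion; precision is non-increasing — hold
regardless and are what the acceptance checks assert. The unit tests
additionally exercise a milder corruption (a quarter of the features) where
relaxation visibly recovers recall at the cost of precision. The precision
convention for an all-rejecting register or system is 1.0 with an
`all_rejected` flag, so the precision/recall trade-off statement stays
well defined at the extremes.

## The experiments

All five experiment drivers return one metrics row per condition
(`precision_reg`/`recall_reg` macro-averaged over registers, with a micro
option; system precision counting correct decisions among non-rejected
cues; mean register entropy; mean accepting-register count; mean
cue-retrieval similarity where applicable), and are deterministic given the
configuration.

1. **Granularity sweep** (`m = 0..9`): one register per class, rem split
   registered in full. Entropy grows strictly with `m`; the `m = 0` row is
   the structurally forced 10%/100%/10-acceptors/0-bits quadruple.
2. **Overlapped registers**: each register holds two classes. Its rows also
   carry the matching single-class bank's mean entropy; the overlapped
   entropy dominates it at every `m` and strictly for `m ≥ 1` (at `m = 0`
   both are exactly zero — one-row tables are zero-entropy alike, so the
   dominance is an equality there).
3. **Fill sweep** at `64 × 32`: registers filled with 1–100% of the rem
   split (at least one instance per class, nested across fills). Entropy
   and recall grow with fill; precision stays high.
4. **Retrieval similarity**: the cues are the first rem instance of each
   class — registered at every fill level, hence accepted across the whole
   entropy range, mirroring the published design of following cues accepted
   at all entropy levels. Each cue is retrieved ten times under the
   triangular policy; similarity (1 minus the mean range-scaled absolute
   feature difference, capped at 1) declines as entropy grows.
5. **Occlusion × relaxation**: the two half-feature corruption settings
   crossed with `relax = 0..3`, reporting the recall/precision/rejection
   trade-off discussed above.

## Limitations

The memory model itself has no learning beyond disjunctive accumulation and
no forgetting; capacity control happens entirely through quantization depth
and data volume. The dense table representation is deliberate (the
operations are then single-pass boolean scans) and is not meant for very
large `m`. The generator's independence assumptions mean that passing the
qualitative tests here demonstrates the mechanics of the entropy trade-off,
not performance on any real image corpus; connecting a real encoder is a
matter of writing a feature table in the CSV format the corpus functions
already read.
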