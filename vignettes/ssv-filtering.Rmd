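---
title: "Ungapped Viterbi filtering with 8-bit reprojected scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ungapped Viterbi filtering with 8-bit reprojected scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvfilter)
```

## The model and its assumptions

A nucleotide profile HMM assigns each of its $K$ match positions an emission
distribution over A, C, G, T, stored in HMMER3 files as negative natural-log
likelihoods $s(j,c)$. The single-segment ungapped Viterbi (SSV) statistic is
the score of the best *ungapped* diagonal alignment between a target
sequence and the match states — no inserts, deletes, or multi-segment jump
state. Scored in bits against a uniform background,
$b(j,c) = \log_2\!\big(e^{-s(j,c)} / \tfrac14\big)$, the maximal segment
score of a random sequence is well approximated by a Gumbel distribution,
which is what makes a P-value threshold meaningful:
$P(S \ge s) = 1 - \exp(-e^{-\lambda (s - \mu)})$.

Assumptions worth stating explicitly:

* **Uniform background.** The $1/4$ in the bit conversion and the uniform
  random targets of the calibration simulation assume compositionally
  unbiased DNA. GC-skewed targets shift the null upward or downward; the
  Gumbel parameters should then be calibrated on representative background.
* **Length dependence.** The Gumbel location $\mu$ grows roughly
  logarithmically with target length. Precomputed statistics in HMMER files
  are calibrated under HMMER's conventions; when this package calibrates by
  simulation it does so at a user-chosen `seq_len` and the fitted null is
  the per-sequence maximum at *that* length. Calibrate at a length
  comparable to the sequences you will filter.
* **Filtering, not scoring.** The 8-bit engine deliberately forgets scores
  above the threshold (the accumulator resets); it answers "where did the
  score cross", not "how high did it go".

## Threshold projection

Given a P-target $p$ (default 0.02, the conventional pass rate of the
ungapped filter stage), the threshold in bits is
$t = \mu - \ln(-\ln(1-p))/\lambda + a$, where $a$ (`adjust_bits`, default 0)
is an explicit knob standing in for the unspecified adjustment that accounts
for the transitions the ungapped model removes; we found no published value
for it, so it defaults to "none" rather than a guess. Which `STATS` line of
the model file supplies $(\mu, \lambda)$ is likewise configurable
(`MSV` by default, the line associated with ungapped-filter statistics).

Emissions are then scaled so that $t$ maps to the fixed accumulator value
256: $\tau = 256/t$ and $s' = 2\tau - s\,\tau \log_2 e$, rounded to the
nearest integer and cast to signed 8-bit. Two numerical conventions are
deliberate and unit-tested:

* **Ties round away from zero** (C `lround`), so the R implementation and
  any C oracle agree on `*.5` projections.
* **Saturation, not wraparound**, at $[-128, 127]$: saturation preserves
  score order; wraparound would turn a very good emission into a very bad
  one. `clamped_count` on the projected model exposes how many entries
  saturated — a nonzero count signals quantization stress (very small $t$,
  i.e. very permissive thresholds, or `*` impossible emissions, which map
  to the finite sentinel 999 nats precisely so that they saturate at
  $-128$ and can never participate in a passing segment).

The unrounded identity is exact by construction: any full-precision segment
whose bit score is exactly $t$ projects to an accumulated score of exactly
256; rounding perturbs a length-$\ell$ segment by at most $\ell/2$.

## The 8-bit cell rule

With accumulator $M \in [0,255]$ and addend $P \in [-128,127]$, the
intermediate sum $T = M + P$ is computed at ordinary integer precision and
two reset rules are applied: $T < 0$ resets to zero (the alignment is worth
abandoning), and $T \ge 256$ reports a hit *and* resets to zero. The
hardware formulation — an 8-bit full adder whose carry bit, combined with
the addend's sign bit, detects both cases without a comparator — is
mathematically identical; the suite verifies the equivalence exhaustively
on all $256 \times 256$ (accumulator, addend) pairs. We adopted the
"reaches 256" (\(\ge\)) convention throughout: that is the carry-bit
semantics, and a strict reading of $>256$ would make the carry detection
wrong by one.

A consequence worth knowing: a zero addend can never fire a hit
($T \le 255$), and because the accumulator resets on every crossing, a long
strong alignment produces a *chain* of crossing cells spaced roughly
$256/\bar{s'}$ apart rather than one hit.

## Evaluation orders

`ssv_hits_rowmajor()` is the reference order. `ssv_hits_segmented()`
reproduces the accelerator's order: the padded target is cut into length-$n$
segments (default $n = 12{,}288$, the reference hardware's processing
element count); each segment is swept across all model positions as
width-$n$ column passes; the rightmost cell of each column is queued and
dequeued as the leftmost input of the next segment, with the first segment
seeded by zeros. Since every cell still receives exactly
$M(i-1,j-1)$, the dataflow — and therefore the hit set — is identical;
only the traversal order changes. This is asserted exactly on randomized
instances, so $n$ is a pure performance/padding parameter, never a result
parameter.

Targets are concatenated and padded to a multiple of $n$ with seeded random
residues; padding hits are discarded during resolution by a simple
coordinate test.

## Hit resolution and boundary validation

All-to-all search concatenates every sequence and every model into two
global coordinate spaces, so a diagonal can run across a record boundary
and accumulate score that no single (sequence, model) pair would produce.
The host-side validity check re-runs the recurrence restricted to the
candidate's own pair, along the single diagonal through the hit cell —
sufficient because the recurrence along one diagonal is self-contained.

One design choice here was genuinely open. Restricting validation to "does
the restricted diagonal cross *at the candidate's cell*" looks natural but
is subtly lossy: carry-over across a boundary can shift a genuine crossing
a few cells early, and under the strict rule the shifted candidate is
rejected while the true in-pair cell was never reported — a real hit would
be silently lost to concatenation. We therefore re-run the *entire*
restricted diagonal and report every cell at which it crosses, remapping
the hit to its true in-pair coordinates; only diagonals that never cross
in-pair are rejected as boundary artifacts. This keeps the completeness
property — every hit the row-major engine finds on isolated pairs appears
in the validated output of the concatenated search — which the suite
property-tests on planted fixtures. In the hit-dense regime (near-zero
thresholds, adversarial score matrices) no per-diagonal rule can be
perfectly complete, because an early crossing that resolves into a
*different* record pair still perturbs downstream accumulators; the filter
is designed for, and tested in, the rare-hit regime it is actually operated
in.

Reported positions are the threshold-crossing cell (the hit's end),
1-based, per the usual convention of homology search tools; a start
estimate would require information the 8-bit engine does not retain.

## Calibration by simulation

Synthetic models carry no precomputed statistics, so
`calibrate_gumbel_by_simulation()` estimates them directly: $N$ i.i.d.
uniform random sequences are scored with the full-precision max-score
recurrence in background-normalized bits, and a Gumbel is fitted to the
maxima by maximum likelihood (moment initialization, BFGS on
$(\mu, \log \beta)$). The fit is deterministic under a fixed seed, and
parameter recovery on known Gumbel samples is tested to 5% at $N = 5000$.
For the acceptance experiment (below) we calibrate with $N = 2000$ null
sequences of the same 1 kb length as the evaluation set, chosen a priori:
matching lengths makes the fitted null exactly the per-sequence statistic
being thresholded, and at $N = 2000$ the calibration error contributes a
few percent (multiplicative) to the realized pass rate, small against the
acceptance band.

## What the synthetic generator does and does not emulate

`generate_model()` draws per-position emission distributions from a
symmetric Dirichlet; concentration 0.5 gives informative positions
(typical per-position information content around 0.5–1.5 bits), large
concentrations approach the uninformative background. `generate_targets()`
draws uniform i.i.d. DNA. `plant_segment()` overwrites a chosen diagonal
with the model's consensus letter with probability `strength`, recording
both the expected and the realized full-precision bit score of the planted
run, so tests can reason about the rounding envelope exactly.

This stated world deliberately omits: indels (meaningless to an ungapped
statistic), compositional bias, repeats, and realistic family evolution. A
green planted-recovery test therefore establishes that the engine finds
strong ungapped signals above threshold and rejects boundary artifacts —
it does not establish sensitivity on real, gapped homology, which is the
downstream pipeline's job.

## Degenerate inputs and edge conventions

* Empty code vectors, non-nucleotide alphabets, truncated model records,
  and K/LENG mismatches are errors naming the offending file line.
* IUPAC ambiguity letters are replaced by a seeded draw from the letter's
  own expansion (R → {A,G}), not from all four letters — strictly closer to
  the intended distribution; `ambig_mode = "uniform"` restores the looser
  convention. U is treated as T. Replacement positions are recorded.
* Out-of-matrix predecessors contribute 0 (first row/column), matching the
  zero-seeded first segment column.
* Duplicate crossings at identical cells (possible when several candidates
  share a diagonal) are deduplicated; repeated crossings at distinct cells
  are all reported.
* The reference hardware's capacity limits (16 Gbp of sequence, 1,048,576
  model positions, 469,762,048 hits) are memory-bank artifacts, enforced
  here as warnings only.
* Only the forward strand is searched by default; `strand = "both"` adds a
  reverse-complement pass and reports minus-strand crossings in forward
  coordinates.

## Known limitations

* Per-hit scores are not reported: the engine's accumulator caps at 255 by
  design.
* Simulation calibration is the only path for models without STATS lines;
  it does not reproduce HMMER's own $\mu,\lambda$ estimation procedure, so
  thresholds for file-borne statistics follow the file, and thresholds for
  synthetic models follow the simulation, and the two conventions should
  not be mixed within one comparison.
* The segmented engine is a dataflow emulation, not a cycle-accurate model:
  FIFO depths, hit-report partitioning trees, and terminator bits of the
  hardware design have no observable effect on results and are not
  represented.
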