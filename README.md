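# ssvfilter

Single-segment ungapped Viterbi (SSV) homology filtering for nucleotide
profile hidden Markov models, in R.

## The problem

Annotating a genome against a library of pHMMs (e.g. Rfam families) with a
full Forward/Viterbi pipeline is expensive, so production search tools run a
cheap first-pass filter: the **SSV** score, the best-scoring *ungapped*
diagonal alignment between a target sequence and the model's match states.
Only sequences whose SSV score clears a P-value threshold (conventionally
P ≤ 0.02, so ~1/50 random sequences pass) are handed to the expensive
stages. Hardware accelerators for this filter evaluate the dynamic
programming matrix with 8-bit integer arithmetic and report every cell that
crosses the threshold, rather than just a per-sequence maximum. This
package is a faithful, testable software implementation of that filter
design: same scoring projection, same 8-bit cell semantics, same
concatenated all-to-all layout and host-side hit validation.

## The method

For model position `j` and nucleotide `c` with negative-log emission score
`s(j,c)`, the bit score against the uniform background is
`log2(e^{-s} / (1/4))`. Given a Gumbel null `P(S ≥ s) = 1 − exp(−exp(−λ(s−μ)))`,
the threshold at P-target `p` is `t = μ − ln(−ln(1−p))/λ`, and emissions
are reprojected with the scaling factor

```
τ = 256 / t,     s′ = 2τ − s·τ·log2(e)
```

rounded to the nearest integer and saturated to signed 8-bit range. An
accumulated score then crosses the model-specific threshold **iff** it
reaches the fixed value 256. The DP recurrence per cell is

```
T(i,j) = M(i−1,j−1) + P(j, c_i)
M(i,j) = 0      if T < 0            (underflow reset)
       = 0      if T ≥ 256          (threshold hit, reset)
       = T      otherwise,          0 ≤ M ≤ 255
```

evaluated either row-major or in the segmented column order of a
systolic-array accelerator (length-`n` sequence segments, score queue
carrying segment-boundary columns; both orders are provably identical and
tested to be so). Hits are `(i, j)` cell coordinates in the concatenated
sequence/model spaces, resolved back to per-record positions and validated
by re-running the recurrence restricted to the hit's own (sequence, model)
pair, which removes artifacts of boundary crossing and random padding.

## Worked example

```r
library(ssvfilter)

# a synthetic family and 5 random 1 kb targets, with a strong 40-residue
# ungapped segment of the model planted into target 3 at position 201
targets <- generate_targets(count = 5, length = 1000, seed = 101)
model   <- generate_model(K = 60, concentration = 0.5, seed = 102, name = "fam1")
planted <- plant_segment(targets, model, seq_index = 3, seq_start = 200,
                         model_start = 10, length = 40, strength = 1, seed = 103)
write_fasta(planted$targets, "targets.fa")
write_hmm_file(list(model), "fam1.hmm")

cfg <- run_config(p_value = 0.02, seed = 7, calibration = "simulate",
                  calib_n_seqs = 1000, calib_seq_len = 1000)
res <- run_search("targets.fa", "fam1.hmm", cfg)
res$hits[, c("seq_name", "seq_pos", "model_name", "model_pos", "status")]
```

prints

```
  seq_name seq_pos model_name model_pos    status
1  target3     214       fam1        24 validated
2  target3     229       fam1        39 validated
```

with a run summary reporting `threshold t = 18.76 bits, tau = 13.644`
against a planted segment worth `53.4 bits`. Both hits sit inside the
planted rectangle: positions are the threshold-*crossing* cells (the hit's
end, 1-based), and the accumulator resets after each crossing, so a long
strong segment yields a chain of crossings rather than a single one. The
other four targets produce no hits at P ≤ 0.02 for this seed.

A command-line front end wraps the same pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ssv_filter.R", package = "ssvfilter"))') \
    --pvalue 0.02 --calibrate 1000:1000 --seed 7 --out hits.tsv \
    targets.fa fam1.hmm
```

## Layout

- `R/phmm_io.R` — HMMER3 nucleotide model read/write, model database
- `R/sequence_io.R` — FASTA input, 2-bit encoding, padded concatenation
- `R/projection.R` — Gumbel thresholds, τ scaling, int8 reprojection,
  simulation calibration
- `R/ssv_core.R`, `src/ssv_kernel.cpp` — the three DP engines
- `R/hits.R` — hit resolution and boundary validation, TSV/BED output
- `R/synthetic.R` — model/target/planted-segment generator with ground truth
- `R/pipeline.R`, `inst/cli/ssv_filter.R` — end-to-end search and CLI
- `vignettes/ssv-filtering.Rmd` — the methods vignette
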