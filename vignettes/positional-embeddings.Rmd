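---
title: "Small positional embeddings for profile and structure search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small positional embeddings for profile and structure search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posembed)
```

## The problem

Detecting homology between proteins below roughly 20% sequence identity --
the "twilight zone" -- is beyond direct amino-acid comparison.  Profile HMMs
and structure search extend sensitivity into that regime, but both carry a
heavy preprocessing step: building a multiple sequence alignment, or
predicting a full 3D structure.  A protein language model can shortcut both.
Its masked-prediction head yields, for each position, a probability
distribution over the 20 amino acids -- exactly the match-emission row of a
profile HMM -- and its positional embeddings carry enough local structural
signal that a small convolutional head can translate them into the 20-letter
3Di structure alphabet used by structure search engines.  Both outputs are
*small positional embeddings*: one probability vector, or even one letter,
per residue, which drop directly into speed-optimised search engines.

This package implements that conversion workflow end to end at desk scale:
the multi-pass masked profiling algorithm, the profile and database file
formats, the convolutional 3Di head and its training loop, the
mixture-Dirichlet prior estimation needed to re-parameterise a profile-HMM
engine for a structure alphabet, and the two benchmark statistics used to
judge remote-homology search sensitivity.  The real language model is
deliberately out of scope: every function that needs one is written against
a small embedder contract (`new_embedder()`), and the packaged
`toy_embedder()` is a deterministic stand-in satisfying the same contract.

## Masked-marginal profiles

`predict_profile()` converts a single sequence into a positional profile:

1. Prepend `M`.  Language models trained on full-length proteins put a
   strong prior on position 1 being methionine; domain fragments usually do
   not start with one, so the artificial first position absorbs that bias
   and is discarded from the output.
2. Partition the positions into `stride` mask sets: pass *p* masks
   positions congruent to *p* modulo the stride (default 7), so the masks
   shift one position to the right on each pass.
3. Run the embedder once per pass and keep, for each masked position, the
   20 amino-acid logits from the pass that owns it.
4. Softmax (temperature 1, over exactly the 20 canonical logits) turns each
   position's logits into probabilities.

The stride of 7 mirrors the masking density the underlying models saw in
pretraining (about 1/7 of positions masked); masking every position
individually would be more faithful but costs a forward pass per residue.
Positions are counted *including* the prepended `M`: it occupies model
position 1 and takes part in the schedule, so the first original residue is
model position 2.  Whether the original implementation counted the
prepended residue is not determinable from its description; this choice is
documented here and enforced by the tests.  Ambiguity codes (X/B/Z/U/O) are
passed through to the embedder untouched; output distributions are always
over the 20 canonical amino acids.

```{r}
emb <- toy_embedder(seed = 1, dimensionality = 8)
p <- predict_profile("ACDEFGHIKLMNPQ", emb, id = "demo")
head(tidy(p))
```

## Profile files, sampled MSAs, paired databases

`write_hmmer3_profile()` emits HMMER3 ASCII text readable by stock
`hmmsearch`/`hmmscan` (verified against HMMER 3.4 in the tests);
`write_hhsuite_hhm()` emits the HH-suite `.hhm` layout.  Only match
emissions are predicted.  Insert emissions default to a flat background and
transitions to a single constant vector (M→M 0.95, M→I = M→D 0.025,
I→I = D→D 0.2): state-transition prediction is an open problem, so the
writers make the neutral choice explicit in `profile_defaults()` rather
than pretending to knowledge the predictor does not have.  Encoding
precision is the round-trip tolerance: `.hmm` stores −ln p to five
decimals (round trip ≤ 1e−5 absolute), `.hhm` stores round(−1000·log2 p)
(round trip ≤ 5e−4 relative).  E-value calibration lines are omitted;
`sample_msa()` (default 40 sequences, each column drawn i.i.d. from the
profile row) exists precisely so that `hmmbuild` can rebuild a calibrated
profile, with or without its own Dirichlet priors, from the sampled
alignment.

`write_paired_sequence_db()` lays out matched amino-acid/3Di sequence sets
in the MMseqs2-style data/index/dbtype triple: null-terminated payloads, a
tab-separated `key offset length` index, and a 4-byte type tag.  Read-back
is byte-exact and index consistency is part of the round-trip tests.

## The 3Di head

The head mapping positional embeddings to 3Di states is a two-layer 1D CNN:
2560→300 channels (kernel 5, stride 1, padding 3) then 300→21 (kernel 5,
stride 1, padding 1) -- 20 structure states plus one padding class -- with a
ReLU between the layers (the layer count and shapes are fixed; the
activation is this package's choice).  The padding arithmetic preserves
length (L → L+2 → L), checked exhaustively for L = 1..64, and the parameter
count has the closed form 2560·300·5 + 300 + 300·21·5 + 21 = 3,871,821.

Training uses a weighted cross-entropy: the per-class weights are 0.1 × the
diagonal of the packaged 3Di substitution matrix, so structurally
conserved, information-rich states weigh more, and the padding class weighs
zero.  Batches of 15 randomly selected sequences are right-padded to the
batch maximum with the padding class; padded positions are excluded from
the loss and from accuracy.  The optimiser is AdamW (learning rate 0.001,
decoupled weight decay 0.001, biases not decayed) with the learning rate
multiplied by 0.98 every 100 batches.  Everything -- initialisation, batch
selection, the full history -- is determined by the seeds.  The original
recipe's second stage (unfreezing the final transformer layer) only makes
sense with a real backbone; `train_head()` exposes it as a no-op hook so
the protocol slot is visible in the code.

There is no deep-learning framework underneath: the convolutions, backprop
and AdamW are implemented directly in base R matrix operations (im2col plus
hand-derived gradients), which keeps the package self-contained and the
arithmetic auditable.  At desk scale (embedding width ≲ 32, a few hundred
batches) this trains in seconds to minutes on one CPU.

`filter_and_split()` reproduces the dataset protocol: keep lengths in the
inclusive range [120, 1000] ("smaller than 120" and "larger than 1000" are
read as strict exclusions), then split 90/5/5 by largest-remainder
rounding, so 1000 sequences give exactly 900/50/50.

## Mixture-Dirichlet priors

To repurpose a profile-HMM engine for a structure alphabet, its amino-acid
background frequencies and Dirichlet priors must be replaced with values
estimated from structure-alphabet alignment columns.
`collect_column_counts()` keeps columns with more than 10 non-gap residues
(the depth rule is necessarily per-column: an alignment's row count is
constant), `estimate_background()` pools and normalises with a pseudocount,
and `fit_mixture_dirichlet()` maximises the Dirichlet-multinomial mixture
likelihood (default: 9 components, seed 17, 20 symbols, mirroring the
`seed / components / alphabet-size` convention of the equivalent
`esl-mixdchlet fit -s 17 9 20` invocation).

The objective excludes the multinomial coefficient (ordered-draw
convention): it is constant in the parameters, so fitted mixtures are
unaffected, but absolute log-likelihoods are only comparable within this
convention.  Column weighting is available but off by default -- nothing in
the protocol description indicates it.  The EM inner step updates each
component's concentrations by the standard fixed-point (minorise-maximise)
iteration for the Polya distribution, so the objective is non-decreasing;
this is asserted on every fit in the tests.  Numerical guards: a
concentration floor of 1e−4 (degenerate single-symbol data otherwise drives
concentrations to 0; hitting the floor warns), five random restarts by
default, and log-sum-exp throughout.  `export_priors()` writes the mixture
and background as a documented plain-text block with a lossless reader.

## Benchmark statistics

Two evaluation protocols are implemented, both validated against
brute-force oracles on randomized instances:

* **Identity-binned top-hit accuracy.**  `bin_by_identity()` computes each
  test sequence's percent identity to its nearest same-family training
  sequence; `tophit_accuracy()` scores, per bin, whether the top-scoring
  hit's family (or its clan, over clan-labelled queries only) is correct.
  Queries with no hits count as wrong.  Percent identity is defined here as
  identical pairs over all alignment columns (gaps included) of an
  affine-gap global alignment (BLOSUM62, gap open 10, extend 1, Gotoh
  algorithm with a fixed traceback tie-break); the published benchmarks
  inherit their splits and never pin down this definition, so the package
  fixes one and documents it.  Default bins are 2 percentage points wide.
* **Sensitivity to the first false positive.**  For each query with at
  least one possible true positive at every level, walk the bitscore-ranked
  hits: family-level true positives share the family, superfamily-level
  ones share the superfamily but not the family, fold-level ones share the
  fold but not the superfamily; anything from a different fold is a false
  positive, everything else is ignored.  Sensitivity is the fraction of
  possible true positives found before the first false positive;
  `sensitivity_summary()` gives cumulative curves and means.

Ties in bitscores are broken by target id after sorting by score, making
every statistic permutation-invariant and engine-independent.
`two_iteration_search()` wraps any engine satisfying the
`(queries, targets, flags) → hits` contract: a default first pass, then a
relaxed maximum-sensitivity pass (`--max -Z 1 --domZ 1 -E 1000000
--domE 1000000` by default) restricted to queries with zero first-pass
hits.

## Synthetic data

Everything above is exercised without external downloads:

* `gen_families()` evolves each family from a random ancestor by seeded
  point substitutions only -- no indels, keeping identity arithmetic exact
  (an indel-free regime is a simplification; real families have them).
  Test members are calibrated by iterative mutate-and-measure until their
  nearest-train identity lands in the requested range (±5 points).
* `gen_embedding_3di_dataset()` draws each position's 3Di state uniformly
  and emits the state's mean vector plus isotropic Gaussian noise.  With
  means at scale 3 and unit noise the classes are essentially separable
  (the trained head reaches ≥95% held-out accuracy); with coincident means
  accuracy must fall to chance, and does.
* `gen_mixture_counts()` samples component → Dirichlet → multinomial,
  exactly the generative model the fitter assumes.

These generators match the estimators' assumptions by construction.  That
is the point -- they validate the machinery -- but it also bounds what
passing tests show: real embeddings are not Gaussian mixtures, real
families have indels and rate heterogeneity, and real profile columns are
not i.i.d. Dirichlet-multinomial.  Results on synthetic data demonstrate
correctness of the implementations, not expected performance on biological
data.

## Problem sizes and reproducibility

Default test and acceptance runs use deliberately small configurations:
embedding width 16 and ~1000 training batches for the head-recovery
experiment, 2000 columns of 50 counts for mixture recovery, 500 random
profiles for round-trip checks, 10,000-sequence sampled MSAs for the
convergence check, and six-family benchmarks for the end-to-end run.  These
sizes were chosen as the smallest at which each statistical claim is
comfortably testable.  Every stochastic step takes an explicit seed, and
all generators restore the global RNG state, so two runs with equal seeds
are bit-identical.

The MSA-convergence check uses a fixed seed and a profile with
realistically concentrated rows (Gamma(0.3)-derived).  The 0.02
total-variation bound at n = 10,000 is a law-of-large-numbers bound whose
constant depends on row entropy: for near-uniform rows the expected
per-column TV is about 0.017, so the worst column of a long profile can
brush the bound, while concentrated rows -- the regime actual predicted
profiles live in -- sit well below it on average.  The acceptance report
therefore records both the maximum and the mean per-column TV.

## Known limitations

* No real language-model weights: the embedder contract is the boundary.
  Plugging in a real model is supported but never required or tested.
* Written `.hmm` profiles carry no E-value calibration; use the sampled-MSA
  + `hmmbuild` route when calibrated E-values matter.
* The hhm transition/Neff defaults are this package's documented choice,
  not a claim about any other writer's values.
* The packaged 3Di substitution matrix is synthetic (symmetric, integer,
  positive diagonal); substitute the real Foldseek matrix for production
  use.
* `fit_mixture_dirichlet()` finds local maxima; restarts mitigate but do
  not guarantee global optimality.
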