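---
title: "Classifying short non-coding RNA families from raw sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying short non-coding RNA families from raw sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short non-coding RNAs (under 200 nt) — tRNAs, snoRNAs, miRNAs, riboswitches
and many others — are grouped into families of common ancestry and function.
The dominant computational route to family assignment goes through predicted
secondary structure, which is accurate but expensive (structure prediction is
polynomial of high degree in sequence length) and fragile when transcript
boundaries are uncertain. `ncrnafam` implements the alternative this package
is built around: predict the family **directly from the raw sequence**, using
lightweight encodings and convolutional or recurrent networks, plus a
Monte Carlo Dropout rejection step that abstains on sequences the model
cannot place — including non-functional (shuffled) input.

## Sequence encodings

Two encoding families turn a sequence of length at most `max_len` into a
fixed-size one-hot array:

* **Non-overlapping k-mers (1D).** Consecutive disjoint k-letter words, each
  one-hot over the `4^k` canonical words in lexicographic order (A<C<G<T).
  A 100-nt sequence at k = 2 becomes 50 vectors of 16 entries. `k` ranges
  over 1–3; positions number `ceiling(max_len / k)`.
* **Space-filling curves (2D).** The sequence is folded onto a square grid
  along a Hilbert, Morton (Z-order) or Snake (boustrophedon) traversal, so a
  1D neighbourhood becomes (for Hilbert/Snake) a 2D neighbourhood. At
  `max_len = 200` the grids are 16×16 (Hilbert/Morton need a power-of-two
  side) and 15×15 (Snake).

Vacant positions are filled by one of three padding schemes: `new` (a symbol
outside the DNA alphabet, with its own channel), `constant` (a fixed DNA
letter, default A), or `random` (i.i.d. uniform DNA letters). The published
experiments found random padding to hurt curve encodings specifically, which
is why the scheme is a first-class parameter here.

Conventions the source description leaves open, fixed once in this package:

* **Hilbert orientation**: the classic order-n construction starting at
  (0,0) and ending at (side−1, 0), via the standard iterative decode. Any
  fixed variant preserves locality equally.
* **Morton bit order**: row bit more significant in each interleaved pair;
  first cell (0,0).
* **Snake**: even rows left→right.
* **Trailing partial k-word**: sequences are padded up to
  `k * ceiling(max_len/k)` before chunking, so "200/k" positions is realised
  as 100 / 67 for k = 2 / 3.
* **Pad words** (`new` scheme, k-mer): any word containing the pad symbol
  maps to a single dedicated channel rather than expanding to `5^k` words.
  Consequence: a trailing partial word is not recoverable by decoding, so
  the encode/decode round trip is exact for the curve encodings and for
  k-mer when sequence length is a multiple of k (the stored original length
  strips constant/random padding in the other cases).

## Dataset preparation

* **Canonical filter** (`filter_canonical`): drop records with letters
  outside {A,C,G,T}, drop records longer than `max_len` (default 200), then
  drop classes with fewer than `min_class_size` (default 400) survivors. The
  per-sequence length rule is exposed here; a per-class average-length rule
  can be composed by the caller, since the reference procedure screened
  classes by average length before per-sequence cuts.
* **Length-predictability screen** (`screen_length_predictable`): 10-fold CV
  of a decision tree whose only feature is sequence length; classes with
  mean F1 above 0.80 can be classified by length alone and should be
  removed, otherwise "family identity" degenerates into "sequence length".
  The tree is a small hand-written 1D CART (gini, binary splits); no tree
  package is assumed, and the contract is the CV-F1 threshold, not the tree
  flavour.
* **Homology-aware split** (`similarity_aware_split`): stratified 84/8/8
  random split per class, then iterated greedy repair: any held-out sequence
  with normalized Hamming similarity ≥ 0.50 to a same-class training
  sequence is moved to train, until a fixed point. Moving violators into
  train (rather than discarding) preserves dataset size. Similarity between
  unequal lengths counts every position beyond the shorter sequence as a
  mismatch and normalizes by the longer length — a conservative choice the
  source leaves open. The audit table stores every held-out record's final
  maximum similarity to train so either convention (similarity or distance)
  can be reported.
* **Boundary noise** (`add_boundary_noise`): models transcript-boundary
  uncertainty by adding flanks totalling `round(percent/100 × N)` bases
  (round half up), split 5′/3′ uniformly; flank bases come from a
  first-order Markov chain fitted to the record itself, preserving its
  nucleotide and dinucleotide composition. Robustness experiments noise the
  **whole dataset** (train, validation, test) and re-run the pipeline per
  level, matching the reference protocol.
* **Dinucleotide-preserving shuffle** (`dinucleotide_shuffle`): the
  Altschul–Erickson Eulerian-path construction; exact conservation of the
  dinucleotide multiset (hence endpoints and composition) is asserted, and
  for short sequences the outputs are verified against brute-force
  enumeration of valid arrangements.

## Models

No deep-learning framework exists in this package's target environment, so
the network engine is implemented here in R: convolutions as im2col + BLAS
matrix products, hand-written backpropagation (verified against
finite-difference gradients for all three families), Adam/AMSGrad, and
early stopping on validation loss with best-weight restoration.

* **Standard CNN**: 0–3 blocks of convolution (kernel 3, "same" padding) →
  ReLU → max-pool (window 2, stride 2) → 50% dropout; then dense 1000 and
  500 (ReLU) and a softmax output. Filters follow `32·2^i`; the published
  rule is ambiguous at the first block, so the index starts at 1
  (64/128/256), exposed as `filter_base_index`. 1D for k-mer input, 2D for
  curves. Trained with Adam at 1e-3, batch 128, up to 100 epochs, patience
  10 — all four unstated in the source and fixed here.
* **Improved CNN**: 5 convolution layers (filters 32/32/64/64/128 — the
  per-layer counts are unstated and chosen here) with batch normalization,
  Leaky ReLU (slope 0.3) and max-pooling; Gaussian noise (sd 0.1, unstated)
  after every 2 layers; 20% dropout after the last; dense 128 and 64;
  AMSGrad at 5e-4. Pooling becomes a no-op once a spatial dim reaches 1.
* **BiLSTM**: two bidirectional LSTM layers (50/100/150 units) alternating
  with 20% dropout, then a dense softmax. It consumes variable-length
  un-padded k-mer encodings; batches are padded to the batch maximum with
  carry-state masking, so padding never leaks into the final state. A
  trailing partial k-word is dropped (no pad symbol exists in this route).

Class order is always the lexicographic sort of training labels; ties in
argmax go to the lowest class index.

## Uncertainty and rejection

`mc_dropout_predict` runs `N_mc = 50` forward passes with dropout active at
inference (rates as trained; batch normalization stays on running statistics,
Gaussian noise stays off), giving each record an `N_mc × C` sample of class
distributions. Two estimators condense it:

* **Information Entropy** `H = −Σ_k p̄_k log2(p̄_k + ε)` on the MC-mean
  distribution p̄, in bits; `ε = 1e-12` (unstated in the source).
* **Top Difference** `D = p̄_{k1} − c·σ_{k1} − (p̄_{k2} + c·σ_{k2})` over the
  two top-mean classes, `c = 0.6`.

Decision rules: reject when `D < 0`; reject when `H` exceeds one third of
the maximal entropy, `(1/3)·log2(C)`. The printed form of the entropy
threshold in the source is typographically corrupted ("H>13log2(1C)"); this
package reads it as one third of the maximum, exposes the threshold as a
parameter, and makes no claim about the original intent. Evaluation after
rejection computes metrics on accepted records only and reports the rejected
fraction separately.

## Synthetic data: what it emulates, and what it does not

`generate_family_dataset` stands in for a family database download: each
family owns private motifs planted at random positions in i.i.d. (optionally
Markov) background, with overlapping length distributions (defaults: family
means in [60, 160] nt, ±30 spread, truncated to [20, 200]; 3 motifs of
10 nt, insertion probability 0.9, per-position mutation 0.05). By design a
length-only classifier fails on the default world — the screen flags
nothing — so a green classification test shows motif content, not length, is
being learned. What the generator does **not** emulate: secondary-structure
constraints, covariance-model emission correlations, realistic phylogenetic
similarity gradients within families, or class imbalance. A green end-to-end
test therefore establishes that the pipeline learns planted sequence motifs
under the stated noise, not that it reproduces published accuracies on real
family databases.

The scaled-down acceptance world (8 families × 500 sequences, "easy" motifs:
2 per family, 10 nt, insertion probability 1, no mutation) uses family mean
lengths in [40, 55] nt (bounds [25, 65]) rather than the generator defaults,
so that 200% boundary noise — up to 3N = 195 nt — still fits the fixed
`max_len = 200` layouts that the 16×16 grids are sized for. This mirrors the
constraint implicit in the reference experiments and was fixed before any
result was measured. Training for these experiments is adapted to desk
hardware — Adam at 5e-3, batch 256, at most 45 epochs with patience 8 —
because the full-scale defaults (1e-3, batch 128, up to 100 epochs) would
take hours on one CPU for four retrained pipelines; the architectures
themselves are unchanged. At this configuration the 1-mer model converges
to a held-out accuracy a little above 0.9 on the stated world.

Two caveats the test suite makes explicit. First, with a single
convolution/pooling stage the classifier has little translation tolerance:
retraining the whole pipeline under 200% boundary noise costs the 1-mer
model more accuracy than the deep multi-pool architectures of the
full-scale setting lose, although the ordering the experiments probe —
k-mer encodings degrade less than Hilbert grids — is reproduced. The model
memorizes noisy positions rather than failing to fit them (training
accuracy far above validation), so this is a capacity/data limit of the
scaled world, not an optimization artifact. Second, because
dinucleotide-preserving shuffles keep each family's motif-driven base
composition intact, a 1-mer model that partly keys on composition assigns
many shuffles confidently to their source family; shuffled sequences still
draw clearly higher Monte Carlo entropy than functional ones on average,
and rejection improves the accepted-set metrics, but the
functional-vs-shuffled ROC separation on this synthetic world sits below
what full-scale real-sequence experiments report.

## Numerical choices and degenerate inputs

* Softmax/cross-entropy computed jointly with max-shift; `log(p + 1e-12)`.
* Max-pool drops an odd trailing row/column (floor semantics) and routes
  gradients to the first maximum on ties.
* Batch normalization uses biased batch variance, momentum 0.99, eps 1e-3,
  running statistics at evaluation.
* The dinucleotide shuffle resamples last-exit edges until they form an
  arborescence into the final base (expected few tries on a 4-vertex
  multigraph); sequences with a unique arrangement (e.g. homopolymers) pass
  through unchanged.
* `similarity_aware_split` warns and keeps a class wholly in train when it
  has fewer than 3 records; an empty validation set is an error at training
  time.
* All stochastic operations take explicit integer seeds and are
  bit-reproducible under them; training is deterministic given the spec seed
  (single-threaded R RNG).

## Known limitations

* The network engine is CPU-bound R; it is sized for the ≤200 nt, few-class
  regime of the package's experiments, not for 300k-sequence databases.
* BiLSTM training cost grows with batch max-length; bucketing by length is
  not implemented.
* The improved CNN's unstated hyper-parameters (filter counts, noise sd)
  are this package's choices; published test13 numbers are not reproduced
  here at desk scale.
* Rejection thresholds were taken from the stated rules, not re-tuned; the
  entropy threshold reading is documented above.
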