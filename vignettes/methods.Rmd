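---
title: "Methods: model, numerics and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, numerics and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aopred` classifies short peptides (2–50 residues) as antioxidant or not by
fusing two learned views of the same molecule: a sequence view computed by a
stack of extended-LSTM blocks, and a structure view computed by a message
passing neural network (MPNN) over the peptide's molecular graph. This
vignette records the model definitions, the numerical choices, and the
evaluation protocol in enough detail to reimplement them, and states where
this package makes its own choices.

All of the model code is hand-written, vectorized base R with analytic
backpropagation — no deep-learning framework is required. Every gradient is
verified against central finite differences in the test suite, and every
recurrence is verified against an independent scalar-loop transcription of
its defining equations.

## Sequence view: extended LSTM

Sequences are tokenized over the 20 standard amino acids plus a padding
symbol and right-padded to a fixed length of 50. An embedding table maps
tokens to 128-dimensional vectors; positions beyond a sequence's true length
are masked out of every recurrence and of the mean-pooled readout, so the
embedding of a sequence is invariant to the amount of padding and to the
other members of its batch (both properties are tested).

The encoder stacks two residual block types.

**sLSTM block.** A scalar-memory LSTM with exponential gating. With
pre-activations $\tilde i, \tilde f, \tilde z, \tilde o$ (each an affine map
of the input and the previous hidden state), the recurrence is

$$
m_t = \max(\tilde f_t + m_{t-1},\; \tilde i_t), \qquad
f'_t = e^{\tilde f_t + m_{t-1} - m_t}, \qquad
i'_t = e^{\tilde i_t - m_t},
$$
$$
c_t = f'_t c_{t-1} + i'_t \tanh(\tilde z_t), \qquad
n_t = f'_t n_{t-1} + i'_t, \qquad
h_t = \sigma(\tilde o_t)\, \frac{c_t}{\max(n_t, 10^{-6})}.
$$

The stabilizer $m_t$ makes the exponentials safe: the applied gates
$f'_t, i'_t$ never exceed 1, so no overflow is possible regardless of the
pre-activation scale. The floor $10^{-6}$ on the normalizer guards the
division early in training when $n_t$ can be tiny. In backpropagation the
stabilizer is treated as a constant (detached): because $h_t$ depends on
$m_t$ only through the ratio $c_t / n_t$, in which the common factor
$e^{-m_t}$ cancels exactly, its true gradient contribution is zero, and
detaching it avoids propagating a non-differentiable `max`.

Two exact invariances follow from the algebra and are tested: (i) shifting
both gate biases by the same constant in a single step leaves $h, c, n$
unchanged and shifts $m$ by that constant; (ii) shifting only the input-gate
bias across all steps rescales $c$ and $n$ by a common factor that cancels in
$h$. (A multi-step shift of *both* biases is **not** an invariance — the
forget branch carries $m_{t-1}$ forward, so the shifts compound — and the
suite deliberately does not assert it.)

**mLSTM block.** A matrix-memory LSTM with multi-head attention-style
projections. Per head, with query/key/value projections $q_t, k_t, v_t$
(keys scaled by $1/\sqrt{d}$) and scalar exponential gates stabilized exactly
as above,

$$
C_t = f'_t C_{t-1} + i'_t\, v_t k_t^\top, \qquad
n_t = f'_t n_{t-1} + i'_t k_t, \qquad
h_t = \frac{C_t q_t}{\max(|n_t^\top q_t|, 10^{-6})}.
$$

The implementation evaluates this recurrence in a parallel (attention-like)
form over the whole sequence: a decay matrix built from cumulative
log-forget-gates is stabilized per row, exponentiated, and multiplied
element-wise into $QK^\top$. The tests verify that this parallel form equals
the stepwise recurrence to ~1e-14.

Each block wraps its mixer in a residual connection with a pre-normalization
and a gated feed-forward layer. The full encoder has **695,568 parameters
(0.70 M)**; this count is asserted in the tests. The sequence embedding is
the masked mean of the final hidden states projected to 128 dimensions.

## Structure view: molecular graph and MPNN

`peptide_to_smiles()` builds a SMILES string for any linear peptide by
concatenating residue templates (backbone `N-Cα-C(=O)` plus a side chain per
residue, with the C-terminal carboxyl closing the chain). The string is then
canonicalized with OpenBabel, which also assigns aromaticity — OpenBabel is
the chemistry oracle; this package does not implement an aromaticity
perception model of its own. For throughput, canonicalization is batched:
all unique molecules in a dataset go through a single `obabel` process
invocation rather than one round-trip per molecule.

The canonical SMILES is parsed by a small pure-R reader covering the organic
subset plus bracket atoms (isotope, chirality markers, explicit hydrogens,
charge), branches, ring-closure digits including `%nn`, and the bond symbols
`- = # : / \`. Implicit hydrogen counts follow the SMILES valence rules
(smallest default valence that covers the bond-order sum, aromatic bonds
counting 1.5); ring membership is computed as the non-bridge edges of the
graph via fundamental cycles of a BFS spanning tree. Multi-fragment SMILES
(dots) are rejected — a peptide is a single connected molecule.

Each atom becomes a node with 13 features: element one-hot over
{C, N, O, S, other}, degree one-hot over 1–4, formal charge, aromatic flag,
implicit-hydrogen count, and ring membership. Each bond carries 5 features:
single/double/aromatic one-hot, conjugation, and ring membership. This
feature set is this package's own concrete reconstruction of a standard
small-molecule featurization; it is versioned (`FEATURIZER_VERSION`), and
checkpoints refuse to load across featurizer versions.

The MPNN runs 3 rounds of message passing. In round $t$, node $v$ sums
messages $[h_u \,\|\, e_{uv}]$ over its neighbors $u$, then applies a
degree-conditioned linear update with a sigmoid nonlinearity — nodes of
degree 1, 2, 3 and ≥4 use separate weight matrices, which lets the network
distinguish chain, branch and ring contexts without attention. The readout
is the mean over node states projected to 128 dimensions. Summation and mean
make the embedding exactly invariant to atom relabeling (tested over 50
random permutations of 10 real peptide graphs). The hidden width is 71,
giving **74,962 parameters (75 k)**, also asserted.

## Fusion and training

Three fusion strategies are provided. The default, *hierarchical*, passes
each 128-dimensional view through its own 64-unit ReLU stage, concatenates,
and applies a fully connected head (128 → 64 → 32 → 1) with dropout after the
hidden layers. *Concatenation* joins the raw views (256 → 64 → 32 → 1).
*Cross-attention* lets each view attend to the other before the
concatenation head; with a single token per view the softmax is degenerate
(a weight of exactly 1), so at this granularity it reduces to a learned
bilinear exchange — it is included for API completeness and documented as
such. Single-view models (`view = "sequence"` or `"graph"`) reuse the same
head on one branch, which is how the ablations are run.

Training minimizes binary cross-entropy on logits with Adam and decoupled
weight decay. Dropout uses inverted scaling. Default hyperparameters are
learning rate 1e-5, weight decay 3e-3, dropout 0.2, batch size 64, up to 300
epochs with early-stopping patience 30. Batch order and dropout masks are
drawn from seeds derived deterministically from the training seed, so a
fixed-seed run is bit-reproducible end to end (tested: two identical
train→predict runs produce identical histories and predictions).

The total model has 797,411 parameters, within an 800 k budget.

## Synthetic benchmark and the desk-scale protocol

`generate_separable_benchmark(seed = 7)` draws 800 training and 200 test
peptides whose class-conditional residue compositions are mixed toward
antioxidant-enriched residues with bias 0.6. Because the generative model is
known, a Bayes-style composition oracle (`oracle_predict()`) upper-bounds
achievable accuracy (≥ 0.95 on this benchmark). The generator's parameters
are study conditions, not tuning knobs.

The published full-scale protocol (300 epochs, patience 30, lr 1e-5) is far
beyond a desk-scale test budget, so the package's acceptance checks use a
deliberately small protocol chosen once and then frozen: learning rate 1e-3,
batch 64, 12 epochs, no early stopping. Under it the fused model reaches
roughly 0.93–0.94 test accuracy and each single view roughly 0.92–0.93, in
about ten minutes of single-core CPU; the gates are fused ≥ 0.90, oracle
≥ 0.95, and fused ≥ best single view − 0.02.

Published benchmark accuracies on AnOxPePred, AnOxPP and AOPP (around 0.80,
0.97 and 0.90) require the original datasets and hours of training; they are
documented as a replication recipe (`replication_recipe()`) and are **not**
asserted by any test.

## Evaluation

`compute_metrics()` reports accuracy, precision, sensitivity, specificity
and the Matthews correlation coefficient from a confusion table, with
explicit `*_defined` flags instead of NaNs when a denominator is zero (the
convention used is 0 for an undefined MCC or precision, flagged). It is
verified against an independent oracle on 1000 random confusion tables and
on the worked example TP=3, TN=2, FP=1, FN=1 → MCC = 5/12.
`cross_validate()` performs stratified k-fold CV with an inner 10%
validation carve-out per fold; `paired_t_test()` compares configurations
across folds (degenerate zero-variance cases are flagged, not silently
significant); `length_stratified_eval()` splits performance at a residue
threshold (default 15) to expose short- vs long-peptide behavior;
`grid_search()` ranks hyperparameter combinations by CV accuracy with MCC as
the tiebreak.

## Limitations

* The SMILES writer covers linear peptides of the 20 standard residues only
  — no cyclic peptides, no post-translational modifications.
* The pure-R SMILES parser targets OpenBabel's canonical output for such
  molecules; it is not a general-purpose cheminformatics parser.
* Cross-attention fusion is degenerate at one token per view (see above).
* Training is single-threaded base R: suitable for the desk-scale synthetic
  benchmark and for small datasets, not for large-scale screening.
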