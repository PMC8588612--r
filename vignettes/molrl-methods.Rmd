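---
title: "Multi-objective reinforcement learning for de novo molecule design: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective reinforcement learning for de novo molecule design: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Drug candidates rarely need to bind just one protein. A molecule aimed at
two receptor subtypes must also stay away from anti-targets such as the
hERG potassium channel, whose inhibition causes cardiotoxicity. `molrl`
implements a generative workflow for this *polypharmacology* setting: a
recurrent SMILES language model proposes molecules, a battery of
per-target scoring functions (QSAR regressors or deterministic oracles)
predicts their potencies, and policy-gradient reinforcement learning
pushes the generator toward molecules that satisfy *all* potency
objectives simultaneously while staying chemically diverse.

## The generator

A molecule is a SMILES string, lexed into tokens: bracket atoms (`[nH]`,
`[O-]`) and two-letter halogens are single tokens, as are `%NN` ring
closures; `GO` and `END` delimit sequences. The vocabulary is rebuilt
from whatever corpus is supplied (sorted union of observed tokens), so
the package is not tied to any fixed token list.

The language model is an embedding (default 128-d) followed by stacked
LSTM layers (default 3 x 512; a GRU cell is available as an ablation
switch) and a softmax output head. Training is teacher-forced
negative-log-likelihood minimization with Adam (learning rate 1e-3,
batch size 512 by default); a held-out validation split is scored each
epoch and the best-validation checkpoint kept, which matters for
fine-tuning on small focused sets. Sampling is plain autoregressive
multinomial sampling at temperature 1. Sequences that fail to emit `END`
within `max_len` tokens (default 100) are counted invalid.

No deep-learning framework is available to R in this stack, so the
forward and backward passes are written directly against BLAS-backed
matrix operations. The backward pass is verified against central finite
differences in the test suite for both cell types; this is the part of
the package most worth that level of paranoia, because the policy
gradient reuses exactly the same machinery.

## Scoring and rewards

Each objective couples a predictor with a direction and a threshold.
Predicted potency pX (negative log10 of Ki/Kd/IC50/EC50) lives on
[3, 10]; predictions are clipped to that range and min-max normalized,

$$R_i = \frac{pX_i - 3}{7} \quad\text{(high affinity)}, \qquad
  R_i = 1 - \frac{pX_i - 3}{7} \quad\text{(low affinity / anti-target)},$$

with $R_i = 0$ for an unparseable SMILES. pX 6.5 — the conventional
activity cutoff — maps to the default threshold $t_i = 0.5$. A molecule
is **desired** when $R_i > t_i$ strictly on every objective.

Two schemes reduce the score vector to one scalar reward per molecule:

* **Weighted sum (WS).** Weights are dynamic: each objective's ratio
  $r_i = N_i^{smaller}/N_i^{larger}$ of below- to above-threshold
  molecules in the current batch is normalized to
  $w_i = r_i / \sum_k r_k$, and $R^* = \sum_i w_i R_i$. Harder
  objectives therefore get more weight as training proceeds. When no
  molecule clears a threshold the denominator is replaced by 1, which
  preserves the monotone "harder gets more weight" behaviour without
  infinities.
* **Pareto front (PF).** Dominance is evaluated on desirability-
  transformed scores $D_i = \min(1, R_i/t_i)$, which caps credit above
  the threshold so that among satisficing molecules only diversity
  matters. The batch is partitioned by fast non-dominated sorting,
  fronts ordered from dominated to dominant; within a front molecules
  are ranked by mean Tanimoto distance (ECFP6) to the rest of the front,
  most distant first — diversity replaces crowding distance. With global
  1-based rank $k$ along the full ordering (all undesired molecules
  before all desired; invalid strings at the very bottom),
  $$R^*_k = \frac{k}{2N_{und}} \ \text{(undesired)}, \qquad
    R^*_k = 0.5 + \frac{k - N_{und}}{2N_{des}} \ \text{(desired)},$$
  so undesired rewards tile (0, 0.5] and desired rewards tile (0.5, 1],
  the best molecule receiving exactly 1. Degenerate batches (no desired,
  or no undesired) use whichever branch applies over the whole range;
  ties in mean Tanimoto distance keep input order for determinism.

The agent is updated by gradient ascent on
$J(\theta) = \sum_b R^*_b \sum_t \log G_A(y_t \mid y_{<t})$ — a
reward-weighted likelihood, implemented as the NLL backward pass with
per-sequence weights.

## Exploration strategy

Three networks share a vocabulary: the **agent** $G_A$ (trained), the
**crossover net** $G_C$ (refreshed from the agent at iteration
boundaries), and the **mutation net** $G_M$ (the frozen pretrained
model). At every token position of every sequence an independent uniform
draw routes the step: with probability $1-\varepsilon$ the token is
sampled from the blend of $G_A$'s and $G_C$'s distributions, otherwise
from $G_M$. The blend is the renormalized arithmetic mean of the two
probability vectors; the geometric mean is available behind a config
switch. The arithmetic mean was chosen as the default because it is
symmetric and preserves the support of both policies (a geometric mean
zeroes any token either policy rules out).

An *iteration* ends when the desired fraction of molecules sampled from
the agent alone (a fixed-size probe, default 200 per epoch) has not
improved for `patience` consecutive epochs (default 3); $G_C$ is then
overwritten with $G_A$'s parameters. Training stops when an iteration's
best desired fraction does not exceed the previous iteration's, or at
`max_iterations` (default 20). These two defaults are package choices —
exposed in `explorer_config()` — as is measuring the plateau on
agent-only samples, which follows from the stop rule being a statement
about the agent. With $\varepsilon = 0$ and $G_C = G_A$ the whole scheme
reduces exactly to plain agent sampling (the tests pin this down to
stream identity).

## The QSAR environment

Molecules are featurized to 2067 dimensions: a 2048-bit ECFP6
fingerprint plus 19 physico-chemical descriptors (molecular weight,
Wildman–Crippen logP and MR, H-bond acceptors/donors, rotatable and
amide bonds, bridgehead/hetero/spiro/heavy atom counts, fraction of sp3
carbons, aliphatic/saturated/total/aromatic ring and heterocycle counts,
valence electrons, TPSA). Features are min-max scaled with statistics
from the training split only; unseen values clip to [0, 1].

Bioactivity tables are cleaned to one record per (canonical molecule,
target): duplicate measurements average; rows labeled inactive without a
measured value are imputed at pX 3.99 with sample weight 0.1 (measured
rows weigh 1.0), which lets low-quality negatives inform the model
without dominating it. Four regressors are available: random forest
(1000 trees, mtry p/3 — the regression-forest convention; the default
and the recommended environment), RBF-kernel SVM (an optional inner-CV
grid over C in 2^[-5, 5] and gamma in 2^[-15, 5]; off by default since a
30-fit grid is disproportionate at desk scale), PLS, and a multi-task
feedforward net (hidden layers 4000/2000/1000,
ReLU, dropout 0.2, Adam at 1e-3, masked per-target loss). Weights are
honoured natively by the forest (case weights) and the multi-task net
(weighted loss); the installed SVM and PLS implementations have no
per-case regression weights, so those fits are unweighted and say so.
Evaluation offers 5-fold cross-validation (random, seeded) and a
temporal split at a configurable cutoff year. Predictions are clipped to
[3, 10] before reward normalization since regressors can extrapolate.

Toy oracles — affine maps of deterministic properties (aromatic ring
count, heteroatoms, rotatable bonds, logP, ...) into [3, 10] — stand in
for trained models wherever speed and determinism matter more than
realism, in tests and in the shipped objective configurations.

## Chemistry backend and validity

OpenBabel (via ChemmineOB) is the parser, canonicalizer, SMARTS matcher
and fingerprint engine. Two of its behaviours required explicit
handling. First, it silently repairs truncated input — `"C("` parses as
methane — so validity here is a conjunction: the string must lex under
the SMILES grammar with balanced branches and paired ring closures *and*
parse to a molecule. Second, it accepts hypervalent atoms (pentavalent
carbon, divalent fluorine) with only a warning, so every atom's total
valence is checked against its element's allowed set, adjusted for
formal charge. Uniqueness is always computed on canonical SMILES, since
raw-string uniqueness is trivially inflated by atom reordering.

OpenBabel's ECFP6 is 4096 bits; it is folded to 2048 by OR-ing congruent
positions to meet the 2048-bit contract. Folded bit positions do not
correspond to any other toolkit's Morgan hashing, which is immaterial
here because fingerprints are only consumed internally (Tanimoto
distances, QSAR features).

## Evaluation metrics

For a generated set: validity (parseable fraction), desirability
(all-objectives fraction), uniqueness (distinct canonical SMILES over
total), and Solow–Polasky diversity
$I(A) = \frac{1}{|A|}\, e^{\top} F^{-1} e$ with kernel
$F_{ij} = e^{-\theta d_{ij}}$ on Tanimoto distances. $\theta$ is not
fixed by the method; the package defaults to $\theta = 1$ and reports it
alongside every value, because diversities at different $\theta$ are not
comparable. A singleton set scores exactly 1; duplicates drive the value
toward $1/|A|$. Duplicate molecules make $F$ singular, so a ridge of
1e-8 is added and the linear system solved directly; on distinct sets
this perturbs results below 1e-6. Substructure profiles report the
percentage of valid molecules matching benzene, furan and purine SMARTS
patterns (the purine pattern is tautomer-tolerant so N-substituted
purines match).

Drug-likeness: QED is implemented from the published desirability
functions and property weights, with a documented subset of sixteen
structural-alert SMARTS rather than the full published list — absolute
values can differ slightly from other implementations, while ranges and
monotonicity are preserved. The synthetic-accessibility score keeps the
fragment-contribution-plus-complexity-penalty structure of the standard
heuristic but calibrates fragment frequencies on a reference corpus
supplied by the caller (the package's own synthetic corpus by default),
because the conventional PubChem-derived contribution table is not
redistributable here. SA values are therefore corpus-relative; the
[1, 10] scale and the penalties for spiro/bridgehead centres,
macrocycles and size are retained.

## Synthetic data

`fixture_corpus()` enumerates scaffold-substituent combinations from a
fixed template library (benzene, pyridine, furan, thiophene, pyrrole,
naphthalene, purine, saturated rings, biphenyls; 30 common substituents,
with ring-closure digits chosen so nested rings never collide). All
~1,300 enumerable molecules are valid by construction. `generate_fixtures()`
adds a three-target bioactivity table in which pX is an affine function
of a computable property (aromatic rings for T1, heteroatoms for T2,
rotatable bonds for T3) plus Gaussian noise (sd 0.3 pX units), with ~10%
"Not Active" rows and ~10% duplicated measurements, and writes toy-oracle
objective configurations for a multi-target case (maximize T1, T2;
minimize T3) and a target-specific case (maximize T1; minimize T2, T3).
The oracle scales were chosen once so that, under the default thresholds,
a minority of corpus molecules is desired (two or more aromatic rings,
four or more heteroatoms, five or fewer rotatable bonds) — enough signal
to fine-tune on, with clear headroom for RL to improve into.

What this emulates — and what it does not: the corpus has a narrow,
regular grammar, molecules are small, and the "bioactivity" is exactly
learnable from descriptors. Passing tests on these fixtures demonstrates
that the machinery (tokenization, likelihood training, reward shaping,
the exploration loop, the metrics) behaves as specified; it says nothing
about performance on real screening data, where activity landscapes are
not property-linear and validity is harder to learn.

## Problem sizes and numerical choices

The shipped tests and the reproduction script run everything at desk
scale, chosen as the smallest sizes at which each claim is
demonstrable: corpora of 60–500 molecules, generators of 1–2 recurrent
layers with 16–128 hidden units, likelihood training of tens of epochs,
RL batches of ~200 sequences with a 1000-molecule before/after probe.
The architecture defaults (128/512x3) remain those a full-scale run
would use. Other numerical choices: softmax log-probabilities are
floored at 1e-300 before logging; Adam uses the standard
(0.9, 0.999, 1e-8) moments; LSTM forget-gate biases start at +1;
non-dominated sorting is the vectorized O(n^2 m) dominance-matrix
construction followed by standard front peeling, cross-checked in the
tests against an independent brute-force oracle; all randomness flows
through R's RNG from explicit seeds, and a single master seed fans out
to per-stage seeds (`seed + k`) in the pipeline.

## Known limitations

* Validity is parser-based: valence screening catches hypervalent atoms,
  but aromatic perception quirks of the backend (e.g. anti-aromatic
  rings it kekulizes) pass where stricter toolkits refuse.
* SVM and PLS fits ignore the 0.1 sample weights (no weighted-regression
  support in the installed backends); the random forest and multi-task
  net honour them.
* SA scores are calibrated per reference corpus and are not comparable
  across calibrations or to PubChem-calibrated implementations.
* The pure-R recurrent nets are CPU-bound; ChEMBL-scale pretraining is
  out of reach, which is why all shipped experiments are fixture-scale.
* Stereochemistry is not modelled (no chiral tokens in the fixture
  grammar; the tokenizer passes `/`, `\` and bracket stereo markers
  through untested at scale).
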