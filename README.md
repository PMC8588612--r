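# molrl

De novo design of drug-like molecules by multi-objective reinforcement
learning over a SMILES language model, in R.

## The problem

In polypharmacology a candidate molecule must bind several targets at
once — say, two adenosine-receptor subtypes — while avoiding
anti-targets such as the hERG channel. `molrl` implements a complete
desk-scale workflow for this setting:

* a **SMILES recurrent language model** (embedding → stacked LSTM →
  softmax; pure R, finite-difference-verified backprop) pretrained on a
  corpus and fine-tuned on a focused set;
* a **QSAR environment**: 2048-bit ECFP6 + 19 physico-chemical
  descriptors (2067-D), bioactivity-table preparation (duplicate
  averaging, pX 3.99 / weight 0.1 imputation of inactives), random
  forest / SVM / PLS / multi-task net regressors, plus fast
  deterministic toy oracles;
* **reward shaping** over per-target objectives. Predicted potency pX ∈
  [3, 10] is min-max normalized, `R = (pX − 3)/7`, inverted for
  anti-targets; a molecule is *desired* when every objective exceeds its
  threshold (0.5 ⇔ pX 6.5). Scalarization is either a **dynamic
  weighted sum** (`w_i ∝ N_i^below / N_i^above`, harder objectives get
  more weight) or a **Pareto scheme**: non-dominated sorting on
  desirability-capped scores, fronts ordered worst-first, Tanimoto
  diversity replacing crowding distance within fronts, and rank-based
  rewards tiling (0, 0.5] for undesired and (0.5, 1] for desired
  molecules;
* a **policy-gradient loop** maximizing `J(θ) = Σ_t log G(y_t|y_<t)·R*`
  with an agent / crossover / mutation exploration strategy: per token
  position, with probability ε the frozen pretrained net supplies the
  sampling distribution, otherwise the blend of the agent and a
  periodically refreshed crossover copy;
* an **evaluation suite**: validity / desirability / uniqueness,
  Solow–Polasky diversity `I(A) = eᵀF⁻¹e / |A|` with
  `F_ij = exp(−θ·d_Tanimoto)`, substructure profiles (purine, furan,
  benzene), and SA / QED drug-likeness.

Everything runs offline: a synthetic scaffold-enumeration corpus and
property-linear bioactivity fixtures stand in for database extracts.
See `vignettes/molrl-methods.Rmd` for the model, assumptions and
limitations.

## Worked example

Score molecules against a multi-target objective set (maximize predicted
affinity at two pseudo-targets, minimize at an off-target), then reward
them under the Pareto scheme:

```r
library(molrl)

objectives <- list(
  objective_spec(toy_oracle("aromatic_rings", scale = 2.0, offset = 3),
                 "high_affinity", name = "A1"),
  objective_spec(toy_oracle("heteroatoms", scale = 0.9, offset = 3),
                 "high_affinity", name = "A2A"),
  objective_spec(toy_oracle("rotatable_bonds", scale = 0.6, offset = 3),
                 "low_affinity", name = "offtarget")
)

mols <- c("c1nc2c(n1CC(=O)N)cncn2",  # purine with a polar side chain
          "c1ccc(-c2ccccc2)cc1",     # biphenyl
          "CCCCCCCC",                # octane
          "C(")                      # invalid on purpose
sm <- score_batch(mols, objectives)
round(sm$scores, 3)
#>         A1   A2A offtarget
#> [1,] 0.571 0.771     0.829
#> [2,] 0.571 0.000     0.914
#> [3,] 0.000 0.000     0.571
#> [4,] 0.000 0.000     0.000
sm$desired
#> [1]  TRUE FALSE FALSE FALSE
```

Only the purine clears every threshold. The Pareto reward ranks the
batch (invalid strings at the bottom) and tiles the intervals:

```r
pareto_reward(sm)$reward
#> [1] 1.0000000 0.5000000 0.3333333 0.1666667
```

The desired molecule gets reward 1; the three undesired ones fill
(0, 0.5] evenly — exactly the spread the policy gradient needs. An
evaluation report over the synthetic corpus:

```r
eval_report(fixture_corpus(100, seed = 1), objectives)
#> Evaluation of 100 molecules
#>   validity:     100.00%
#>   desirability:   8.00%
#>   uniqueness:   100.00%
#>   diversity:    0.0249 (theta = 1)
#>   substructures: purine 8.00%, furan 11.00%, benzene 36.00%
#>   SA  mean 3.75  |  QED mean 0.599
```

8% of the corpus is desired before any training; the RL loop
(`train_rl()`, or `run_pipeline()` for the full
pretrain → fine-tune → RL → sample → evaluate chain) raises that
fraction substantially while keeping validity high — the acceptance test
in `tests/testthat/test-acceptance.R` demonstrates the improvement on a
1000-molecule sample. A thin CLI over the same functions is installed at
`inst/cli/molrl` (subcommands `fixtures`, `pretrain`, `finetune`,
`train-rl`, `sample`, `evaluate`, `run`).

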