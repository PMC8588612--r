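# Shared fixtures for the suite. Everything is generated in code; the
# heavier objects are built once per test run and memoized here.

.helper_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.helper_env[[key]])) .helper_env[[key]] <- force(expr)
  .helper_env[[key]]
}

# small, varied set of hand-picked valid molecules
REF_MOLS <- c(
  ethanol = "CCO", benzene = "c1ccccc1", toluene = "Cc1ccccc1",
  pyridine = "c1ccncc1", furan = "c1ccoc1",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  naphthalene = "c1ccc2ccccc2c1", piperidine = "C1CCNCC1",
  spirodecane = "C1CCC2(CC1)CCCC2", norbornane = "C1CC2CCC1C2"
)

tiny_corpus <- function() memo("tiny_corpus", fixture_corpus(60, seed = 11))

tiny_vocab <- function() memo("tiny_vocab", build_vocabulary(tiny_corpus()))

tiny_net <- function(seed = 2) {
  new_generator(tiny_vocab(), d_emb = 8L, d_hid = 16L, n_layers = 2L,
                seed = seed)
}

# a language model trained on the tiny corpus just enough that a minority
# of its samples are valid molecules (shared by the RL tests)
trained_tiny <- function() {
  memo("trained_tiny", {
    net <- new_generator(tiny_vocab(), d_emb = 16L, d_hid = 64L,
                         n_layers = 1L, seed = 4)
    train_lm(net, tiny_corpus(), epochs = 60L, batch_size = 16L,
             lr = 5e-3, seed = 5)$net
  })
}

# a generator whose every parameter is zero: uniform softmax at each step
uniform_net <- function(vocab = tiny_vocab()) {
  net <- new_generator(vocab, d_emb = 4L, d_hid = 6L, n_layers = 1L, seed = 1)
  flat <- molrl:::.flatten_params(net$params)
  net$params <- molrl:::.unflatten_into(net$params, lapply(flat, function(x) x * 0))
  net
}

# toy objectives mirroring the multi-target case: maximize two, minimize one
toy_objectives <- function() {
  list(
    objective_spec(toy_oracle("aromatic_rings", scale = 2.0, offset = 3),
                   "high_affinity", name = "T1"),
    objective_spec(toy_oracle("heteroatoms", scale = 0.9, offset = 3),
                   "high_affinity", name = "T2"),
    objective_spec(toy_oracle("rotatable_bonds", scale = 0.6, offset = 3),
                   "low_affinity", name = "T3")
  )
}

# independent brute-force oracle for non-dominated sorting: repeatedly
# peel the set of solutions not dominated by any remaining solution
# (best front), then reverse so the most dominated layer comes first
brute_force_fronts <- function(x) {
  dominates_pair <- function(a, b) all(a >= b) && any(a > b)
  remaining <- seq_len(nrow(x))
  fronts <- list()
  while (length(remaining)) {
    top <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && dominates_pair(x[j, ], x[i, ])
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- top
    remaining <- setdiff(remaining, top)
  }
  rev(fronts)
}

expect_same_partition <- function(got, want) {
  expect_equal(length(got), length(want))
  for (k in seq_along(got)) {
    expect_setequal(got[[k]], want[[k]])
  }
}
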