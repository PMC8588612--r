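test_that("per-step output is a probability distribution", {
  net <- tiny_net()
  B <- 4L
  state <- molrl:::.init_state(net, B)
  x <- net$params$E[sample(length(net$vocab$tokens), B, replace = TRUE), ]
  st <- molrl:::.rnn_step(net, state, x)
  expect_true(all(st$p >= 0))
  expect_equal(rowSums(st$p), rep(1, B), tolerance = 1e-6)
})

test_that("NLL matches the closed form for a uniform model and is non-negative", {
  net <- uniform_net()
  V <- length(net$vocab$tokens)
  # sequence of L chemical tokens has L + 1 targets (END included)
  expect_equal(nll_loss(net, "CCO"), 4 * log(V), tolerance = 1e-10)
  expect_equal(nll_loss(net, "CC"), 3 * log(V), tolerance = 1e-10)
  trained <- tiny_net()
  expect_gte(nll_loss(trained, "CCO"), 0)
  expect_error(nll_loss(trained, list(c(1L, 999L))), "out of vocabulary")
})

test_that("likelihood of a sequence is invariant to batch composition", {
  net <- tiny_net()
  solo <- sequence_loglik(net, "CCO")
  batch <- sequence_loglik(net, c("CCO", "c1ccccc1", "CCCC"))
  expect_equal(batch[1], solo, tolerance = 1e-12)
})

test_that("backward pass matches finite-difference gradients for both cells", {
  for (cell in c("lstm", "gru")) {
    net <- new_generator(tiny_vocab(), d_emb = 3L, d_hid = 4L, n_layers = 2L,
                         cell = cell, seed = 3)
    seqs <- molrl:::.as_index_sequences(net, c("CCO", "c1ccccc1"))
    enc <- molrl:::.encode_matrix(net, seqs)
    w <- c(0.7, 1.3)
    fwd <- molrl:::.lm_forward(net, enc, keep_cache = TRUE)
    grads <- molrl:::.lm_backward(net, enc, fwd, seq_w = w)
    lossfun <- function(p) {
      n2 <- net
      n2$params <- p
      -sum(w * molrl:::.lm_forward(n2, enc)$seq_logp) / 2
    }
    pf <- molrl:::.flatten_params(net$params)
    gf <- molrl:::.flatten_params(grads)
    set.seed(10)
    for (k in names(pf)) {
      idx <- sample(length(pf[[k]]), min(4, length(pf[[k]])))
      for (i in idx) {
        eps <- 1e-6
        up <- pf; up[[k]][i] <- up[[k]][i] + eps
        dn <- pf; dn[[k]][i] <- dn[[k]][i] - eps
        num <- (lossfun(molrl:::.unflatten_into(net$params, up)) -
                  lossfun(molrl:::.unflatten_into(net$params, dn))) / (2 * eps)
        expect_equal(gf[[k]][i], num, tolerance = 1e-4,
                     label = sprintf("%s grad %s[%d]", cell, k, i))
      }
    }
  }
})

test_that("likelihood training reduces the loss and logs validation each epoch", {
  net <- tiny_net()
  fit <- train_lm(net, tiny_corpus(), epochs = 5L, batch_size = 16L,
                  lr = 5e-3, seed = 4)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_equal(nrow(fit$history), 5L)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_gte(fit$best_epoch, 1L)
  expect_error(train_lm(net, character(0)), "empty corpus")
})

test_that("training is deterministic under a fixed seed", {
  f1 <- train_lm(tiny_net(), tiny_corpus(), epochs = 3L, batch_size = 16L,
                 seed = 7)
  f2 <- train_lm(tiny_net(), tiny_corpus(), epochs = 3L, batch_size = 16L,
                 seed = 7)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)
})

test_that("sampling terminates, flags truncation, and rescoring agrees", {
  net <- tiny_net()
  sb <- sample_smiles(net, 30L, max_len = 12L, seed = 5)
  expect_length(sb$smiles, 30L)
  expect_true(all(lengths(sb$tokens) <= 12L))
  expect_false(any(sb$valid & !sb$ended))   # truncated implies invalid
  resc <- sequence_loglik(net, sb$tokens, ended = sb$ended)
  expect_equal(resc[sb$ended], sb$loglik[sb$ended], tolerance = 1e-10)
})

test_that("a model with all mass on END emits empty sequences", {
  net <- uniform_net()
  # push the END output bias far up: softmax concentrates on END
  net$params$b_out[2] <- 50
  sb <- sample_smiles(net, 10L, max_len = 10L, seed = 6)
  expect_true(all(sb$smiles == ""))
  expect_true(all(sb$ended))
})

test_that("a model trained to memorize one SMILES reproduces it", {
  target <- "c1ccc(C)cc1"
  vocab <- build_vocabulary(target)
  net <- new_generator(vocab, d_emb = 8L, d_hid = 24L, n_layers = 1L, seed = 8)
  fit <- train_lm(net, rep(target, 20), epochs = 180L, batch_size = 20L,
                  lr = 1e-2, val_frac = 0, seed = 9)
  sb <- sample_smiles(fit$net, 10L, max_len = 20L, seed = 10)
  expect_true(all(sb$smiles == target))
})

test_that("checkpoints round-trip through disk", {
  net <- tiny_net()
  dir <- withr::local_tempdir()
  save_generator(net, dir)
  back <- load_generator(dir)
  expect_identical(back$params, net$params)
  expect_identical(back$vocab$tokens, net$vocab$tokens)
  expect_identical(back$cell, net$cell)
})
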