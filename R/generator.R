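# SMILES recurrent language model.
#
# Architecture: token embedding (default 128-d) -> stacked recurrent layers
# (default 3 x 512 LSTM cells; GRU available as an ablation switch) ->
# linear output head -> softmax over the vocabulary. Trained by teacher
# forcing with a negative log-likelihood loss (Adam), sampled
# autoregressively token by token. The same forward/backward machinery
# also serves the policy-gradient update in the RL loop, where each
# sequence's log-likelihood is weighted by its scalar reward.
#
# No deep-learning framework is available to R in this stack; the
# forward/backward passes are explicit and vectorized over the batch, and
# are verified against finite-difference gradients in the test suite.

#' Create a generator network
#'
#' Initializes a SMILES language model over a vocabulary. Weights are
#' drawn uniformly from \[-0.08, 0.08\] (LSTM forget-gate biases start at
#' +1).
#'
#' @param vocab a `smiles_vocab` (see [build_vocabulary()]).
#' @param d_emb embedding dimension (default 128).
#' @param d_hid hidden units per recurrent layer (default 512).
#' @param n_layers number of recurrent layers (default 3).
#' @param cell `"lstm"` (default) or `"gru"`.
#' @param seed RNG seed for weight initialization.
#' @return object of class `generator_net`.
#' @export
new_generator <- function(vocab, d_emb = 128L, d_hid = 512L, n_layers = 3L,
                          cell = c("lstm", "gru"), seed = 1L) {
  stopifnot(inherits(vocab, "smiles_vocab"), d_emb >= 1, d_hid >= 1,
            n_layers >= 1)
  cell <- match.arg(cell)
  V <- length(vocab$tokens)
  set.seed(seed)
  ru <- function(n, r, c) matrix(stats::runif(n, -0.08, 0.08), r, c)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1L) d_emb else d_hid
    if (cell == "lstm") {
      b <- numeric(4L * d_hid)
      b[(d_hid + 1L):(2L * d_hid)] <- 1  # forget gate bias
      layers[[l]] <- list(W = ru((d_in + d_hid) * 4L * d_hid,
                                 d_in + d_hid, 4L * d_hid), b = b)
    } else {
      layers[[l]] <- list(
        Wg = ru((d_in + d_hid) * 2L * d_hid, d_in + d_hid, 2L * d_hid),
        bg = numeric(2L * d_hid),
        Wn = ru((d_in + d_hid) * d_hid, d_in + d_hid, d_hid),
        bn = numeric(d_hid))
    }
  }
  params <- list(
    E = ru(V * d_emb, V, d_emb),
    layers = layers,
    W_out = ru(d_hid * V, d_hid, V),
    b_out = numeric(V)
  )
  structure(
    list(vocab = vocab, d_emb = as.integer(d_emb), d_hid = as.integer(d_hid),
         n_layers = as.integer(n_layers), cell = cell, params = params),
    class = "generator_net"
  )
}

#' @export
print.generator_net <- function(x, ...) {
  np <- sum(unlist(lapply(.flatten_params(x$params), length)))
  cat(sprintf(
    "generator_net: %s, vocab %d, embedding %d, %d x %d hidden, %s parameters\n",
    toupper(x$cell), length(x$vocab$tokens), x$d_emb, x$n_layers, x$d_hid,
    format(np, big.mark = ",")))
  invisible(x)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter-tree utilities (Adam works on the flattened tree) -------

.flatten_params <- function(p) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in seq_along(x)) {
        key <- if (!is.null(names(x)) && nzchar(names(x)[nm])) names(x)[nm] else nm
        walk(x[[nm]], c(prefix, key))
      }
    } else {
      out[[paste(prefix, collapse = ".")]] <<- x
    }
  }
  walk(p, character(0))
  out
}

.unflatten_into <- function(p, flat) {
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in seq_along(x)) {
        key <- if (!is.null(names(x)) && nzchar(names(x)[nm])) names(x)[nm] else nm
        x[[nm]] <- walk(x[[nm]], c(prefix, key))
      }
      x
    } else {
      flat[[paste(prefix, collapse = ".")]]
    }
  }
  walk(p, character(0))
}

.adam_new <- function(params) {
  flat <- .flatten_params(params)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

.adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  pf <- .flatten_params(params)
  gf <- .flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(pf)) {
    g <- gf[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    pf[[k]] <- pf[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = .unflatten_into(params, pf), state = state)
}

.zero_like <- function(params) {
  .unflatten_into(params, lapply(.flatten_params(params), function(x) x * 0))
}

# ---- recurrent cells ----------------------------------------------------

# One step of the full stack. state: list per layer (h, and c for lstm).
# Returns probabilities (B x V), new state, and (optionally) the caches
# needed for backprop.
.rnn_step <- function(net, state, x, keep_cache = FALSE) {
  H <- net$d_hid
  caches <- if (keep_cache) vector("list", net$n_layers) else NULL
  inp <- x
  for (l in seq_len(net$n_layers)) {
    pl <- net$params$layers[[l]]
    h_prev <- state[[l]]$h
    if (net$cell == "lstm") {
      c_prev <- state[[l]]$c
      z <- cbind(inp, h_prev)
      a <- sweep(z %*% pl$W, 2, pl$b, "+")
      i_ <- .sigmoid(a[, 1:H, drop = FALSE])
      f_ <- .sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
      g_ <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
      o_ <- .sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
      c_ <- f_ * c_prev + i_ * g_
      h_ <- o_ * tanh(c_)
      if (keep_cache) {
        caches[[l]] <- list(z = z, i = i_, f = f_, g = g_, o = o_,
                            c_prev = c_prev, c = c_)
      }
      state[[l]] <- list(h = h_, c = c_)
    } else {
      z <- cbind(inp, h_prev)
      ag <- sweep(z %*% pl$Wg, 2, pl$bg, "+")
      u_ <- .sigmoid(ag[, 1:H, drop = FALSE])
      r_ <- .sigmoid(ag[, (H + 1):(2 * H), drop = FALSE])
      zn <- cbind(inp, r_ * h_prev)
      nq <- tanh(sweep(zn %*% pl$Wn, 2, pl$bn, "+"))
      h_ <- (1 - u_) * nq + u_ * h_prev
      if (keep_cache) {
        caches[[l]] <- list(z = z, zn = zn, u = u_, r = r_, nq = nq,
                            h_prev = h_prev)
      }
      state[[l]] <- list(h = h_)
    }
    inp <- h_
  }
  logits <- sweep(inp %*% net$params$W_out, 2, net$params$b_out, "+")
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  p <- e / rowSums(e)
  list(p = p, state = state, caches = caches, h_top = inp)
}

.init_state <- function(net, B) {
  lapply(seq_len(net$n_layers), function(l) {
    if (net$cell == "lstm") {
      list(h = matrix(0, B, net$d_hid), c = matrix(0, B, net$d_hid))
    } else {
      list(h = matrix(0, B, net$d_hid))
    }
  })
}

# ---- batched teacher-forced forward/backward ---------------------------

# Encode token-index sequences (without GO/END) into padded input/target
# matrices. X[t, b] = input token at step t (GO first); Y[t, b] = target
# token (sequence then END when `ended[b]`); M[t, b] = loss mask.
.encode_matrix <- function(net, seqs, ended = NULL) {
  B <- length(seqs)
  if (is.null(ended)) ended <- rep(TRUE, B)
  lens <- vapply(seqs, length, integer(1)) + as.integer(ended)
  Tm <- max(lens)
  GO <- 1L; END <- 2L
  X <- matrix(END, Tm, B)   # padding input is inert
  Y <- matrix(END, Tm, B)
  M <- matrix(0, Tm, B)
  for (b in seq_len(B)) {
    s <- seqs[[b]]
    full_y <- if (ended[b]) c(s, END) else s
    full_x <- c(GO, utils::head(full_y, -1L))
    X[seq_along(full_x), b] <- full_x
    Y[seq_along(full_y), b] <- full_y
    M[seq_len(lens[b]), b] <- 1
  }
  list(X = X, Y = Y, M = M, lens = lens)
}

# Forward pass; when seq_w given, per-sequence weighted NLL (used both for
# likelihood training, seq_w = 1, and policy gradient, seq_w = R*). Loss is
# mean over sequences of seq_w * sum_t -log p(y_t).
.lm_forward <- function(net, enc, keep_cache = FALSE) {
  X <- enc$X; Y <- enc$Y; M <- enc$M
  Tm <- nrow(X); B <- ncol(X)
  state <- .init_state(net, B)
  steps <- if (keep_cache) vector("list", Tm) else NULL
  logp <- matrix(0, Tm, B)
  for (t in seq_len(Tm)) {
    x <- net$params$E[X[t, ], , drop = FALSE]
    st <- .rnn_step(net, state, x, keep_cache = keep_cache)
    state <- st$state
    pick <- cbind(seq_len(B), Y[t, ])
    logp[t, ] <- log(pmax(st$p[pick], 1e-300))
    if (keep_cache) {
      steps[[t]] <- list(p = st$p, caches = st$caches, h_top = st$h_top)
    }
  }
  seq_logp <- colSums(logp * M)
  list(seq_logp = seq_logp, steps = steps)
}

# Backward pass for loss = -(1/B) * sum_b seq_w[b] * seq_logp[b].
.lm_backward <- function(net, enc, fwd, seq_w) {
  X <- enc$X; Y <- enc$Y; M <- enc$M
  Tm <- nrow(X); B <- ncol(X); H <- net$d_hid; V <- nrow(net$params$E)
  grads <- .zero_like(net$params)
  wb <- seq_w / B
  # recurrent carry: gradients wrt h (and c) flowing into each layer
  carry <- lapply(seq_len(net$n_layers), function(l) {
    list(dh = matrix(0, B, H), dc = matrix(0, B, H))
  })
  for (t in rev(seq_len(Tm))) {
    st <- fwd$steps[[t]]
    w_tb <- wb * M[t, ]
    dlogits <- st$p * w_tb
    pick <- cbind(seq_len(B), Y[t, ])
    dlogits[pick] <- dlogits[pick] - w_tb
    grads$W_out <- grads$W_out + crossprod(st$h_top, dlogits)
    grads$b_out <- grads$b_out + colSums(dlogits)
    d_inp <- dlogits %*% t(net$params$W_out)   # gradient wrt top h
    for (l in rev(seq_len(net$n_layers))) {
      ch <- st$caches[[l]]
      pl <- net$params$layers[[l]]
      d_in_width <- if (l == 1L) net$d_emb else H
      if (net$cell == "lstm") {
        dh <- d_inp + carry[[l]]$dh
        tc <- tanh(ch$c)
        dc <- carry[[l]]$dc + dh * ch$o * (1 - tc^2)
        dao <- (dh * tc) * ch$o * (1 - ch$o)
        dai <- (dc * ch$g) * ch$i * (1 - ch$i)
        daf <- (dc * ch$c_prev) * ch$f * (1 - ch$f)
        dag <- (dc * ch$i) * (1 - ch$g^2)
        da <- cbind(dai, daf, dag, dao)
        grads$layers[[l]]$W <- grads$layers[[l]]$W + crossprod(ch$z, da)
        grads$layers[[l]]$b <- grads$layers[[l]]$b + colSums(da)
        dz <- da %*% t(pl$W)
        carry[[l]] <- list(dh = dz[, (d_in_width + 1):(d_in_width + H),
                                   drop = FALSE],
                           dc = dc * ch$f)
      } else {
        dh <- d_inp + carry[[l]]$dh
        dnq <- dh * (1 - ch$u)
        dan <- dnq * (1 - ch$nq^2)
        du <- dh * (ch$h_prev - ch$nq)
        dau <- du * ch$u * (1 - ch$u)
        dh_prev <- dh * ch$u
        dzn <- dan %*% t(pl$Wn)
        drh <- dzn[, (d_in_width + 1):(d_in_width + H), drop = FALSE]
        dr <- drh * ch$h_prev
        dh_prev <- dh_prev + drh * ch$r
        dar <- dr * ch$r * (1 - ch$r)
        dag_ <- cbind(dau, dar)
        grads$layers[[l]]$Wg <- grads$layers[[l]]$Wg + crossprod(ch$z, dag_)
        grads$layers[[l]]$bg <- grads$layers[[l]]$bg + colSums(dag_)
        grads$layers[[l]]$Wn <- grads$layers[[l]]$Wn + crossprod(ch$zn, dan)
        grads$layers[[l]]$bn <- grads$layers[[l]]$bn + colSums(dan)
        dzg <- dag_ %*% t(pl$Wg)
        dh_prev <- dh_prev + dzg[, (d_in_width + 1):(d_in_width + H),
                                 drop = FALSE]
        dz <- dzg
        carry[[l]] <- list(dh = dh_prev, dc = NULL)
      }
      d_x_part <- dz[, 1:d_in_width, drop = FALSE]
      if (net$cell == "gru") {
        d_x_part <- d_x_part + dzn[, 1:d_in_width, drop = FALSE]
      }
      d_inp <- d_x_part
    }
    rs <- rowsum(d_inp, X[t, ])
    idx <- as.integer(rownames(rs))
    grads$E[idx, ] <- grads$E[idx, , drop = FALSE] + rs
  }
  grads
}

#' Negative log-likelihood of encoded sequences
#'
#' Mean over sequences of the summed per-token negative log-probability
#' under the model, with GO as the first input and END as the final
#' target.
#'
#' @param net a `generator_net`.
#' @param sequences list of integer token-index vectors (without GO/END),
#'   or a character vector of SMILES to tokenize.
#' @return scalar mean NLL (non-negative).
#' @export
nll_loss <- function(net, sequences) {
  enc <- .as_index_sequences(net, sequences)
  fwd <- .lm_forward(net, .encode_matrix(net, enc))
  mean(-fwd$seq_logp)
}

.as_index_sequences <- function(net, sequences) {
  if (is.character(sequences)) {
    lapply(sequences, function(s) {
      vocab_encode(net$vocab, tokenize_smiles(s, vocab = net$vocab))
    })
  } else if (is.list(sequences)) {
    lapply(sequences, function(s) {
      s <- as.integer(s)
      if (any(s < 1L | s > length(net$vocab$tokens))) {
        stop("token index out of vocabulary")
      }
      s
    })
  } else stop("sequences must be a list of index vectors or SMILES strings")
}

#' Log-likelihood of token sequences
#'
#' Per-sequence log-probability (sum over steps, END included when the
#' sequence terminated) under the model; matches the log-likelihood
#' accumulated during sampling for the same sequences.
#'
#' @inheritParams nll_loss
#' @param ended logical vector: whether each sequence emitted END (default
#'   all TRUE).
#' @return numeric vector of per-sequence log-likelihoods.
#' @export
sequence_loglik <- function(net, sequences, ended = NULL) {
  enc <- .as_index_sequences(net, sequences)
  fwd <- .lm_forward(net, .encode_matrix(net, enc, ended = ended))
  fwd$seq_logp
}

#' Train the language model
#'
#' Teacher-forced NLL training with Adam. A held-out validation split is
#' scored every epoch and the best-validation parameters are retained
#' (used for fine-tuning, where the validation set takes no part in the
#' parameter updates).
#'
#' @param net a `generator_net`.
#' @param corpus character vector of SMILES (tokenizable under the net's
#'   vocabulary; failures are dropped with a warning).
#' @param epochs training epochs.
#' @param batch_size sequences per gradient step (default 512).
#' @param lr Adam learning rate (default 1e-3).
#' @param val_frac fraction held out for validation (default 0.1; 0
#'   disables and the final parameters are kept).
#' @param seed RNG seed (shuffling and the validation split).
#' @param verbose print per-epoch losses.
#' @return list with `net` (best checkpoint), `history` (data.frame of
#'   epoch, train_loss, val_loss), `best_epoch`.
#' @export
train_lm <- function(net, corpus, epochs = 10L, batch_size = 512L, lr = 1e-3,
                     val_frac = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "generator_net"))
  if (!is.character(corpus) || length(corpus) == 0L) stop("empty corpus")
  seqs <- list()
  dropped <- 0L
  for (s in corpus) {
    e <- tryCatch(vocab_encode(net$vocab, tokenize_smiles(s, vocab = net$vocab)),
                  error = function(e) NULL)
    if (is.null(e)) dropped <- dropped + 1L else seqs[[length(seqs) + 1L]] <- e
  }
  if (dropped > 0L) warning(sprintf("train_lm: dropped %d untokenizable SMILES", dropped))
  if (length(seqs) < 2L) stop("not enough tokenizable sequences")

  set.seed(seed)
  n <- length(seqs)
  n_val <- floor(val_frac * n)
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  val_enc <- if (n_val > 0) .encode_matrix(net, seqs[val_idx]) else NULL

  adam <- .adam_new(net$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = net$params, epoch = 0L)
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0
    n_seen <- 0L
    for (start in seq(1, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(ord))]
      enc <- .encode_matrix(net, seqs[idx])
      fwd <- .lm_forward(net, enc, keep_cache = TRUE)
      grads <- .lm_backward(net, enc, fwd, seq_w = rep(1, length(idx)))
      upd <- .adam_update(net$params, grads, adam, lr)
      net$params <- upd$params
      adam <- upd$state
      ep_loss <- ep_loss + sum(-fwd$seq_logp)
      n_seen <- n_seen + length(idx)
    }
    train_loss <- ep_loss / n_seen
    val_loss <- if (!is.null(val_enc)) {
      mean(-.lm_forward(net, val_enc)$seq_logp)
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    track <- if (is.na(val_loss)) train_loss else val_loss
    if (track < best$loss) best <- list(loss = track, params = net$params,
                                        epoch = ep)
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", ep, train_loss, val_loss))
    }
  }
  if (val_frac > 0) net$params <- best$params
  list(net = net, history = history, best_epoch = best$epoch)
}

#' Sample SMILES from the model
#'
#' Autoregressive multinomial sampling: starting from GO, each step's
#' token is drawn from the model's softmax until END is emitted or
#' `max_len` tokens have been generated (sequences hitting the cap are
#' flagged invalid). Per-sequence log-likelihoods accumulate the log
#' probability of every drawn token, END included.
#'
#' @param net a `generator_net`.
#' @param n number of sequences.
#' @param max_len maximum chemical tokens per sequence (default 100).
#' @param seed optional RNG seed.
#' @return object of class `sample_batch`: list with `smiles`, `tokens`
#'   (index vectors), `loglik`, `ended`, `valid`, `canonical`.
#' @export
sample_smiles <- function(net, n, max_len = 100L, seed = NULL) {
  stopifnot(inherits(net, "generator_net"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  res <- .sample_engine(list(net), n = n, max_len = max_len)
  .finish_sample_batch(net, res)
}

# Core sampling loop. `nets` is a list of 1 or 3 generator nets sharing a
# vocabulary; with 3 nets (agent, crossover, mutation) the per-step token
# distribution is the epsilon-mixture used by the exploration strategy.
# Returns token index sequences (no GO/END), ended flags, and the log
# probability of each drawn token under the *sampling* distribution.
.sample_engine <- function(nets, n, max_len, epsilon = 0,
                           combine = "arithmetic") {
  net <- nets[[1]]
  V <- length(net$vocab$tokens)
  GO <- 1L; END <- 2L
  B <- n
  states <- lapply(nets, .init_state, B = B)
  cur <- rep(GO, B)
  alive <- rep(TRUE, B)
  seqs <- vector("list", B)
  for (b in seq_len(B)) seqs[[b]] <- integer(0)
  loglik <- numeric(B)
  ended <- rep(FALSE, B)
  for (t in seq_len(max_len + 1L)) {  # +1 allows END after max_len tokens
    ps <- vector("list", length(nets))
    for (k in seq_along(nets)) {
      x <- nets[[k]]$params$E[cur, , drop = FALSE]
      st <- .rnn_step(nets[[k]], states[[k]], x)
      states[[k]] <- st$state
      ps[[k]] <- st$p
    }
    if (length(nets) == 1L) {
      p <- ps[[1]]
    } else {
      # mixture: mean of agent and crossover distributions, unless the
      # per-sequence epsilon draw routes this step to the mutation net
      p_ac <- if (combine == "geometric") {
        sqrt(ps[[1]] * ps[[2]])
      } else {
        (ps[[1]] + ps[[2]]) / 2
      }
      p_ac <- p_ac / rowSums(p_ac)
      # with epsilon = 0 no mutation draw is made at all, so sampling
      # reduces exactly to the blended (or plain) policy stream
      use_m <- if (epsilon > 0) stats::runif(B) <= epsilon else rep(FALSE, B)
      p <- p_ac
      if (any(use_m)) p[use_m, ] <- ps[[3]][use_m, , drop = FALSE]
    }
    # multinomial draw per row (inverse CDF)
    u <- stats::runif(B)
    cs <- p %*% upper.tri(matrix(0, V, V), diag = TRUE)
    nxt <- max.col(cs >= u, ties.method = "first")
    nxt[!alive] <- END
    pick <- cbind(seq_len(B), nxt)
    step_lp <- log(pmax(p[pick], 1e-300))
    for (b in which(alive)) {
      if (nxt[b] == END) {
        ended[b] <- TRUE
        alive[b] <- FALSE
        loglik[b] <- loglik[b] + step_lp[b]
      } else if (length(seqs[[b]]) < max_len) {
        seqs[[b]] <- c(seqs[[b]], nxt[b])
        loglik[b] <- loglik[b] + step_lp[b]
      } else {
        alive[b] <- FALSE   # hit the length cap without END: truncated
      }
    }
    cur <- nxt
    if (!any(alive)) break
  }
  list(seqs = seqs, ended = ended, loglik = loglik)
}

.finish_sample_batch <- function(net, res) {
  smiles <- vapply(res$seqs, function(s) {
    detokenize(vocab_decode(net$vocab, s))
  }, character(1))
  v <- is_valid_smiles(smiles)
  valid <- v$valid & res$ended          # truncated sequences count invalid
  structure(
    list(smiles = smiles, tokens = res$seqs, loglik = res$loglik,
         ended = res$ended, valid = valid, canonical = v$canonical),
    class = "sample_batch"
  )
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("sample_batch: %d sequences, %.1f%% valid, %d unique canonical\n",
              length(x$smiles), 100 * mean(x$valid),
              length(unique(stats::na.omit(x$canonical)))))
  invisible(x)
}

#' Save / load a generator checkpoint
#'
#' A checkpoint is a directory holding the vocabulary (plain text), a JSON
#' manifest of the architecture, and the parameters, so fine-tuning and RL
#' can always resume from an earlier stage.
#'
#' @param net a `generator_net`.
#' @param dir checkpoint directory (created if needed).
#' @export
save_generator <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vocabulary(net$vocab, file.path(dir, "vocabulary.txt"))
  jsonlite::write_json(
    list(d_emb = net$d_emb, d_hid = net$d_hid, n_layers = net$n_layers,
         cell = net$cell),
    file.path(dir, "config.json"), auto_unbox = TRUE)
  saveRDS(net$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_generator
#' @export
load_generator <- function(dir) {
  vocab <- read_vocabulary(file.path(dir, "vocabulary.txt"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  net <- new_generator(vocab, d_emb = cfg$d_emb, d_hid = cfg$d_hid,
                       n_layers = cfg$n_layers, cell = cfg$cell)
  net$params <- readRDS(file.path(dir, "params.rds"))
  net
}
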