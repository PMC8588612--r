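# Policy-gradient reinforcement learning with the agent / crossover /
# mutation exploration strategy.
#
# Three networks share one vocabulary: the agent G_A (the policy being
# trained), the crossover net G_C (a periodically refreshed copy of the
# agent, blended with it during sampling), and the mutation net G_M (the
# frozen pretrained model, consulted with probability epsilon per token
# position to inject off-policy tokens). Each epoch a batch is sampled
# from the mixed policy, scored against the objectives, reduced to scalar
# rewards by the PF or WS scheme, and the agent is updated by gradient
# ascent on J(theta) = E[R*] = sum_t log G_A(y_t | y_<t) * R*.
#
# An iteration ends when the agent's desired fraction has not improved for
# `patience` consecutive epochs; the crossover net is then refreshed from
# the agent. Training stops when an iteration's best desired fraction does
# not exceed the previous iteration's.

#' Exploration/trainer configuration
#'
#' @param epsilon mutation rate in \[0, 1\]: per-position probability that
#'   token sampling is routed to the frozen mutation net.
#' @param batch_size sequences sampled per epoch.
#' @param lr Adam learning rate for the policy gradient.
#' @param patience epochs without desirability improvement that end an
#'   iteration (default 3).
#' @param max_iterations hard cap on iterations (default 20).
#' @param max_len token cap per sampled sequence.
#' @param eval_n sample size for the per-epoch desirability measurement on
#'   the agent alone (plateau detection; default 200).
#' @param seed RNG seed for the whole run.
#' @param combine how G_A and G_C step distributions are blended:
#'   `"arithmetic"` mean (default) or `"geometric"` mean, renormalized.
#' @return list of class `explorer_config`.
#' @export
explorer_config <- function(epsilon = 0.01, batch_size = 256L, lr = 1e-3,
                            patience = 3L, max_iterations = 20L,
                            max_len = 100L, eval_n = 200L, seed = 1L,
                            combine = c("arithmetic", "geometric")) {
  stopifnot(epsilon >= 0, epsilon <= 1, batch_size >= 1, patience >= 1,
            max_iterations >= 1)
  structure(list(epsilon = epsilon, batch_size = as.integer(batch_size),
                 lr = lr, patience = as.integer(patience),
                 max_iterations = as.integer(max_iterations),
                 max_len = as.integer(max_len), eval_n = as.integer(eval_n),
                 seed = as.integer(seed), combine = match.arg(combine)),
            class = "explorer_config")
}

#' Sample from the epsilon-mixed three-network policy
#'
#' At every token position of every sequence a uniform draw decides the
#' step distribution: with probability `1 - epsilon` the blend of the
#' agent's and crossover net's distributions, otherwise the mutation
#' net's. With `epsilon = 0` the mutation net is never consulted, and when
#' the agent and crossover nets share parameters the blend reduces to
#' plain agent sampling.
#'
#' @param agent,crossover,mutation `generator_net`s over one vocabulary.
#' @param n number of sequences.
#' @param epsilon mutation rate.
#' @param max_len token cap.
#' @param combine `"arithmetic"` or `"geometric"` blend of agent and
#'   crossover distributions.
#' @return a `sample_batch` (log-likelihoods are under the sampling
#'   mixture, not the agent).
#' @export
sample_mixed <- function(agent, crossover, mutation, n, epsilon = 0.01,
                         max_len = 100L, combine = "arithmetic") {
  nets <- list(agent, crossover, mutation)
  vt <- lapply(nets, function(x) x$vocab$tokens)
  if (!all(vapply(vt, identical, logical(1), vt[[1]]))) {
    stop("agent, crossover and mutation nets must share one vocabulary")
  }
  res <- .sample_engine(nets, n = n, max_len = max_len, epsilon = epsilon,
                        combine = combine)
  .finish_sample_batch(agent, res)
}

#' Policy-gradient update of the agent
#'
#' One Adam ascent step on `J(theta) = sum_b R*_b * sum_t log
#' G_A(y_t | y_<t)` for the given sequences. Sequences with zero reward
#' contribute nothing.
#'
#' @param agent a `generator_net`.
#' @param sequences list of token-index sequences (as in
#'   `sample_batch$tokens`), or a `sample_batch`.
#' @param rewards numeric vector in \[0, 1\], one scalar per sequence.
#' @param lr Adam learning rate.
#' @param ended logical: whether each sequence terminated with END
#'   (taken from the `sample_batch` when one is given).
#' @param adam_state optional persistent Adam state (returned element
#'   `adam_state` can be fed back in).
#' @return list with `agent` (updated net), `objective` (the value of J),
#'   `adam_state`.
#' @export
policy_gradient_update <- function(agent, sequences, rewards, lr = 1e-3,
                                   ended = NULL, adam_state = NULL) {
  if (inherits(sequences, "sample_batch")) {
    ended <- sequences$ended
    sequences <- sequences$tokens
  }
  if (length(sequences) != length(rewards)) {
    stop("one reward per sequence required")
  }
  keep <- lengths(sequences) > 0L | (ended %||% rep(TRUE, length(sequences)))
  seqs <- .as_index_sequences(agent, sequences[keep])
  rew <- rewards[keep]
  enc <- .encode_matrix(agent, seqs, ended = (ended %||% rep(TRUE, length(sequences)))[keep])
  fwd <- .lm_forward(agent, enc, keep_cache = TRUE)
  objective <- sum(rew * fwd$seq_logp)
  if (any(rew != 0)) {
    grads <- .lm_backward(agent, enc, fwd, seq_w = rew)
    if (is.null(adam_state)) adam_state <- .adam_new(agent$params)
    upd <- .adam_update(agent$params, grads, adam_state, lr)
    agent$params <- upd$params
    adam_state <- upd$state
  }
  list(agent = agent, objective = objective, adam_state = adam_state)
}

#' Reinforcement-learning training loop
#'
#' Runs the full exploration strategy. The mutation net should be the
#' pretrained model and both the agent and crossover nets start from the
#' fine-tuned model; the mutation net's parameters are never touched, and
#' the crossover net is only ever overwritten with the agent's parameters
#' at iteration boundaries.
#'
#' @param agent,crossover,mutation initial `generator_net`s (crossover
#'   defaults to a copy of the agent; mutation defaults to the agent —
#'   supply the pretrained net for real runs).
#' @param objectives list of [objective_spec()]s.
#' @param scheme `"PF"` or `"WS"` reward scheme.
#' @param config an [explorer_config()].
#' @param verbose print per-epoch progress.
#' @return list of class `rl_fit`: `agent` (trained net), `crossover`,
#'   `history` (per-epoch data.frame: iteration, epoch, validity,
#'   desirability, uniqueness, mean_reward, objective), and
#'   `iteration_best` (best desired fraction per iteration).
#' @export
train_rl <- function(agent, objectives, scheme = c("PF", "WS"),
                     config = explorer_config(), crossover = NULL,
                     mutation = NULL, verbose = FALSE) {
  scheme <- match.arg(toupper(scheme[1]), c("PF", "WS"))
  stopifnot(inherits(agent, "generator_net"), inherits(config, "explorer_config"))
  if (is.null(crossover)) crossover <- agent
  if (is.null(mutation)) mutation <- agent
  set.seed(config$seed)

  history <- data.frame()
  iteration_best <- numeric(0)
  boundary_log <- data.frame()
  adam_state <- NULL
  prev_best <- -Inf
  epoch_total <- 0L
  empty_streak <- 0L

  for (iter in seq_len(config$max_iterations)) {
    iter_best <- -Inf
    stale <- 0L
    repeat {
      epoch_total <- epoch_total + 1L
      batch <- sample_mixed(agent, crossover, mutation,
                            n = config$batch_size, epsilon = config$epsilon,
                            max_len = config$max_len,
                            combine = config$combine)
      if (!any(batch$valid)) {
        empty_streak <- empty_streak + 1L
        if (empty_streak >= 5L) {
          stop("no valid molecules sampled for 5 consecutive epochs; ",
               "the policy has collapsed - check pretraining and epsilon")
        }
      } else {
        empty_streak <- 0L
      }
      sm <- score_batch(batch$smiles, objectives)
      rew <- scheme_reward(sm, scheme)
      upd <- policy_gradient_update(agent, batch, rew, lr = config$lr,
                                    adam_state = adam_state)
      agent <- upd$agent
      adam_state <- upd$adam_state

      # plateau detection on the agent alone
      eval_batch <- sample_smiles(agent, config$eval_n,
                                  max_len = config$max_len)
      eval_sm <- score_batch(eval_batch$smiles, objectives)
      des_frac <- mean(eval_sm$desired)
      history <- rbind(history, data.frame(
        iteration = iter, epoch = epoch_total,
        validity = mean(batch$valid),
        desirability = mean(sm$desired),
        uniqueness = length(unique(stats::na.omit(batch$canonical))) /
          length(batch$smiles),
        agent_desirability = des_frac,
        mean_reward = mean(rew),
        objective = upd$objective))
      if (verbose) {
        message(sprintf(
          "iter %d epoch %d: valid %.2f desired %.2f agent-desired %.2f J %.2f",
          iter, epoch_total, mean(batch$valid), mean(sm$desired), des_frac,
          upd$objective))
      }
      if (des_frac > iter_best) {
        iter_best <- des_frac
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (stale >= config$patience) break
    }
    iteration_best <- c(iteration_best, iter_best)
    stop_now <- iter_best <= prev_best    # stop criterion
    prev_best <- max(prev_best, iter_best)
    ch_before <- param_hash(crossover)
    if (!stop_now) {
      crossover$params <- agent$params    # iteration boundary: G_C <- G_A
    }
    boundary_log <- rbind(boundary_log, data.frame(
      iteration = iter, agent_hash = param_hash(agent),
      crossover_hash_before = ch_before,
      crossover_hash_after = param_hash(crossover),
      mutation_hash = param_hash(mutation)))
    if (stop_now) break
  }
  structure(list(agent = agent, crossover = crossover, history = history,
                 iteration_best = iteration_best,
                 boundary_log = boundary_log, scheme = scheme,
                 config = config),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf(
    "rl_fit (%s scheme): %d iterations, %d epochs; best desired fraction %.3f\n",
    x$scheme, length(x$iteration_best), nrow(x$history),
    max(x$iteration_best)))
  invisible(x)
}

# parameter hash used by the invariant tests and run logs
param_hash <- function(net) {
  flat <- .flatten_params(net$params)
  sum(vapply(seq_along(flat), function(i) {
    s <- flat[[i]]
    sum(s * seq_along(s)) * i
  }, numeric(1)))
}
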