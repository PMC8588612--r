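# End-to-end orchestration: fixtures -> pretrain -> fine-tune -> RL ->
# sample -> evaluate, with artifacts persisted per stage so a rerun picks
# up where it stopped.

#' Assemble a run configuration
#'
#' All knobs of the end-to-end pipeline with their defaults. The single
#' `seed` fans out deterministically to per-stage seeds (`seed + k` for
#' stage k in fixtures, pretraining, fine-tuning, RL, sampling), so a run
#' is replayable from its persisted configuration alone.
#'
#' @param out_dir output/artifact directory.
#' @param corpus optional path to a pretraining corpus (one SMILES per
#'   line); when `NULL`, fixtures are generated into `out_dir`.
#' @param objectives path to an objectives JSON (see [load_objectives()]);
#'   `NULL` uses the generated fixture objectives.
#' @param case objective use case (`"multi_target"` or
#'   `"target_specific"`).
#' @param scheme reward scheme, `"PF"` or `"WS"`.
#' @param epsilon mutation rate for the exploration strategy.
#' @param seed master seed.
#' @param n_molecules fixture corpus size.
#' @param d_emb,d_hid,n_layers,cell generator architecture.
#' @param pretrain_epochs,finetune_epochs likelihood-training epochs.
#' @param batch_size batch size for likelihood training and RL sampling.
#' @param lr learning rate (all stages).
#' @param max_len token cap per sequence.
#' @param rl_patience,rl_max_iterations,rl_eval_n RL loop controls (see
#'   [explorer_config()]).
#' @param sample_n molecules sampled for the final evaluation.
#' @param theta diversity kernel decay for the report.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("molrl_run_"),
                       corpus = NULL, objectives = NULL,
                       case = "multi_target", scheme = "PF", epsilon = 0.01,
                       seed = 1L, n_molecules = 200L,
                       d_emb = 128L, d_hid = 512L, n_layers = 3L,
                       cell = "lstm",
                       pretrain_epochs = 50L, finetune_epochs = 20L,
                       batch_size = 128L, lr = 1e-3, max_len = 100L,
                       rl_patience = 3L, rl_max_iterations = 20L,
                       rl_eval_n = 200L, sample_n = 1000L, theta = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s] started", name))
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[%s] done (%.1fs)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  res
}

#' Run the full pipeline
#'
#' Orchestrates fixture generation (when no corpus is supplied),
#' likelihood pretraining, fine-tuning on the molecules of the activity
#' table, reinforcement learning with the epsilon-mixed exploration
#' strategy, sampling, and evaluation. Every stage persists its artifacts
#' under `config$out_dir` (`pretrained/`, `finetuned/`, `agent/`,
#' `samples.smi`, `report.json`); a rerun over an existing directory skips
#' stages whose artifacts are already present.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return list with the final evaluation report (`report`), the RL
#'   history, and the artifact paths.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    lapply(unclass(config), function(x) if (is.null(x)) NA else x),
    file.path(out, "run_config.json"), auto_unbox = TRUE, pretty = TRUE)

  # fixtures / inputs
  corpus_path <- config$corpus
  objectives_path <- config$objectives
  if (is.null(corpus_path) || is.null(objectives_path)) {
    fx_dir <- file.path(out, "fixtures")
    if (!file.exists(file.path(fx_dir, "corpus.smi"))) {
      .stage("fixtures", verbose,
             generate_fixtures(fx_dir, seed = config$seed,
                               n_molecules = config$n_molecules))
    }
    corpus_path <- corpus_path %||% file.path(fx_dir, "corpus.smi")
    objectives_path <- objectives_path %||% file.path(fx_dir, "objectives.json")
  }
  corpus <- read_corpus(corpus_path)
  objectives <- load_objectives(objectives_path, case = config$case)

  # pretraining
  pre_dir <- file.path(out, "pretrained")
  if (file.exists(file.path(pre_dir, "params.rds"))) {
    pretrained <- load_generator(pre_dir)
  } else {
    pretrained <- .stage("pretrain", verbose, {
      vocab <- build_vocabulary(corpus)
      net <- new_generator(vocab, d_emb = config$d_emb, d_hid = config$d_hid,
                           n_layers = config$n_layers, cell = config$cell,
                           seed = config$seed + 1L)
      fit <- train_lm(net, corpus, epochs = config$pretrain_epochs,
                      batch_size = config$batch_size, lr = config$lr,
                      seed = config$seed + 1L)
      utils::write.csv(fit$history, file.path(out, "pretrain_history.csv"),
                       row.names = FALSE)
      save_generator(fit$net, pre_dir)
      fit$net
    })
  }

  # fine-tuning on the activity table's molecules (when fixtures are used,
  # the subset of the corpus that is desired under the objectives; this
  # mirrors fine-tuning on a ligand set)
  ft_dir <- file.path(out, "finetuned")
  if (file.exists(file.path(ft_dir, "params.rds"))) {
    finetuned <- load_generator(ft_dir)
  } else {
    finetuned <- .stage("finetune", verbose, {
      sm <- score_batch(corpus, objectives)
      focus <- corpus[sm$desired | ws_reward(sm, rep(1 / ncol(sm$scores),
                                                     ncol(sm$scores))) >=
                        stats::median(ws_reward(sm, rep(1 / ncol(sm$scores),
                                                        ncol(sm$scores))))]
      if (length(focus) < 10L) focus <- corpus
      fit <- train_lm(pretrained, focus, epochs = config$finetune_epochs,
                      batch_size = config$batch_size, lr = config$lr,
                      seed = config$seed + 2L)
      utils::write.csv(fit$history, file.path(out, "finetune_history.csv"),
                       row.names = FALSE)
      save_generator(fit$net, ft_dir)
      fit$net
    })
  }

  # reinforcement learning
  agent_dir <- file.path(out, "agent")
  rl_history <- NULL
  if (file.exists(file.path(agent_dir, "params.rds"))) {
    agent <- load_generator(agent_dir)
    hist_path <- file.path(out, "rl_history.csv")
    if (file.exists(hist_path)) rl_history <- utils::read.csv(hist_path)
  } else {
    rl <- .stage("train-rl", verbose, {
      cfgrl <- explorer_config(epsilon = config$epsilon,
                               batch_size = config$batch_size,
                               lr = config$lr, patience = config$rl_patience,
                               max_iterations = config$rl_max_iterations,
                               max_len = config$max_len,
                               eval_n = config$rl_eval_n,
                               seed = config$seed + 3L)
      train_rl(finetuned, objectives, scheme = config$scheme, config = cfgrl,
               crossover = finetuned, mutation = pretrained,
               verbose = verbose)
    })
    agent <- rl$agent
    rl_history <- rl$history
    save_generator(agent, agent_dir)
    utils::write.csv(rl_history, file.path(out, "rl_history.csv"),
                     row.names = FALSE)
  }

  # sampling + evaluation
  samples_path <- file.path(out, "samples.smi")
  samples <- .stage("sample", verbose, {
    set.seed(config$seed + 4L)
    sb <- sample_smiles(agent, config$sample_n, max_len = config$max_len)
    writeLines(sb$smiles, samples_path)
    sb
  })
  report <- .stage("evaluate", verbose,
                   eval_report(samples$smiles, objectives,
                               theta = config$theta))
  jsonlite::write_json(
    list(validity = report$validity, desirability = report$desirability,
         uniqueness = report$uniqueness, diversity = report$diversity,
         theta = report$theta,
         substructures = as.list(report$substructures)),
    file.path(out, "report.json"), auto_unbox = TRUE, pretty = TRUE)

  list(report = report, rl_history = rl_history,
       paths = list(out = out, pretrained = pre_dir, finetuned = ft_dir,
                    agent = agent_dir, samples = samples_path,
                    report = file.path(out, "report.json")))
}
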