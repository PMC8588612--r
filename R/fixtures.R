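# Synthetic fixtures: a valid-SMILES corpus enumerated from scaffold x
# substituent templates, bioactivity tables with known (property-linear)
# structure, and toy-oracle objective specifications. Together these make
# every stage of the pipeline runnable offline and deterministically.

# scaffold templates with a %s substitution slot (placed where a branch is
# chemically legal) and plain scaffolds without one
.fx_templates <- c(
  "c1ccc(%s)cc1",          # benzene
  "c1ccnc(%s)c1",          # pyridine
  "c1cc(%s)oc1",           # furan
  "c1cc(%s)sc1",           # thiophene
  "c1cc(%s)[nH]c1",        # pyrrole
  "c1ccc2cc(%s)ccc2c1",    # naphthalene
  "C1CCC(%s)CC1",          # cyclohexane
  "C1CCN(%s)CC1",          # piperidine
  "O1CCN(%s)CC1",          # morpholine
  "c1nc2c(n1%s)cncn2",     # purine (N-substituted)
  "c1ccc(-c2ccccc2%s)cc1", # biphenyl
  "c1ccc(Oc2ccc(%s)cc2)cc1" # diphenyl ether
)
.fx_plain <- c("c1ccccc1", "c1ccoc1", "c1ccncc1", "C1CCCCC1",
               "c1nc2[nH]cnc2cn1", "c1ccc2ccccc2c1")
.fx_substituents <- c(
  "C", "CC", "CCC", "CCCC", "O", "OC", "OCC", "N", "NC", "N(C)C",
  "F", "Cl", "Br", "C#N", "C(F)(F)F", "C(=O)O", "C(=O)OC", "C(=O)N",
  "C(=O)C", "CO", "CN", "CCO", "CCN", "S(C)(=O)=O", "OC(=O)C",
  # ring substituents use digit 9: scaffold ring 1/2 labels stay open
  # across the insertion point, so substituents must not reuse them
  "NC(=O)C", "c9ccccc9", "Cc9ccccc9", "OCc9ccccc9", "n9cccc9"
)

#' Enumerate a synthetic valid-SMILES corpus
#'
#' Deterministically samples scaffold-substituent combinations from a
#' fixed template library (benzene, pyridine, furan, thiophene, pyrrole,
#' naphthalene, purine, saturated rings, biphenyls, with 30 common
#' substituents), yielding unique, parseable SMILES. The library spans the
#' substructures and property ranges the toy objectives and the profiled
#' ring systems refer to.
#'
#' @param n number of molecules.
#' @param seed RNG seed (same seed, same corpus).
#' @return character vector of `n` unique valid SMILES.
#' @export
fixture_corpus <- function(n = 200L, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  pool <- character(0)
  # full single-substituent enumeration, shuffled, plus double-substituted
  # benzenes if more are needed
  singles <- c(.fx_plain,
               as.vector(outer(.fx_templates, .fx_substituents,
                               function(t, s) sprintf(t, s))))
  pool <- sample(singles)
  if (n > length(pool)) {
    doubles <- as.vector(outer(
      .fx_substituents, .fx_substituents,
      function(a, b) sprintf("c1cc(%s)ccc1%s", a, b)))
    pool <- c(pool, sample(doubles))
  }
  if (n > length(pool)) {
    stop(sprintf("fixture corpus supports at most %d molecules", length(pool)))
  }
  smi <- pool[seq_len(min(n * 1.1, length(pool)))]
  v <- is_valid_smiles(smi)
  out <- smi[v$valid]
  if (length(out) < n) stop("internal error: fixture templates produced too few valid SMILES")
  out[seq_len(n)]
}

# property-linear generating functions for the three pseudo-targets; the
# same properties drive the matching toy oracles, so QSAR models trained
# on these tables can be checked for parameter recovery
.fx_target_defs <- list(
  T1 = list(property = "aromatic_rings", scale = 2.0, offset = 3.0),
  T2 = list(property = "heteroatoms", scale = 0.9, offset = 3.0),
  T3 = list(property = "rotatable_bonds", scale = 0.6, offset = 3.0)
)

#' Generate the full offline fixture set
#'
#' Writes (a) a pretraining corpus (one SMILES per line), (b) a
#' bioactivity TSV for three pseudo-targets whose pX is an affine function
#' of computable properties plus Gaussian noise — including duplicated
#' measurements and "Not Active" rows, so dataset preparation is
#' exercised — and (c) toy-oracle objective configurations for the
#' multi-target case (maximize T1 and T2, minimize off-target T3) and the
#' target-specific case (maximize T1, minimize T2 and T3).
#'
#' @param dir output directory (created).
#' @param seed RNG seed; all outputs are byte-reproducible given the seed.
#' @param n_molecules corpus size (>= 50).
#' @param sigma Gaussian noise sd added to the generating function
#'   (default 0.3 pX units).
#' @return invisibly, a list of the written paths.
#' @export
generate_fixtures <- function(dir, seed = 7L, n_molecules = 200L, sigma = 0.3) {
  stopifnot(n_molecules >= 50L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- fixture_corpus(n_molecules, seed = seed)
  corpus_path <- file.path(dir, "corpus.smi")
  writeLines(corpus, corpus_path)

  set.seed(seed + 1L)
  rows <- list()
  for (tid in names(.fx_target_defs)) {
    def <- .fx_target_defs[[tid]]
    base <- def$offset + def$scale * .oracle_property(def$property, corpus)
    px <- pmin(pmax(base + stats::rnorm(length(corpus), 0, sigma), 3), 10)
    year <- sample(2005:2020, length(corpus), replace = TRUE)
    not_active <- stats::runif(length(corpus)) < 0.10
    rows[[tid]] <- data.frame(
      smiles = corpus, target_id = tid,
      pX = ifelse(not_active, NA_real_, round(px, 3)),
      label = ifelse(not_active, "Not Active", ""),
      year = year, stringsAsFactors = FALSE)
    # duplicate measurements for ~10% of measured molecules
    dup <- which(!not_active & stats::runif(length(corpus)) < 0.10)
    if (length(dup)) {
      d <- rows[[tid]][dup, ]
      d$pX <- round(pmin(pmax(base[dup] + stats::rnorm(length(dup), 0, sigma), 3), 10), 3)
      rows[[tid]] <- rbind(rows[[tid]], d)
    }
  }
  activity <- do.call(rbind, rows)
  activity <- activity[order(activity$target_id, activity$smiles), ]
  activity_path <- file.path(dir, "activity.tsv")
  utils::write.table(activity, activity_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  oracle_cfg <- function(tid, direction) {
    def <- .fx_target_defs[[tid]]
    list(name = tid, type = "toy_oracle", property = def$property,
         scale = def$scale, offset = def$offset,
         direction = direction, threshold = 0.5)
  }
  specs <- list(
    multi_target = list(
      description = "maximize affinity at T1 and T2, minimize at off-target T3",
      objectives = list(oracle_cfg("T1", "high_affinity"),
                        oracle_cfg("T2", "high_affinity"),
                        oracle_cfg("T3", "low_affinity"))),
    target_specific = list(
      description = "maximize affinity at T1 only, minimize at T2 and T3",
      objectives = list(oracle_cfg("T1", "high_affinity"),
                        oracle_cfg("T2", "low_affinity"),
                        oracle_cfg("T3", "low_affinity")))
  )
  objectives_path <- file.path(dir, "objectives.json")
  jsonlite::write_json(specs, objectives_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(corpus = corpus_path, activity = activity_path,
                 objectives = objectives_path))
}

#' Build objective specs from a configuration
#'
#' Reads an objectives configuration (a JSON file written by
#' [generate_fixtures()], or an equivalent list) and instantiates the
#' [objective_spec()]s for one use case. Entries of type `"toy_oracle"`
#' become oracles; entries of type `"model"` load a saved predictor from
#' `path`.
#'
#' @param config path to the JSON file, or the parsed list.
#' @param case which use case to instantiate (e.g. `"multi_target"`,
#'   `"target_specific"`); ignored when the config is already a flat list
#'   of objective entries.
#' @return list of `objective_spec` objects.
#' @export
load_objectives <- function(config, case = "multi_target") {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  entries <- if (!is.null(config[[case]])) config[[case]]$objectives else config
  lapply(entries, function(e) {
    predictor <- switch(e$type %||% "toy_oracle",
      toy_oracle = toy_oracle(e$property, scale = e$scale, offset = e$offset),
      model = if (dir.exists(e$path)) load_predictor(e$path) else readRDS(e$path),
      stop("unknown objective type: ", e$type)
    )
    objective_spec(predictor, direction = e$direction,
                   threshold = e$threshold %||% 0.5, name = e$name)
  })
}
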