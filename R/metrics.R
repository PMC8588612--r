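# Evaluation of generated molecule sets: validity / desirability /
# uniqueness coefficients, Tanimoto distances, Solow-Polasky diversity,
# substructure profiles, and drug-likeness scores (SA, QED).

#' Validity, desirability and uniqueness coefficients
#'
#' Validity is the fraction of strings parsed to molecules; desirability
#' the fraction of molecules meeting every objective threshold (see
#' [score_batch()]); uniqueness the fraction of distinct canonical SMILES
#' among the total (so atom-reordered duplicates collapse).
#'
#' @param smiles character vector of SMILES.
#' @param objectives optional list of [objective_spec()]s; without them
#'   desirability is `NA`.
#' @return named list: `validity`, `desirability`, `uniqueness` (all in
#'   \[0, 1\]).
#' @export
eval_coefficients <- function(smiles, objectives = NULL) {
  stopifnot(length(smiles) >= 1L)
  v <- is_valid_smiles(smiles)
  n <- length(smiles)
  desirability <- if (!is.null(objectives)) {
    sm <- score_batch(smiles, objectives)
    sum(sm$desired) / n
  } else NA_real_
  list(validity = sum(v$valid) / n,
       desirability = desirability,
       uniqueness = length(unique(v$canonical[v$valid])) / n)
}

#' Tanimoto distance between two fingerprints
#'
#' `1 - |a intersect b| / |a union b|` on fingerprint bit sets: 0 for
#' identical fingerprints, 1 for disjoint ones. Two empty fingerprints
#' are defined to be at distance 0.
#'
#' @param fp_a,fp_b 0/1 vectors of equal length.
#' @return distance in \[0, 1\].
#' @export
tanimoto_distance <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprint length mismatch")
  a <- fp_a != 0
  b <- fp_b != 0
  un <- sum(a | b)
  if (un == 0L) return(0)
  1 - sum(a & b) / un
}

#' Pairwise Tanimoto distance matrix
#'
#' @param fp 0/1 matrix, one fingerprint per row.
#' @return symmetric distance matrix with zero diagonal.
#' @export
tanimoto_distance_matrix <- function(fp) {
  m <- fp != 0
  storage.mode(m) <- "numeric"
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  un <- outer(ones, ones, "+") - inter
  d <- 1 - ifelse(un > 0, inter / un, 1)
  diag(d) <- 0
  dimnames(d) <- NULL
  d
}

#' Solow-Polasky diversity
#'
#' The population-utility diversity `I(A) = (1/|A|) e' F^-1 e`, where
#' `F = [f(d_ij)] = [exp(-theta d_ij)]` is the similarity kernel on
#' pairwise Tanimoto distances of ECFP6 fingerprints. A singleton set has
#' diversity exactly 1; a set of near-duplicates approaches `1/|A|`; a set
#' of mutually maximally distant molecules approaches 1. Values are only
#' comparable at the same `theta`.
#'
#' The kernel of a set containing duplicates is singular, so a ridge
#' `1e-8 I` is added and the linear system `F x = e` is solved directly
#' rather than forming an inverse; on distinct sets this perturbs the
#' result below 1e-6.
#'
#' @param smiles character vector of valid SMILES (invalid input is an
#'   error listing the offenders).
#' @param theta kernel decay rate (default 1).
#' @param fingerprints optional precomputed fingerprint matrix.
#' @return diversity in (0, 1], with attribute `theta`.
#' @export
solow_polasky_diversity <- function(smiles, theta = 1, fingerprints = NULL) {
  stopifnot(length(smiles) >= 1L, theta > 0)
  if (is.null(fingerprints)) {
    v <- is_valid_smiles(smiles)
    if (any(!v$valid)) {
      stop("solow_polasky_diversity: invalid SMILES: ",
           paste(utils::head(smiles[!v$valid], 5), collapse = ", "))
    }
    fingerprints <- morgan_fp(smiles)
  }
  m <- nrow(fingerprints)
  if (m == 1L) {
    return(structure(1, theta = theta))
  }
  d <- tanimoto_distance_matrix(fingerprints)
  f <- exp(-theta * d)
  diag(f) <- diag(f) + 1e-8
  x <- solve(f, rep(1, m))
  structure(sum(x) / m, theta = theta)
}

# SMARTS patterns for the profiled ring systems. The purine pattern keeps
# the pyrimidine-fused imidazole skeleton without pinning the N-H
# tautomer; N-substituted purines (e.g. caffeine) still match.
SUBSTRUCTURE_SMARTS <- c(
  purine = "c1nc2c(n1)ncnc2",
  furan = "c1ccoc1",
  benzene = "c1ccccc1"
)

#' Substructure profile of a molecule set
#'
#' Fraction of valid molecules containing at least one match of each
#' profiled ring system (purine, furan, benzene), as percentages.
#'
#' @param smiles character vector of SMILES; invalid strings are excluded
#'   from the denominator.
#' @param smarts named character vector of SMARTS patterns (defaults to
#'   the three profiled ring systems).
#' @return named numeric vector of percentages in \[0, 100\].
#' @export
substructure_profile <- function(smiles, smarts = SUBSTRUCTURE_SMARTS) {
  stopifnot(length(smiles) >= 1L)
  v <- is_valid_smiles(smiles)
  valid <- smiles[v$valid]
  out <- stats::setNames(rep(0, length(smarts)), names(smarts))
  if (length(valid) == 0L) return(out)
  for (nm in names(smarts)) {
    out[nm] <- 100 * mean(.ob_smarts_count(valid, smarts[[nm]]) > 0)
  }
  out
}

#' Drug-likeness scores (SA and QED)
#'
#' Per-molecule synthetic-accessibility score (1 easy to 10 hard; see
#' [sa_score()]) and quantitative estimate of drug-likeness (0 to 1; see
#' [qed_score()]). Invalid molecules are skipped and counted.
#'
#' @param smiles character vector of SMILES.
#' @param sa_reference optional reference corpus for the SA fragment
#'   calibration (see [sa_score()]).
#' @return list with `table` (data.frame: smiles, SA, QED for valid
#'   molecules), `summary` (mean/median/sd of each score), `n_skipped`.
#' @export
drug_likeness <- function(smiles, sa_reference = NULL) {
  v <- is_valid_smiles(smiles)
  valid <- smiles[v$valid]
  if (length(valid) == 0L) {
    return(list(table = data.frame(smiles = character(0), SA = numeric(0),
                                   QED = numeric(0)),
                summary = NULL, n_skipped = sum(!v$valid)))
  }
  sa <- sa_score(valid, reference = sa_reference)
  qed <- qed_score(valid)
  tab <- data.frame(smiles = valid, SA = sa, QED = qed,
                    stringsAsFactors = FALSE)
  list(
    table = tab,
    summary = data.frame(
      score = c("SA", "QED"),
      mean = c(mean(sa), mean(qed)),
      median = c(stats::median(sa), stats::median(qed)),
      sd = c(stats::sd(sa), stats::sd(qed))),
    n_skipped = sum(!v$valid)
  )
}

#' Full evaluation report for a generated molecule set
#'
#' Bundles the coefficient triple, Solow-Polasky diversity (over unique
#' valid molecules), the substructure profile and SA/QED summaries.
#'
#' @param smiles character vector of SMILES.
#' @param objectives optional list of [objective_spec()]s.
#' @param theta diversity kernel decay (reported alongside the value).
#' @param max_diversity_n diversity is computed on at most this many
#'   unique molecules (uniform subsample, seeded) to bound the kernel
#'   solve.
#' @return list of class `eval_report`.
#' @export
eval_report <- function(smiles, objectives = NULL, theta = 1,
                        max_diversity_n = 1000L) {
  co <- eval_coefficients(smiles, objectives)
  v <- is_valid_smiles(smiles)
  uniq <- unique(v$canonical[v$valid])
  diversity <- NA_real_
  if (length(uniq) >= 1L) {
    if (length(uniq) > max_diversity_n) {
      uniq <- uniq[seq(1L, length(uniq), length.out = max_diversity_n)]
    }
    diversity <- as.numeric(solow_polasky_diversity(uniq, theta = theta))
  }
  dl <- drug_likeness(smiles)
  structure(
    list(n = length(smiles),
         validity = 100 * co$validity,
         desirability = if (is.na(co$desirability)) NA_real_ else 100 * co$desirability,
         uniqueness = 100 * co$uniqueness,
         diversity = diversity, theta = theta,
         substructures = substructure_profile(smiles),
         drug_likeness = dl$summary),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation of %d molecules\n", x$n))
  cat(sprintf("  validity:     %6.2f%%\n", x$validity))
  if (!is.na(x$desirability)) {
    cat(sprintf("  desirability: %6.2f%%\n", x$desirability))
  }
  cat(sprintf("  uniqueness:   %6.2f%%\n", x$uniqueness))
  cat(sprintf("  diversity:    %6.4f (theta = %g)\n", x$diversity, x$theta))
  cat(sprintf("  substructures: purine %.2f%%, furan %.2f%%, benzene %.2f%%\n",
              x$substructures["purine"], x$substructures["furan"],
              x$substructures["benzene"]))
  if (!is.null(x$drug_likeness)) {
    cat(sprintf("  SA  mean %.2f  |  QED mean %.3f\n",
                x$drug_likeness$mean[1], x$drug_likeness$mean[2]))
  }
  invisible(x)
}
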