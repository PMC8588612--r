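# Drug-likeness scoring: QED and a synthetic-accessibility heuristic.

# ---- QED ----------------------------------------------------------------
# Quantitative estimate of drug-likeness (Bickerton et al., Nat. Chem.
# 2012): eight molecular properties are each mapped through a fitted
# asymmetric double-sigmoid desirability function and combined as a
# weighted geometric mean. The desirability parameters and property
# weights below are the published ones. The structural-alerts term uses a
# documented subset of common reactive/toxicophore patterns rather than
# the full published list, so absolute values can differ slightly from
# other implementations.

.qed_ads_params <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 1e-09,
             e = 0.713820843, f = 0.920922555, dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, dmax = 104.5686167),
  ROTB   = c(a = 0.01,        b = 272.4121427, c = 2.558379970, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, dmax = 105.4420403),
  AROM   = c(a = 3.217788970, b = 957.7374108, c = 2.274627939, d = 1e-09,
             e = 1.317690384, f = 0.375760881, dmax = 312.3372610),
  ALERTS = c(a = 0.01,        b = 1199.094025, c = -0.09002883, d = 1e-09,
             e = 0.185904477, f = 0.875193782, dmax = 417.7253140)
)

.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
                  ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# structural alerts: a documented subset of common reactive groups and
# toxicophores (nitro, azo, Michael acceptor, epoxide, ...)
QED_ALERT_SMARTS <- c(
  nitro = "[N+](=O)[O-]",
  azo = "N=N",
  aldehyde = "[CX3H1]=O",
  acyl_halide = "C(=O)[F,Cl,Br,I]",
  alkyl_halide = "[CX4][Cl,Br,I]",
  michael_acceptor = "[CX3]=[CX3][CX3]=[OX1]",
  epoxide = "C1OC1",
  aziridine = "C1NC1",
  isocyanate = "N=C=O",
  thiol = "[SX2H]",
  hydrazine = "[NX3][NX3]",
  peroxide = "[OX2][OX2]",
  disulfide = "[SX2][SX2]",
  phosphorus = "[P]",
  quaternary_N = "[NX4+]",
  long_aliphatic_chain = "[CR0][CR0][CR0][CR0][CR0][CR0][CR0]"
)

.ads <- function(x, p) {
  d <- p["a"] + p["b"] /
    (1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])) *
    (1 - 1 / (1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])))
  unname(d / p["dmax"])
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted QED: eight properties (molecular weight, logP, H-bond
#' acceptors/donors, polar surface area, rotatable bonds, aromatic rings,
#' structural alerts) are mapped through published desirability functions
#' and combined as a weighted geometric mean. Values lie in (0, 1); larger
#' is more drug-like.
#'
#' @param smiles character vector of valid SMILES.
#' @param weights named weight vector over the eight properties (defaults
#'   to the published mean weights; all-1 gives the unweighted variant).
#' @return numeric vector of QED values in \[0, 1\].
#' @export
qed_score <- function(smiles, weights = .qed_weights) {
  stopifnot(length(smiles) >= 1L)
  pc <- physchem_descriptors(smiles)
  alerts <- rep(0L, length(smiles))
  for (p in QED_ALERT_SMARTS) {
    alerts <- alerts + as.integer(.ob_smarts_count(smiles, p) > 0)
  }
  props <- cbind(
    MW = pc[, "MW"], ALOGP = pc[, "logP"], HBA = pc[, "HBA"],
    HBD = pc[, "HBD"], PSA = pc[, "TPSA"], ROTB = pc[, "n_rotatable"],
    AROM = pc[, "n_aromatic_rings"], ALERTS = alerts
  )
  vapply(seq_len(nrow(props)), function(i) {
    d <- vapply(colnames(props), function(nm) {
      max(.ads(props[i, nm], .qed_ads_params[[nm]]), 1e-10)
    }, numeric(1))
    exp(sum(weights * log(d)) / sum(weights))
  }, numeric(1))
}

# ---- synthetic accessibility -------------------------------------------
# Fragment-contribution + complexity-penalty score in the spirit of the
# Ertl-Schuffenhauer SA score, on a 1 (easy) .. 10 (hard) scale. The
# fragment term measures how familiar each atom's radius-2 environment is
# relative to a reference corpus (calibrated at first use; the package's
# synthetic corpus by default — scores are therefore corpus-relative, not
# comparable to implementations calibrated on PubChem). The complexity
# term penalizes spiro/bridgehead centres, macrocycles and molecular
# size.

# per-atom radius-2 environment identifiers from the molecular graph
.atom_environments <- function(smiles) {
  mols <- .ob_parse(smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    stop(".atom_environments: invalid SMILES: ",
         paste(utils::head(smiles[bad], 5), collapse = ", "))
  }
  get_atom <- .ob("OBMol_GetAtom"); get_bond <- .ob("OBMol_GetBond")
  n_atoms_f <- .ob("OBMol_NumAtoms"); n_bonds_f <- .ob("OBMol_NumBonds")
  z_f <- .ob("OBAtom_GetAtomicNum"); ar_f <- .ob("OBAtom_IsAromatic")
  b_beg <- .ob("OBBond_GetBeginAtomIdx"); b_end <- .ob("OBBond_GetEndAtomIdx")
  b_ord <- .ob("OBBond_GetBondOrder"); b_ar <- .ob("OBBond_IsAromatic")
  lapply(mols, function(m) {
    na <- n_atoms_f(m); nb <- n_bonds_f(m)
    z <- integer(na); ar <- logical(na)
    for (i in seq_len(na)) {
      a <- get_atom(m, i); z[i] <- z_f(a); ar[i] <- ar_f(a)
    }
    adj <- vector("list", na)
    for (i in seq_len(nb) - 1L) {
      b <- get_bond(m, i)
      p <- b_beg(b); q <- b_end(b)
      o <- if (b_ar(b)) "~" else as.character(b_ord(b))
      adj[[p]] <- c(adj[[p]], stats::setNames(q, o))
      adj[[q]] <- c(adj[[q]], stats::setNames(p, o))
    }
    env0 <- paste0(z, ifelse(ar, "a", ""), ":", lengths(adj))
    env1 <- vapply(seq_len(na), function(i) {
      nb1 <- adj[[i]]
      paste0(env0[i], "(",
             paste(sort(paste0(names(nb1), env0[nb1])), collapse = ","), ")")
    }, character(1))
    vapply(seq_len(na), function(i) {
      nb1 <- adj[[i]]
      paste0(env1[i], "[",
             paste(sort(paste0(names(nb1), env1[nb1])), collapse = ";"), "]")
    }, character(1))
  })
}

.sa_calibration <- function(reference) {
  key <- paste0("salib#", length(reference), "#",
                substr(paste(reference[1:min(5, length(reference))],
                             collapse = ""), 1, 60))
  hit <- .cache_get("sa", key)
  if (!is.null(hit)) return(hit)
  envs <- unlist(.atom_environments(reference))
  tab <- table(envs)
  lib <- list(logfreq = log1p(as.numeric(tab)),
              names = names(tab))
  lib$max <- max(lib$logfreq)
  .cache_set("sa", key, lib)
  lib
}

#' Synthetic-accessibility score
#'
#' Heuristic SA score on a 1 (easy to synthesize) to 10 (hard) scale,
#' combining a fragment-familiarity term — how frequent each atom's
#' radius-2 environment is in a reference corpus — with complexity
#' penalties for spiro and bridgehead centres, macrocycles and molecular
#' size:
#' \deqn{SA = 1 + 5(1 - \bar{f}) + 0.5[\log_2(1 + n_{spiro}) +
#'   \log_2(1 + n_{bridge})] + 1_{macrocycle} + 0.05 \max(0, n_{heavy}-30)}
#' clipped to \[1, 10\], where \eqn{\bar{f}} is the molecule's mean
#' normalized log-frequency of atom environments. Calibration is
#' corpus-relative: by default the package's built-in synthetic corpus,
#' so scores are comparable within one calibration only.
#'
#' @param smiles character vector of valid SMILES.
#' @param reference character vector of SMILES used to calibrate fragment
#'   frequencies (default: the built-in synthetic reference corpus).
#' @return numeric vector of SA scores in \[1, 10\].
#' @export
sa_score <- function(smiles, reference = NULL) {
  stopifnot(length(smiles) >= 1L)
  if (is.null(reference)) reference <- .default_sa_reference()
  lib <- .sa_calibration(reference)
  envs <- .atom_environments(smiles)
  pc <- physchem_descriptors(smiles)
  macro <- .ob_smarts_count(smiles, "[r;!r3;!r4;!r5;!r6;!r7;!r8]") > 0
  vapply(seq_along(smiles), function(i) {
    lf <- lib$logfreq[match(envs[[i]], lib$names)]
    lf[is.na(lf)] <- 0
    familiarity <- if (lib$max > 0) mean(lf) / lib$max else 0
    raw <- 1 + 5 * (1 - familiarity) +
      0.5 * (log2(1 + pc[i, "n_spiro"]) + log2(1 + pc[i, "n_bridgehead"])) +
      as.numeric(macro[i]) +
      0.05 * max(0, pc[i, "n_heavy"] - 30)
    min(max(raw, 1), 10)
  }, numeric(1))
}

.default_sa_reference <- function() {
  hit <- .cache_get("sa", "default_reference")
  if (!is.null(hit)) return(hit)
  ref <- fixture_corpus(n = 300, seed = 20090211L)
  .cache_set("sa", "default_reference", ref)
  ref
}
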