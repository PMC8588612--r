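# Molecule featurization: 2048-bit ECFP6 fingerprint + 19 physico-chemical
# descriptors = 2067-dimensional vector per molecule.
#
# The physchem block, in fixed order:
#   MW, logP, HBA, HBD, n_rotatable, n_amide, n_bridgehead, n_hetero,
#   n_spiro, n_heavy, frac_csp3, n_aliphatic_rings, n_saturated_rings,
#   n_rings, n_aromatic_rings, n_heterocycles, n_valence_electrons,
#   TPSA, MR
# MW/logP/HBA/HBD/TPSA/MR come from OpenBabel's property engine
# (Wildman-Crippen logP and MR); the topological counts are computed from
# the molecular graph (SSSR ring perception, bond rotor/amide flags,
# hybridization states).

PHYSCHEM_NAMES <- c(
  "MW", "logP", "HBA", "HBD", "n_rotatable", "n_amide", "n_bridgehead",
  "n_hetero", "n_spiro", "n_heavy", "frac_csp3", "n_aliphatic_rings",
  "n_saturated_rings", "n_rings", "n_aromatic_rings", "n_heterocycles",
  "n_valence_electrons", "TPSA", "MR"
)

# valence electrons per element (neutral atom, main group)
.valence_e <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5,
                S = 6, Cl = 7, As = 5, Se = 6, Br = 7, Te = 6, I = 7)

.formula_valence_electrons <- function(formula) {
  # formula strings like "C8H10N4O2" (charges suffixed as +/- are ignored)
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    cnt <- suppressWarnings(as.integer(gsub("[^0-9]", "", p)))
    if (is.na(cnt)) cnt <- 1L
    ve <- .valence_e[el]
    if (is.na(ve)) ve <- 4  # unparameterized element: neutral guess
    total <- total + ve * cnt
  }
  total
}

# Topological counts for one parsed OBMol.
.graph_counts <- function(mol) {
  num_atoms <- .ob("OBMol_NumAtoms")(mol)
  num_bonds <- .ob("OBMol_NumBonds")(mol)
  get_atom <- .ob("OBMol_GetAtom")
  get_bond <- .ob("OBMol_GetBond")
  atom_num <- .ob("OBAtom_GetAtomicNum")
  atom_hyb <- .ob("OBAtom_GetHyb")
  atom_arom <- .ob("OBAtom_IsAromatic")

  z <- integer(num_atoms)
  hyb <- integer(num_atoms)
  arom <- logical(num_atoms)
  for (i in seq_len(num_atoms)) {
    a <- get_atom(mol, i)
    z[i] <- atom_num(a)
    hyb[i] <- atom_hyb(a)
    arom[i] <- atom_arom(a)
  }

  n_rot <- 0L
  n_amide <- 0L
  is_rotor <- .ob("OBBond_IsRotor")
  is_amide <- .ob("OBBond_IsAmide")
  for (i in seq_len(num_bonds) - 1L) {
    b <- get_bond(mol, i)
    if (is_rotor(b)) n_rot <- n_rot + 1L
    if (is_amide(b)) n_amide <- n_amide + 1L
  }

  # SSSR ring systems
  rings <- .ob("OBMol_GetSSSR")(mol)
  n_rings <- .ob("vectorpOBRing_size")(rings)
  ring_item <- .ob("vectorpOBRing___getitem__")
  ring_path <- .ob("OBRing__path_get")
  ring_arom <- .ob("OBRing_IsAromatic")
  paths <- vector("list", n_rings)
  aromatic_ring <- logical(n_rings)
  for (k in seq_len(n_rings)) {
    r <- ring_item(rings, k - 1L)
    paths[[k]] <- as.integer(ring_path(r))
    aromatic_ring[k] <- ring_arom(r)
  }

  hetero_ring <- vapply(paths, function(p) any(z[p] != 6L), logical(1))
  saturated_ring <- vapply(seq_len(n_rings), function(k) {
    !aromatic_ring[k] && all(hyb[paths[[k]]] == 3L)
  }, logical(1))

  # spiro atoms: shared atom of a ring pair that shares exactly one atom
  # bridgeheads: endpoints of a shared path of >= 2 atoms between two rings
  #   that also carry a third ring-bond neighbour within the shared set
  spiro_atoms <- integer(0)
  bridge_atoms <- integer(0)
  if (n_rings >= 2L) {
    for (a_ in seq_len(n_rings - 1L)) {
      for (b_ in (a_ + 1L):n_rings) {
        shared <- intersect(paths[[a_]], paths[[b_]])
        if (length(shared) == 1L) {
          spiro_atoms <- union(spiro_atoms, shared)
        } else if (length(shared) >= 3L) {
          # shared path longer than one bond -> bridged pair; the endpoints
          # of that path (atoms with one neighbour inside the shared set
          # along either ring) are the bridgeheads
          ends <- shared[vapply(shared, function(at) {
            nb <- unique(c(
              .ring_neighbours(paths[[a_]], at),
              .ring_neighbours(paths[[b_]], at)
            ))
            sum(nb %in% shared) <= 2L && length(nb) >= 3L
          }, logical(1))]
          bridge_atoms <- union(bridge_atoms, ends)
        }
      }
    }
  }

  n_c <- sum(z == 6L)
  list(
    n_rotatable = n_rot,
    n_amide = n_amide,
    n_bridgehead = length(bridge_atoms),
    n_hetero = sum(!z %in% c(1L, 6L)),
    n_spiro = length(spiro_atoms),
    n_heavy = sum(z > 1L),
    frac_csp3 = if (n_c == 0L) 0 else sum(z == 6L & hyb == 3L) / n_c,
    n_aliphatic_rings = sum(!aromatic_ring),
    n_saturated_rings = sum(saturated_ring),
    n_rings = n_rings,
    n_aromatic_rings = sum(aromatic_ring),
    n_heterocycles = sum(hetero_ring)
  )
}

# neighbours of atom `at` along the cyclic ring path `p`
.ring_neighbours <- function(p, at) {
  i <- match(at, p)
  if (is.na(i)) return(integer(0))
  n <- length(p)
  p[c(if (i == 1L) n else i - 1L, if (i == n) 1L else i + 1L)]
}

#' Physico-chemical descriptors
#'
#' Computes the 19 physico-chemical descriptors used alongside the
#' fingerprint block: molecular weight, Wildman-Crippen logP, hydrogen-bond
#' acceptor and donor counts, rotatable bonds, amide bonds, bridgehead
#' atoms, heteroatoms, spiro atoms, heavy atoms, fraction of sp3 carbons,
#' aliphatic / saturated / total / aromatic ring counts, heterocycles,
#' valence electrons, topological polar surface area and Wildman-Crippen
#' molar refractivity.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric matrix, one row per molecule, 19 named columns.
#' @export
physchem_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  out <- matrix(NA_real_, nrow = length(smiles), ncol = length(PHYSCHEM_NAMES),
                dimnames = list(NULL, PHYSCHEM_NAMES))
  todo <- which(vapply(smiles, function(s) is.null(.cache_get("desc", s)),
                       logical(1)))
  if (length(todo)) {
    mols <- .ob_parse(smiles[todo])
    bad <- vapply(mols, is.null, logical(1))
    if (any(bad)) {
      stop("physchem_descriptors: invalid SMILES: ",
           paste(utils::head(smiles[todo][bad], 5), collapse = ", "))
    }
    props <- ChemmineOB::prop_OB(mols)
    get_formula <- .ob("OBMol_GetFormula")
    for (k in seq_along(todo)) {
      gc_ <- .graph_counts(mols[[k]])
      row <- c(
        MW = as.numeric(props[k, "MW"]),
        logP = as.numeric(props[k, "logP"]),
        HBA = as.numeric(props[k, "HBA1"]),
        HBD = as.numeric(props[k, "HBD"]),
        n_rotatable = gc_$n_rotatable,
        n_amide = gc_$n_amide,
        n_bridgehead = gc_$n_bridgehead,
        n_hetero = gc_$n_hetero,
        n_spiro = gc_$n_spiro,
        n_heavy = gc_$n_heavy,
        frac_csp3 = gc_$frac_csp3,
        n_aliphatic_rings = gc_$n_aliphatic_rings,
        n_saturated_rings = gc_$n_saturated_rings,
        n_rings = gc_$n_rings,
        n_aromatic_rings = gc_$n_aromatic_rings,
        n_heterocycles = gc_$n_heterocycles,
        n_valence_electrons = .formula_valence_electrons(get_formula(mols[[k]])),
        TPSA = as.numeric(props[k, "TPSA"]),
        MR = as.numeric(props[k, "MR"])
      )
      .cache_set("desc", smiles[todo[k]], unname(row))
    }
  }
  for (i in seq_along(smiles)) out[i, ] <- .cache_get("desc", smiles[i])
  out
}

#' Featurize molecules into 2067-dimensional descriptor vectors
#'
#' Concatenates the 2048-bit ECFP6 fingerprint with the 19 physico-chemical
#' descriptors of [physchem_descriptors()], giving the fixed 2067-column
#' representation consumed by the QSAR models. Values are raw; min-max
#' scaling to \[0,1\] is fit on the training split by [fit_scaler()].
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric matrix with `length(smiles)` rows and 2067 columns
#'   (`fp0001`..`fp2048`, then the physchem names).
#' @export
featurize <- function(smiles) {
  v <- is_valid_smiles(smiles)
  if (any(!v$valid)) {
    stop("featurize: invalid SMILES: ",
         paste(utils::head(smiles[!v$valid], 5), collapse = ", "))
  }
  fp <- morgan_fp(smiles, nbits = 2048L)
  colnames(fp) <- sprintf("fp%04d", seq_len(ncol(fp)))
  pc <- physchem_descriptors(smiles)
  cbind(fp, pc)
}

#' Min-max feature scaler
#'
#' Fits per-feature minimum and range on a training matrix; `apply_scaler`
#' maps features to \[0,1\], clipping unseen values outside the training
#' range. Constant features map to 0.
#'
#' @param x numeric training matrix (rows = molecules).
#' @return an object of class `minmax_scaler`.
#' @export
fit_scaler <- function(x) {
  stopifnot(is.matrix(x))
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  structure(list(min = mins, range = pmax(maxs - mins, 0)),
            class = "minmax_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `minmax_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"), is.matrix(x),
            ncol(x) == length(scaler$min))
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  out <- sweep(sweep(x, 2, scaler$min, "-"), 2, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[, scaler$range == 0] <- 0
  out
}
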