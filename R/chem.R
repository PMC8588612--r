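# Chemistry backend: validity, canonicalization, fingerprints.
#
# OpenBabel (via ChemmineOB) is the molecule parser. It is deliberately
# forgiving — it silently repairs a truncated branch such as "C(" — so
# validity here is a two-stage test: (1) a structural screen on the token
# stream (balanced branches, paired ring closures, known tokens), then
# (2) an OpenBabel parse that must yield a molecule with at least one atom.
# Canonical SMILES, ECFP6 fingerprints and descriptor lookups are memoized
# per process because the RL loop re-scores many duplicate molecules.

.chem_cache <- new.env(parent = emptyenv())

# Low-level OpenBabel bindings (SWIG layer of ChemmineOB, not exported there).
.ob <- function(fn) utils::getFromNamespace(fn, "ChemmineOB")

.cache_get <- function(map, key) {
  if (is.null(.chem_cache[[map]])) .chem_cache[[map]] <- new.env(parent = emptyenv())
  get0(key, envir = .chem_cache[[map]], inherits = FALSE)
}
.cache_set <- function(map, key, value) {
  if (is.null(.chem_cache[[map]])) .chem_cache[[map]] <- new.env(parent = emptyenv())
  assign(key, value, envir = .chem_cache[[map]])
  invisible(value)
}

#' Clear the molecule cache
#'
#' Canonical SMILES, fingerprints and descriptors are memoized per session;
#' this empties the cache (mainly useful in benchmarks).
#' @export
clear_chem_cache <- function() {
  rm(list = ls(.chem_cache), envir = .chem_cache)
  invisible(NULL)
}

# Structural screen on the token stream. Returns TRUE/FALSE, never errors.
.structurally_ok <- function(smiles) {
  toks <- tryCatch(tokenize_smiles(smiles), error = function(e) NULL)
  if (is.null(toks)) return(FALSE)
  depth <- 0L
  open_rings <- character(0)
  has_atom <- FALSE
  for (tk in toks) {
    if (tk == "(") {
      depth <- depth + 1L
    } else if (tk == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (grepl("^[0-9]$|^%[0-9][0-9]$", tk)) {
      lab <- sub("^%", "", tk)
      if (lab %in% open_rings) {
        open_rings <- setdiff(open_rings, lab)
      } else {
        open_rings <- c(open_rings, lab)
      }
    } else if (!tk %in% c("-", "=", "#", "$", ":", "/", "\\", ".")) {
      has_atom <- TRUE
    }
  }
  depth == 0L && length(open_rings) == 0L && has_atom
}

# Parse a character vector of SMILES with OpenBabel, preserving order via
# line titles. Returns a list of OBMol references with NULL for failures.
.ob_parse <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(list())
  input <- paste(sprintf("%s __%d__", smiles, seq_len(n)), collapse = "\n")
  mols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", input, identity),
    error = function(e) list()
  )
  out <- vector("list", n)
  get_title <- .ob("OBMol_GetTitle")
  num_atoms <- .ob("OBMol_NumAtoms")
  for (m in mols) {
    title <- tryCatch(get_title(m), error = function(e) "")
    idx <- suppressWarnings(as.integer(sub("^__([0-9]+)__$", "\\1", title)))
    if (!is.na(idx) && idx >= 1L && idx <= n && num_atoms(m) > 0) {
      out[[idx]] <- m
    }
  }
  out
}

#' SMILES validity and canonical form
#'
#' A string is valid when it lexes under the SMILES grammar, its branches
#' and ring closures are balanced, the chemistry parser yields a
#' molecule, and every atom's total valence is chemically allowed for its
#' element and formal charge (the parser itself would accept, e.g.,
#' pentavalent carbon with only a warning).
#' Uniqueness accounting throughout the package is done on the
#' canonical form returned here, so `"OCC"` and `"CCO"` collapse to one
#' molecule.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns `smiles`, `valid` (logical) and
#'   `canonical` (canonical SMILES, `NA` where invalid).
#' @examples
#' is_valid_smiles(c("CCO", "C(", "OCC"))
#' @export
is_valid_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  valid <- logical(n)
  canonical <- rep(NA_character_, n)

  todo <- integer(0)
  for (i in seq_len(n)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) next
    hit <- .cache_get("canon", s)
    if (!is.null(hit)) {
      valid[i] <- !is.na(hit)
      canonical[i] <- hit
    } else if (.structurally_ok(s)) {
      todo <- c(todo, i)
    } else {
      .cache_set("canon", s, NA_character_)
    }
  }

  if (length(todo)) {
    mols <- .ob_parse(smiles[todo])
    for (k in seq_along(mols)) {
      if (!is.null(mols[[k]]) && !.valence_ok(mols[[k]])) mols[k] <- list(NULL)
    }
    can <- .ob_canonical(smiles[todo], mols)
    for (k in seq_along(todo)) {
      i <- todo[k]
      valid[i] <- !is.na(can[k])
      canonical[i] <- can[k]
      .cache_set("canon", smiles[i], can[k])
    }
  }
  data.frame(smiles = smiles, valid = valid, canonical = canonical,
             stringsAsFactors = FALSE)
}

# Valence screen. OpenBabel accepts hypervalent atoms (pentavalent
# carbon, divalent fluorine, ...) with a warning only; molecules carrying
# them are treated as invalid here. Allowed total valences (bond orders
# plus implicit hydrogens) per element, adjusted for formal charge:
# N/O/P/S gain one per positive charge, lose one per negative; carbon
# loses one per unit of either charge.
.allowed_valences <- list(
  `1` = 1L, `5` = 3L, `6` = 4L, `7` = 3L, `8` = 2L, `9` = 1L, `14` = 4L,
  `15` = c(3L, 5L), `16` = c(2L, 4L, 6L), `17` = 1L, `35` = 1L, `53` = 1L
)

.valence_ok <- function(mol) {
  n <- .ob("OBMol_NumAtoms")(mol)
  get_atom <- .ob("OBMol_GetAtom")
  z_f <- .ob("OBAtom_GetAtomicNum")
  v_f <- .ob("OBAtom_GetTotalValence")
  q_f <- .ob("OBAtom_GetFormalCharge")
  for (i in seq_len(n)) {
    a <- get_atom(mol, i)
    z <- z_f(a)
    allowed <- .allowed_valences[[as.character(z)]]
    if (is.null(allowed)) next             # unparameterized element: skip
    q <- q_f(a)
    if (q != 0L) {
      if (abs(q) > 1L) return(FALSE)
      allowed <- if (z %in% c(7L, 8L, 15L, 16L)) allowed + q
                 else allowed - abs(q)
    }
    if (!v_f(a) %in% allowed) return(FALSE)
  }
  TRUE
}

# Canonical SMILES for pre-parsed molecules (NULL entries -> NA).
.ob_canonical <- function(smiles, mols) {
  conv <- .ob("OBConversion")()
  .ob("OBConversion_SetOutFormat")(conv, "can")
  write_string <- .ob("OBConversion_WriteString")
  vapply(seq_along(smiles), function(k) {
    m <- mols[[k]]
    if (is.null(m)) return(NA_character_)
    out <- tryCatch(write_string(conv, m), error = function(e) NA_character_)
    if (is.na(out)) return(NA_character_)
    out <- sub("\t.*$", "", sub("\n$", "", out))
    out <- trimws(out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1))
}

#' Canonical SMILES
#'
#' Convenience wrapper around [is_valid_smiles()]; errors if any input is
#' invalid.
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  v <- is_valid_smiles(smiles)
  if (any(!v$valid)) {
    stop("invalid SMILES: ", paste(utils::head(v$smiles[!v$valid], 5), collapse = ", "))
  }
  v$canonical
}

#' ECFP6 fingerprints
#'
#' Extended-connectivity fingerprints of radius 3, computed by OpenBabel's
#' ECFP6 implementation (4096 bits) and folded to `nbits` by OR-ing
#' congruent positions. The default 2048 bits matches the featurization
#' contract used by the QSAR models and Tanimoto calculations.
#'
#' @param smiles character vector of valid SMILES.
#' @param nbits folded fingerprint width (power of two up to 4096).
#' @return 0/1 integer matrix, one row per molecule, `nbits` columns.
#' @export
morgan_fp <- function(smiles, nbits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L,
            nbits >= 1L, 4096L %% nbits == 0L)
  key <- function(s) paste0(s, "#", nbits)
  out <- matrix(0L, nrow = length(smiles), ncol = nbits)
  todo <- which(vapply(smiles, function(s) is.null(.cache_get("fp", key(s))),
                       logical(1)))
  if (length(todo)) {
    chk <- is_valid_smiles(smiles[todo])
    if (any(!chk$valid)) {
      stop("morgan_fp: invalid SMILES: ",
           paste(utils::head(smiles[todo][!chk$valid], 5), collapse = ", "))
    }
    mols <- .ob_parse(smiles[todo])
    raw <- ChemmineOB::fingerprint_OB(mols, "ECFP6")
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
    fold <- (seq_len(ncol(raw)) - 1L) %% nbits + 1L
    for (k in seq_along(todo)) {
      v <- integer(nbits)
      set <- fold[raw[k, ] != 0]
      v[set] <- 1L
      .cache_set("fp", key(smiles[todo[k]]), v)
    }
  }
  for (i in seq_along(smiles)) out[i, ] <- .cache_get("fp", key(smiles[i]))
  rownames(out) <- names(smiles)
  out
}

# Shared low-level molecule accessors -----------------------------------

# Parse one valid SMILES, error otherwise.
.ob_parse_one <- function(smiles) {
  m <- .ob_parse(smiles)[[1]]
  if (is.null(m)) stop("cannot parse SMILES: ", smiles)
  m
}

# OpenBabel bulk properties for a batch of valid SMILES (memoized).
.ob_props <- function(smiles) {
  cols <- c("HBA1", "HBD", "logP", "MR", "MW", "TPSA")
  res <- matrix(NA_real_, nrow = length(smiles), ncol = length(cols),
                dimnames = list(NULL, cols))
  todo <- which(vapply(smiles, function(s) is.null(.cache_get("props", s)),
                       logical(1)))
  if (length(todo)) {
    mols <- .ob_parse(smiles[todo])
    bad <- vapply(mols, is.null, logical(1))
    if (any(bad)) {
      stop(".ob_props: invalid SMILES: ",
           paste(utils::head(smiles[todo][bad], 5), collapse = ", "))
    }
    p <- ChemmineOB::prop_OB(mols)
    for (k in seq_along(todo)) {
      .cache_set("props", smiles[todo[k]],
                 as.numeric(p[k, cols]))
    }
  }
  for (i in seq_along(smiles)) res[i, ] <- .cache_get("props", smiles[i])
  res
}

# Count of unique SMARTS matches per molecule over a batch of valid SMILES.
.ob_smarts_count <- function(smiles, pattern) {
  key <- function(s) paste0(s, "#", pattern)
  res <- integer(length(smiles))
  todo <- which(vapply(smiles, function(s) is.null(.cache_get("smarts", key(s))),
                       logical(1)))
  if (length(todo)) {
    mols <- .ob_parse(smiles[todo])
    bad <- vapply(mols, is.null, logical(1))
    if (any(bad)) {
      stop(".ob_smarts_count: invalid SMILES: ",
           paste(utils::head(smiles[todo][bad], 5), collapse = ", "))
    }
    cnt <- ChemmineOB::smartsSearch_OB(mols, pattern, uniqueMatches = TRUE)
    for (k in seq_along(todo)) {
      .cache_set("smarts", key(smiles[todo[k]]), as.integer(cnt[k]))
    }
  }
  for (i in seq_along(smiles)) res[i] <- .cache_get("smarts", key(smiles[i]))
  res
}
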