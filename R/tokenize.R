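# SMILES lexing, vocabulary construction and sequence encoding.
#
# The generator treats a SMILES string as a sentence over a finite token
# alphabet: atoms (including multi-character elements and whole bracket
# expressions), bond/branch/ring-closure symbols, plus the control tokens
# GO (sequence start) and END (sequence stop).

TOK_GO <- "GO"
TOK_END <- "END"

# Two-letter elements recognised outside brackets. Only Cl and Br occur in
# the SMILES organic subset; matching them before single letters is what
# keeps "CCl" from lexing as C,C,l.
.two_letter <- c("Cl", "Br")
.single_atom <- c("B", "C", "N", "O", "P", "S", "F", "I",
                  "b", "c", "n", "o", "p", "s")
.symbols <- c("-", "=", "#", "$", ":", "/", "\\", "(", ")", ".",
              as.character(0:9))

#' Split a SMILES string into tokens
#'
#' Lexes a SMILES string under the standard grammar: bracket expressions
#' (`[nH]`, `[O-]`, ...) are captured greedily as single tokens, two-letter
#' halogens (`Cl`, `Br`) are matched before single letters, and `%NN`
#' two-digit ring closures are one token.
#'
#' @param smiles a single SMILES string.
#' @param vocab optional [smiles_vocab] object; when supplied, every emitted
#'   token must be a vocabulary member.
#' @return character vector of tokens. Concatenating them reproduces
#'   `smiles` exactly.
#' @examples
#' tokenize_smiles("CCl")       # "C"  "Cl"
#' tokenize_smiles("c1ccccc1")
#' @export
tokenize_smiles <- function(smiles, vocab = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop(sprintf("tokenization error: unterminated bracket expression starting at position %d in '%s'",
                     i, smiles))
      }
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)]))) {
        stop(sprintf("tokenization error: malformed '%%NN' ring closure at position %d in '%s'",
                     i, smiles))
      }
      out <- c(out, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .two_letter) {
      out <- c(out, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% .single_atom || ch %in% .symbols) {
      out <- c(out, ch)
      i <- i + 1L
    } else {
      stop(sprintf("tokenization error: unknown token '%s' at position %d in '%s'",
                   ch, i, smiles))
    }
  }
  if (!is.null(vocab)) {
    bad <- setdiff(out, vocab$tokens)
    if (length(bad)) {
      stop(sprintf("tokenization error: token(s) not in vocabulary: %s",
                   paste(unique(bad), collapse = ", ")))
    }
  }
  out
}

#' Reassemble a SMILES string from tokens
#'
#' Inverse of [tokenize_smiles()]: concatenates chemical tokens, dropping any
#' GO/END control tokens.
#'
#' @param tokens character vector of tokens.
#' @return single SMILES string.
#' @export
detokenize <- function(tokens) {
  paste(tokens[!tokens %in% c(TOK_GO, TOK_END)], collapse = "")
}

#' Build a token vocabulary from a SMILES corpus
#'
#' Collects the union of tokens over every string in `corpus`, sorts them for
#' reproducibility, and prepends the control tokens GO and END. Strings that
#' fail to lex are skipped with a warning; the skip count is attached to the
#' result.
#'
#' @param corpus character vector of SMILES strings.
#' @return a `smiles_vocab` object: list with `tokens` (GO first, END second,
#'   then sorted chemical tokens) and `n_skipped`.
#' @export
build_vocabulary <- function(corpus) {
  if (!is.character(corpus) || length(corpus) == 0L) {
    stop("'corpus' must be a non-empty character vector")
  }
  toks <- character(0)
  skipped <- 0L
  for (s in corpus) {
    t <- tryCatch(tokenize_smiles(s), error = function(e) NULL)
    if (is.null(t)) {
      skipped <- skipped + 1L
    } else {
      toks <- c(toks, t)
    }
  }
  if (skipped > 0L) {
    warning(sprintf("build_vocabulary: skipped %d unparseable SMILES", skipped))
  }
  chem <- sort(unique(toks), method = "radix")
  if (length(chem) == 0L) stop("no tokenizable SMILES in corpus")
  new_vocab(chem, n_skipped = skipped)
}

new_vocab <- function(chem_tokens, n_skipped = 0L) {
  stopifnot(!any(c(TOK_GO, TOK_END) %in% chem_tokens))
  structure(
    list(tokens = c(TOK_GO, TOK_END, chem_tokens), n_skipped = n_skipped),
    class = "smiles_vocab"
  )
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat(sprintf("SMILES vocabulary: %d tokens (incl. GO/END)\n", length(x$tokens)))
  cat(" ", paste(utils::head(x$tokens, 30), collapse = " "),
      if (length(x$tokens) > 30) "..." else "", "\n")
  invisible(x)
}

#' @export
length.smiles_vocab <- function(x) length(x$tokens)

#' Token/index conversion
#'
#' Tokens map to 1-based contiguous indices in vocabulary order (GO = 1,
#' END = 2).
#'
#' @param vocab a `smiles_vocab`.
#' @param tokens character vector of tokens.
#' @return integer indices.
#' @export
vocab_encode <- function(vocab, tokens) {
  idx <- match(tokens, vocab$tokens)
  if (anyNA(idx)) {
    stop(sprintf("tokens not in vocabulary: %s",
                 paste(unique(tokens[is.na(idx)]), collapse = ", ")))
  }
  idx
}

#' @rdname vocab_encode
#' @param indices integer vector of 1-based token indices.
#' @export
vocab_decode <- function(vocab, indices) {
  if (any(indices < 1L | indices > length(vocab$tokens))) {
    stop("token index out of vocabulary range")
  }
  vocab$tokens[indices]
}

#' Read or write a vocabulary file
#'
#' Plain text, one token per line, GO on the first line and END on the
#' second, so vocabularies travel with model checkpoints.
#'
#' @param vocab a `smiles_vocab`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  toks <- readLines(path, warn = FALSE)
  toks <- toks[nzchar(toks)]
  if (length(toks) < 3L || toks[1] != TOK_GO || toks[2] != TOK_END) {
    stop("malformed vocabulary file: expected GO and END on the first two lines")
  }
  new_vocab(toks[-(1:2)])
}

#' Read a SMILES corpus file
#'
#' Accepts either plain text (one SMILES per line) or TSV with a header
#' containing a `smiles` column; other columns are preserved as attributes
#' when `as_table = TRUE`.
#'
#' @param path file path.
#' @param as_table return the full data.frame for TSV input.
#' @return character vector of SMILES (default), or a data.frame.
#' @export
read_corpus <- function(path, as_table = FALSE) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first) || grepl("^smiles(\t|$)", tolower(first))) {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
    names(df) <- tolower(names(df))
    if (!"smiles" %in% names(df)) stop("TSV corpus lacks a 'smiles' column")
    if (as_table) return(df)
    return(df$smiles)
  }
  smi <- readLines(path, warn = FALSE)
  smi <- trimws(smi)
  smi[nzchar(smi)]
}
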