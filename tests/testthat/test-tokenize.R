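test_that("tokenizer emits multi-character atoms and bracket expressions as single tokens", {
  expect_equal(tokenize_smiles("CCl"), c("C", "Cl"))
  expect_equal(tokenize_smiles("CBr"), c("C", "Br"))
  expect_equal(tokenize_smiles("c1ccccc1"),
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_equal(tokenize_smiles("C[nH]1cccc1")[2], "[nH]")
  expect_equal(tokenize_smiles("[O-]C"), c("[O-]", "C"))
  expect_equal(tokenize_smiles("C%12CC%12")[2], "%12")
})

test_that("tokenization round-trips every fixture molecule", {
  for (s in c(tiny_corpus(), unname(REF_MOLS))) {
    expect_identical(detokenize(tokenize_smiles(s)), s)
  }
})

test_that("tokenizer rejects malformed input with informative errors", {
  expect_error(tokenize_smiles(""), "non-empty")
  expect_error(tokenize_smiles("CxC"), "unknown token 'x' at position 2")
  expect_error(tokenize_smiles("C[nH"), "unterminated bracket")
  expect_error(tokenize_smiles("C%1C"), "ring closure")
  vocab <- build_vocabulary(c("CC", "CO"))
  expect_error(tokenize_smiles("CCl", vocab = vocab), "not in vocabulary")
})

test_that("vocabulary construction is a sorted union with GO/END first", {
  v <- build_vocabulary(c("CC", "CO"))
  expect_identical(v$tokens[1:2], c("GO", "END"))
  expect_true(all(c("C", "O") %in% v$tokens))
  v2 <- build_vocabulary(c("CCl", "c1ccccc1"))
  expect_true("Cl" %in% v2$tokens)
  expect_false("l" %in% v2$tokens)
  expect_error(build_vocabulary(character(0)), "non-empty")
})

test_that("vocabulary is idempotent and order-insensitive", {
  corpus <- tiny_corpus()
  v1 <- build_vocabulary(corpus)
  v2 <- build_vocabulary(rev(corpus))
  v3 <- build_vocabulary(c(corpus, corpus))
  expect_identical(v1$tokens, v2$tokens)
  expect_identical(v1$tokens, v3$tokens)
})

test_that("unparseable corpus entries are skipped with a warning and counted", {
  expect_warning(v <- build_vocabulary(c("CCO", "C?C", "CC")), "skipped 1")
  expect_equal(v$n_skipped, 1L)
})

test_that("token/index maps are a contiguous bijection", {
  v <- tiny_vocab()
  idx <- vocab_encode(v, v$tokens)
  expect_identical(idx, seq_along(v$tokens))
  expect_identical(vocab_decode(v, idx), v$tokens)
  expect_error(vocab_encode(v, "no-such-token"), "not in vocabulary")
  expect_error(vocab_decode(v, length(v$tokens) + 1L), "out of vocabulary")
})

test_that("vocabulary files round-trip through disk", {
  v <- tiny_vocab()
  path <- withr::local_tempfile(fileext = ".txt")
  write_vocabulary(v, path)
  lines <- readLines(path)
  expect_identical(lines[1:2], c("GO", "END"))
  expect_identical(read_vocabulary(path)$tokens, v$tokens)
  writeLines(c("A", "B"), path)
  expect_error(read_vocabulary(path), "malformed")
})

test_that("corpus reader handles plain and TSV input", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "", "c1ccccc1 "), path)
  expect_identical(read_corpus(path), c("CCO", "c1ccccc1"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("smiles\tpX", "CCO\t5.0"), tsv)
  expect_identical(read_corpus(tsv), "CCO")
  expect_equal(read_corpus(tsv, as_table = TRUE)$px, 5.0)
})
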