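test_that("the coefficient triple counts validity, desirability and uniqueness", {
  co <- eval_coefficients(c("CCO", "C(", "c1ccccc1"))
  expect_equal(co$validity, 2 / 3)
  co2 <- eval_coefficients(c("CCO", "CCO", "CCC"))
  expect_equal(co2$uniqueness, 2 / 3)
  # atom reordering is not uniqueness
  co3 <- eval_coefficients(c("CCO", "OCC"))
  expect_equal(co3$uniqueness, 1 / 2)
  # desirability of an all-invalid batch is zero, and N_valid + N_invalid = N
  objs <- toy_objectives()
  co4 <- eval_coefficients(c("C(", "C)"), objs)
  expect_equal(co4$desirability, 0)
  expect_equal(co4$validity, 0)
  co5 <- eval_coefficients(c("CCO", "Cn1cnc2c1ncnc2", "C("), objs)
  expect_lte(co5$desirability, co5$validity)
})

test_that("Tanimoto distance follows the bit-set definition", {
  expect_equal(tanimoto_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(tanimoto_distance(c(1, 0, 0), c(0, 1, 1)), 1)
  a <- c(1, 1, 1, 0)   # bits {1,2,3}
  b <- c(0, 1, 1, 1)   # bits {2,3,4}
  expect_equal(tanimoto_distance(a, b), 0.5)
  expect_equal(tanimoto_distance(c(0, 0), c(0, 0)), 0)  # both empty
  expect_error(tanimoto_distance(c(1, 0), c(1, 0, 0)), "length mismatch")
  # matrix form agrees with the pairwise definition
  m <- rbind(a, b, c(1, 0, 0, 0))
  d <- tanimoto_distance_matrix(m)
  expect_equal(d[1, 2], 0.5)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3))
})

test_that("diversity matches its closed forms", {
  expect_equal(as.numeric(solow_polasky_diversity("CCO")), 1.0)
  # two maximally distant molecules at theta = 1: 2/(1 + e^-1) / 2
  fp <- rbind(c(1, 0), c(0, 1))
  got <- as.numeric(solow_polasky_diversity(c("a", "b"), theta = 1,
                                            fingerprints = fp))
  expect_equal(got, 1 / (1 + exp(-1)), tolerance = 1e-6)
  # two identical molecules: the d -> 0 limit of the 2x2 closed form
  dup <- rbind(c(1, 0), c(1, 0))
  expect_equal(as.numeric(solow_polasky_diversity(c("a", "b"),
                                                  fingerprints = dup)),
               0.5, tolerance = 1e-4)
  expect_error(solow_polasky_diversity(c("CCO", "C(")), "invalid SMILES")
})

test_that("diversity is permutation-invariant and never rises on duplication", {
  mols <- c("CCO", "c1ccccc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "C1CCNCC1")
  d1 <- as.numeric(solow_polasky_diversity(mols))
  d2 <- as.numeric(solow_polasky_diversity(rev(mols)))
  expect_equal(d1, d2, tolerance = 1e-9)
  d_dup <- as.numeric(solow_polasky_diversity(c(mols, mols[1])))
  expect_lte(d_dup, d1 + 1e-9)
  expect_true(d1 > 0 && d1 <= 1)
})

test_that("substructure profile matches known ring systems", {
  expect_equal(unname(substructure_profile("Cc1ccccc1")["benzene"]), 100)
  caffeine <- "Cn1cnc2c1c(=O)n(C)c(=O)n2C"
  expect_equal(unname(substructure_profile(caffeine)["purine"]), 100)
  prof <- substructure_profile("CCO")
  expect_equal(unname(prof), c(0, 0, 0))
  # monotone under adding a matching molecule
  base <- substructure_profile(c("CCO", "CCC"))
  more <- substructure_profile(c("CCO", "CCC", "c1ccccc1"))
  expect_gte(more["benzene"], base["benzene"])
  # furan positive case and invalid exclusion from the denominator
  prof2 <- substructure_profile(c("c1ccoc1", "C("))
  expect_equal(unname(prof2["furan"]), 100)
})

test_that("drug-likeness scores stay in their declared ranges", {
  mols <- c("CC(=O)Oc1ccccc1C(=O)O", unname(REF_MOLS)[1:6])
  dl <- drug_likeness(mols)
  expect_equal(nrow(dl$table), length(mols))
  expect_true(all(dl$table$SA >= 1 & dl$table$SA <= 10))
  expect_true(all(dl$table$QED >= 0 & dl$table$QED <= 1))
  expect_true(all(is.finite(dl$table$SA)))
  # identical molecules give identical scores
  twice <- drug_likeness(c("CCO", "CCO"))
  expect_equal(twice$table$SA[1], twice$table$SA[2])
  expect_equal(twice$table$QED[1], twice$table$QED[2])
  # invalid molecules are skipped with a count
  skip <- drug_likeness(c("CCO", "C("))
  expect_equal(skip$n_skipped, 1L)
})

test_that("evaluation reports aggregate the metrics on the percentage scale", {
  objs <- toy_objectives()
  smiles <- c(fixture_corpus(20, seed = 8), "C(")
  rep_ <- eval_report(smiles, objs)
  expect_s3_class(rep_, "eval_report")
  expect_true(rep_$validity >= 0 && rep_$validity <= 100)
  expect_lte(rep_$desirability, rep_$validity)
  expect_true(rep_$diversity > 0 && rep_$diversity <= 1)
  expect_equal(rep_$theta, 1)
  out <- capture.output(print(rep_))
  expect_true(any(grepl("validity", out)))
})
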