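test_that("dataset preparation collapses duplicates and imputes unlabeled rows", {
  raw <- data.frame(
    smiles = c("CCO", "OCC", "c1ccccc1", "c1ccccc1", "CCN", "CCC"),
    target_id = c("T1", "T1", "T1", "T2", "T1", "T1"),
    pX = c(6.0, 7.0, 5.5, NA, NA, NA),
    label = c("", "", "", "Active", "Not Active", ""),
    stringsAsFactors = FALSE
  )
  ds <- prepare_dataset(raw)
  # CCO/OCC same molecule: mean of 6 and 7
  cco <- ds[ds$smiles == canonical_smiles("CCO") & ds$target_id == "T1", ]
  expect_equal(cco$pX, 6.5)
  expect_equal(cco$weight, 1.0)
  expect_equal(cco$quality, "measured")
  # "Not Active" row: imputed
  ccn <- ds[ds$smiles == canonical_smiles("CCN"), ]
  expect_equal(ccn$pX, 3.99)
  expect_equal(ccn$weight, 0.1)
  expect_equal(ccn$quality, "low_quality")
  # row with neither pX nor label rejected
  expect_equal(attr(ds, "n_rejected"), 1L)
  expect_false(canonical_smiles("CCC") %in% ds$smiles)
  # one record per (molecule, target)
  expect_equal(anyDuplicated(paste(ds$smiles, ds$target_id)), 0L)
})

test_that("activity classification threshold sits at pX 6.5", {
  expect_true(6.4 < molrl:::PX_ACTIVE_THRESHOLD)
  expect_equal(normalize_px(molrl:::PX_ACTIVE_THRESHOLD, "high_affinity"), 0.5)
})

test_that("toy oracles are deterministic affine property maps", {
  orc <- toy_oracle("aromatic_rings", scale = 1, offset = 3)
  expect_equal(predict(orc, "c1ccccc1"), 4.0)   # one aromatic ring
  expect_equal(predict(orc, "CCO"), 3.0)        # clipped at the floor
  expect_equal(predict(orc, "CCO"), predict(orc, "CCO"))
  big <- toy_oracle("heavy_atoms", scale = 1, offset = 3)
  expect_equal(predict(big, "CCCCCCCCCC"), 10)  # clipped at the ceiling
})

test_that("random forest recovers a planted property signal", {
  mols <- fixture_corpus(120, seed = 3)
  pc <- physchem_descriptors(mols)
  set.seed(4)
  px <- pmin(pmax(3 + 0.8 * pc[, "n_aromatic_rings"] +
                    0.3 * pc[, "n_hetero"] + rnorm(120, 0, 0.2), 3), 10)
  ds <- data.frame(smiles = mols, target_id = "T", pX = px, weight = 1)
  train <- ds[1:90, ]
  test <- ds[91:120, ]
  m <- train_predictor(train, "RF", hyperparams = list(num.trees = 300),
                       seed = 5)
  pred <- predict(m, test$smiles)
  rmse <- sqrt(mean((pred - test$pX)^2))
  rmse_const <- sqrt(mean((mean(train$pX) - test$pX)^2))
  expect_lt(rmse, rmse_const)
  expect_true(all(pred >= 3 & pred <= 10))
})

test_that("degenerate datasets are rejected or warned about", {
  one <- data.frame(smiles = "CCO", target_id = "T", pX = 5)
  expect_error(train_predictor(one, "RF"), "at least 2 distinct")
  const <- data.frame(smiles = c("CCO", "CCC", "CCN"), target_id = "T",
                      pX = c(5, 5, 5))
  expect_warning(m <- train_predictor(const, "RF",
                                      hyperparams = list(num.trees = 50)),
                 "constant pX")
  expect_s3_class(m, "qsar_model")
})

test_that("SVM, PLS and the multi-task net train and predict in range", {
  mols <- fixture_corpus(60, seed = 6)
  pc <- physchem_descriptors(mols)
  set.seed(7)
  mk <- function(tid, coef_col, sc) data.frame(
    smiles = mols, target_id = tid,
    pX = pmin(pmax(3.5 + sc * pc[, coef_col] + rnorm(60, 0, 0.2), 3), 10))
  ds1 <- mk("A", "n_aromatic_rings", 1.5)
  for (algo in c("SVM", "PLS")) {
    m <- train_predictor(ds1, algo, hyperparams = list(ncomp = 3), seed = 8)
    p <- predict(m, mols[1:10])
    expect_length(p, 10L)
    expect_true(all(p >= 3 & p <= 10))
  }
  ds2 <- rbind(ds1, mk("B", "n_hetero", 0.8))
  m <- train_predictor(ds2, "MTDNN", seed = 8,
                       hyperparams = list(hidden = c(32, 16), epochs = 30,
                                          batch_size = 16))
  p_all <- predict(m, mols[1:5], target = "all")
  expect_equal(dim(p_all), c(5L, 2L))
  expect_equal(colnames(p_all), c("A", "B"))
  pB <- predict(m, mols[1:5], target = "B")
  expect_true(all(pB >= 3 & pB <= 10))
  # sample-weight plumbing warns where the backend cannot honour weights
  ds1$weight <- rep(c(1, 0.1), length.out = nrow(ds1))
  expect_warning(train_predictor(ds1, "SVM", seed = 8), "ignores sample weights")
})

test_that("models persist to a directory with manifest and predict identically", {
  mols <- fixture_corpus(40, seed = 14)
  ds <- data.frame(smiles = mols, target_id = "T",
                   pX = predict(toy_oracle("heteroatoms", 0.9, 3), mols))
  m <- train_predictor(ds, "RF", hyperparams = list(num.trees = 100), seed = 2)
  dir <- withr::local_tempdir()
  save_predictor(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$algorithm, "RF")
  expect_false(is.null(manifest$training_hash))
  back <- load_predictor(dir)
  probe <- mols[1:8]
  expect_equal(predict(back, probe), predict(m, probe))
})

test_that("cross-validation and temporal evaluation behave as defined", {
  mols <- fixture_corpus(80, seed = 9)
  orc <- toy_oracle("heteroatoms", scale = 0.9, offset = 3)
  ds <- data.frame(smiles = mols, target_id = "T",
                   pX = predict(orc, mols),
                   year = rep(c(2010, 2018), each = 40))
  # a perfect oracle evaluated on its own generating function
  ev <- evaluate_predictor(orc, ds)
  expect_equal(ev$RMSE, 0)
  # constant predictions give non-positive R2
  expect_lte(molrl:::.regression_metrics(ds$pX, rep(mean(ds$pX), 80))$R2, 0)
  # cv5 on a refit model recovers most of the signal
  m <- train_predictor(ds, "RF", hyperparams = list(num.trees = 200), seed = 1)
  cv <- evaluate_predictor(m, ds, "cv5", seed = 1)
  expect_gt(cv$R2, 0.5)
  expect_equal(cv$n_test, 80L)
  # fold assignment is seeded but the estimate is stable across seeds
  cv2 <- evaluate_predictor(m, ds, "cv5", seed = 2)
  expect_lt(abs(cv$R2 - cv2$R2), 0.1)
  # temporal split: trains strictly before the cutoff
  tm <- evaluate_predictor(m, ds, "temporal", cutoff_year = 2015, seed = 1)
  expect_equal(tm$n_test, 40L)
  expect_error(evaluate_predictor(m, ds, "temporal", cutoff_year = 1990),
               "one side")
  expect_error(evaluate_predictor(m, ds[, 1:3], "temporal"), "year")
})
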