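test_that("pX normalization hits its endpoints, midpoint, and inversion", {
  expect_equal(normalize_px(6.5, "high_affinity"), 0.5)
  expect_equal(normalize_px(3.0, "high_affinity"), 0.0)
  expect_equal(normalize_px(10.0, "high_affinity"), 1.0)
  expect_equal(normalize_px(3.0, "low_affinity"), 1.0)
  # out-of-range predictions are clipped first
  expect_equal(normalize_px(c(-2, 14), "high_affinity"), c(0, 1))
})

test_that("the two directions are monotone mirrors summing to one", {
  px <- seq(3, 10, by = 0.25)
  hi <- normalize_px(px, "high_affinity")
  lo <- normalize_px(px, "low_affinity")
  expect_true(all(diff(hi) > 0))
  expect_true(all(diff(lo) < 0))
  expect_equal(hi + lo, rep(1, length(px)))
})

test_that("batch scoring zeroes invalid molecules and applies the strict threshold", {
  objs <- toy_objectives()
  sm <- score_batch(c("C(", "Cn1cnc2c1ncnc2", "CCO"), objs)
  expect_equal(unname(sm$scores[1, ]), c(0, 0, 0))
  expect_false(sm$desired[1])
  expect_true(all(sm$scores >= 0 & sm$scores <= 1))
  # strict inequality at the threshold: a score of exactly t is undesired
  sm2 <- structure(list(scores = rbind(c(0.6, 0.7, 0.9), c(0.6, 0.5, 0.9)),
                        valid = c(TRUE, TRUE), thresholds = rep(0.5, 3)),
                   class = "score_matrix")
  desired <- sm2$valid & apply(sweep(sm2$scores, 2, sm2$thresholds, ">"), 1, all)
  expect_identical(desired, c(TRUE, FALSE))
})

test_that("dynamic weights reproduce the worked ratio example and sum to one", {
  s <- cbind(c(rep(0.4, 8), rep(0.6, 2)),   # 8 below / 2 above: r = 4
             c(rep(0.4, 2), rep(0.6, 8)))   # 2 below / 8 above: r = 0.25
  w <- ws_weights(s, c(0.5, 0.5))
  expect_equal(w, c(0.9412, 0.0588), tolerance = 1e-4)
  expect_equal(sum(w), 1)
  # identical distributions: uniform weights
  expect_equal(ws_weights(cbind(c(.3, .7), c(.3, .7)), c(.5, .5)), c(.5, .5))
  # all above threshold on every objective still sums to 1
  expect_equal(sum(ws_weights(cbind(c(.8, .9), c(.7, .9)), c(.5, .5))), 1)
})

test_that("harder objectives always get larger weight", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    s <- cbind(runif(n), runif(n), runif(n))
    w <- ws_weights(s, rep(0.5, 3))
    above <- colSums(s > 0.5)
    # strictly fewer above-threshold molecules => weight at least as large
    ord <- order(above)
    expect_true(all(diff(w[ord]) <= 1e-12))
  }
})

test_that("weighted-sum reward is the dot product", {
  expect_equal(ws_reward(rbind(c(1, 1, 1)), c(0.2, 0.3, 0.5)), 1)
  expect_equal(ws_reward(rbind(c(0, 0, 0)), c(0.2, 0.3, 0.5)), 0)
  expect_equal(ws_reward(rbind(c(0.5, 1.0)), c(0.5, 0.5)), 0.75)
})

test_that("desirability transform caps above threshold and is continuous at it", {
  expect_equal(desirability(0.8, 0.5), 1.0)
  expect_equal(desirability(0.25, 0.5), 0.5)
  expect_equal(desirability(0.5, 0.5), 1.0)   # boundary: 0.5 / 0.5
  m <- desirability(rbind(c(0.2, 0.9), c(0.5, 0.1)), c(0.5, 0.5))
  expect_equal(m, rbind(c(0.4, 1), c(1, 0.2)))
})

test_that("Pareto dominance is strict and irreflexive", {
  expect_true(dominates(c(0.9, 0.9), c(0.5, 0.5)))
  expect_false(dominates(c(0.8, 0.2), c(0.2, 0.8)))
  expect_false(dominates(c(0.2, 0.8), c(0.8, 0.2)))
  expect_false(dominates(c(0.5, 0.5), c(0.5, 0.5)))
  expect_true(dominates(c(0.5, 0.6), c(0.5, 0.5)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length mismatch")
})

test_that("non-dominated sorting matches the worked example and handles ties", {
  x <- rbind(a = c(0.9, 0.9), b = c(0.6, 0.6), c = c(0.8, 0.2), d = c(0.2, 0.8))
  fronts <- non_dominated_sort(x)
  expect_same_partition(fronts, list(c(2L, 3L, 4L), 1L))
  same <- matrix(0.5, nrow = 5, ncol = 3)
  expect_length(non_dominated_sort(same), 1L)
  expect_equal(non_dominated_sort(matrix(c(1, 2), 1)), list(1L))
})

test_that("non-dominated sorting agrees with the brute-force oracle", {
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    m <- sample(2:4, 1)
    # sprinkle duplicates to exercise tie handling
    x <- matrix(sample(seq(0, 1, 0.1), n * m, replace = TRUE), n, m)
    got <- non_dominated_sort(x)
    want <- brute_force_fronts(x)
    expect_same_partition(got, want)
  }
})

test_that("within-front ranking orders by mean Tanimoto distance, stably", {
  # rows 1 and 2 are similar to each other (distance 1/3) and both
  # maximally distant from row 3, so the outlier ranks first and the
  # tied pair keeps input order
  fp <- rbind(c(1, 1, 1, 0, 0, 0),
              c(1, 1, 0, 0, 0, 0),
              c(0, 0, 0, 1, 1, 1))
  expect_equal(rank_within_front(1:3, fp), c(3L, 1L, 2L))
  expect_equal(rank_within_front(5L, fp), 5L)          # singleton unchanged
  # exact ties keep input order
  tied <- rbind(c(1, 0), c(0, 1), c(1, 1))
  d <- tanimoto_distance_matrix(tied)
  expect_equal(rank_within_front(1:2, rbind(c(1, 0, 0), c(1, 0, 0))), 1:2)
})

test_that("Pareto rewards reproduce the worked interval examples", {
  mk_sm <- function(scores, valid, desired) {
    structure(list(smiles = paste0("m", seq_len(nrow(scores))),
                   canonical = paste0("m", seq_len(nrow(scores))),
                   valid = valid, scores = scores,
                   thresholds = rep(0.5, ncol(scores)), desired = desired),
              class = "score_matrix")
  }
  fp4 <- diag(4)[, rep(1:4, length.out = 8)]  # 4 distinct fingerprints
  # 2 undesired + 2 desired -> rewards (0.25, 0.50, 0.75, 1.00)
  sm <- mk_sm(rbind(c(.2, .2), c(.4, .4), c(.6, .7), c(.9, .9)),
              valid = rep(TRUE, 4), desired = c(FALSE, FALSE, TRUE, TRUE))
  pr <- pareto_reward(sm, fingerprints = fp4)
  expect_setequal(pr$reward[1:2], c(0.25, 0.50))
  expect_setequal(pr$reward[3:4], c(0.75, 1.00))
  expect_equal(sort(pr$reward), c(0.25, 0.5, 0.75, 1.0))
  # the more dominated undesired molecule gets the lower reward
  expect_lt(pr$reward[1], pr$reward[2])
  # all desired (N_undesired = 0) -> (0.625, 0.75, 0.875, 1.0)
  sm2 <- mk_sm(rbind(c(.6, .6), c(.7, .7), c(.8, .8), c(.9, .9)),
               valid = rep(TRUE, 4), desired = rep(TRUE, 4))
  pr2 <- pareto_reward(sm2, fingerprints = fp4)
  expect_equal(sort(pr2$reward), c(0.625, 0.75, 0.875, 1.0))
  # single undesired molecule -> 0.5
  sm3 <- mk_sm(rbind(c(.2, .2)), valid = TRUE, desired = FALSE)
  expect_equal(pareto_reward(sm3, fingerprints = rbind(c(1, 0)))$reward, 0.5)
})

test_that("Pareto rewards fill their intervals and grow with rank", {
  objs <- toy_objectives()
  set.seed(44)
  pool <- fixture_corpus(120, seed = 5)
  for (rep in 1:5) {
    smiles <- c(sample(pool, 25), "C(", "C)")   # include invalid strings
    sm <- score_batch(smiles, objs)
    pr <- pareto_reward(sm)
    und <- !sm$desired
    expect_true(all(pr$reward[und] > 0 & pr$reward[und] <= 0.5))
    if (any(sm$desired)) {
      expect_true(all(pr$reward[sm$desired] > 0.5 & pr$reward[sm$desired] <= 1))
      expect_equal(max(pr$reward[sm$desired]), 1.0)
    }
    # strictly monotone in the global rank k
    ord <- order(pr$rank)
    expect_true(all(diff(pr$reward[ord]) > 0))
    # invalid molecules sit at the bottom of the ranking
    expect_true(all(pr$rank[!sm$valid] <= sum(!sm$valid)))
  }
})

test_that("scheme dispatch produces rewards in [0,1] with invalid at zero or bottom", {
  objs <- toy_objectives()
  smiles <- c(fixture_corpus(15, seed = 6), "C(")
  sm <- score_batch(smiles, objs)
  for (scheme in c("PF", "WS")) {
    r <- scheme_reward(sm, scheme)
    expect_length(r, length(smiles))
    expect_true(all(r >= 0 & r <= 1))
  }
  expect_equal(scheme_reward(sm, "WS")[length(smiles)], 0)
})

test_that("the score dump table is written with audit columns", {
  objs <- toy_objectives()
  sm <- score_batch(c("CCO", "c1ccccc1"), objs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_dump(sm, path, scheme = "PF")
  tab <- read.delim(path)
  expect_true(all(c("smiles", "desired", "front", "k", "R_star") %in% names(tab)))
  expect_equal(nrow(tab), 2L)
})
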