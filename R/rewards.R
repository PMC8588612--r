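# Reward shaping: per-objective normalized scores and their aggregation
# into one scalar reward per molecule, by either the dynamic weighted-sum
# (WS) scheme or the Pareto-front (PF) scheme.
#
# Each objective couples a predictor (QSAR model or toy oracle) with a
# desired direction: high affinity (reward grows with predicted pX) or low
# affinity (reward is the inverted score, used for off-targets). Predicted
# pX is min-max normalized from [3, 10] onto [0, 1]; invalid SMILES score
# 0 on every objective. A molecule is "desired" when every objective's
# score strictly exceeds its threshold (0.5 by default, i.e. pX 6.5 for a
# high-affinity objective).

#' Define a scoring objective
#'
#' @param predictor a `qsar_model` (trained regressor or [toy_oracle()]).
#' @param direction `"high_affinity"` (maximize predicted pX) or
#'   `"low_affinity"` (minimize it; the normalized score is inverted).
#' @param threshold desirability threshold on the normalized score, in
#'   (0, 1); default 0.5 (equivalent to pX 6.5 under high affinity).
#' @param name optional objective label.
#' @param target passed to `predict()` for multi-task models.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(predictor, direction = c("high_affinity",
                                                    "low_affinity"),
                           threshold = 0.5, name = NULL, target = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(predictor, "qsar_model") || is.function(predictor),
            threshold > 0, threshold < 1)
  structure(
    list(predictor = predictor, direction = direction, threshold = threshold,
         name = name %||% direction, target = target),
    class = "objective_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Min-max normalization of predicted pX
#'
#' Maps pX, clipped to \[3, 10\], onto \[0, 1\]: `(pX - 3) / 7` for a
#' high-affinity objective, `1 - (pX - 3) / 7` for a low-affinity
#' (off-target) objective. pX 6.5 maps to 0.5 under high affinity — the
#' default desirability threshold.
#'
#' @param pX numeric vector of predicted pX values.
#' @param direction `"high_affinity"` or `"low_affinity"`.
#' @return numeric vector in \[0, 1\].
#' @examples
#' normalize_px(6.5, "high_affinity")  # 0.5
#' normalize_px(3.0, "low_affinity")   # 1.0
#' @export
normalize_px <- function(pX, direction = c("high_affinity", "low_affinity")) {
  direction <- match.arg(direction)
  px <- pmin(pmax(pX, PX_MIN), PX_MAX)
  r <- (px - PX_MIN) / (PX_MAX - PX_MIN)
  if (direction == "low_affinity") 1 - r else r
}

#' Score a batch of molecules against the objectives
#'
#' Valid molecules are scored by every objective's predictor and the
#' predictions min-max normalized ([normalize_px()]); invalid SMILES score
#' 0 on all objectives. The `desired` flag marks valid molecules whose
#' scores strictly exceed every objective's threshold.
#'
#' @param smiles character vector of SMILES (may contain invalid strings).
#' @param objectives list of [objective_spec()] objects.
#' @return object of class `score_matrix`: list with `smiles`, `canonical`,
#'   `valid`, `scores` (n x m matrix in \[0,1\]), `thresholds`, `desired`.
#' @export
score_batch <- function(smiles, objectives) {
  stopifnot(length(objectives) >= 1L)
  if (inherits(objectives, "objective_spec")) objectives <- list(objectives)
  stopifnot(all(vapply(objectives, inherits, logical(1), "objective_spec")))
  v <- is_valid_smiles(smiles)
  m <- length(objectives)
  scores <- matrix(0, nrow = length(smiles), ncol = m,
                   dimnames = list(NULL, vapply(objectives, `[[`, "", "name")))
  if (any(v$valid)) {
    vs <- smiles[v$valid]
    for (j in seq_len(m)) {
      obj <- objectives[[j]]
      px <- tryCatch(
        predict(obj$predictor, vs, target = obj$target),
        error = function(e) {
          stop(sprintf("predictor failed for objective '%s': %s",
                       obj$name, conditionMessage(e)))
        })
      scores[v$valid, j] <- normalize_px(px, obj$direction)
    }
  }
  thresholds <- vapply(objectives, `[[`, numeric(1), "threshold")
  desired <- v$valid &
    apply(sweep(scores, 2, thresholds, ">"), 1, all)
  structure(
    list(smiles = smiles, canonical = v$canonical, valid = v$valid,
         scores = scores, thresholds = thresholds, desired = desired),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d molecules x %d objectives; %.1f%% valid, %.1f%% desired\n",
              length(x$smiles), ncol(x$scores), 100 * mean(x$valid),
              100 * mean(x$desired)))
  invisible(x)
}

#' Dynamic weighted-sum weights
#'
#' For each objective the desired ratio `r_i = N_smaller / N_larger`
#' counts generated molecules scoring below vs above the threshold;
#' weights are the normalized ratios `w_i = r_i / sum(r)`. Harder
#' objectives (few molecules above threshold) thus receive larger weight.
#' When no molecule exceeds a threshold the denominator is replaced by 1,
#' preserving the monotone harder-objective-larger-weight behaviour
#' without infinities.
#'
#' @param score_matrix a `score_matrix` (or plain numeric matrix of
#'   scores).
#' @param thresholds per-objective thresholds (taken from the
#'   `score_matrix` when omitted).
#' @return numeric weight vector summing to 1.
#' @export
ws_weights <- function(score_matrix, thresholds = NULL) {
  s <- if (inherits(score_matrix, "score_matrix")) score_matrix$scores else score_matrix
  stopifnot(is.matrix(s), nrow(s) >= 1L)
  thresholds <- thresholds %||%
    (if (inherits(score_matrix, "score_matrix")) score_matrix$thresholds
     else rep(0.5, ncol(s)))
  r <- vapply(seq_len(ncol(s)), function(j) {
    n_small <- sum(s[, j] <= thresholds[j])
    n_large <- sum(s[, j] > thresholds[j])
    n_small / max(n_large, 1)
  }, numeric(1))
  if (sum(r) == 0) return(rep(1 / ncol(s), ncol(s)))
  r / sum(r)
}

#' Weighted-sum reward
#'
#' Scalar reward `R* = sum_i w_i R_i` for each molecule.
#'
#' @param score_matrix a `score_matrix` or numeric score matrix (rows =
#'   molecules).
#' @param w weight vector (length = number of objectives).
#' @return numeric vector of rewards in \[0, 1\].
#' @export
ws_reward <- function(score_matrix, w) {
  s <- if (inherits(score_matrix, "score_matrix")) score_matrix$scores else score_matrix
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  stopifnot(ncol(s) == length(w))
  as.numeric(s %*% w)
}

#' Desirability transform
#'
#' `D_i = 1` when the score strictly exceeds its threshold, `R_i / t_i`
#' otherwise (so the boundary value `R_i = t_i` maps to 1 by continuity).
#' The Pareto-front scheme ranks molecules on these transformed scores,
#' which caps credit for exceeding a threshold.
#'
#' @param R numeric scores in \[0, 1\] (vector or matrix).
#' @param t threshold(s) in (0, 1\]; recycled across columns for a matrix.
#' @return desirabilities, same shape as `R`.
#' @export
desirability <- function(R, t = 0.5) {
  stopifnot(all(t > 0))
  if (is.matrix(R)) {
    tt <- matrix(rep(t, each = nrow(R)), nrow = nrow(R))
    ifelse(R > tt, 1, R / tt)
  } else {
    ifelse(R > t, 1, R / t)
  }
}

#' Pareto dominance
#'
#' `x` dominates `y` when `x_j >= y_j` for every objective and `x_j > y_j`
#' for at least one.
#'
#' @param x,y numeric vectors of equal length.
#' @return logical scalar.
#' @export
dominates <- function(x, y) {
  if (length(x) != length(y)) stop("dominates: length mismatch")
  all(x >= y) && any(x > y)
}

#' Non-dominated sorting
#'
#' Partitions score vectors into successive Pareto fronts using the fast
#' non-dominated sorting algorithm, and returns them ordered from the most
#' dominated layer first to the non-dominated (best) layer last — the
#' ordering under which the global rank index k increases with quality.
#'
#' @param vectors numeric matrix (rows = solutions) or list of equal-length
#'   numeric vectors.
#' @return list of integer index vectors, one per front, worst front
#'   first.
#' @export
non_dominated_sort <- function(vectors) {
  x <- if (is.list(vectors)) do.call(rbind, vectors) else vectors
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  stopifnot(n >= 1L)
  # dominance matrix, vectorized per objective: dom[i, j] <=> i dominates j
  ge_all <- matrix(TRUE, n, n)
  gt_any <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(x))) {
    cmp <- outer(x[, j], x[, j], ">=")
    ge_all <- ge_all & cmp
    gt_any <- gt_any | outer(x[, j], x[, j], ">")
  }
  dom <- ge_all & gt_any
  diag(dom) <- FALSE
  dominated_by_count <- colSums(dom)
  dominates_list <- apply(dom, 1, which, simplify = FALSE)
  fronts <- list()
  current <- which(dominated_by_count == 0L)
  remaining <- dominated_by_count
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominates_list[[i]]) {
        remaining[j] <- remaining[j] - 1L
        if (remaining[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  rev(fronts)   # most dominated layer first
}

#' Rank molecules within a Pareto front by Tanimoto distance
#'
#' Members of one front are ordered by their mean Tanimoto distance to the
#' other members (ECFP6 fingerprints), descending: the most dissimilar
#' molecule comes first, i.e. highest within the front. This replaces the
#' crowding distance of classical non-dominated sorting and favours
#' chemical diversity. Ties keep input order (stable sort).
#'
#' @param members integer indices of the front's molecules.
#' @param fingerprints 0/1 matrix of fingerprints for the whole batch
#'   (rows indexed by `members`).
#' @return `members` reordered, best (most distant) first.
#' @export
rank_within_front <- function(members, fingerprints) {
  if (length(members) <= 1L) return(members)
  fp <- fingerprints[members, , drop = FALSE]
  d <- tanimoto_distance_matrix(fp)
  mean_d <- rowSums(d) / (length(members) - 1L)
  members[order(-mean_d)]
}

#' Pareto-front scheme rewards
#'
#' Molecules are ranked globally: all undesired molecules precede all
#' desired ones; within each group, fronts are traversed from most
#' dominated to non-dominated, each front internally ordered by mean
#' Tanimoto distance ([rank_within_front()], most distant ranked highest).
#' Invalid molecules sit at the very bottom. With 1-based global rank k,
#' rewards are `k / (2 N_undesired)` for undesired molecules — evenly
#' filling (0, 0.5] — and `0.5 + (k - N_undesired) / (2 N_desired)` for
#' desired molecules — evenly filling (0.5, 1], the best molecule scoring
#' exactly 1.
#'
#' Dominance is computed on desirability-transformed scores
#' ([desirability()]), capping credit above each objective's threshold.
#'
#' @param score_matrix a `score_matrix` from [score_batch()].
#' @param fingerprints optional fingerprint matrix for the batch (computed
#'   from the valid molecules when omitted; invalid rows may be zero).
#' @return list with `reward` (numeric vector in (0, 1]), `rank` (global
#'   1-based k), `front` (front index per molecule, 1 = most dominated,
#'   NA for invalid).
#' @export
pareto_reward <- function(score_matrix, fingerprints = NULL) {
  stopifnot(inherits(score_matrix, "score_matrix"))
  n <- length(score_matrix$smiles)
  desired <- score_matrix$desired
  valid <- score_matrix$valid
  if (is.null(fingerprints)) {
    fingerprints <- matrix(0L, n, 2048L)
    if (any(valid)) {
      fingerprints[valid, ] <- morgan_fp(score_matrix$smiles[valid])
    }
  }
  D <- desirability(score_matrix$scores, score_matrix$thresholds)

  order_group <- function(idx) {
    # global ordering within a desired/undesired group: dominated fronts
    # first, each front ordered most-Tanimoto-distant first; reversed so
    # that position increases with quality (front-best last)
    if (length(idx) <= 1L) return(idx)
    fronts <- non_dominated_sort(D[idx, , drop = FALSE])
    unlist(lapply(fronts, function(f) {
      rev(rank_within_front(idx[f], fingerprints))
    }))
  }
  und_valid <- which(valid & !desired)
  des <- which(desired)
  invalid <- which(!valid)
  ordering <- c(invalid, order_group(und_valid), order_group(des))

  k <- integer(n)
  k[ordering] <- seq_len(n)
  n_und <- sum(!desired)
  n_des <- sum(desired)
  reward <- numeric(n)
  if (n_und > 0) {
    und <- !desired
    reward[und] <- k[und] / (2 * n_und)
  }
  if (n_des > 0) {
    reward[desired] <- 0.5 + (k[desired] - n_und) / (2 * n_des)
  }
  front <- rep(NA_integer_, n)
  valid_idx <- c(und_valid, des)
  if (length(valid_idx)) {
    fr <- non_dominated_sort(D[valid_idx, , drop = FALSE])
    for (fi in seq_along(fr)) front[valid_idx[fr[[fi]]]] <- fi
  }
  list(reward = reward, rank = k, front = front)
}

#' Scalar rewards under a named scheme
#'
#' Dispatch helper used by the RL loop: `"PF"` calls [pareto_reward()],
#' `"WS"` computes dynamic weights on the batch then [ws_reward()].
#'
#' @param score_matrix a `score_matrix`.
#' @param scheme `"PF"` or `"WS"`.
#' @return numeric reward vector (one scalar per molecule).
#' @export
scheme_reward <- function(score_matrix, scheme = c("PF", "WS")) {
  scheme <- match.arg(toupper(scheme), c("PF", "WS"))
  if (scheme == "PF") {
    pareto_reward(score_matrix)$reward
  } else {
    w <- ws_weights(score_matrix)
    r <- ws_reward(score_matrix, w)
    r[!score_matrix$valid] <- 0
    r
  }
}

#' Write a per-molecule score audit table
#'
#' TSV dump of the batch: SMILES, per-objective scores, desired flag, and
#' under the PF scheme the front index, global rank and final reward.
#'
#' @param score_matrix a `score_matrix`.
#' @param path output TSV path.
#' @param scheme reward scheme used for the `R_star` column.
#' @export
write_score_dump <- function(score_matrix, path, scheme = "PF") {
  df <- data.frame(smiles = score_matrix$smiles,
                   score_matrix$scores, check.names = FALSE)
  df$valid <- score_matrix$valid
  df$desired <- score_matrix$desired
  if (toupper(scheme) == "PF") {
    pr <- pareto_reward(score_matrix)
    df$front <- pr$front
    df$k <- pr$rank
    df$R_star <- pr$reward
  } else {
    df$R_star <- scheme_reward(score_matrix, "WS")
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
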