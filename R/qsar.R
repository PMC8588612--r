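# QSAR environment: bioactivity dataset preparation, regressor training
# (RF / SVM / PLS / multi-task neural net), evaluation, and deterministic
# toy oracles used as desk-scale stand-ins for trained models.
#
# pX is the negative log10 of a measured potency (pKi, pKd, pIC50, pEC50);
# the working range is [3, 10] and the activity threshold is pX = 6.5.

PX_MIN <- 3.0
PX_MAX <- 10.0
PX_INACTIVE <- 3.99       # imputed value for "Not Active" / unlabeled rows
W_LOW_QUALITY <- 0.1
W_MEASURED <- 1.0
PX_ACTIVE_THRESHOLD <- 6.5

#' Prepare a bioactivity dataset
#'
#' Cleans a raw activity table into one record per (molecule, target):
#' SMILES are canonicalized, duplicate measurements of the same molecule
#' against the same target are collapsed to their mean pX, and rows without
#' a measured pX but labeled (e.g. "Not Active") are imputed at pX 3.99
#' with sample weight 0.1. Measured rows carry weight 1.0. Rows with
#' neither a pX nor a label, and rows with unparseable SMILES, are dropped;
#' the counts are attached as attributes.
#'
#' @param records data.frame with columns `smiles`, `target_id`, and at
#'   least one of `pX` (numeric, may be NA) and `label` (character);
#'   optional `year` column for temporal splits (earliest year kept on
#'   collapse).
#' @return data.frame of class `bioactivity_data` with columns `smiles`
#'   (canonical), `target_id`, `pX`, `quality` ("measured"/"low_quality"),
#'   `weight`, and `year` if supplied. Attributes `n_rejected` and
#'   `n_invalid_smiles` report dropped rows.
#' @export
prepare_dataset <- function(records) {
  stopifnot(is.data.frame(records))
  names(records) <- tolower(names(records))
  names(records)[names(records) == "px"] <- "pX"
  if (!all(c("smiles", "target_id") %in% names(records))) {
    stop("records must have 'smiles' and 'target_id' columns")
  }
  if (!"pX" %in% names(records)) records$pX <- NA_real_
  records$pX <- suppressWarnings(as.numeric(records$pX))
  has_label <- if ("label" %in% names(records)) {
    !is.na(records$label) & nzchar(trimws(records$label))
  } else rep(FALSE, nrow(records))

  usable <- is.finite(records$pX) | has_label
  n_rejected <- sum(!usable)
  records <- records[usable, , drop = FALSE]
  has_label <- has_label[usable]

  v <- is_valid_smiles(records$smiles)
  n_invalid <- sum(!v$valid)
  keep <- v$valid
  records <- records[keep, , drop = FALSE]
  records$smiles <- v$canonical[keep]
  has_label <- has_label[keep]
  if (nrow(records) == 0L) stop("no usable records after filtering")

  measured <- is.finite(records$pX)
  records$pX[!measured] <- PX_INACTIVE
  records$quality <- ifelse(measured, "measured", "low_quality")
  has_year <- "year" %in% names(records)

  key <- paste(records$smiles, records$target_id, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), key), function(idx) {
    r <- records[idx, , drop = FALSE]
    m <- r$quality == "measured"
    if (any(m)) {
      px <- mean(r$pX[m])           # measured values dominate mixed groups
      quality <- "measured"
    } else {
      px <- PX_INACTIVE
      quality <- "low_quality"
    }
    data.frame(
      smiles = r$smiles[1], target_id = r$target_id[1], pX = px,
      quality = quality,
      weight = if (quality == "measured") W_MEASURED else W_LOW_QUALITY,
      year = if (has_year) suppressWarnings(min(r$year, na.rm = TRUE)) else NA,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  if (!has_year) out$year <- NULL
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_invalid_smiles") <- n_invalid
  class(out) <- c("bioactivity_data", "data.frame")
  out
}

#' Deterministic toy scoring oracle
#'
#' A stand-in predictor mapping a computable molecular property through an
#' affine function into the pX range \[3, 10\]. Used to exercise the RL
#' loop without any trained model: scoring is deterministic and fast.
#'
#' @param property one of `"aromatic_rings"`, `"rings"`, `"heteroatoms"`,
#'   `"hetero_fraction"`, `"logP"`, `"TPSA"`, `"MW"`, `"heavy_atoms"`,
#'   `"rotatable_bonds"`.
#' @param scale,offset the oracle predicts `offset + scale * property`,
#'   clipped to \[3, 10\].
#' @return object of classes `toy_oracle` and `qsar_model`; score molecules
#'   with [predict()].
#' @examples
#' orc <- toy_oracle("aromatic_rings", scale = 1, offset = 3)
#' predict(orc, "c1ccccc1")  # 4: one aromatic ring
#' @export
toy_oracle <- function(property = "aromatic_rings", scale = 1, offset = 3) {
  properties <- c("aromatic_rings", "rings", "heteroatoms", "hetero_fraction",
                  "logP", "TPSA", "MW", "heavy_atoms", "rotatable_bonds")
  property <- match.arg(property, properties)
  structure(
    list(algorithm = "toy_oracle", property = property,
         scale = scale, offset = offset),
    class = c("toy_oracle", "qsar_model")
  )
}

.oracle_property <- function(property, smiles) {
  pc <- physchem_descriptors(smiles)
  switch(property,
    aromatic_rings = pc[, "n_aromatic_rings"],
    rings = pc[, "n_rings"],
    heteroatoms = pc[, "n_hetero"],
    hetero_fraction = pc[, "n_hetero"] / pmax(pc[, "n_heavy"], 1),
    logP = pc[, "logP"],
    TPSA = pc[, "TPSA"],
    MW = pc[, "MW"],
    heavy_atoms = pc[, "n_heavy"],
    rotatable_bonds = pc[, "n_rotatable"]
  )
}

#' @export
predict.toy_oracle <- function(object, newdata, ...) {
  vals <- object$offset + object$scale * .oracle_property(object$property, newdata)
  unname(pmin(pmax(vals, PX_MIN), PX_MAX))
}

#' @export
print.toy_oracle <- function(x, ...) {
  cat(sprintf("toy oracle: pX = %.3g + %.3g * %s, clipped to [%.1f, %.1f]\n",
              x$offset, x$scale, x$property, PX_MIN, PX_MAX))
  invisible(x)
}

#' Train a QSAR regressor
#'
#' Fits a regression model predicting pX from the 2067-dimensional
#' featurization ([featurize()]), min-max scaled with statistics from the
#' training data. Sample weights (1.0 measured / 0.1 imputed) are honoured
#' by the random forest (`ranger` case weights) and the multi-task neural
#' net (weighted loss); `e1071`'s SVM and `mixOmics`' PLS have no per-case
#' regression weights, so those fits are unweighted (a warning is issued
#' when weights differ).
#'
#' @param dataset a `bioactivity_data` data.frame (see [prepare_dataset()]),
#'   or any data.frame with `smiles`, `pX` and optionally `weight`,
#'   `target_id` columns.
#' @param algorithm `"RF"` (default; 1000 trees, mtry p/3), `"SVM"` (RBF
#'   kernel; set `hyperparams$tune = TRUE` for an inner-CV grid over
#'   C in 2^\[-5, 5\] and gamma in 2^\[-15, 5\]), `"PLS"`, `"MTDNN"`
#'   (multi-task feedforward net, hidden layers 4000/2000/1000, ReLU,
#'   dropout 0.2, Adam lr 1e-3, 100 epochs, masked per-target loss), or
#'   `"toy_oracle"` (returns `hyperparams$oracle` unchanged).
#' @param target which `target_id` to train on (single-task algorithms);
#'   default: all rows. MTDNN always trains on all targets jointly.
#' @param hyperparams named list overriding algorithm defaults
#'   (`num.trees`, `cost`, `gamma`, `ncomp`, `hidden`, `epochs`, `lr`,
#'   `dropout`, `batch_size`).
#' @param seed integer seed for stochastic fits.
#' @return object of class `qsar_model` with elements `algorithm`, `fit`,
#'   `scaler`, `targets`, `config`.
#' @export
train_predictor <- function(dataset, algorithm = c("RF", "SVM", "PLS", "MTDNN",
                                                   "toy_oracle"),
                            target = NULL, hyperparams = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "toy_oracle") {
    if (is.null(hyperparams$oracle)) stop("toy_oracle requires hyperparams$oracle")
    return(hyperparams$oracle)
  }
  stopifnot(is.data.frame(dataset), all(c("smiles", "pX") %in% names(dataset)))
  if (!is.null(target) && "target_id" %in% names(dataset) && algorithm != "MTDNN") {
    dataset <- dataset[dataset$target_id %in% target, , drop = FALSE]
  }
  if (length(unique(dataset$smiles)) < 2L) {
    stop("need at least 2 distinct molecules to train")
  }
  w <- if ("weight" %in% names(dataset)) dataset$weight else rep(1, nrow(dataset))
  if (stats::var(dataset$pX) == 0) {
    warning("constant pX in training data; model will predict a constant")
  }

  x_raw <- featurize(dataset$smiles)
  scaler <- fit_scaler(x_raw)
  x <- apply_scaler(scaler, x_raw)
  y <- dataset$pX
  set.seed(seed)

  fit <- switch(algorithm,
    RF = {
      # regression-forest default mtry = p/3 (ranger's sqrt(p) default
      # targets classification and under-samples sparse informative bits)
      hp <- utils::modifyList(
        list(num.trees = 1000, mtry = max(floor(ncol(x) / 3), 1)),
        hyperparams)
      ranger::ranger(x = x, y = y, num.trees = hp$num.trees, mtry = hp$mtry,
                     case.weights = w, seed = seed)
    },
    SVM = {
      if (length(unique(w)) > 1L)
        warning("SVM fit ignores sample weights (unsupported by e1071)")
      hp <- utils::modifyList(list(cost = 1, gamma = 1 / ncol(x),
                                   tune = FALSE), hyperparams)
      if (isTRUE(hp$tune)) {
        # inner-CV grid over the standard RBF ranges C in 2^[-5,5],
        # gamma in 2^[-15,5] (coarse steps keep this desk-scale)
        tuned <- e1071::tune.svm(x, y, kernel = "radial", scale = FALSE,
                                 cost = 2^seq(-5, 5, by = 2.5),
                                 gamma = 2^seq(-15, 5, by = 5))
        hp$cost <- tuned$best.parameters$cost
        hp$gamma <- tuned$best.parameters$gamma
      }
      # features are already min-max scaled; e1071's internal scaling
      # would warn on constant fingerprint columns
      e1071::svm(x = x, y = y, kernel = "radial",
                 cost = hp$cost, gamma = hp$gamma, scale = FALSE)
    },
    PLS = {
      if (length(unique(w)) > 1L)
        warning("PLS fit ignores sample weights (unsupported by mixOmics)")
      hp <- utils::modifyList(list(ncomp = 5), hyperparams)
      keep <- which(apply(x, 2, stats::var) > 0)
      list(pls = mixOmics::pls(x[, keep, drop = FALSE], y,
                               ncomp = min(hp$ncomp, length(keep) - 1L)),
           keep = keep)
    },
    MTDNN = {
      hp <- utils::modifyList(
        list(hidden = c(4000, 2000, 1000), epochs = 100, lr = 1e-3,
             dropout = 0.2, batch_size = 128), hyperparams)
      tids <- if ("target_id" %in% names(dataset)) dataset$target_id else "y"
      targets <- sort(unique(tids))
      mols <- unique(dataset$smiles)
      Y <- matrix(NA_real_, length(mols), length(targets),
                  dimnames = list(mols, targets))
      Wm <- matrix(0, length(mols), length(targets))
      for (i in seq_len(nrow(dataset))) {
        Y[dataset$smiles[i], tids[i]] <- y[i]
        Wm[match(dataset$smiles[i], mols), match(tids[i], targets)] <- w[i]
      }
      xm <- x[match(mols, dataset$smiles), , drop = FALSE]
      .mlp_train(xm, Y, Wm, hidden = hp$hidden, epochs = hp$epochs,
                 lr = hp$lr, dropout = hp$dropout,
                 batch_size = hp$batch_size, seed = seed)
    }
  )
  targets <- if ("target_id" %in% names(dataset)) sort(unique(dataset$target_id)) else NULL
  train_hash <- sum(vapply(dataset$smiles, function(s) {
    sum(utf8ToInt(s))
  }, numeric(1)) * seq_len(nrow(dataset))) + sum(y * 1000)
  structure(
    list(algorithm = algorithm, fit = fit, scaler = scaler, targets = targets,
         config = list(hyperparams = hyperparams, seed = seed,
                       n_train = nrow(dataset), train_hash = train_hash)),
    class = "qsar_model"
  )
}

#' Predict pX for molecules
#'
#' Featurizes `newdata` (SMILES), applies the model's stored min-max
#' scaler, and returns predicted pX clipped to \[3, 10\] — regressors can
#' extrapolate beyond the declared range, and downstream reward
#' normalization assumes it.
#'
#' @param object a fitted `qsar_model`.
#' @param newdata character vector of valid SMILES.
#' @param target for multi-task models, which output column to return
#'   (default: first; `"all"` returns the full matrix).
#' @param ... unused.
#' @return numeric vector of predicted pX (or matrix for `target = "all"`).
#' @export
predict.qsar_model <- function(object, newdata, target = NULL, ...) {
  x <- apply_scaler(object$scaler, featurize(newdata))
  out <- switch(object$algorithm,
    RF = stats::predict(object$fit, data = x)$predictions,
    SVM = as.numeric(stats::predict(object$fit, x)),
    PLS = {
      p <- stats::predict(object$fit$pls,
                          x[, object$fit$keep, drop = FALSE])$predict
      as.numeric(p[, 1, dim(p)[3]])
    },
    MTDNN = {
      p <- .mlp_predict(object$fit, x)
      if (identical(target, "all")) {
        pmin(pmax(p, PX_MIN), PX_MAX)
      } else {
        col <- if (is.null(target)) 1L else match(target, colnames(p))
        if (is.na(col)) stop("unknown target: ", target)
        p[, col]
      }
    }
  )
  if (is.matrix(out)) return(out)
  pmin(pmax(as.numeric(out), PX_MIN), PX_MAX)
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("QSAR model [%s], %d training molecules%s\n", x$algorithm,
              x$config$n_train,
              if (!is.null(x$targets))
                paste0(", targets: ", paste(x$targets, collapse = ", "))
              else ""))
  invisible(x)
}

#' Evaluate a QSAR model by cross-validation or temporal split
#'
#' `cv5` refits the model's algorithm on 5 random folds (seeded) and pools
#' out-of-fold predictions; `temporal` trains on records before
#' `cutoff_year` and tests on the rest. Reports R-squared (coefficient of
#' determination about the test-set mean) and RMSE.
#'
#' @param predictor a fitted `qsar_model` (its algorithm/hyperparameters are
#'   reused for refits).
#' @param dataset a `bioactivity_data` data.frame; `temporal` requires a
#'   `year` column.
#' @param scheme `"cv5"` or `"temporal"`.
#' @param cutoff_year split year for the temporal scheme.
#' @param seed fold-assignment seed.
#' @return list with `R2`, `RMSE`, `n_test`.
#' @export
evaluate_predictor <- function(predictor, dataset, scheme = c("cv5", "temporal"),
                               cutoff_year = 2015, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(predictor, "qsar_model"))
  if (predictor$algorithm == "toy_oracle") {
    pred <- predict(predictor, dataset$smiles)
    return(.regression_metrics(dataset$pX, pred))
  }
  refit <- function(d) {
    train_predictor(d, algorithm = predictor$algorithm,
                    hyperparams = predictor$config$hyperparams, seed = seed)
  }
  if (scheme == "cv5") {
    set.seed(seed)
    folds <- sample(rep_len(1:5, nrow(dataset)))
    pred <- numeric(nrow(dataset))
    for (f in 1:5) {
      m <- refit(dataset[folds != f, , drop = FALSE])
      pred[folds == f] <- predict(m, dataset$smiles[folds == f])
    }
    .regression_metrics(dataset$pX, pred)
  } else {
    if (!"year" %in% names(dataset)) stop("temporal split requires a 'year' column")
    train <- dataset$year < cutoff_year
    if (!any(train) || all(train)) {
      stop("temporal split puts all records on one side of the cutoff")
    }
    m <- refit(dataset[train, , drop = FALSE])
    pred <- predict(m, dataset$smiles[!train])
    .regression_metrics(dataset$pX[!train], pred)
  }
}

.regression_metrics <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  list(R2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       RMSE = sqrt(mean((obs - pred)^2)),
       n_test = length(obs))
}

#' Save / load a QSAR model
#'
#' A model directory holds the fitted model object, its feature scaler,
#' and a JSON manifest recording the algorithm, hyperparameters and a
#' hash of the training set, so provenance travels with the model.
#'
#' @param model a fitted `qsar_model`.
#' @param dir directory to create/read.
#' @export
save_predictor <- function(model, dir) {
  stopifnot(inherits(model, "qsar_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$fit, file.path(dir, "model.rds"))
  saveRDS(model$scaler, file.path(dir, "scaler.rds"))
  jsonlite::write_json(
    list(algorithm = model$algorithm,
         hyperparameters = model$config$hyperparams,
         seed = model$config$seed,
         n_train = model$config$n_train,
         training_hash = model$config$train_hash,
         targets = model$targets),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")
  invisible(dir)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(
    list(algorithm = manifest$algorithm,
         fit = readRDS(file.path(dir, "model.rds")),
         scaler = readRDS(file.path(dir, "scaler.rds")),
         targets = manifest$targets,
         config = list(hyperparams = as.list(manifest$hyperparameters),
                       seed = manifest$seed, n_train = manifest$n_train,
                       train_hash = manifest$training_hash)),
    class = "qsar_model"
  )
}

# ---- minimal multi-task MLP (weighted masked MSE, Adam) ----------------
# Used for the MTDNN algorithm; no deep-learning framework is available to
# R in this stack, so the forward/backward pass is written directly.

.mlp_init <- function(d_in, hidden, d_out, seed) {
  set.seed(seed)
  dims <- c(d_in, hidden, d_out)
  lapply(seq_len(length(dims) - 1L), function(i) {
    s <- sqrt(6 / (dims[i] + dims[i + 1]))
    list(W = matrix(stats::runif(dims[i] * dims[i + 1], -s, s),
                    dims[i], dims[i + 1]),
         b = numeric(dims[i + 1]))
  })
}

.mlp_train <- function(x, Y, Wmask, hidden, epochs, lr, dropout, batch_size,
                       seed) {
  layers <- .mlp_init(ncol(x), hidden, ncol(Y), seed)
  ms <- lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  vs <- lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  tstep <- 0L
  n <- nrow(x)
  Yz <- Y
  Yz[is.na(Yz)] <- 0
  Wmask[is.na(Y)] <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      # forward with inverted dropout on hidden activations
      acts <- list(xb)
      masks <- list()
      for (li in seq_along(layers)) {
        z <- sweep(acts[[li]] %*% layers[[li]]$W, 2, layers[[li]]$b, "+")
        if (li < length(layers)) {
          z[z < 0] <- 0
          if (dropout > 0) {
            dm <- matrix(stats::rbinom(length(z), 1, 1 - dropout) / (1 - dropout),
                         nrow(z), ncol(z))
            z <- z * dm
            masks[[li]] <- dm
          }
        }
        acts[[li + 1L]] <- z
      }
      pred <- acts[[length(acts)]]
      wb <- Wmask[idx, , drop = FALSE]
      delta <- 2 * wb * (pred - Yz[idx, , drop = FALSE]) / max(sum(wb), 1)
      grads <- vector("list", length(layers))
      for (li in rev(seq_along(layers))) {
        grads[[li]] <- list(W = crossprod(acts[[li]], delta),
                            b = colSums(delta))
        if (li > 1L) {
          delta <- delta %*% t(layers[[li]]$W)
          if (dropout > 0) delta <- delta * masks[[li - 1L]]
          delta[acts[[li]] <= 0] <- 0
        }
      }
      tstep <- tstep + 1L
      for (li in seq_along(layers)) {
        for (p in c("W", "b")) {
          ms[[li]][[p]] <- 0.9 * ms[[li]][[p]] + 0.1 * grads[[li]][[p]]
          vs[[li]][[p]] <- 0.999 * vs[[li]][[p]] + 0.001 * grads[[li]][[p]]^2
          mhat <- ms[[li]][[p]] / (1 - 0.9^tstep)
          vhat <- vs[[li]][[p]] / (1 - 0.999^tstep)
          layers[[li]][[p]] <- layers[[li]][[p]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
    }
  }
  list(layers = layers, targets = colnames(Y))
}

.mlp_predict <- function(fit, x) {
  a <- x
  for (li in seq_along(fit$layers)) {
    a <- sweep(a %*% fit$layers[[li]]$W, 2, fit$layers[[li]]$b, "+")
    if (li < length(fit$layers)) a[a < 0] <- 0
  }
  colnames(a) <- fit$targets
  a
}
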