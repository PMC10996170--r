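# Supervised four-class protocol: 70/30 split, five-fold cross-validated
# model comparison (gradient boosting, random forest, multinomial
# logistic reference), grid-search tuning, held-out evaluation with the
# one-vs-rest confusion-matrix metric formulas, and split-gain feature
# importance ranking.

.ALGORITHMS <- c("gradient_boosting_ensemble", "random_forest_ensemble",
                 "multinomial_logistic")

#' Train/test split specification
#'
#' @param test_fraction Held-out fraction (default 0.30).
#' @param seed Integer seed for the partition.
#' @param stratified Stratify the split by class (default TRUE).
#' @param group_by_participant Keep all clips of a participant on one
#'   side of the split (default FALSE: clip-level split; the grouped
#'   option avoids leaking participant identity across the split).
#' @return A validated list of class \code{SplitSpec}.
#' @export
splitSpec <- function(test_fraction = 0.30, seed = 1L, stratified = TRUE,
                      group_by_participant = FALSE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified),
                 group_by_participant = isTRUE(group_by_participant)),
            class = "SplitSpec")
}

#' Model specification
#'
#' @param algorithm One of \code{"gradient_boosting_ensemble"} (xgboost),
#'   \code{"random_forest_ensemble"} (ranger) or
#'   \code{"multinomial_logistic"} (nnet reference model).
#' @param grid Named list of candidate hyperparameter values for grid
#'   search; defaults per algorithm are supplied when omitted.
#' @return A list of class \code{ModelSpec}.
#' @export
modelSpec <- function(algorithm, grid = NULL) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  if (is.null(grid)) grid <- .defaultGrid(algorithm)
  structure(list(algorithm = algorithm, grid = grid), class = "ModelSpec")
}

.defaultGrid <- function(algorithm) {
  switch(algorithm,
    gradient_boosting_ensemble =
      list(max_depth = c(3, 6), eta = c(0.1, 0.3), nrounds = 150),
    random_forest_ensemble = list(num.trees = c(200, 400)),
    multinomial_logistic = list(decay = c(1e-4, 1e-2)))
}

.defaultParams <- function(algorithm) {
  lapply(.defaultGrid(algorithm), `[`, 1L)
}

#' Default model roster
#'
#' The three compared algorithms: gradient boosting, random forest and
#' the multinomial logistic reference.
#' @return List of [modelSpec()] objects.
#' @export
defaultModelSpecs <- function() {
  lapply(.ALGORITHMS, modelSpec)
}

# ---------------------------------------------------------------------------
# splitting
# ---------------------------------------------------------------------------

#' Split a feature table into train and test sets
#'
#' Disjoint, exhaustive partition with test size round(n * test_fraction)
#' (per class when stratified). With \code{group_by_participant},
#' participants are assigned whole to one side, accumulating into the
#' test set until the target size is reached. Errors if any class ends up
#' absent from the training side.
#'
#' @param table Feature table (see [buildFeatureTable()]).
#' @param spec A [splitSpec()].
#' @return List with data.frame elements \code{train} and \code{test}.
#' @export
splitTrainTest <- function(table, spec = splitSpec()) {
  if (!nrow(table) || is.null(table$label)) stop("table must be non-empty with labels")
  n <- nrow(table)
  target <- round(n * spec$test_fraction)
  test_idx <- withr::with_seed(spec$seed, {
    if (spec$group_by_participant) {
      parts <- sample(unique(table$participant_id))
      idx <- integer()
      for (p in parts) {
        if (length(idx) >= target) break
        idx <- c(idx, which(table$participant_id == p))
      }
      idx
    } else if (spec$stratified) {
      unlist(lapply(split(seq_len(n), table$label), function(ii) {
        if (!length(ii)) return(integer())
        sample(ii, round(length(ii) * spec$test_fraction))
      }), use.names = FALSE)
    } else {
      sample(n, target)
    }
  })
  train <- table[setdiff(seq_len(n), test_idx), , drop = FALSE]
  test <- table[test_idx, , drop = FALSE]
  missing_cls <- setdiff(levels(droplevels(table$label)),
                         as.character(unique(train$label)))
  if (length(missing_cls))
    stop("class(es) ", paste(missing_cls, collapse = ", "),
         " absent from the training split; supply more data, a smaller ",
         "test_fraction, or a stratified ungrouped split")
  list(train = train, test = test)
}

# stratified fold ids, 1..k, deterministic given seed
.stratifiedFolds <- function(y, k, seed) {
  tabcnt <- table(y)
  tabcnt <- tabcnt[tabcnt > 0]
  if (any(tabcnt < k))
    stop("class(es) ", paste(names(tabcnt)[tabcnt < k], collapse = ", "),
         " have fewer than k = ", k, " members; use a smaller k")
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in names(tabcnt)) {
      ii <- sample(which(y == cls))
      folds[ii] <- rep_len(seq_len(k), length(ii))
    }
  })
  folds
}

# ---------------------------------------------------------------------------
# model fitting / prediction
# ---------------------------------------------------------------------------

.fitModel <- function(algorithm, params, X, y, seed = 1L) {
  lev <- levels(y)
  params <- modifyList(.defaultParams(algorithm), as.list(params))
  fit <- withr::with_seed(seed, switch(algorithm,
    gradient_boosting_ensemble = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(lev),
                      eval_metric = "mlogloss",
                      tree_method = "exact",  # mid-gap split thresholds
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    random_forest_ensemble = {
      ranger::ranger(x = X, y = y, probability = TRUE,
                     num.trees = params$num.trees,
                     importance = "impurity", seed = seed,
                     num.threads = 1)
    },
    multinomial_logistic = {
      ctr <- colMeans(X)
      scl <- apply(X, 2L, sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      df <- as.data.frame(scale(X, ctr, scl))
      names(df) <- paste0("V", seq_len(ncol(df)))
      df$.y <- y
      m <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                          MaxNWts = 1e6, maxit = 200,
                          decay = params$decay)
      list(fit = m, center = ctr, scale = scl)
    }))
  structure(list(algorithm = algorithm, params = params, fit = fit,
                 levels = lev, features = colnames(X)),
            class = "pfmusModel")
}

# class-probability matrix, columns in full level order
.predictProb <- function(model, X) {
  X <- X[, model$features, drop = FALSE]
  lev <- model$levels
  prob <- switch(model$algorithm,
    gradient_boosting_ensemble = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(X))
      if (!is.matrix(p))                 # older releases return a vector
        p <- matrix(p, ncol = length(lev), byrow = TRUE)
      dimnames(p) <- list(NULL, lev)
      p
    },
    random_forest_ensemble = {
      p <- predict(model$fit, data = X, num.threads = 1)$predictions
      full <- matrix(0, nrow(X), length(lev),
                     dimnames = list(NULL, lev))
      full[, colnames(p)] <- p
      full
    },
    multinomial_logistic = {
      df <- as.data.frame(scale(X, model$fit$center, model$fit$scale))
      names(df) <- paste0("V", seq_len(ncol(df)))
      p <- predict(model$fit$fit, newdata = df, type = "probs")
      if (is.null(dim(p)))
        p <- matrix(p, nrow = nrow(df),
                    dimnames = list(NULL, model$fit$fit$lev))
      full <- matrix(0, nrow(X), length(lev),
                     dimnames = list(NULL, lev))
      full[, colnames(p)] <- p
      full
    })
  prob
}

.predictClass <- function(model, X) {
  prob <- .predictProb(model, X)
  factor(colnames(prob)[max.col(prob, ties.method = "first")],
         levels = model$levels)
}

# ---------------------------------------------------------------------------
# metrics
# ---------------------------------------------------------------------------

#' Per-class and macro metrics from a confusion matrix
#'
#' One-vs-rest reduction: for class c, TP = C[c, c], FP = column sum -
#' TP, FN = row sum - TP, TN = total - TP - FP - FN. Per-class accuracy =
#' (TP + TN) / (TP + FP + FN + TN), recall = TP / (TP + FN), precision =
#' TP / (TP + FP), F1 = 2 * precision * recall / (precision + recall).
#' Macro metrics are unweighted class means; overall accuracy is
#' trace / total. Undefined 0/0 ratios are reported as 0 and flagged.
#'
#' @param confusion Square non-negative integer matrix, rows = true
#'   class, columns = predicted class.
#' @return List with \code{accuracy} (overall), macro \code{recall},
#'   \code{precision}, \code{f1}, a \code{per_class} data.frame (TP, FP,
#'   FN, TN, accuracy, recall, precision, f1, undefined_flag) and
#'   \code{total}.
#' @export
#' @examples
#' metricsFromConfusion(diag(c(10, 10, 10, 10)))
metricsFromConfusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop("confusion matrix must contain non-negative integers")
  total <- sum(confusion)
  if (total <= 0) stop("confusion matrix total must be positive")
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- paste0("class", seq_len(nrow(confusion)))
  ratio0 <- function(num, den) ifelse(den == 0, 0, num / den)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn
  rec <- ratio0(tp, tp + fn)
  prec <- ratio0(tp, tp + fp)
  f1 <- ratio0(2 * prec * rec, prec + rec)
  flag <- (tp + fn == 0) | (tp + fp == 0) |
    (prec + rec == 0 & (tp + fn > 0) & (tp + fp > 0))
  per_class <- data.frame(
    class = cls, TP = tp, FP = fp, FN = fn, TN = tn,
    accuracy = (tp + tn) / total, recall = rec, precision = prec,
    f1 = f1, undefined_flag = flag, row.names = NULL)
  list(accuracy = sum(tp) / total,
       recall = mean(rec), precision = mean(prec), f1 = mean(f1),
       per_class = per_class, total = total)
}

#' Macro one-vs-rest AUC from class probabilities
#'
#' For each class, the area under the ROC curve of that class's predicted
#' probability against the one-vs-rest truth (equivalently the
#' Mann-Whitney U statistic normalised by the number of
#' positive-negative pairs, with ties counted one half); the macro AUC is
#' the unweighted mean over classes. Classes absent from \code{y} are
#' excluded with a warning.
#'
#' @param y True class labels.
#' @param prob Numeric matrix of class probabilities, one named column
#'   per class.
#' @return Macro-averaged AUC in [0, 1].
#' @export
#' @examples
#' y <- c("A", "A", "B", "B")
#' prob <- cbind(A = c(.9, .6, .4, .1), B = c(.1, .4, .6, .9))
#' macroAUC(y, prob)
macroAUC <- function(y, prob) {
  lev <- colnames(prob)
  present <- lev[lev %in% as.character(unique(y))]
  absent <- setdiff(lev, present)
  if (length(absent))
    warning("class(es) absent from test set excluded from macro AUC: ",
            paste(absent, collapse = ", "))
  if (!length(present)) return(NA_real_)
  aucs <- vapply(present, function(cls) {
    resp <- factor(y == cls, levels = c(FALSE, TRUE))
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = resp,
                                   predictor = prob[, cls],
                                   quiet = TRUE, direction = "<",
                                   levels = c(FALSE, TRUE))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

.confusionFrom <- function(truth, pred, lev) {
  tb <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  matrix(as.integer(tb), nrow = length(lev),
         dimnames = list(lev, lev))
}

# ---------------------------------------------------------------------------
# cross-validation, tuning, evaluation
# ---------------------------------------------------------------------------

#' Compare models by k-fold cross-validation
#'
#' Fits every spec with its default hyperparameters on stratified k-fold
#' splits of the training set and reports fold-mean accuracy, AUC,
#' recall, precision and F1, ranked by accuracy. The multinomial logistic
#' reference is always included.
#'
#' @param train Training feature table.
#' @param specs List of [modelSpec()] objects.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment and the fits.
#' @return Data frame, one row per model, ranked by mean CV accuracy
#'   (attribute \code{folds} carries the fold assignment).
#' @export
crossValidateModels <- function(train, specs = defaultModelSpecs(),
                                k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  algos <- vapply(specs, function(s) s$algorithm, character(1))
  if (!"multinomial_logistic" %in% algos)
    specs <- c(specs, list(modelSpec("multinomial_logistic")))
  y <- droplevels(train$label)
  folds <- .stratifiedFolds(y, k, seed)
  X <- .featureMatrix(train)
  yfull <- train$label

  rows <- lapply(specs, function(spec) {
    fm <- matrix(NA_real_, k, 5L,
                 dimnames = list(NULL, c("accuracy", "auc", "recall",
                                         "precision", "f1")))
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- .fitModel(spec$algorithm, lapply(spec$grid, `[`, 1L),
                         X[tr, , drop = FALSE], droplevels(yfull[tr]),
                         seed = seed + f)
      prob <- .predictProb(model, X[!tr, , drop = FALSE])
      pred <- colnames(prob)[max.col(prob, ties.method = "first")]
      cm <- .confusionFrom(yfull[!tr], pred, model$levels)
      met <- metricsFromConfusion(cm)
      fm[f, ] <- c(met$accuracy,
                   suppressWarnings(macroAUC(yfull[!tr], prob)),
                   met$recall, met$precision, met$f1)
    }
    data.frame(model = spec$algorithm, t(colMeans(fm)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  out
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustively evaluates every combination of the spec's grid by mean
#' k-fold cross-validated accuracy (same fold assignment for every
#' combination); ties are broken in favour of the first-listed
#' combination. The winning combination is refitted on the full training
#' set.
#'
#' @param train Training feature table.
#' @param spec A [modelSpec()] with a non-empty grid.
#' @param k Number of folds (default 5).
#' @param seed Seed for folds and fits.
#' @return The refitted model (class \code{pfmusModel}) with attributes
#'   \code{cv_accuracy} and the chosen \code{params} stored inside.
#' @export
gridSearchTune <- function(train, spec, k = 5L, seed = 1L) {
  if (is.null(spec$grid) || !length(spec$grid))
    stop("hyperparameter grid is empty")
  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  y <- train$label
  folds <- .stratifiedFolds(droplevels(y), k, seed)
  X <- .featureMatrix(train)
  best <- NULL
  best_acc <- -Inf
  for (ci in seq_len(nrow(combos))) {
    params <- as.list(combos[ci, , drop = FALSE])
    accs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      model <- .fitModel(spec$algorithm, params, X[tr, , drop = FALSE],
                         droplevels(y[tr]), seed = seed + f)
      pred <- .predictClass(model, X[!tr, , drop = FALSE])
      mean(as.character(pred) == as.character(y[!tr]))
    }, numeric(1))
    acc <- mean(accs)
    if (acc > best_acc) {           # strict: first-listed wins ties
      best_acc <- acc
      best <- params
    }
  }
  model <- .fitModel(spec$algorithm, best, X, droplevels(y), seed = seed)
  model$cv_accuracy <- best_acc
  model
}

#' Evaluate a fitted model on the held-out test set
#'
#' Predictions give the 4x4 confusion matrix (rows = truth), which is
#' reduced to per-class and macro metrics; AUC is the macro-averaged
#' one-vs-rest area under the ROC curve computed from the predicted
#' class probabilities (classes absent from the test set are excluded
#' with a warning; a model without probability scores reports AUC NA).
#'
#' @param model A fitted \code{pfmusModel}.
#' @param test Test feature table.
#' @return List with \code{metrics} (accuracy, auc, recall, precision,
#'   f1), \code{confusion}, \code{per_class} and the predicted classes.
#' @export
evaluateModel <- function(model, test) {
  if (!nrow(test)) stop("test set is empty")
  X <- .featureMatrix(test)
  prob <- tryCatch(.predictProb(model, X), error = function(e) NULL)
  if (is.null(prob)) {
    warning("model provides no probability scores; AUC reported missing")
    pred <- predict(model$fit, X)
    auc <- NA_real_
  } else {
    pred <- colnames(prob)[max.col(prob, ties.method = "first")]
    auc <- macroAUC(test$label, prob)
  }
  cm <- .confusionFrom(test$label, pred, model$levels)
  met <- metricsFromConfusion(cm)
  list(metrics = list(accuracy = met$accuracy, auc = auc,
                      recall = met$recall, precision = met$precision,
                      f1 = met$f1),
       confusion = cm, per_class = met$per_class,
       predictions = factor(pred, levels = model$levels))
}

#' Ranked feature importances
#'
#' The n highest importance scores of a fitted tree-ensemble model
#' (split-gain for gradient boosting, impurity for random forest),
#' descending; ties broken alphabetically by feature name.
#'
#' @param model A fitted \code{pfmusModel}.
#' @param n Number of features to return (default 10; the full ranking
#'   when n exceeds the feature count).
#' @return Data frame with columns \code{feature} and \code{importance}.
#' @export
topFeatureImportances <- function(model, n = 10L) {
  imp <- switch(model$algorithm,
    gradient_boosting_ensemble = {
      tab <- xgboost::xgb.importance(model = model$fit)
      setNames(tab$Gain, tab$Feature)
    },
    random_forest_ensemble = model$fit$variable.importance,
    stop("model of type '", model$algorithm,
         "' does not provide feature importances"))
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n)
}
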