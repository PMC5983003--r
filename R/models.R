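#' Specify a learning algorithm
#'
#' Algorithms are implemented by contract on top of standard R learners:
#' random forest (100 trees by default), RBF-kernel SVM with logistic
#' probability calibration, decision tree (optionally bagged), one-hidden-
#' layer neural network, reduced-error-pruned regression tree, and
#' RBF-kernel support vector regression.
#'
#' @param algorithm one of "random-forest", "svm-rbf", "decision-tree",
#'   "neural-net", "reptree", "svr-rbf".
#' @param ... hyperparameter overrides: `ntree` (random-forest), `cost`
#'   (svm-rbf/svr-rbf), `bag` (decision-tree bagging repetitions), `size`,
#'   `decay`, `maxit` (neural-net).
#' @return A `LearnerSpec` list.
#' @export
learnerSpec <- function(algorithm = c("random-forest", "svm-rbf",
                                      "decision-tree", "neural-net",
                                      "reptree", "svr-rbf"), ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    "random-forest" = list(ntree = 100),
    "svm-rbf" = list(cost = 1),
    "decision-tree" = list(bag = 1),
    "neural-net" = list(size = 8, decay = 0.1, maxit = 300),
    "reptree" = list(minCp = 1e-4),
    "svr-rbf" = list(cost = 1))
  params <- utils::modifyList(defaults, list(...))
  structure(list(algorithm = algorithm, params = params),
            class = "LearnerSpec")
}

# fit on `train`, return out-of-fold predictions for `test`:
# classification -> probability of the "affected" class; regression -> value
trainPredict <- function(spec, train, test, featCols, task) {
  fx <- stats::as.formula(paste("output ~",
                                paste(featCols, collapse = " + ")))
  tr <- train[, c(featCols, "output")]
  te <- test[, featCols, drop = FALSE]
  p <- spec$params
  switch(spec$algorithm,
    "random-forest" = {
      m <- randomForest::randomForest(x = tr[, featCols, drop = FALSE],
                                      y = tr$output, ntree = p$ntree)
      if (task == "classification")
        predict(m, te, type = "prob")[, "affected"]
      else as.numeric(predict(m, te))
    },
    "svm-rbf" = {
      m <- e1071::svm(fx, data = tr, kernel = "radial", cost = p$cost,
                      probability = TRUE)
      pr <- predict(m, te, probability = TRUE)
      attr(pr, "probabilities")[, "affected"]
    },
    "decision-tree" = {
      probs <- replicate(p$bag, {
        idx <- if (p$bag > 1) sample.int(nrow(tr), replace = TRUE)
               else seq_len(nrow(tr))
        m <- rpart::rpart(fx, data = tr[idx, ], method = "class")
        predict(m, te, type = "prob")[, "affected"]
      })
      if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(te))
      rowMeans(probs)
    },
    "neural-net" = {
      m <- nnet::nnet(fx, data = tr, size = p$size, decay = p$decay,
                      maxit = p$maxit, trace = FALSE, MaxNWts = 10000)
      as.numeric(predict(m, te, type = "raw"))
    },
    "reptree" = {
      m <- rpart::rpart(fx, data = tr, method = "anova",
                        control = rpart::rpart.control(cp = p$minCp))
      cp <- m$cptable[which.min(m$cptable[, "xerror"]), "CP"]
      as.numeric(predict(rpart::prune(m, cp = cp), te))
    },
    "svr-rbf" = {
      m <- e1071::svm(fx, data = tr, type = "eps-regression",
                      kernel = "radial", cost = p$cost)
      as.numeric(predict(m, te))
    })
}

# stratified (classification) or plain (regression) k-fold assignment
foldAssignment <- function(y, scheme, k) {
  n <- length(y)
  if (scheme == "loocv") return(seq_len(n))
  folds <- integer(n)
  if (is.factor(y)) {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

# Se/Sp/PPV/BAR/MCC/AUC from binary truth and predictions; the positive
# class (P) is "affected". AUC is the rank (Mann-Whitney) statistic over
# scores, ties averaged; MCC/AUC are NA when undefined.
classMetrics <- function(truth, predicted, score = NULL) {
  TP <- sum(predicted == "affected" & truth == "affected")
  FN <- sum(predicted == "unaffected" & truth == "affected")
  TN <- sum(predicted == "unaffected" & truth == "unaffected")
  FP <- sum(predicted == "affected" & truth == "unaffected")
  Se <- TP / (TP + FN)
  Sp <- TN / (TN + FP)
  PPV <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  denom <- sqrt((TP + FP)) * sqrt((TP + FN)) * sqrt((TN + FP)) *
    sqrt((TN + FN))
  MCC <- if (denom > 0) (TP * TN - FP * FN) / denom else NA_real_
  AUC <- NA_real_
  nP <- TP + FN
  nN <- TN + FP
  if (!is.null(score) && nP > 0 && nN > 0) {
    r <- rank(score)
    AUC <- (sum(r[truth == "affected"]) - nP * (nP + 1) / 2) / (nP * nN)
  }
  c(Se = Se, Sp = Sp, PPV = PPV, BAR = 0.5 * (Se + Sp), MCC = MCC,
    AUC = AUC)
}

#' Performance metrics from predictions and truth
#'
#' Classification: supply the probability of the "affected" class; rows
#' with probability >= 0.5 are predicted affected (ties conservatively to
#' affected). Regression: supply numeric predictions; the Pearson
#' correlation r is reported and both predictions and truth are also
#' thresholded at `threshold` (affected strictly below) to yield the
#' classification metrics, mirroring the evaluation protocol.
#'
#' @param truth factor (unaffected/affected) or numeric activity values.
#' @param prob probability of the affected class (classification).
#' @param predicted numeric predictions (regression).
#' @param threshold activity threshold separating affected (< threshold)
#'   from unaffected.
#' @return Named numeric vector: Se, Sp, PPV, BAR, MCC, AUC, r, and the
#'   confusion counts as attribute "confusion".
#' @export
computeMetrics <- function(truth, prob = NULL, predicted = NULL,
                           threshold = -2) {
  if (is.factor(truth)) {
    stopifnot(!is.null(prob))
    predCls <- factor(ifelse(prob >= 0.5, "affected", "unaffected"),
                      levels = c("unaffected", "affected"))
    m <- c(classMetrics(truth, predCls, score = prob), r = NA_real_)
  } else {
    stopifnot(!is.null(predicted))
    truthCls <- ifelse(truth < threshold, "affected", "unaffected")
    predCls <- ifelse(predicted < threshold, "affected", "unaffected")
    m <- c(classMetrics(truthCls, predCls),
           r = if (sd(predicted) > 0 && sd(truth) > 0)
             cor(truth, predicted) else NA_real_)
    predCls <- factor(predCls, levels = c("unaffected", "affected"))
    truth <- factor(truthCls, levels = c("unaffected", "affected"))
  }
  conf <- c(TP = sum(predCls == "affected" & truth == "affected"),
            FP = sum(predCls == "affected" & truth == "unaffected"),
            TN = sum(predCls == "unaffected" & truth == "unaffected"),
            FN = sum(predCls == "unaffected" & truth == "affected"))
  attr(m, "confusion") <- conf
  m
}

#' Cross-validated model evaluation
#'
#' Leave-one-out or stratified k-fold cross-validation: every row is
#' predicted exactly once by a model trained without it. Regression
#' predictions are additionally thresholded at -2.0 to report the
#' classification metrics. Deterministic for a fixed seed.
#'
#' @param dataset a [VariantDataset-class].
#' @param learner a [learnerSpec()].
#' @param scheme "k-fold" or "loocv".
#' @param k number of folds (k-fold).
#' @param seed integer seed controlling fold assignment and any stochastic
#'   learner internals.
#' @return An [EvaluationResult-class].
#' @export
crossValidate <- function(dataset, learner, scheme = c("k-fold", "loocv"),
                          k = 10, seed = 1) {
  scheme <- match.arg(scheme)
  feat <- dataset@features
  featCols <- featureColumns(dataset)
  task <- dataset@task
  y <- feat$output
  if (task == "classification" && any(table(y) < 2))
    stop("need at least 2 rows per class")
  n <- nrow(feat)
  pred <- numeric(n)
  withr::with_seed(seed, {
    folds <- foldAssignment(y, scheme, k)
    for (f in sort(unique(folds))) {
      tr <- feat[folds != f, , drop = FALSE]
      te <- feat[folds == f, , drop = FALSE]
      if (task == "classification" && any(table(tr$output) == 0))
        stop("class absent from a training fold; use larger folds")
      pred[folds == f] <- trainPredict(learner, tr, te, featCols, task)
    }
  })
  buildEvaluation(feat, pred, task,
                  scheme = if (scheme == "loocv") "loocv"
                           else sprintf("%d-fold", k),
                  seed = seed, folds = folds)
}

buildEvaluation <- function(feat, pred, task, scheme, seed, folds = NULL) {
  meta <- feat[, startsWith(names(feat), "."), drop = FALSE]
  if (task == "classification") {
    m <- computeMetrics(feat$output, prob = pred)
    predictions <- cbind(meta,
      data.frame(truth = feat$output, prob_affected = pred,
                 predicted = factor(ifelse(pred >= 0.5, "affected",
                                           "unaffected"),
                                    levels = c("unaffected", "affected"))))
  } else {
    m <- computeMetrics(feat$output, predicted = pred)
    predictions <- cbind(meta,
      data.frame(truth = feat$output, predicted_value = pred,
                 predicted = factor(ifelse(pred < -2, "affected",
                                           "unaffected"),
                                    levels = c("unaffected", "affected"))))
  }
  if (!is.null(folds)) predictions$.fold <- folds
  new("EvaluationResult", predictions = predictions, metrics = m,
      confusion = attr(m, "confusion"), scheme = scheme, task = task,
      seed = as.integer(seed))
}

#' Average class probabilities across classifiers
#'
#' The combined classifier: per-row mean of the affected-class
#' probabilities of two or more classification evaluations over the same
#' rows; the predicted class is the probability argmax, with exact 0.5
#' ties resolved conservatively to "affected".
#'
#' @param results list of classification [EvaluationResult-class] objects
#'   over identical rows, or a list of numeric probability vectors.
#' @return An [EvaluationResult-class] (when given evaluations) or a
#'   data.frame with `prob_affected` and `predicted`.
#' @export
combinedClassifier <- function(results) {
  if (length(results) < 2) stop("need at least 2 classifiers to combine")
  if (all(vapply(results, is, TRUE, class2 = "EvaluationResult"))) {
    truths <- lapply(results, function(r) r@predictions$truth)
    if (!all(vapply(truths, identical, TRUE, y = truths[[1]])))
      stop("classifiers were evaluated on different row sets")
    probs <- vapply(results, function(r) r@predictions$prob_affected,
                    numeric(nrow(results[[1]]@predictions)))
    feat0 <- results[[1]]@predictions
    feat <- feat0[, startsWith(names(feat0), "."), drop = FALSE]
    feat$output <- feat0$truth
    buildEvaluation(feat, rowMeans(probs), "classification",
                    scheme = paste0("combined:",
                                    results[[1]]@scheme),
                    seed = results[[1]]@seed)
  } else {
    lens <- lengths(results)
    if (length(unique(lens)) != 1) stop("probability vectors differ in length")
    prob <- rowMeans(do.call(cbind, results))
    data.frame(prob_affected = prob,
               predicted = factor(ifelse(prob >= 0.5, "affected",
                                         "unaffected"),
                                  levels = c("unaffected", "affected")))
  }
}

#' Shuffle a dataset's output labels
#'
#' Inputs stay attached to their rows; only the output attribute is
#' permuted. Used to build label-permutation control datasets.
#'
#' @param dataset a [VariantDataset-class].
#' @param permutation integer permutation of the row indices.
#' @return A [VariantDataset-class].
#' @export
shuffleOutputs <- function(dataset, permutation) {
  stopifnot(identical(sort(permutation),
                      seq_len(nrow(dataset@features))))
  out <- dataset
  out@features$output <- dataset@features$output[permutation]
  out@features$.log2_effect <- dataset@features$.log2_effect[permutation]
  out
}

#' Label-permutation control experiment
#'
#' Repeatedly shuffles the output attribute among the rows, re-runs the
#' cross-validation per shuffle, and reports the null distribution of
#' BAR/MCC (or r for regression) together with the empirical p-value: the
#' fraction of shuffles reaching at least the observed performance.
#'
#' @inheritParams crossValidate
#' @param nShuffles number of label permutations.
#' @return List with `observed` (EvaluationResult), `null` (data.frame of
#'   per-shuffle metrics), `summary` (mean and sd per metric) and `p`.
#' @export
permutationControl <- function(dataset, learner,
                               scheme = c("k-fold", "loocv"), k = 10,
                               nShuffles = 100, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(nShuffles >= 1)
  observed <- crossValidate(dataset, learner, scheme, k, seed)
  n <- nrow(dataset@features)
  perms <- withr::with_seed(seed, replicate(nShuffles, sample.int(n),
                                            simplify = FALSE))
  keyMetric <- if (dataset@task == "classification") "BAR" else "r"
  null <- do.call(rbind, lapply(seq_len(nShuffles), function(s) {
    ev <- crossValidate(shuffleOutputs(dataset, perms[[s]]), learner,
                        scheme, k, seed = seed + s)
    as.data.frame(as.list(ev@metrics))
  }))
  p <- mean(null[[keyMetric]] >= observed@metrics[[keyMetric]])
  list(observed = observed, null = null,
       summary = data.frame(metric = names(null),
                            mean = colMeans(as.matrix(null)),
                            sd = apply(as.matrix(null), 2, sd),
                            row.names = NULL),
       p = p)
}

#' Learning curve over training-set size
#'
#' For each size, draws `reps` stratified random subsamples, runs k-fold
#' cross-validation on each, and aggregates mean and standard deviation of
#' BAR, MCC and AUC (classification) or r (regression). With the full
#' dataset size and one repetition this reduces to a plain k-fold run.
#'
#' @inheritParams crossValidate
#' @param sizes integer vector of subsample sizes (each >= 20).
#' @param reps subsamples per size.
#' @return data.frame with one row per (size, metric): mean, sd, reps.
#' @export
learningCurve <- function(dataset, sizes, reps, learner, k = 10, seed = 1) {
  if (any(sizes < 20)) stop("sizes below 20 give degenerate folds")
  n <- nrow(dataset@features)
  if (max(sizes) > n) stop("size exceeds dataset size")
  y <- dataset@features$output
  metricNames <- if (dataset@task == "classification")
    c("BAR", "MCC", "AUC") else "r"
  rows <- list()
  for (size in sizes) {
    vals <- matrix(NA_real_, reps, length(metricNames),
                   dimnames = list(NULL, metricNames))
    for (rep in seq_len(reps)) {
      idx <- withr::with_seed(seed + 7919L * rep + size, {
        if (is.factor(y)) {
          take <- unlist(lapply(levels(y), function(cls) {
            from <- which(y == cls)
            sample(from, round(size * length(from) / n))
          }))
        } else take <- sample.int(n, size)
        sort(take)
      })
      sub <- dataset
      sub@features <- dataset@features[idx, , drop = FALSE]
      ev <- crossValidate(sub, learner, "k-fold", k,
                          seed = seed + rep - 1L)
      vals[rep, ] <- ev@metrics[metricNames]
    }
    for (mn in metricNames)
      rows[[length(rows) + 1L]] <-
        data.frame(size = size, metric = mn, mean = mean(vals[, mn]),
                   sd = if (reps > 1) sd(vals[, mn]) else 0, reps = reps)
  }
  do.call(rbind, rows)
}

#' Performance stratified by a row grouping
#'
#' Recomputes the confusion and metrics within each level of a grouping of
#' the evaluated rows (e.g. depth class, secondary structure, or polarity
#' pair of native and replacement residue), with the composition
#' percentage of each group.
#'
#' @param evaluation a classification [EvaluationResult-class].
#' @param grouping factor/character vector aligned with the evaluation's
#'   prediction rows.
#' @return data.frame: group, n, percent, Se..AUC metrics.
#' @export
stratifiedPerformance <- function(evaluation, grouping) {
  pr <- evaluation@predictions
  stopifnot(length(grouping) == nrow(pr))
  grouping <- as.factor(grouping)
  rows <- lapply(levels(grouping), function(g) {
    sel <- grouping == g
    if (!any(sel))
      return(data.frame(group = g, n = 0L, percent = 0,
                        t(setNames(rep(NA_real_, 6),
                                   c("Se", "Sp", "PPV", "BAR", "MCC",
                                     "AUC")))))
    m <- computeMetrics(droplevels0(pr$truth[sel]),
                        prob = pr$prob_affected[sel])
    data.frame(group = g, n = sum(sel),
               percent = 100 * sum(sel) / nrow(pr),
               t(m[c("Se", "Sp", "PPV", "BAR", "MCC", "AUC")]))
  })
  do.call(rbind, rows)
}

# keep both levels even if a group lacks one class
droplevels0 <- function(f) factor(f, levels = c("unaffected", "affected"))

#' Position-by-replacement prediction array
#'
#' Grid over structure positions (columns) and the 20 replacement residues
#' (rows): each cell is "correct" or "incorrect" for an evaluated variant
#' (a variant represented by several rows is correct only if all its rows
#' are), "not-a-variant" on the native diagonal, and "no-data" otherwise.
#'
#' @param evaluation a classification [EvaluationResult-class] whose
#'   predictions carry `.position`, `.native` and `.replacement`.
#' @param structure the evaluated [CoarseStructure-class].
#' @return Character matrix, 20 replacements x positions.
#' @export
predictionArray <- function(evaluation, structure) {
  pr <- evaluation@predictions
  stopifnot(all(c(".position", ".native", ".replacement") %in% names(pr)))
  s <- structure@sites[structure@sites$chain == structure@chainOrder[1], ]
  posNums <- s$resnum
  arr <- matrix("no-data", 20, length(posNums),
                dimnames = list(AMINO_ACIDS, posNums))
  for (j in seq_along(posNums))
    arr[s$resType[j], j] <- "not-a-variant"
  ok <- tapply(pr$predicted == pr$truth,
               paste0(pr$.position, ":", pr$.replacement), all)
  for (nm in names(ok)) {
    parts <- strsplit(nm, ":")[[1]]
    j <- match(as.integer(parts[1]), posNums)
    if (!is.na(j))
      arr[parts[2], j] <- if (ok[[nm]]) "correct" else "incorrect"
  }
  arr
}
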