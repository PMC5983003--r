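test_that("metrics follow their defining formulas", {
  # constructed confusion TP=50 FN=10 TN=40 FP=20 via hard probabilities
  truth <- factor(c(rep("affected", 60), rep("unaffected", 60)),
                  levels = c("unaffected", "affected"))
  prob <- c(rep(1, 50), rep(0, 10), rep(0, 40), rep(1, 20))
  m <- computeMetrics(truth, prob = prob)
  expect_equal(unname(m["Se"]), 50 / 60)
  expect_equal(unname(m["Sp"]), 40 / 60)
  expect_equal(unname(m["PPV"]), 50 / 70)
  expect_equal(unname(m["BAR"]), 0.5 * (50 / 60 + 40 / 60))
  expect_equal(unname(m["MCC"]), directMCC(50, 20, 40, 10))
  expect_equal(attr(m, "confusion"),
               c(TP = 50L, FP = 20L, TN = 40L, FN = 10L))

  # perfect predictions
  mPerf <- computeMetrics(truth, prob = as.numeric(truth == "affected"))
  expect_equal(unname(mPerf[c("MCC", "AUC")]), c(1, 1))

  # AUC agrees with an independent ROC implementation, ties included
  pr <- withr::with_seed(5, round(runif(120), 2))
  mAuc <- computeMetrics(truth, prob = pr)
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = pr,
                                        levels = c("unaffected", "affected"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(unname(mAuc["AUC"]), ref, tolerance = 1e-12)

  # single-class truth leaves MCC/AUC undefined
  one <- computeMetrics(factor(rep("affected", 5),
                               levels = c("unaffected", "affected")),
                        prob = c(1, 1, 0, 1, 1))
  expect_true(is.na(one["MCC"]) && is.na(one["AUC"]))
})

test_that("probability averaging implements the combined classifier", {
  out <- combinedClassifier(list(0.9, 0.7))
  expect_equal(out$prob_affected, 0.8)
  expect_equal(as.character(out$predicted), "affected")
  # idempotence on identical inputs
  expect_identical(combinedClassifier(list(c(0.2, 0.6), c(0.2, 0.6))),
                   combinedClassifier(list(c(0.2, 0.6), c(0.2, 0.6))))
  # hard 0/1 probabilities reduce to majority vote (ties to affected)
  votes <- withr::with_seed(8, replicate(4, sample(0:1, 30, TRUE),
                                         simplify = FALSE))
  got <- combinedClassifier(votes)$predicted
  tallies <- Reduce(`+`, votes)
  expect_equal(as.character(got),
               ifelse(tallies >= 2, "affected", "unaffected"))
  expect_error(combinedClassifier(list(0.5)), "at least 2")
  expect_error(combinedClassifier(list(c(0.1, 0.2), 0.3)), "length")
})

test_that("cross-validation schemes satisfy their structural contracts", {
  ds <- separableDataset(100, seed = 3)
  # unbalance to 60/40
  feats <- ds@features
  feats$output[feats$output == "affected"][1:10] <- "unaffected"
  ds@features <- feats
  ev <- crossValidate(ds, learnerSpec("decision-tree"), "k-fold", 10,
                      seed = 2)
  folds <- ev@predictions$.fold
  expect_equal(sort(unique(folds)), 1:10)
  byFold <- table(folds, ev@predictions$truth)
  expect_true(all(byFold[, "unaffected"] %in% 5:7))
  expect_true(all(byFold[, "affected"] %in% 3:5))

  evLoo <- crossValidate(separableDataset(40), learnerSpec("decision-tree"),
                         "loocv")
  expect_equal(length(unique(evLoo@predictions$.fold)), 40)
})

test_that("all four classifiers separate an easy two-class problem", {
  ds <- separableDataset(160)
  for (alg in c("random-forest", "svm-rbf", "decision-tree", "neural-net")) {
    ev <- crossValidate(ds, learnerSpec(alg), "k-fold", 10, seed = 5)
    expect_gt(ev@metrics["BAR"], 0.95)
  }
})

test_that("evaluation is deterministic for a fixed seed", {
  ds <- separableDataset(80)
  e1 <- crossValidate(ds, learnerSpec("random-forest"), "k-fold", 10,
                      seed = 9)
  e2 <- crossValidate(ds, learnerSpec("random-forest"), "k-fold", 10,
                      seed = 9)
  expect_identical(e1@predictions, e2@predictions)
  expect_identical(e1@metrics, e2@metrics)
})

test_that("regression thresholding is consistent with pre-thresholded classes", {
  truth <- withr::with_seed(12, rnorm(200, -1.5, 2))
  pred <- truth + withr::with_seed(13, rnorm(200, 0, 1))
  m <- computeMetrics(truth, predicted = pred)
  truthCls <- factor(ifelse(truth < -2, "affected", "unaffected"),
                     levels = c("unaffected", "affected"))
  mCls <- computeMetrics(truthCls,
                         prob = as.numeric(pred < -2))
  expect_equal(unname(m["BAR"]), unname(mCls["BAR"]))
  expect_equal(unname(m["r"]), cor(truth, pred))
})

test_that("label permutation controls behave as a null", {
  ds <- separableDataset(80)
  lrn <- learnerSpec("decision-tree")
  obs <- crossValidate(ds, lrn, "k-fold", 10, seed = 4)
  # identity permutation reproduces the unshuffled evaluation exactly
  same <- crossValidate(shuffleOutputs(ds, seq_len(80)), lrn, "k-fold", 10,
                        seed = 4)
  expect_identical(obs@metrics, same@metrics)

  pc <- permutationControl(ds, lrn, "k-fold", 10, nShuffles = 8, seed = 4)
  expect_equal(nrow(pc$null), 8)
  # a separable signal beats every shuffle
  expect_true(all(pc$null$BAR < pc$observed@metrics["BAR"]))
  expect_lt(pc$p, 1 / 8 + 1e-12)
})

test_that("learning curves reduce to plain CV at full size and grow with n", {
  ds <- separableDataset(120, gap = 1.2, seed = 17)
  lc <- learningCurve(ds, sizes = 120, reps = 1,
                      learner = learnerSpec("random-forest", ntree = 60),
                      k = 10, seed = 6)
  plain <- crossValidate(ds, learnerSpec("random-forest", ntree = 60),
                         "k-fold", 10, seed = 6)
  expect_equal(lc$mean[lc$metric == "BAR"], unname(plain@metrics["BAR"]))
  expect_equal(nrow(lc), 3)  # one row per metric at a single size

  lc2 <- learningCurve(ds, sizes = c(24, 120), reps = 3,
                       learner = learnerSpec("random-forest", ntree = 60),
                       k = 6, seed = 6)
  expect_equal(nrow(lc2), 6)
  expect_true(all(lc2$reps == 3))
  barMeans <- lc2$mean[lc2$metric == "BAR"]
  expect_lt(barMeans[1], barMeans[2])  # more data, better separation
  expect_error(learningCurve(ds, sizes = 10, reps = 1,
                             learner = learnerSpec("random-forest")),
               "degenerate")
})

test_that("stratified performance partitions rows and matches direct tallies", {
  ds <- separableDataset(100)
  ev <- crossValidate(ds, learnerSpec("random-forest"), "k-fold", 10,
                      seed = 3)
  whole <- stratifiedPerformance(ev, rep("all", 100))
  expect_equal(whole$BAR, unname(ev@metrics["BAR"]))
  expect_equal(whole$percent, 100)

  grp <- rep(c("g1", "g2"), 50)
  strat <- stratifiedPerformance(ev, grp)
  expect_equal(sum(strat$n), 100)
  expect_equal(sum(strat$percent), 100)
  for (g in c("g1", "g2")) {
    sel <- grp == g
    direct <- computeMetrics(ev@predictions$truth[sel],
                             prob = ev@predictions$prob_affected[sel])
    expect_equal(strat$BAR[strat$group == g], unname(direct["BAR"]))
  }
})

test_that("prediction arrays reconcile with the confusion totals", {
  study <- studyFixture()
  ds <- classificationDataset(study, "monomer-27")
  ev <- crossValidate(ds, learnerSpec("random-forest"), "k-fold", 10,
                      seed = 2)
  arr <- predictionArray(ev, study$structure)
  expect_equal(dim(arr), c(20, 89))
  # native diagonal is never a variant
  sA <- study$structure@sites[study$structure@sites$chain == "A", ]
  for (j in c(1, 45, 89))
    expect_equal(arr[sA$resType[j], j], "not-a-variant")
  nCells <- sum(arr %in% c("correct", "incorrect"))
  expect_equal(nCells, length(unique(ev@predictions$.variant)))
  expect_equal(sum(arr == "correct"),
               sum(ev@predictions$predicted == ev@predictions$truth))

  perfect <- ev
  perfect@predictions$predicted <- perfect@predictions$truth
  expect_false(any(predictionArray(perfect, study$structure) ==
                     "incorrect"))
})
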