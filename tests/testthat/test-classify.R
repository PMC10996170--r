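test_that("split sizes, stratification and reproducibility hold", {
  tab <- separableTable(n_per_class = 10L)        # n = 40, balanced
  sp <- splitSpec(test_fraction = 0.3, seed = 4L)
  parts <- splitTrainTest(tab, sp)
  expect_equal(nrow(parts$test), 12L)             # 3 per class
  expect_equal(as.vector(table(parts$test$label)), rep(3L, 4))
  expect_equal(nrow(parts$train) + nrow(parts$test), 40L)
  expect_length(intersect(parts$train$clip_id, parts$test$clip_id), 0L)
  # identical spec => identical partition
  parts2 <- splitTrainTest(tab, sp)
  expect_identical(parts$test$clip_id, parts2$test$clip_id)

  # unstratified n = 10 at 0.3 -> |test| = 3
  tab10 <- separableTable(n_per_class = 10L)[seq(1, 40, 4), ]
  p10 <- splitTrainTest(tab10, splitSpec(stratified = FALSE, seed = 2L))
  expect_equal(nrow(p10$test), 3L)
  expect_equal(nrow(p10$train), 7L)
})

test_that("participant-grouped splits never span a participant", {
  tab <- separableTable(n_per_class = 10L)
  # one participant holds 40% of the clips, 4 from every class
  pbig_rows <- c(1:4, 11:14, 21:24, 31:34)
  tab$participant_id <- sprintf("p%02d", 1:40)
  tab$participant_id[pbig_rows] <- "pBig"
  for (seed in 1:5) {
    parts <- splitTrainTest(tab, splitSpec(seed = seed,
                                           group_by_participant = TRUE))
    both <- intersect(unique(parts$train$participant_id),
                      unique(parts$test$participant_id))
    expect_length(both, 0L)
    expect_equal(sort(c(parts$train$clip_id, parts$test$clip_id)),
                 sort(tab$clip_id))
  }
})

test_that("a class stranded outside the training side raises the remediation error", {
  tab <- separableTable(n_per_class = 6L)
  # two participants; one holds every UNDETERMINABLE clip, so whichever
  # side it lands on, some class is missing from train
  tab$participant_id <- ifelse(tab$label == "UNDETERMINABLE", "pA", "pB")
  expect_error(splitTrainTest(tab, splitSpec(test_fraction = 0.4,
                                             group_by_participant = TRUE)),
               "absent from the training split")
})

test_that("confusion-matrix metrics follow the one-vs-rest formulas", {
  m <- metricsFromConfusion(diag(c(10, 10, 10, 10)))
  expect_equal(m$accuracy, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$f1, 1)

  # balanced truth, everything predicted as class 1
  cm <- matrix(0L, 4, 4, dimnames = list(pfmClasses(), pfmClasses()))
  cm[, 1] <- 10L
  m2 <- metricsFromConfusion(cm)
  expect_equal(m2$accuracy, 0.25)
  expect_equal(m2$recall, 0.25)
  # classes 2-4: no predictions at all -> precision 0/0 -> 0, flagged
  expect_equal(m2$per_class$precision[2:4], rep(0, 3))
  expect_true(all(m2$per_class$undefined_flag[2:4]))

  # 2-class matrix padded with zeros
  cm3 <- rbind(c(8, 2, 0, 0), c(3, 7, 0, 0), rep(0, 4), rep(0, 4))
  m3 <- metricsFromConfusion(cm3)
  expect_equal(m3$accuracy, 15 / 20)
  expect_equal(m3$per_class$precision[1], 8 / 11)
  expect_equal(m3$per_class$recall[1], 8 / 10)

  # per-class TP + FP + FN + TN = total, for every class
  set.seed(2)
  cm4 <- matrix(rpois(16, 5), 4, 4)
  m4 <- metricsFromConfusion(cm4)
  expect_equal(m4$per_class$TP + m4$per_class$FP + m4$per_class$FN +
                 m4$per_class$TN, rep(sum(cm4), 4))

  expect_error(metricsFromConfusion(matrix(1, 2, 3)), "square")
  expect_error(metricsFromConfusion(matrix(-1, 2, 2)), "non-negative")
})

test_that("macro AUC equals exhaustive pair counting", {
  # 6-item binary score set with one inversion
  truth <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  score <- c(0.1, 0.2, 0.6, 0.5, 0.7, 0.9)
  expected <- aucOracle(truth, score)
  expect_equal(expected, 8 / 9)
  prob <- cbind(A = 1 - score, B = score)
  y <- ifelse(truth, "B", "A")
  # binary one-vs-rest: both classes give the same AUC
  expect_equal(macroAUC(y, prob), expected)

  # multiclass sets (<= 20 items), against per-class pair counting
  set.seed(6)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    y <- sample(pfmClasses()[1:3], n, replace = TRUE)
    while (length(unique(y)) < 3) y <- sample(pfmClasses()[1:3], n, TRUE)
    prob <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, pfmClasses()[1:3]))
    prob <- prob / rowSums(prob)
    manual <- mean(vapply(pfmClasses()[1:3], function(cls)
      aucOracle(y == cls, prob[, cls]), numeric(1)))
    expect_equal(macroAUC(y, prob), manual, tolerance = 1e-12)
  }

  # scores independent of labels: AUC near 1/2 over 20 seeds
  nulls <- vapply(1:20, function(s) {
    set.seed(100 + s)
    y <- sample(rep(c("A", "B"), 15))
    sc <- runif(30)
    macroAUC(y, cbind(A = 1 - sc, B = sc))
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.1)

  expect_warning(macroAUC(rep("A", 4), cbind(A = runif(4), B = runif(4))),
                 "absent")
})

test_that("cross-validation ranks a separable problem near-perfectly and is deterministic", {
  tab <- separableTable(n_per_class = 12L)
  specs <- list(modelSpec("gradient_boosting_ensemble"),
                modelSpec("gradient_boosting_ensemble"))
  cv <- suppressWarnings(crossValidateModels(tab, specs, k = 5L, seed = 3L))
  # the logistic reference is always appended
  expect_true("multinomial_logistic" %in% cv$model)
  expect_equal(nrow(cv), 3L)
  gbm_rows <- cv[cv$model == "gradient_boosting_ensemble", ]
  expect_gte(max(gbm_rows$accuracy), 0.95)
  # duplicate spec -> identical metric rows under the fixed fold seed
  expect_equal(gbm_rows[1, -1], gbm_rows[2, -1], ignore_attr = TRUE)
  # ranking is by accuracy, descending
  expect_true(all(diff(cv$accuracy) <= 0))
  # a class with fewer members than k cannot be folded
  thin <- tab[c(1:6, 13:14, 25:30, 37:42), ]
  expect_error(crossValidateModels(thin, specs, k = 5L), "fewer than k")
})

test_that("permuted labels drive cross-validated accuracy to chance", {
  accs <- vapply(1:20, function(s) {
    tab <- separableTable(n_per_class = 12L, seed = 200 + s)
    tab$label <- withr::with_seed(300 + s, sample(tab$label))
    cv <- suppressWarnings(crossValidateModels(
      tab, list(modelSpec("gradient_boosting_ensemble",
                          grid = list(nrounds = 40))),
      k = 4L, seed = s))
    cv$accuracy[cv$model == "gradient_boosting_ensemble"]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.10)
})

test_that("grid search is exhaustive, tie-stable and interaction-aware", {
  tab <- separableTable(n_per_class = 10L)
  # singleton grid: returns that combination
  m1 <- gridSearchTune(tab, modelSpec("gradient_boosting_ensemble",
                                      grid = list(max_depth = 4,
                                                  eta = 0.3,
                                                  nrounds = 60)), k = 3L)
  expect_equal(m1$params$max_depth, 4)
  expect_error(gridSearchTune(tab, structure(list(
    algorithm = "gradient_boosting_ensemble", grid = list()),
    class = "ModelSpec")), "empty")

  # both depths solve the separable problem -> tie -> first-listed wins
  m2 <- gridSearchTune(tab, modelSpec("gradient_boosting_ensemble",
                                      grid = list(max_depth = c(2, 6),
                                                  eta = 0.3,
                                                  nrounds = 60)), k = 3L)
  expect_equal(m2$params$max_depth, 2)
  expect_equal(m2$cv_accuracy, 1)

  # XOR-style fixture: stumps cannot represent the interaction
  set.seed(9)
  n <- 240
  x1 <- runif(n, -1, 1); x2 <- runif(n, -1, 1)
  xor_tab <- data.frame(
    clip_id = sprintf("c%03d", 1:n), recording_id = "r",
    participant_id = "p", f1 = x1, f2 = x2,
    label = factor(ifelse(xor(x1 > 0, x2 > 0), "CORRECT", "NONE"),
                   levels = pfmClasses()))
  m3 <- gridSearchTune(xor_tab, modelSpec("gradient_boosting_ensemble",
                                          grid = list(max_depth = c(1, 6),
                                                      eta = 0.3,
                                                      nrounds = 80)),
                       k = 3L, seed = 2L)
  expect_equal(m3$params$max_depth, 6)
})

test_that("evaluation reports perfect metrics for a perfect classifier", {
  tab <- separableTable(n_per_class = 12L)
  parts <- splitTrainTest(tab, splitSpec(seed = 8L))
  model <- gridSearchTune(parts$train,
                          modelSpec("gradient_boosting_ensemble",
                                    grid = list(max_depth = 3, eta = 0.3,
                                                nrounds = 80)), k = 3L)
  ev <- evaluateModel(model, parts$test)
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(ev$metrics$auc, 1)
  expect_equal(sum(ev$confusion), nrow(parts$test))
  expect_equal(unname(diag(ev$confusion)),
               as.vector(table(parts$test$label)))
  expect_error(evaluateModel(model, parts$test[0, ]), "empty")
})

test_that("feature importances surface the informative feature, ranked", {
  tab <- separableTable(n_per_class = 12L)
  model <- gridSearchTune(tab, modelSpec("gradient_boosting_ensemble",
                                         grid = list(max_depth = 3,
                                                     eta = 0.3,
                                                     nrounds = 60)),
                          k = 3L)
  imp <- topFeatureImportances(model, 10L)
  expect_equal(imp$feature[1], "base_elevation")
  expect_true(all(diff(imp$importance) <= 0))
  # n larger than the feature count: full ranked list
  impAll <- topFeatureImportances(model, 1000L)
  expect_lte(nrow(impAll), 5L)

  lr <- gridSearchTune(tab, modelSpec("multinomial_logistic",
                                      grid = list(decay = 1e-3)), k = 3L)
  expect_error(topFeatureImportances(lr), "importances")
})
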