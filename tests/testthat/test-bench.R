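test_that("stratified split reproduces the printed cohort partition", {
  t <- generate_feature_cohort(1531, 185 / 1531, n_features = 3,
                               class_shift = 1, seed = 2)
  expect_equal(sum(t$label == "degraded"), 185)
  sp <- stratified_split(t, 0.7, seed = 9)
  expect_equal(nrow(sp$train), 1071)
  expect_equal(nrow(sp$test), 460)
  expect_equal(sum(sp$test$label == "healthy"), 404)
  expect_equal(sum(sp$test$label == "degraded"), 56)
  expect_equal(sum(sp$train$label == "degraded"), 129)
})

test_that("split partitions are disjoint, exhaustive and ratio-preserving", {
  t <- generate_feature_cohort(10, 0.5, n_features = 2, class_shift = 1, seed = 4)
  idx <- stratified_split_index(t$label, 0.5, seed = 1)
  expect_length(intersect(idx$train, idx$test), 0)
  expect_setequal(c(idx$train, idx$test), 1:10)
  expect_equal(sum(t$label[idx$train] == "degraded"), 2)  # floor(5 * 0.5)
  expect_equal(length(idx$train), 4)
})

test_that("degenerate folds are rejected", {
  y <- factor(c(rep("healthy", 20), rep("degraded", 3)),
              levels = c("healthy", "degraded"))
  expect_error(osteotex:::stratified_folds(y, folds = 5, seed = 1),
               class = "osteotex_fold_degeneracy")
})

test_that("metrics follow confusion-matrix arithmetic exactly", {
  # perfect predictor
  y <- factor(rep(c("healthy", "degraded"), c(10, 5)),
              levels = c("healthy", "degraded"))
  m <- classification_metrics(y, y, scores = as.numeric(y == "degraded"))
  expect_equal(unname(m[c("accuracy", "sensitivity", "precision", "f_score", "auc")]),
               c(1, 1, 1, 1, 1))
  # constant-healthy predictor on the printed test composition (404 vs 56)
  y2 <- factor(rep(c("healthy", "degraded"), c(404, 56)),
               levels = c("healthy", "degraded"))
  pred2 <- factor(rep("healthy", 460), levels = c("healthy", "degraded"))
  m2 <- classification_metrics(y2, pred2)
  expect_equal(unname(m2["sensitivity"]), 0)
  expect_equal(unname(m2["accuracy"]), 404 / 460)
  expect_equal(unname(m2["f_score"]), 0)
  # random predictions against the brute-force counter
  set.seed(6)
  for (i in 1:10) {
    truth <- sample(c("healthy", "degraded"), 60, TRUE)
    pred <- sample(c("healthy", "degraded"), 60, TRUE)
    cm <- oracle_metrics(truth, pred)
    m3 <- classification_metrics(truth, pred)
    expect_equal(unname(m3["accuracy"]), (cm[["tp"]] + cm[["tn"]]) / 60)
    sens <- if (cm[["tp"]] + cm[["fn"]] > 0) cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]) else 0
    expect_equal(unname(m3["sensitivity"]), sens)
  }
})

test_that("rank-based AUC is calibrated and matches pROC", {
  set.seed(3)
  aucs <- replicate(100, {
    truth <- rep(c("healthy", "degraded"), c(60, 40))
    classification_metrics(truth, truth, scores = runif(100))[["auc"]]
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
  truth <- rep(c("healthy", "degraded"), c(30, 20))
  scores <- c(rnorm(30), rnorm(20, 1))
  ours <- classification_metrics(truth,
                                 ifelse(scores > 0.5, "degraded", "healthy"),
                                 scores)[["auc"]]
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                        levels = c("healthy", "degraded"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("grid search selects by mean CV F-score with stable tie-breaks", {
  t <- generate_feature_cohort(120, 0.4, n_features = 4, class_shift = 6, seed = 8)
  # one-row grid: trivially selected
  g1 <- grid_search_cv(t, "LR", data.frame(penalty = "L2", C = 1), 5, seed = 2)
  expect_equal(g1$best_params$C, 1)
  expect_equal(nrow(g1$cv_table), 1)
  # a separable cohort reaches near-perfect CV F
  expect_gt(g1$cv_mean, 0.95)
  # duplicated grid rows: the first is chosen
  g2 <- grid_search_cv(t, "LR", data.frame(penalty = c("L2", "L2"), C = c(1, 1)),
                       5, seed = 2)
  expect_equal(rownames(as.data.frame(g2$best_params)), "1")
  expect_equal(g2$cv_table$cv_mean[1], g2$cv_table$cv_mean[2])
})

test_that("all three classifier backends fit, score and evaluate", {
  t <- generate_feature_cohort(150, 0.3, n_features = 4, class_shift = 4, seed = 12)
  sp <- stratified_split(t, 0.7, seed = 3)
  for (cls in c("LR", "SVM", "GBT")) {
    gs <- grid_search_cv(sp$train, cls, default_grids()[[cls]], 5, seed = 4)
    m <- evaluate_model(gs$fit, sp$test)
    expect_true(all(m >= 0 & m <= 1))
    expect_gt(m[["f_score"]], 0.6)
    expect_gt(m[["auc"]], 0.8)
  }
})

test_that("benchmark covers every cell without test-set leakage", {
  t <- generate_feature_cohort(140, 0.25, n_features = 5, class_shift = 3, seed = 20)
  datasets <- list(A = t[, 1:4], B = t[, c(1, 4:6)])
  mat <- build_resampled_matrix(datasets, seed = 5)
  expect_length(mat$resampled, 10)
  tiny <- list(LR = data.frame(penalty = "L2", C = 1),
               SVM = data.frame(kernel = "radial", C = 1, gamma = "scale"))
  report <- run_benchmark(mat, tiny, folds = 5, seed = 6)
  expect_equal(nrow(report), 20)  # 2 datasets x 5 techniques x 2 classifiers
  expect_true(all(report$f_score >= 0 & report$f_score <= 1))
  # exactly one flagged best per dataset x technique
  agg <- aggregate(best ~ dataset + technique, report, sum)
  expect_true(all(agg$best == 1))
  # leakage check via row fingerprints
  fp <- function(d) apply(round(d[, setdiff(names(d), c("label", "origin")),
                                  drop = FALSE], 10), 1, paste, collapse = "|")
  for (dn in names(datasets)) {
    test_fp <- fp(mat$test[[dn]])
    for (tech in c("UNDERSAMPLING", "SMOTE", "ADASYN", "SMOTETomek", "SMOTEENN")) {
      r <- mat$resampled[[paste(dn, tech, sep = "|")]]
      expect_length(intersect(test_fp, fp(r$table)), 0)
    }
  }
})

test_that("the best model degrades as the training minority shrinks", {
  t <- generate_feature_cohort(260, 0.3, n_features = 4, class_shift = 2.5, seed = 30)
  sp <- stratified_split(t, 0.7, seed = 7)
  tr <- sp$train
  min_idx <- which(tr$label == "degraded")
  fs <- vapply(c(1, 0.4, 0.12), function(keep) {
    drop <- min_idx[-seq_len(max(2, floor(length(min_idx) * keep)))]
    tr2 <- if (length(drop)) tr[-drop, ] else tr
    gs <- grid_search_cv(tr2, "LR", data.frame(penalty = "L2", C = 1), 3, seed = 8)
    evaluate_model(gs$fit, sp$test)[["f_score"]]
  }, numeric(1))
  expect_true(fs[1] >= fs[3])
  expect_true(fs[2] >= fs[3] - 0.05)
})
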