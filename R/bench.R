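# Stratified splitting, 5-fold grid-search model selection maximising the
# F-score, held-out evaluation, and the dataset x technique x classifier
# benchmark matrix. Degraded is the positive class throughout.
#
# Classifier backends: glmnet (logistic regression with L1/L2/elastic-net
# penalties), e1071::svm (linear/polynomial/RBF kernels) and xgboost
# (gradient-boosted trees). Features are z-scored inside each CV fold using
# fold-training statistics only (and on the full training set for the final
# refit); the scaler travels with the fitted model.

#' Stratified train/test split indices
#'
#' Per-class floor allocation: `floor(n_class * train_fraction)` rows of each
#' class go to training, the remainder to test. Disjoint and exhaustive.
#'
#' @param labels factor/character class labels
#' @param train_fraction fraction allocated to training (default 0.7)
#' @param seed integer seed
#' @return list with integer index vectors `train` and `test`
#' @export
stratified_split_index <- function(labels, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(as.character(labels))) {
    idx <- which(as.character(labels) == cl)
    n_tr <- floor(length(idx) * train_fraction)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Stratified train/test split of a feature table
#' @param t feature table with `label` column
#' @inheritParams stratified_split_index
#' @return list with data.frames `train` and `test`
#' @export
stratified_split <- function(t, train_fraction = 0.7, seed = 1L) {
  idx <- stratified_split_index(t$label, train_fraction, seed)
  tr <- t[idx$train, , drop = FALSE]; rownames(tr) <- NULL
  te <- t[idx$test, , drop = FALSE]; rownames(te) <- NULL
  list(train = tr, test = te)
}

# stratified fold assignment (1..folds) for a label vector
stratified_folds <- function(y, folds = 5L, seed = 1L) {
  set.seed(seed)
  f <- integer(length(y))
  for (cl in unique(as.character(y))) {
    idx <- sample(which(as.character(y) == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (any(vapply(split(as.character(y), f), function(s) length(unique(s)), 1L) < 2))
    ot_error("a fold lacks one of the classes", "osteotex_fold_degeneracy")
  f
}

# Metrics ---------------------------------------------------------------------

#' Binary classification metrics with degraded as the positive class
#'
#' @param truth factor/character true labels (healthy/degraded)
#' @param pred predicted labels
#' @param scores numeric scores for the degraded class (probabilities or
#'   decision values); used only for AUC (rank-based, scale-invariant)
#' @return named numeric vector: accuracy, sensitivity, precision, f_score,
#'   auc (NA when `scores` is missing)
#' @export
classification_metrics <- function(truth, pred, scores = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  tp <- sum(truth == "degraded" & pred == "degraded")
  fn <- sum(truth == "degraded" & pred == "healthy")
  fp <- sum(truth == "healthy" & pred == "degraded")
  tn <- sum(truth == "healthy" & pred == "healthy")
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  auc <- NA_real_
  if (!is.null(scores)) {
    pos <- scores[truth == "degraded"]; neg <- scores[truth == "healthy"]
    if (length(pos) && length(neg)) {
      r <- rank(c(pos, neg))  # mid-ranks handle ties
      auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
    }
  }
  c(accuracy = (tp + tn) / length(truth), sensitivity = sens,
    precision = prec, f_score = f1, auc = auc)
}

# Classifier backends ---------------------------------------------------------
# Each backend: fit(x, y, params) -> model; score(model, x) -> degraded score;
# labels are thresholded at 0.5 for probabilities / 0 for decision values.

fit_scaler <- function(x) {
  mu <- colMeans(x); s <- apply(x, 2, sd); s[s == 0] <- 1
  list(mu = mu, s = s)
}
apply_scaler <- function(sc, x) sweep(sweep(x, 2, sc$mu), 2, sc$s, "/")

fit_classifier <- function(x, y, classifier, params) {
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  y01 <- as.integer(y == "degraded")
  model <- switch(classifier,
    LR = {
      alpha <- c(L1 = 1, L2 = 0, ElasticNet = 0.5)[[params$penalty]]
      xs2 <- if (ncol(xs) < 2) cbind(xs, `.pad` = 0) else xs
      # glmnet warns about small class counts on the tiny folds this
      # workflow legitimately uses; the warning carries no information here
      withCallingHandlers(
        glmnet::glmnet(xs2, factor(y01, levels = c(0, 1)), family = "binomial",
                       alpha = alpha, lambda = 1 / (params$C * nrow(xs))),
        warning = function(w) {
          if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    },
    SVM = {
      g <- params$gamma
      gnum <- if (identical(g, "scale")) 1 / (ncol(xs) * max(var(as.numeric(xs)), 1e-12))
        else if (identical(g, "auto")) 1 / ncol(xs)
        else as.numeric(g)
      e1071::svm(xs, factor(y, levels = CLASS_LEVELS), kernel = params$kernel,
                 cost = params$C, gamma = gnum, scale = FALSE)
    },
    GBT = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(xs, label = y01, nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    stop("unknown classifier family: ", classifier)
  )
  structure(list(classifier = classifier, params = params, scaler = sc,
                 model = model), class = "ot_model")
}

# score = degraded probability (LR/GBT) or signed decision value (SVM)
score_classifier <- function(fit, x) {
  xs <- apply_scaler(fit$scaler, x)
  switch(fit$classifier,
    LR = {
      xs2 <- if (ncol(xs) < 2) cbind(xs, `.pad` = 0) else xs
      as.numeric(predict(fit$model, xs2, type = "response"))
    },
    SVM = {
      pr <- predict(fit$model, xs, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient so larger = more degraded, regardless of level order used
      if (grepl("^degraded/", colnames(dv)[1])) as.numeric(dv[, 1])
      else -as.numeric(dv[, 1])
    },
    GBT = as.numeric(predict(fit$model, xgboost::xgb.DMatrix(xs, nthread = 1)))
  )
}

predict_labels <- function(fit, x) {
  s <- score_classifier(fit, x)
  thr <- if (fit$classifier == "SVM") 0 else 0.5
  factor(ifelse(s > thr, "degraded", "healthy"), levels = CLASS_LEVELS)
}

# Hyperparameter grids --------------------------------------------------------

#' Hyperparameter grids for the three classifier families
#'
#' Full grids cover: LR penalties L1/L2/ElasticNet with C at integer powers
#' of ten from 1e-5 to 1e5; SVM kernels linear/polynomial/RBF with the same C
#' range and gamma at powers of two from 2^-2 to 2^5 plus `scale`/`auto`;
#' GBT learning rates 0.01/0.1/0.3/1.0, depths 4/6/8/10 and 1 to 500
#' boosting rounds. `reduced = TRUE` gives small subsets for desk-scale runs.
#'
#' @param reduced use the reduced grids (default TRUE)
#' @return named list of data.frames (`LR`, `SVM`, `GBT`), one row per
#'   hyperparameter combination
#' @export
default_grids <- function(reduced = TRUE) {
  if (reduced) {
    list(
      LR = expand.grid(penalty = c("L2", "L1"), C = c(0.1, 10),
                       stringsAsFactors = FALSE),
      SVM = expand.grid(kernel = c("linear", "radial"), C = c(1, 100),
                        gamma = "scale", stringsAsFactors = FALSE),
      GBT = expand.grid(eta = c(0.1, 0.3), max_depth = c(4, 6), nrounds = 50,
                        stringsAsFactors = FALSE)
    )
  } else {
    list(
      LR = expand.grid(penalty = c("L1", "L2", "ElasticNet"), C = 10^(-5:5),
                       stringsAsFactors = FALSE),
      SVM = expand.grid(kernel = c("linear", "polynomial", "radial"),
                        C = 10^(-5:5),
                        gamma = c(as.character(2^(-2:5)), "auto", "scale"),
                        stringsAsFactors = FALSE),
      GBT = expand.grid(eta = c(0.01, 0.1, 0.3, 1.0),
                        max_depth = c(4, 6, 8, 10),
                        nrounds = c(1, 10, 50, 100, 500),
                        stringsAsFactors = FALSE)
    )
  }
}

#' Grid-search model selection by 5-fold cross-validated F-score
#'
#' Exhaustively enumerates the grid; for each combination computes the mean
#' and standard deviation of the per-fold F-scores (stratified folds, shared
#' across combinations and classifier families for paired comparability);
#' selects the combination with the highest mean (ties: first in enumeration
#' order) and refits it on the full training table.
#'
#' @param train feature table with `label` column
#' @param classifier `"LR"`, `"SVM"` or `"GBT"`
#' @param grid data.frame of hyperparameter combinations (see
#'   [default_grids()])
#' @param folds number of CV folds (default 5)
#' @param seed integer seed (fold assignment)
#' @return list: `fit` (refit best model), `best_params`, `cv_mean`, `cv_sd`,
#'   `cv_table` (per-combination CV statistics)
#' @export
grid_search_cv <- function(train, classifier, grid, folds = 5L, seed = 1L) {
  fx <- split_features(train)
  fold_id <- stratified_folds(fx$y, folds, seed)
  stats <- vapply(seq_len(nrow(grid)), function(gi) {
    params <- as.list(grid[gi, , drop = FALSE])
    fs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_classifier(fx$x[tr, , drop = FALSE], fx$y[tr], classifier, params)
      pred <- predict_labels(fit, fx$x[!tr, , drop = FALSE])
      classification_metrics(fx$y[!tr], pred)[["f_score"]]
    }, numeric(1))
    c(mean = mean(fs), sd = sd(fs))
  }, numeric(2))
  best <- which.max(stats["mean", ])
  best_params <- as.list(grid[best, , drop = FALSE])
  fit <- fit_classifier(fx$x, fx$y, classifier, best_params)
  list(fit = fit, best_params = best_params,
       cv_mean = stats["mean", best], cv_sd = stats["sd", best],
       cv_table = cbind(grid, cv_mean = stats["mean", ], cv_sd = stats["sd", ]))
}

#' Evaluate a fitted model on a held-out feature table
#' @param fit an `ot_model` (from [grid_search_cv()]`$fit`)
#' @param test feature table with `label` column
#' @return named metric vector from [classification_metrics()]
#' @export
evaluate_model <- function(fit, test) {
  fx <- split_features(test)
  classification_metrics(fx$y, predict_labels(fit, fx$x),
                         score_classifier(fit, fx$x))
}

#' Run the full dataset x technique x classifier benchmark
#'
#' For every resampled training set and every classifier family, selects
#' hyperparameters by cross-validated F-score and evaluates on the (never
#' resampled) test partition of the corresponding feature dataset. The
#' best classifier per dataset-technique row (held-out F-score) is flagged.
#'
#' @param matrix_out result of [build_resampled_matrix()]
#' @param grids named list of grids (default [default_grids()])
#' @param folds CV folds (default 5)
#' @param seed integer seed
#' @param verbose print one line per cell
#' @return data.frame with one row per (dataset, technique, classifier):
#'   best hyperparameters (deparsed), CV mean/sd F-score and held-out
#'   accuracy, sensitivity, precision, f_score, auc, plus a `best` flag
#' @export
run_benchmark <- function(matrix_out, grids = default_grids(), folds = 5L,
                          seed = 1L, verbose = FALSE) {
  rows <- list()
  for (key in names(matrix_out$resampled)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    dataset <- parts[1]; technique <- parts[2]
    rtab <- matrix_out$resampled[[key]]$table
    test <- matrix_out$test[[dataset]]
    for (cls in names(grids)) {
      gs <- grid_search_cv(rtab, cls, grids[[cls]], folds,
                           seed = derive_seed(seed, length(rows)))
      met <- evaluate_model(gs$fit, test)
      if (verbose)
        message(sprintf("%s | %s | %s: CV F=%.3f test F=%.3f",
                        dataset, technique, cls, gs$cv_mean, met[["f_score"]]))
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = dataset, technique = technique, classifier = cls,
        best_params = paste(names(gs$best_params),
                            vapply(gs$best_params, as.character, ""),
                            sep = "=", collapse = ";"),
        cv_f_mean = gs$cv_mean, cv_f_sd = gs$cv_sd,
        accuracy = met[["accuracy"]], sensitivity = met[["sensitivity"]],
        precision = met[["precision"]], f_score = met[["f_score"]],
        auc = met[["auc"]], stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  # flag the best classifier per dataset x technique cell-row
  report$best <- FALSE
  for (key in unique(paste(report$dataset, report$technique))) {
    sel <- which(paste(report$dataset, report$technique) == key)
    report$best[sel[which.max(report$f_score[sel])]] <- TRUE
  }
  report
}

#' Summarise a benchmark report in the style of a results table
#'
#' One row per feature set and resampling technique showing the best
#' classifier by held-out F-score with its sensitivity, F-score and AUC.
#'
#' @param report data.frame from [run_benchmark()]
#' @return summary data.frame
#' @export
summarise_benchmark <- function(report) {
  best <- report[report$best, c("dataset", "technique", "classifier",
                                "sensitivity", "f_score", "auc")]
  names(best) <- c("feature_set", "resampling", "best_classifier",
                   "sensitivity", "f_score", "auc_roc")
  rownames(best) <- NULL
  best
}
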