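#!/usr/bin/env Rscript
# Stage 5 — cross-validated classifier benchmark over the 45 datasets.
#
# For every resampled training set, selects hyperparameters for logistic
# regression, SVM and gradient boosting by 5-fold cross-validated F-score
# (degraded = positive class), evaluates on the held-out test partition, and
# writes the 135-cell report plus a best-classifier summary table in the
# style of the results tables of imbalanced-classification studies.

library(osteotex)

files <- list.files("results/resampled", pattern = "__(TRAIN|TEST)\\.csv$",
                    full.names = TRUE)
read_ft <- function(f) {
  d <- read.csv(f, check.names = FALSE)
  d$label <- factor(d$label, levels = c("healthy", "degraded"))
  d
}
dsn <- unique(sub("__(TRAIN|TEST)\\.csv$", "", basename(files)))
train <- lapply(dsn, function(d) read_ft(file.path("results/resampled",
                                                   paste0(d, "__TRAIN.csv"))))
test <- lapply(dsn, function(d) read_ft(file.path("results/resampled",
                                                  paste0(d, "__TEST.csv"))))
names(train) <- names(test) <- dsn

resampled <- list()
for (f in list.files("results/resampled", pattern = "__.*csv$", full.names = TRUE)) {
  key <- sub("\\.csv$", "", basename(f))
  if (grepl("__(TRAIN|TEST)$", key) || key == "balance_summary") next
  d <- read_ft(f)
  origin <- d$origin
  d$origin <- NULL
  parts <- strsplit(key, "__", fixed = TRUE)[[1]]
  resampled[[paste(parts[1], parts[2], sep = "|")]] <-
    structure(list(table = d, technique = parts[2], origin = origin, seed = NA),
              class = "resampling_result")
}
mat <- list(resampled = resampled, train = train, test = test)

report <- run_benchmark(mat, default_grids(reduced = TRUE), folds = 5,
                        seed = 20260303, verbose = FALSE)
dir.create("results/report", showWarnings = FALSE, recursive = TRUE)
write.csv(report, "results/report/benchmark.csv", row.names = FALSE)
summary <- summarise_benchmark(report)
write.csv(summary, "results/report/summary.csv", row.names = FALSE)

cat(sprintf("benchmark: %d cells over %d datasets\n", nrow(report),
            length(resampled)))
best <- summary[which.max(summary$f_score), ]
cat(sprintf("best cell: %s + %s with %s (F = %.3f, AUC = %.3f, sens = %.3f)\n",
            best$feature_set, best$resampling, best$best_classifier,
            best$f_score, best$auc_roc, best$sensitivity))
cat("\nmean held-out F-score by resampling technique (all cells):\n")
print(round(tapply(report$f_score, report$technique, mean), 3))

# figure: held-out F-score by feature set, coloured by resampling technique
# (regenerate results/report/f_scores.png after rerunning the benchmark)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(report, aes(dataset, f_score, colour = technique,
                          shape = classifier)) +
    geom_point(position = position_dodge(width = 0.6), size = 2) +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 40, hjust = 1)) +
    labs(x = NULL, y = "held-out F-score (degraded positive)",
         colour = "resampling", shape = "classifier")
  ggsave("results/report/f_scores.png", p, width = 9, height = 4.5, dpi = 150)
  cat("figure written to results/report/f_scores.png\n")
}
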