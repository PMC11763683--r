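#!/usr/bin/env Rscript
# Stage 4 — stratified split and class-imbalance resampling.
#
# Applies one shared stratified 70/30 split to the nine feature datasets and
# balances each training partition with the five techniques (random
# undersampling, SMOTE, ADASYN, SMOTETomek, SMOTEENN), constraining every
# synthetic sample to the original feature ranges. Test partitions are never
# resampled. Writes the 45 resampled training sets plus the shared
# partitions under results/resampled/.

library(osteotex)

files <- list.files("results/features", full.names = TRUE)
datasets <- lapply(files, function(f) {
  d <- read.csv(f, check.names = FALSE)
  d$label <- factor(d$label, levels = c("healthy", "degraded"))
  d
})
names(datasets) <- sub("\\.csv$", "", basename(files))

mat <- suppressWarnings(build_resampled_matrix(datasets, seed = 20260302))

dir.create("results/resampled", recursive = TRUE, showWarnings = FALSE)
balance <- do.call(rbind, lapply(names(mat$resampled), function(key) {
  r <- mat$resampled[[key]]
  out <- r$table
  out$origin <- r$origin
  write.csv(out, file.path("results/resampled",
                           paste0(gsub("\\|", "__", key), ".csv")),
            row.names = FALSE)
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  data.frame(dataset = parts[1], technique = parts[2], rows = nrow(out),
             healthy = sum(out$label == "healthy"),
             degraded = sum(out$label == "degraded"),
             synthetic = sum(r$origin == "synthetic"))
}))
for (dn in names(datasets)) {
  write.csv(mat$train[[dn]],
            file.path("results/resampled", paste0(dn, "__TRAIN.csv")),
            row.names = FALSE)
  write.csv(mat$test[[dn]],
            file.path("results/resampled", paste0(dn, "__TEST.csv")),
            row.names = FALSE)
}
write.csv(balance, "results/resampled/balance_summary.csv", row.names = FALSE)

cat(sprintf("split: %d train / %d test (%d test degraded)\n",
            nrow(mat$train[[1]]), nrow(mat$test[[1]]),
            sum(mat$test[[1]]$label == "degraded")))
cat(sprintf("wrote %d resampled training sets\n", length(mat$resampled)))
print(head(balance[balance$dataset == "WFS", ], 5))
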