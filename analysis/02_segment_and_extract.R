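#!/usr/bin/env Rscript
# Stage 2/3 — segment the cohort and extract the radiomic feature datasets.
#
# Rebuilds each image's L1-L4 ROI mask from its overlay annotations with the
# four-step contour/divider/fill algorithm, verifies it against the stored
# ground truth (the algorithm is rule-based, so agreement must be exact),
# extracts the 93 texture features and assembles the nine analysis datasets
# under results/features/.

library(osteotex)

manifest <- read.csv("results/cohort/manifest.csv")
cat(sprintf("segmenting %d images...\n", nrow(manifest)))

cohort <- lapply(seq_len(nrow(manifest)), function(i) {
  structure(list(pixels = read_grey_png(file.path("results/cohort",
                                                  manifest$file[i])),
                 label = manifest$label[i]),
            class = "annotated_image")
})
truth <- lapply(file.path("results/cohort", manifest$truth_mask), read_grey_png)

masks <- lapply(cohort, build_mask)
jac <- mapply(mask_jaccard, masks, truth)
cat(sprintf("mask vs ground truth: mean Jaccard %.4f (min %.4f) over %d images\n",
            mean(jac), min(jac), length(jac)))
stopifnot(all(jac == 1))

dir.create("results/features", recursive = TRUE, showWarnings = FALSE)
feats <- extract_cohort(cohort, masks)
datasets <- assemble_datasets(feats)
for (dn in names(datasets))
  write.csv(datasets[[dn]], file.path("results/features", paste0(dn, ".csv")),
            row.names = FALSE)
sizes <- vapply(datasets, function(d) ncol(d) - 1L, integer(1))
cat("feature datasets written:\n")
print(sizes)
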