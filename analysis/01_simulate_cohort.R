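#!/usr/bin/env Rscript
# Stage 1 — simulate an annotated DXA-like cohort.
#
# Generates the synthetic study cohort: grey-level spine images with
# scanner-style overlay annotations (black lateral contours, white divider
# segments bounding L1-L4), known ground-truth ROI masks, and
# healthy/degraded labels at the screening-population imbalance. Writes the
# images, truth masks and a manifest under results/cohort/.

library(osteotex)

out <- "results/cohort"
spec <- cohort_spec(n_patients = 300, degraded_fraction = 0.12,
                    image_height = 120, image_width = 112,
                    texture_separation = 3.0, seed = 20260301)

cohort <- generate_cohort(spec)
manifest <- write_cohort(cohort, out)

labs <- table(vapply(cohort, function(x) x$label, character(1)))
cat(sprintf("simulated %d images (%d x %d): %d degraded (%.1f%%), %d healthy\n",
            length(cohort), spec$image_height, spec$image_width,
            labs[["degraded"]], 100 * labs[["degraded"]] / length(cohort),
            labs[["healthy"]]))
cat(sprintf("artefacts in %s (images/, masks_truth/, manifest.csv)\n", out))
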