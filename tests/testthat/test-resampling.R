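# fixture: two Gaussian blobs with controllable overlap
blob_table <- function(n_maj = 40, n_min = 12, gap = 4, seed = 1, p = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_maj * p), n_maj, p),
             matrix(rnorm(n_min * p, mean = gap / sqrt(p)), n_min, p))
  colnames(x) <- paste0("f", seq_len(p))
  data.frame(label = factor(rep(c("healthy", "degraded"), c(n_maj, n_min)),
                            levels = c("healthy", "degraded")),
             x)
}

test_that("random undersampling balances to the minority count", {
  t <- generate_feature_cohort(1071, 129 / 1071, n_features = 4,
                               class_shift = 2, seed = 3)
  expect_equal(as.vector(table(t$label)), c(942, 129))
  r <- random_undersample(t, seed = 5)
  expect_equal(unname(table(r$table$label)[["healthy"]]), 129)
  expect_equal(unname(table(r$table$label)[["degraded"]]), 129)
  expect_true(all(r$origin == "original"))
  # all original minority rows retained
  expect_equal(sum(r$table$label == "degraded"), sum(t$label == "degraded"))
  # different seeds retain different majority subsets of equal size
  r2 <- random_undersample(t, seed = 6)
  expect_equal(nrow(r2$table), nrow(r$table))
  expect_false(identical(r$table, r2$table))
  # already balanced input is a fixed point up to row order
  tb <- blob_table(15, 15)
  rb <- random_undersample(tb, seed = 1)
  expect_equal(nrow(rb$table), 30)
})

test_that("single-class input is rejected", {
  t <- blob_table(10, 5)
  t$label[] <- "healthy"
  expect_error(random_undersample(t, 1), class = "osteotex_single_class")
  expect_error(smote(t, 3, 1), class = "osteotex_single_class")
})

test_that("SMOTE balances classes and synthesises on minority segments", {
  t <- generate_feature_cohort(1071, 129 / 1071, n_features = 4,
                               class_shift = 2, seed = 3)
  r <- smote(t, k = 5, seed = 11)
  expect_equal(as.vector(table(r$table$label)), c(942, 942))
  expect_equal(sum(r$origin == "synthetic"), 942 - 129)
  expect_true(all(r$table$label[r$origin == "synthetic"] == "degraded"))
  # original rows come first and are untouched
  expect_identical(r$table[seq_len(nrow(t)), ], t)
})

test_that("SMOTE degenerate geometries behave as interpolation dictates", {
  # duplicated minority point: every synthetic row equals that point
  t <- blob_table(6, 0)
  t <- rbind(t, t[1:2, ])
  t$label[7:8] <- "degraded"
  t[7, -1] <- t[8, -1] <- c(5, 5, 5)
  r <- smote(t, k = 1, seed = 2)
  syn <- r$table[r$origin == "synthetic", -1]
  expect_true(all(abs(as.matrix(syn) - 5) < 1e-12))
  # collinear minority: synthetic points stay on the line
  t2 <- blob_table(12, 0, p = 2)
  line <- data.frame(label = factor(rep("degraded", 3),
                                    levels = c("healthy", "degraded")),
                     f1 = c(0, 1, 2), f2 = c(0, 2, 4))
  t2 <- rbind(t2, line)
  r2 <- smote(t2, k = 2, seed = 7)
  syn2 <- as.matrix(r2$table[r2$origin == "synthetic", -1])
  expect_true(all(abs(syn2[, 2] - 2 * syn2[, 1]) < 1e-9))
})

test_that("SMOTE rejects too-small minorities", {
  t <- blob_table(20, 4)
  expect_error(smote(t, k = 5, seed = 1), class = "osteotex_too_few_minority")
})

test_that("ADASYN concentrates quotas near the class boundary", {
  # minority points: three isolated far away, one planted inside the majority
  # blob; the planted point must receive the largest quota
  set.seed(8)
  maj <- matrix(rnorm(24, 0, 0.5), 12, 2)
  mino <- rbind(c(10, 10), c(10.5, 10), c(10, 10.5), c(10.4, 10.6),
                c(11, 10.5), c(10.6, 11), c(0, 0))
  x <- rbind(maj, mino)
  colnames(x) <- c("f1", "f2")
  t <- data.frame(label = factor(rep(c("healthy", "degraded"), c(12, 7)),
                                 levels = c("healthy", "degraded")), x)
  r <- adasyn(t, k = 5, seed = 3)
  expect_equal(as.vector(table(r$table$label)), c(12, 12))
  syn <- as.matrix(r$table[r$origin == "synthetic", -1])
  # the boundary point (0,0) interpolates towards the far cluster, so most
  # synthetic points involve it: they lie far from the pure far-cluster box
  near_far_cluster <- rowSums(syn > 9.5) == 2
  expect_lt(sum(near_far_cluster), nrow(syn) / 2)
  # post-hoc class ratio within 5% of 1
  tab <- table(r$table$label)
  expect_lt(abs(tab[["degraded"]] / tab[["healthy"]] - 1), 0.05)
})

test_that("ADASYN falls back to uniform quotas when density is degenerate", {
  t <- blob_table(30, 8, gap = 50, seed = 2)  # minority island, no majority nbrs
  expect_warning(r <- adasyn(t, k = 5, seed = 4), "degenerate density")
  expect_equal(as.vector(table(r$table$label)), c(30, 30))
})

test_that("Tomek links match the mutual-nearest-neighbour oracle", {
  # constructed: two interleaved points closer to each other than anything else
  t <- blob_table(7, 6, gap = 12, seed = 5, p = 2)
  t[1, -1] <- c(5.0, 5.0)    # healthy outlier next to a degraded point
  t[8, -1] <- c(5.1, 5.1)
  links <- tomek_links(t)
  expect_equal(nrow(links), 1)
  expect_setequal(unlist(links[1, ]), c(1, 8))
  # well separated clusters: no links
  t2 <- blob_table(10, 10, gap = 30, seed = 6)
  expect_equal(nrow(tomek_links(t2)), 0)
  # random table vs brute-force oracle
  t3 <- blob_table(25, 15, gap = 1.5, seed = 7)
  expect_equal(tomek_links(t3), oracle_tomek(t3))
  # removal drops only majority members
  cleaned <- remove_majority_of_links(t)
  expect_equal(nrow(cleaned), 12)
  expect_equal(sum(cleaned$label == "degraded"), 6)
})

test_that("ENN removes majority points stranded in the minority cluster", {
  t <- blob_table(8, 4, gap = 20, seed = 9, p = 2)
  t[1, -1] <- t[10, -1] + 0.01  # majority point deep inside minority cluster
  cleaned <- enn_clean(t, k = 3)
  expect_equal(nrow(cleaned), nrow(t) - 1)
  expect_false(any(abs(as.matrix(cleaned[cleaned$label == "healthy", -1]) -
                         as.numeric(t[1, -1])) < 1e-9))
  # homogeneous, well-separated clusters: nothing removed
  t2 <- blob_table(10, 8, gap = 25, seed = 10)
  expect_equal(nrow(enn_clean(t2, 3)), nrow(t2))
  # monotone: never grows
  t3 <- blob_table(20, 12, gap = 1, seed = 11)
  expect_lte(nrow(enn_clean(t3, 3)), nrow(t3))
})

test_that("hybrid resamplers compose SMOTE with their cleaning step", {
  # separable clusters: SMOTETomek output equals SMOTE output
  t <- blob_table(30, 10, gap = 25, seed = 12)
  s <- smote(t, 5, seed = 20)
  st <- smote_tomek(t, 5, seed = 20)
  expect_equal(st$table, s$table)
  # overlapping clusters: SMOTEENN output strictly smaller than SMOTE output
  t2 <- blob_table(40, 12, gap = 1.2, seed = 13)
  s2 <- smote(t2, 5, seed = 21)
  se <- smote_enn(t2, 5, seed = 21)
  expect_lt(nrow(se$table), nrow(s2$table))
  # SMOTEENN rows are a subset of the SMOTE rows (ENN only removes)
  key <- function(d) paste(d$label,
                           apply(round(as.matrix(d[, c("f1", "f2", "f3")]), 10),
                                 1, paste, collapse = "|"))
  expect_true(all(key(se$table) %in% key(s2$table)))
  # determinism under a fixed seed
  expect_identical(smote_enn(t2, 5, seed = 21)$table, se$table)
})

test_that("range clipping restores the original columnwise bounds", {
  t <- blob_table(30, 10, gap = 6, seed = 14)
  r <- smote(t, 5, seed = 15)
  # inflate one synthetic value beyond the original range
  syn_idx <- which(r$origin == "synthetic")
  r$table$f1[syn_idx[1]] <- max(t$f1) + 10
  r$table$f2[syn_idx[2]] <- min(t$f2) - 10
  clipped <- clip_to_original_range(r, t)
  expect_equal(clipped$table$f1[syn_idx[1]], max(t$f1))
  expect_equal(clipped$table$f2[syn_idx[2]], min(t$f2))
  for (cl in c("f1", "f2", "f3")) {
    expect_equal(range(clipped$table[[cl]]), range(t[[cl]]))
  }
  # identity when already within range
  r2 <- smote(t, 5, seed = 16)
  r2c <- clip_to_original_range(r2, t)
  expect_equal(r2c$table, r2$table)
})

test_that("the resampling matrix covers datasets x techniques and spares tests", {
  co <- generate_cohort(cohort_spec(40, 0.3, 100, 90,
                                    texture_separation = 3, seed = 30))
  feats <- extract_cohort(co, masks = lapply(co, `[[`, "truth_mask"))
  ds <- assemble_datasets(feats)
  mat <- build_resampled_matrix(ds, seed = 2)
  expect_length(mat$resampled, 45)
  for (key in names(mat$resampled)) {
    r <- mat$resampled[[key]]
    dn <- strsplit(key, "|", fixed = TRUE)[[1]][1]
    n_train <- nrow(mat$train[[dn]])
    if (r$technique == "UNDERSAMPLING") expect_lt(nrow(r$table), n_train)
    else expect_gt(nrow(r$table), n_train)
  }
  # test partitions identical to a direct stratified split: never resampled
  idx <- stratified_split_index(ds[[1]]$label, 0.7, seed = 2)
  for (dn in names(ds)) {
    direct <- ds[[dn]][idx$test, , drop = FALSE]
    rownames(direct) <- NULL
    expect_identical(mat$test[[dn]], direct)
  }
  # label conservation: no resampler changes an original row's label
  for (key in names(mat$resampled)) {
    r <- mat$resampled[[key]]
    orig <- r$table[r$origin == "original", ]
    dn <- strsplit(key, "|", fixed = TRUE)[[1]][1]
    expect_true(all(paste(orig$label) %in% paste(mat$train[[dn]]$label)))
    expect_true(all(r$table$label[r$origin == "synthetic"] == "degraded"))
  }
})
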