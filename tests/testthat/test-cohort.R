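test_that("cohort label counts follow the rounding rule", {
  co <- generate_cohort(cohort_spec(100, 0.13, 100, 90, seed = 1))
  labs <- vapply(co, function(x) x$label, character(1))
  expect_length(co, 100)
  expect_equal(sum(labs == "degraded"), 13)
  expect_equal(sum(labs == "healthy"), 87)
})

test_that("a 1531-patient cohort at the screening imbalance has 185 degraded", {
  # image generation at full cohort scale is unnecessary: the label allocation
  # is decided before any pixel is drawn, so a feature cohort checks the count
  t <- generate_feature_cohort(1531, 0.1208, n_features = 2, class_shift = 1, seed = 7)
  expect_equal(sum(t$label == "degraded"), 185)
  expect_equal(sum(t$label == "healthy"), 1346)
})

test_that("equal seeds give bit-identical cohorts, different seeds differ", {
  s <- cohort_spec(4, 0.5, 100, 90, seed = 42)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
  c <- generate_cohort(cohort_spec(4, 0.5, 100, 90, seed = 43))
  expect_false(identical(a[[1]]$pixels, c[[1]]$pixels))
})

test_that("annotation invariants hold on generated images", {
  co <- generate_cohort(cohort_spec(6, 0.34, 120, 100, seed = 5))
  for (im in co) {
    px <- im$pixels
    rows <- which(!is.na(im$left_contour))
    # contour pixels are exactly 0; dividers carry the maximum grey value
    expect_true(all(px[cbind(rows, im$left_contour[rows])] == 0))
    expect_true(all(px[cbind(rows, im$right_contour[rows])] == 0))
    for (d in im$divider_rows) {
      seg <- px[d, (im$left_contour[d] + 1):(im$right_contour[d] - 1)]
      expect_true(all(seg == 255))
    }
    # contours are 8-connected down the rows
    expect_true(all(abs(diff(im$left_contour[rows])) <= 1))
    expect_true(all(abs(diff(im$right_contour[rows])) <= 1))
    # truth mask lies between the contours and the L1/L4 divider rows
    roi <- which(im$truth_mask != 0, arr.ind = TRUE)
    expect_true(all(roi[, 1] >= im$roi_top & roi[, 1] <= im$roi_bottom))
    expect_true(all(roi[, 2] >= im$left_contour[roi[, 1]]))
    expect_true(all(roi[, 2] <= im$right_contour[roi[, 1]]))
    # no tissue pixel collides with the annotation values
    ann <- matrix(FALSE, nrow(px), ncol(px))
    ann[cbind(rows, im$left_contour[rows])] <- TRUE
    ann[cbind(rows, im$right_contour[rows])] <- TRUE
    for (d in im$divider_rows)
      ann[d, (im$left_contour[d] + 1):(im$right_contour[d] - 1)] <- TRUE
    expect_true(all(px[!ann] >= 1 & px[!ann] <= 254))
  }
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(1, 0.5), class = "osteotex_bad_spec")
  expect_error(cohort_spec(10, 0), class = "osteotex_bad_spec")
  expect_error(cohort_spec(10, 1), class = "osteotex_bad_spec")
  expect_error(cohort_spec(10, 0.5, -5, 90), class = "osteotex_bad_spec")
  expect_error(cohort_spec(10, 0.01), class = "osteotex_bad_spec")  # no degraded
  expect_error(generate_feature_cohort(100, 0.2, 4, class_shift = -1),
               class = "osteotex_bad_spec")
})

test_that("feature cohort with zero shift shows no systematic mean difference", {
  # with class_shift = 0 the two-sample t-test on any feature should reject
  # at alpha = 0.01 only at the nominal rate; over 50 seeds more than 4
  # rejections would be wildly improbable (P < 2e-4)
  rejections <- 0
  for (s in 1:50) {
    t <- generate_feature_cohort(120, 0.3, n_features = 3, class_shift = 0, seed = s)
    p <- t.test(t$f01 ~ t$label)$p.value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 4)
})

test_that("a wide-margin feature cohort is linearly separable", {
  t <- generate_feature_cohort(400, 0.25, n_features = 5, class_shift = 6, seed = 3)
  sp <- stratified_split(t, 0.7, seed = 1)
  fit <- suppressWarnings(glm(label ~ ., data = sp$train, family = binomial))
  pred <- ifelse(predict(fit, sp$test, type = "response") > 0.5,
                 "degraded", "healthy")
  m <- classification_metrics(sp$test$label, pred)
  expect_gt(m[["f_score"]], 0.95)
})

test_that("class separation in extracted features grows with texture_separation", {
  seps <- c(0.5, 1.5, 3)
  gaps <- vapply(seps, function(sep) {
    co <- generate_cohort(cohort_spec(30, 0.5, 100, 90, sep, seed = 99))
    f <- extract_cohort(co, masks = lapply(co, `[[`, "truth_mask"))
    x <- as.matrix(f[, -1])
    s <- apply(x, 2, sd); s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")  # pooled-sd units so families are comparable
    mean(abs(colMeans(x[f$label == "degraded", , drop = FALSE]) -
               colMeans(x[f$label == "healthy", , drop = FALSE])))
  }, numeric(1))
  expect_true(all(diff(gaps) >= 0))
})

test_that("PNG round trip preserves pixels and the manifest matches", {
  co <- generate_cohort(cohort_spec(3, 0.34, 100, 90, seed = 2))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_equal(nrow(manifest), 3)
  back <- read_grey_png(file.path(dir, manifest$file[2]))
  expect_identical(back, co[[2]]$pixels)
  mback <- read_grey_png(file.path(dir, manifest$truth_mask[2]))
  expect_identical(mback, co[[2]]$truth_mask)
})
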