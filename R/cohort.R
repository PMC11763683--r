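# Synthetic DXA-like cohort generation.
#
# Emulates annotated lumbar-spine DXA scans as exported by scanner software:
# a grey-level image in which the lateral spine contour is drawn in black
# (grey value 0) and five white horizontal divider segments bound the four
# lumbar vertebrae L1-L4 (top of L1, three internal dividers, bottom of L4).
# Trabecular texture is a stationary Gaussian random field: white noise
# smoothed with a class-dependent Gaussian kernel. Healthy bone gets a short
# correlation length (fine-grained texture); degraded bone a longer one
# (coarser, more homogeneous), with the gap controlled by texture_separation.

#' Specification of a synthetic DXA cohort
#'
#' @param n_patients number of images to generate (>= 2)
#' @param degraded_fraction fraction of images labelled degraded, in (0, 1).
#'   The default 0.13 matches the class imbalance typical of a postmenopausal
#'   screening population, where roughly 13% of spines show a degraded
#'   trabecular microarchitecture.
#' @param image_height,image_width image dimensions in pixels; defaults 300 x
#'   280, the working resolution of lumbar-spine DXA exports.
#' @param texture_separation nonnegative scalar controlling how distinguishable
#'   the two texture classes are (0 = identical distributions). It widens the
#'   correlation-length gap between classes; default 1.5 gives a learnable but
#'   imperfect classification problem.
#' @param seed integer seed; equal seeds give bit-identical cohorts.
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n_patients, degraded_fraction = 0.13,
                        image_height = 300L, image_width = 280L,
                        texture_separation = 1.5, seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2)
    ot_error("n_patients must be >= 2", "osteotex_bad_spec")
  if (!is.numeric(degraded_fraction) ||
      degraded_fraction <= 0 || degraded_fraction >= 1)
    ot_error("degraded_fraction must lie strictly in (0, 1)", "osteotex_bad_spec")
  if (image_height <= 0 || image_width <= 0)
    ot_error("image dimensions must be positive", "osteotex_bad_spec")
  if (image_height < 60 || image_width < 40)
    ot_error("image too small to carry contour and divider annotations",
             "osteotex_bad_spec")
  if (texture_separation < 0)
    ot_error("texture_separation must be nonnegative", "osteotex_bad_spec")
  n_degraded <- round(n_patients * degraded_fraction)
  if (n_degraded < 1 || n_degraded >= n_patients)
    ot_error("cohort must contain at least one sample of each class",
             "osteotex_bad_spec")
  structure(list(
    n_patients = as.integer(n_patients),
    degraded_fraction = degraded_fraction,
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    texture_separation = texture_separation,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Smooth a white-noise field with a separable Gaussian kernel.
# Noise is generated with a margin so the crop carries no edge artefacts.
gaussian_field <- function(nr, nc, sigma) {
  if (sigma <= 0) return(matrix(rnorm(nr * nc), nr, nc))
  rad <- ceiling(3 * sigma)
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pr <- nr + 2 * rad
  pc <- nc + 2 * rad
  z <- matrix(rnorm(pr * pc), pr, pc)
  z <- stats::filter(z, k, sides = 2)            # along columns
  z <- t(stats::filter(t(z), k, sides = 2))      # along rows
  z <- z[(rad + 1):(rad + nr), (rad + 1):(rad + nc), drop = FALSE]
  z <- (z - mean(z)) / sd(z)
  matrix(as.numeric(z), nr, nc)
}

# Geometry of the overlay annotation for a given image size and phase pair.
# Contours are low-amplitude sinusoids around vertical lines at 32% / 68% of
# the width; the slope is kept below one pixel per row so consecutive contour
# pixels are always 8-connected after rounding.
annotation_geometry <- function(h, w, phase_left, phase_right) {
  r0 <- round(0.06 * h) + 1L
  r1 <- h - round(0.06 * h)
  amp <- max(2L, round(0.02 * w))
  period <- (r1 - r0) / 2
  rows <- r0:r1
  lc <- round(0.32 * w + amp * sin(2 * pi * (rows - r0) / period + phase_left))
  rc <- round(0.68 * w + amp * sin(2 * pi * (rows - r0) / period + phase_right))
  left <- rep(NA_integer_, h); left[rows] <- as.integer(lc)
  right <- rep(NA_integer_, h); right[rows] <- as.integer(rc)
  span <- r1 - r0
  t0 <- r0 + round(0.12 * span)
  t1 <- r1 - round(0.12 * span)
  dividers <- as.integer(round(seq(t0, t1, length.out = 5)))
  list(rows = rows, left = left, right = right, divider_rows = dividers)
}

# Tissue grey levels occupy [1, 254]: 0 is reserved for contour annotation
# pixels and 255 for the white divider segments, so the mask algorithm's
# zero test and maximum-grey test can never collide with tissue.
TISSUE_MIN <- 1L
TISSUE_MAX <- 254L
DIVIDER_VALUE <- 255L

clamp_grey <- function(x, lo = TISSUE_MIN, hi = TISSUE_MAX) {
  x <- round(x)
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Background and tissue occupy disjoint grey bands (background <= 75,
# tissue >= 85) so the contour detector's brighter-inside test holds on
# every row by construction, not just in expectation.
BACKGROUND_HI <- 75L
TISSUE_LO <- 85L

# Within-class spread of the latent coarseness (correlation length) of a
# patient's trabecular texture. Classes differ by texture_separation * TAU in
# the latent mean, so texture_separation is the class separation in units of
# the within-class standard deviation.
COARSENESS_TAU <- 0.25
COARSENESS_HEALTHY <- 1.0

generate_annotated_image <- function(h, w, label, texture_separation, seed) {
  set.seed(seed)
  phase_l <- runif(1, 0, 2 * pi)
  phase_r <- runif(1, 0, 2 * pi)
  geo <- annotation_geometry(h, w, phase_l, phase_r)

  # patient-level latent coarseness: healthy bone is fine-grained (short
  # correlation length), degraded bone coarser and more homogeneous; the
  # biological within-class variability makes the classes overlap
  mu_c <- COARSENESS_HEALTHY +
    if (label == "degraded") texture_separation * COARSENESS_TAU else 0
  sigma <- max(0.3, rnorm(1, mu_c, COARSENESS_TAU))
  sd_tissue <- 40 / (1 + 0.15 * max(0, sigma - COARSENESS_HEALTHY))
  # acquisition nuisance, independent of class: small gain/offset jitter
  gain <- rnorm(1, 1, 0.03)
  offset <- rnorm(1, 0, 3)

  spine <- gaussian_field(h, w, sigma)
  backg <- matrix(rnorm(h * w), h, w)

  px <- clamp_grey(55 + 10 * backg, TISSUE_MIN, BACKGROUND_HI)
  # spine interior: brighter tissue between the contours
  for (r in geo$rows) {
    lcr <- geo$left[r]; rcr <- geo$right[r]
    if (rcr - lcr >= 2) {
      cols <- (lcr + 1):(rcr - 1)
      px[r, cols] <- clamp_grey(gain * (160 + offset + sd_tissue * spine[r, cols]),
                                TISSUE_LO, TISSUE_MAX)
    }
  }
  # overlay: black contours, white dividers strictly between the contours
  for (r in geo$rows) {
    px[r, geo$left[r]] <- 0L
    px[r, geo$right[r]] <- 0L
  }
  for (d in geo$divider_rows) {
    px[d, (geo$left[d] + 1):(geo$right[d] - 1)] <- DIVIDER_VALUE
  }
  storage.mode(px) <- "integer"

  top <- geo$divider_rows[1]
  bottom <- geo$divider_rows[5]
  truth <- matrix(0L, h, w)
  for (r in top:bottom) truth[r, geo$left[r]:geo$right[r]] <- 255L

  structure(list(
    pixels = px,
    left_contour = geo$left,
    right_contour = geo$right,
    divider_rows = geo$divider_rows,
    roi_top = top,
    roi_bottom = bottom,
    truth_mask = truth,
    label = label,
    seed = seed
  ), class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image %dx%d, label=%s, ROI rows %d-%d>\n",
              nrow(x$pixels), ncol(x$pixels), x$label, x$roi_top, x$roi_bottom))
  invisible(x)
}

#' Generate a cohort of annotated DXA-like images
#'
#' Produces `n_patients` annotated images with known ground-truth ROI masks and
#' class labels. Exactly `round(n_patients * degraded_fraction)` images carry
#' the degraded label. The generator is fully deterministic under the spec
#' seed: identical specs yield bit-identical cohorts.
#'
#' @param spec a [cohort_spec()]
#' @return a list of `annotated_image` objects, each holding the pixel matrix,
#'   the stored contour coordinates, divider rows, ground-truth mask and label
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  nd <- round(n * spec$degraded_fraction)
  labels <- c(rep("degraded", nd), rep("healthy", n - nd))
  set.seed(derive_seed(spec$seed, 0L))
  labels <- sample(labels)
  lapply(seq_len(n), function(i) {
    generate_annotated_image(spec$image_height, spec$image_width,
                             labels[i], spec$texture_separation,
                             derive_seed(spec$seed, i))
  })
}

#' Generate a labelled multivariate-Gaussian feature table
#'
#' A fast fixture that bypasses imaging: two Gaussian clusters with identity
#' within-class covariance whose mean separation equals `class_shift` in units
#' of the within-class standard deviation (Euclidean norm of the mean
#' difference vector). Labels are imbalanced per `degraded_fraction`.
#'
#' @param n number of rows (>= 4)
#' @param degraded_fraction fraction of degraded rows, in (0, 1)
#' @param n_features number of feature columns (>= 1)
#' @param class_shift nonnegative separation between class means
#' @param seed integer seed
#' @return a data.frame with a `label` factor column (levels healthy,
#'   degraded) and `n_features` numeric columns `f01`, `f02`, ...
#' @export
generate_feature_cohort <- function(n, degraded_fraction, n_features = 8L,
                                    class_shift = 2, seed = 1L) {
  if (n < 4) ot_error("n must be >= 4", "osteotex_bad_spec")
  if (n_features < 1) ot_error("n_features must be >= 1", "osteotex_bad_spec")
  if (class_shift < 0) ot_error("class_shift must be nonnegative", "osteotex_bad_spec")
  if (degraded_fraction <= 0 || degraded_fraction >= 1)
    ot_error("degraded_fraction must lie strictly in (0, 1)", "osteotex_bad_spec")
  nd <- round(n * degraded_fraction)
  if (nd < 1 || nd >= n)
    ot_error("both classes must be represented", "osteotex_bad_spec")
  set.seed(seed)
  labels <- sample(c(rep("degraded", nd), rep("healthy", n - nd)))
  x <- matrix(rnorm(n * n_features), n, n_features)
  delta <- class_shift / sqrt(n_features)
  x[labels == "degraded", ] <- x[labels == "degraded", , drop = FALSE] + delta
  colnames(x) <- sprintf("f%02d", seq_len(n_features))
  out <- data.frame(label = as_label_factor(labels), x,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# PNG / CSV round trip --------------------------------------------------------

#' Write a cohort to disk as grey PNG images plus a manifest
#'
#' Writes `images/<id>.png` (8-bit grey), `masks_truth/<id>.png` (binary
#' ground-truth masks) and `manifest.csv` (file name, label, seed) under `dir`.
#'
#' @param cohort list of `annotated_image` objects
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest data.frame
#' @export
write_cohort <- function(cohort, dir) {
  img_dir <- file.path(dir, "images")
  msk_dir <- file.path(dir, "masks_truth")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("img%04d", seq_along(cohort))
  for (i in seq_along(cohort)) {
    write_grey_png(cohort[[i]]$pixels, file.path(img_dir, paste0(ids[i], ".png")))
    write_grey_png(cohort[[i]]$truth_mask, file.path(msk_dir, paste0(ids[i], ".png")))
  }
  manifest <- data.frame(
    id = ids,
    file = paste0("images/", ids, ".png"),
    truth_mask = paste0("masks_truth/", ids, ".png"),
    label = vapply(cohort, function(im) im$label, character(1)),
    seed = vapply(cohort, function(im) im$seed, integer(1))
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write an 8-bit grey image matrix as PNG
#' @param pixels integer matrix with values in 0..255
#' @param path output file
#' @export
write_grey_png <- function(pixels, path) {
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' Read an 8-bit grey PNG back into an integer matrix
#' @param path PNG file
#' @return integer matrix with values in 0..255
#' @export
read_grey_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m <- round(m * 255)
  storage.mode(m) <- "integer"
  m
}
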