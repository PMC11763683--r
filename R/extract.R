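# Assembly of the 93-feature vector and the nine analysis datasets.

FAMILIES <- c("fois", "glcm", "glrlm", "glszm", "gldm", "ngtdm")
FAMILY_SIZES <- c(fois = 18L, glcm = 24L, glrlm = 16L, glszm = 16L,
                  gldm = 14L, ngtdm = 5L)

#' Extract radiomic texture features from a masked image
#'
#' Computes the requested feature families inside the ROI and concatenates
#' them in stable column order (`fois`, `glcm`, `glrlm`, `glszm`, `gldm`,
#' `ngtdm`). With all six families this yields the full 93-feature vector
#' (18 + 24 + 16 + 16 + 14 + 5).
#'
#' @param image pixel matrix (or `annotated_image`)
#' @param mask matrix, nonzero = ROI
#' @param families `"all"` or a character subset of
#'   `c("fois","glcm","glrlm","glszm","gldm","ngtdm")`
#' @param n_levels grey levels for discretisation (default 32)
#' @param alpha,delta GLDM similarity cutoff and neighbourhood distance
#' @return named numeric vector, names `family_FeatureName`
#' @export
extract_features <- function(image, mask, families = "all", n_levels = 32L,
                             alpha = 0L, delta = 1L) {
  if (identical(families, "all")) families <- FAMILIES
  stopifnot(all(families %in% FAMILIES))
  families <- FAMILIES[FAMILIES %in% families]  # stable order
  px <- get_pixels(image)
  need_q <- any(families != "fois")
  q <- if (need_q) quantise(px, mask, n_levels) else NULL
  parts <- lapply(families, function(f) {
    switch(f,
      fois = first_order_features(px, mask, n_levels),
      glcm = glcm_features(glcm(q)),
      glrlm = glrlm_features(glrlm(q)),
      glszm = glszm_features(glszm(q)),
      gldm = gldm_features(gldm(q, alpha, delta)),
      ngtdm = ngtdm_features(ngtdm(q, delta))
    )
  })
  do.call(c, parts)
}

#' Feature names for a set of families
#' @param families as in [extract_features()]
#' @return character vector of column names in stable order
#' @export
feature_names <- function(families = "all") {
  # derived from a minimal 2x2 probe so names always match extract_features
  probe <- matrix(c(10L, 60L, 120L, 200L), 2, 2)
  names(extract_features(probe, matrix(1L, 2, 2), families, n_levels = 4L))
}

#' Extract features for a whole cohort
#'
#' Runs mask generation (unless ground-truth masks are requested) and feature
#' extraction over a list of annotated images, returning one feature table.
#'
#' @param cohort list of `annotated_image` objects
#' @param masks optional list of masks; default runs [build_mask()] per image
#' @param families,n_levels passed to [extract_features()]
#' @return data.frame: `label` factor column plus feature columns
#' @export
extract_cohort <- function(cohort, masks = NULL, families = "all",
                           n_levels = 32L) {
  if (is.null(masks)) masks <- lapply(cohort, build_mask)
  rows <- mapply(function(im, mk) extract_features(im$pixels, mk, families, n_levels),
                 cohort, masks, SIMPLIFY = FALSE)
  x <- do.call(rbind, rows)
  out <- data.frame(
    label = as_label_factor(vapply(cohort, function(im) im$label, character(1))),
    x, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the nine analysis datasets
#'
#' From a full 93-feature table builds the six per-family datasets plus three
#' combinations: the whole feature set (WFS, 93 columns), GLDM-GLRLM-DS
#' (30 columns) and GLDM-GLRLM-GLSZM-DS (46 columns).
#'
#' @param features data.frame with `label` and the 93 feature columns
#' @return named list of nine data.frames, each with `label` plus its feature
#'   subset: FOIS-DS, GLCM-DS, GLRLM-DS, GLSZM-DS, GLDM-DS, NGTDM-DS, WFS,
#'   GLDM-GLRLM-DS, GLDM-GLRLM-GLSZM-DS
#' @export
assemble_datasets <- function(features) {
  stopifnot("label" %in% names(features))
  pick <- function(fams) {
    cols <- unlist(lapply(fams, function(f)
      grep(paste0("^", f, "_"), names(features), value = TRUE)))
    features[, c("label", cols), drop = FALSE]
  }
  list(
    "FOIS-DS" = pick("fois"),
    "GLCM-DS" = pick("glcm"),
    "GLRLM-DS" = pick("glrlm"),
    "GLSZM-DS" = pick("glszm"),
    "GLDM-DS" = pick("gldm"),
    "NGTDM-DS" = pick("ngtdm"),
    "WFS" = pick(FAMILIES),
    "GLDM-GLRLM-DS" = pick(c("gldm", "glrlm")),
    "GLDM-GLRLM-GLSZM-DS" = pick(c("gldm", "glrlm", "glszm"))
  )
}
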