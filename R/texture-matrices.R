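# Grey-level discretisation and the five texture-matrix families.
#
# All analysis is 2D (DXA is planar). Pixel pairs/runs/zones/neighbourhoods
# are restricted to in-ROI pixels; out-of-ROI cells are NA and break runs,
# zones and neighbourhoods. Directions for GLCM/GLRLM are the four 2D offsets
# at distance 1: (0,1), (1,0), (1,1), (1,-1) in (row, col) convention.

#' Discretise ROI intensities to a fixed number of grey levels
#'
#' Equal-width binning between the ROI minimum and maximum into levels
#' `1..n_levels`: `level(v) = floor((v - min) / width) + 1` with the maximum
#' intensity assigned to the top level. A constant ROI maps entirely to
#' level 1.
#'
#' @param image integer/numeric pixel matrix (or `annotated_image`)
#' @param mask matrix of the same dimensions; nonzero = ROI
#' @param n_levels number of grey levels (>= 2); default 32
#' @return an object of class `quantised_roi`: `levels` (matrix, NA outside
#'   the ROI), `n_levels` (number of occupied levels), `n_pixels`
#' @export
quantise <- function(image, mask, n_levels = 32L) {
  px <- get_pixels(image)
  stopifnot(all(dim(px) == dim(mask)), n_levels >= 2)
  roi <- mask != 0
  if (!any(roi)) ot_error("mask selects no pixels", "osteotex_empty_mask")
  vals <- px[roi]
  lev <- matrix(NA_integer_, nrow(px), ncol(px))
  rng <- max(vals) - min(vals)
  if (rng == 0) {
    lev[roi] <- 1L
  } else {
    width <- rng / n_levels
    l <- floor((vals - min(vals)) / width) + 1
    l[l > n_levels] <- n_levels
    lev[roi] <- as.integer(l)
  }
  structure(list(levels = lev,
                 n_levels = max(lev, na.rm = TRUE),
                 n_pixels = sum(roi)),
            class = "quantised_roi")
}

# shift a matrix by (dr, dc), NA-filling exposed cells
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_integer_, nr, nc)
  sr <- max(1, 1 - dr):min(nr, nr - dr)
  sc <- max(1, 1 - dc):min(nc, nc - dc)
  out[sr, sc] <- m[sr + dr, sc + dc]
  out
}

GLCM_OFFSETS <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

chebyshev_offsets <- function(delta) {
  g <- expand.grid(dr = -delta:delta, dc = -delta:delta)
  g <- g[!(g$dr == 0 & g$dc == 0), , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) c(g$dr[i], g$dc[i]))
}

#' Grey level co-occurrence matrices
#'
#' Symmetric co-occurrence counts of level pairs at distance 1 for the four
#' 2D direction offsets, restricted to pairs where both pixels are in the
#' ROI. Each direction is normalised separately.
#'
#' @param q a [quantise()]d ROI
#' @return object of class `texture_matrix`, family GLCM, with per-direction
#'   integer `counts` and normalised `matrices`
#' @export
glcm <- function(q) {
  stopifnot(inherits(q, "quantised_roi"))
  ng <- q$n_levels
  L <- q$levels
  counts <- lapply(GLCM_OFFSETS, function(off) {
    B <- shift_mat(L, off[1], off[2])
    ok <- !is.na(L) & !is.na(B)
    a <- L[ok]; b <- B[ok]
    cm <- matrix(tabulate((a - 1L) * ng + b, nbins = ng * ng), ng, ng, byrow = TRUE)
    cm + t(cm)  # symmetric: count each pair in both orders
  })
  mats <- lapply(counts, function(cm) if (sum(cm) > 0) cm / sum(cm) else cm)
  structure(list(family = "GLCM", counts = counts, matrices = mats,
                 offsets = GLCM_OFFSETS, n_levels = ng, n_pixels = q$n_pixels),
            class = "texture_matrix")
}

# runs of a vector of levels (NA breaks runs); returns data.frame(level, length)
level_runs <- function(v) {
  if (!length(v)) return(NULL)
  v2 <- ifelse(is.na(v), -1L, v)
  r <- rle(v2)
  keep <- r$values > 0
  if (!any(keep)) return(NULL)
  data.frame(level = r$values[keep], length = r$lengths[keep])
}

# extract the lines of a level matrix along one of the four directions
direction_lines <- function(L, off) {
  nr <- nrow(L); nc <- ncol(L)
  if (off[1] == 0L && off[2] == 1L) {
    lapply(seq_len(nr), function(r) L[r, ])
  } else if (off[1] == 1L && off[2] == 0L) {
    lapply(seq_len(nc), function(cc) L[, cc])
  } else if (off[1] == 1L && off[2] == 1L) {
    unname(split(L, col(L) - row(L)))
  } else {
    unname(split(L, col(L) + row(L)))
  }
}

#' Grey level run length matrices
#'
#' Counts `R(g, l)` of maximal runs of level `g` and length `l` along each of
#' the four directions; NA (out-of-ROI) pixels break runs.
#'
#' @param q a [quantise()]d ROI
#' @return `texture_matrix` (family GLRLM) with per-direction count matrices
#'   `Ng x Lmax`
#' @export
glrlm <- function(q) {
  stopifnot(inherits(q, "quantised_roi"))
  ng <- q$n_levels
  L <- q$levels
  counts <- lapply(GLCM_OFFSETS, function(off) {
    runs <- do.call(rbind, lapply(direction_lines(L, off), level_runs))
    lmax <- max(runs$length)
    m <- matrix(0L, ng, lmax)
    for (i in seq_len(nrow(runs)))
      m[runs$level[i], runs$length[i]] <- m[runs$level[i], runs$length[i]] + 1L
    m
  })
  structure(list(family = "GLRLM", counts = counts, offsets = GLCM_OFFSETS,
                 n_levels = ng, n_pixels = q$n_pixels),
            class = "texture_matrix")
}

#' Grey level size zone matrix
#'
#' Counts `S(g, z)` of 8-connected zones of equal level `g` and size `z`
#' pixels. Direction-free (a single matrix).
#'
#' @param q a [quantise()]d ROI
#' @return `texture_matrix` (family GLSZM) with count matrix `Ng x Zmax`
#' @export
glszm <- function(q) {
  stopifnot(inherits(q, "quantised_roi"))
  ng <- q$n_levels
  lab <- cc_label(q$levels, 8L)
  ids <- lab[lab > 0]
  lev <- q$levels[lab > 0]
  sizes <- tabulate(ids)
  zone_level <- lev[match(seq_along(sizes), ids)]
  zmax <- max(sizes)
  m <- matrix(0L, ng, zmax)
  for (i in seq_along(sizes))
    m[zone_level[i], sizes[i]] <- m[zone_level[i], sizes[i]] + 1L
  structure(list(family = "GLSZM", counts = m, n_levels = ng,
                 n_pixels = q$n_pixels),
            class = "texture_matrix")
}

#' Grey level dependence matrix
#'
#' For each ROI pixel, the dependence `d` is the number of neighbours within
#' Chebyshev distance `delta` whose level differs from the centre by at most
#' `alpha` (out-of-ROI neighbours never count). `D(g, d)` counts pixels of
#' level `g` with dependence `d`; columns are indexed by `d = 0, 1, ...`.
#'
#' @param q a [quantise()]d ROI
#' @param alpha similarity cutoff (default 0: exact level match)
#' @param delta neighbourhood Chebyshev distance (default 1: 8 neighbours)
#' @return `texture_matrix` (family GLDM) with count matrix `Ng x (dmax + 1)`;
#'   column `j` holds dependence `j - 1`
#' @export
gldm <- function(q, alpha = 0L, delta = 1L) {
  stopifnot(inherits(q, "quantised_roi"))
  ng <- q$n_levels
  L <- q$levels
  dep <- matrix(0L, nrow(L), ncol(L))
  for (off in chebyshev_offsets(delta)) {
    B <- shift_mat(L, off[1], off[2])
    dep <- dep + (!is.na(L) & !is.na(B) & abs(L - B) <= alpha)
  }
  roi <- !is.na(L)
  d <- dep[roi]
  g <- L[roi]
  dmax <- max(d)
  m <- matrix(tabulate((g - 1L) * (dmax + 1L) + d + 1L, nbins = ng * (dmax + 1L)),
              ng, dmax + 1L, byrow = TRUE)
  structure(list(family = "GLDM", counts = m, alpha = alpha, delta = delta,
                 n_levels = ng, n_pixels = q$n_pixels),
            class = "texture_matrix")
}

#' Neighbouring grey tone difference matrix
#'
#' For each ROI pixel with at least one in-ROI neighbour within Chebyshev
#' distance `delta`, the absolute difference between its level and the mean
#' level of those neighbours is accumulated per level:
#' `s_g = sum(|g - neighbour mean|)` over pixels of level `g`.
#'
#' @param q a [quantise()]d ROI
#' @param delta neighbourhood Chebyshev distance (default 1)
#' @return `texture_matrix` (family NGTDM) with per-level vectors `s`
#'   (summed differences), `n` (pixel counts) and `n_valid` (pixels with at
#'   least one neighbour)
#' @export
ngtdm <- function(q, delta = 1L) {
  stopifnot(inherits(q, "quantised_roi"))
  ng <- q$n_levels
  L <- q$levels
  nsum <- matrix(0, nrow(L), ncol(L))
  ncnt <- matrix(0L, nrow(L), ncol(L))
  for (off in chebyshev_offsets(delta)) {
    B <- shift_mat(L, off[1], off[2])
    ok <- !is.na(B)
    nsum[ok] <- nsum[ok] + B[ok]
    ncnt <- ncnt + ok
  }
  roi <- !is.na(L)
  valid <- roi & ncnt > 0
  g <- L[valid]
  diff <- abs(L[valid] - nsum[valid] / ncnt[valid])
  s <- vapply(seq_len(ng), function(k) sum(diff[g == k]), numeric(1))
  n <- vapply(seq_len(ng), function(k) sum(g == k), numeric(1))
  structure(list(family = "NGTDM", s = s, n = n, n_valid = sum(valid),
                 delta = delta, n_levels = ng, n_pixels = q$n_pixels),
            class = "texture_matrix")
}
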