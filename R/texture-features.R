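# Scalar feature definitions over the texture matrices, following the
# IBSI-aligned reference radiomics definitions in their 2D form. GLCM and
# GLRLM features are computed per direction and averaged over the four
# directions. Degenerate-case conventions: 0*log(0) = 0, correlation of a
# single-level ROI = 1, NGTDM coarseness capped at 1e6.

EPS <- .Machine$double.eps

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' GLCM features (24)
#'
#' @param m a `texture_matrix` from [glcm()]
#' @return named numeric vector of 24 direction-averaged features
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLCM")
  per_dir <- lapply(m$matrices, glcm_features_one)
  out <- Reduce(`+`, per_dir) / length(per_dir)
  names(out) <- paste0("glcm_", names(per_dir[[1]]))
  out
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)  # == colSums by symmetry
  mu_x <- sum(seq_len(ng) * px)
  sig_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))

  # p_{x+y}(k), k = 2..2Ng ; p_{x-y}(k), k = 0..Ng-1
  ksum <- 2:(2 * ng)
  p_sum <- vapply(ksum, function(k) sum(P[i + j == k]), numeric(1))
  kdif <- 0:(ng - 1)
  p_dif <- vapply(kdif, function(k) sum(P[abs(i - j) == k]), numeric(1))

  hx <- -sum(xlog2(px))
  hxy <- -sum(xlog2(P))
  pipj <- outer(px, px)
  hxy1 <- -sum(P * log2(pipj + EPS))
  hxy2 <- -sum(xlog2(pipj))

  da <- sum(kdif * p_dif)
  contrast <- sum((i - j)^2 * P)
  corr <- if (sig_x > 0) (sum(i * j * P) - mu_x^2) / sig_x^2 else 1
  imc1 <- if (max(hx, hx) > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  # MCC: second largest eigenvalue of Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
  mcc <- {
    nz <- px > 0
    if (sum(nz) < 2) 1 else {
      Pz <- P[nz, nz, drop = FALSE]
      pxz <- px[nz]
      Q <- (Pz / pxz) %*% t(Pz / matrix(pxz, nrow(Pz), ncol(Pz), byrow = TRUE))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, ev[2]))
    }
  }

  c(
    Autocorrelation = sum(i * j * P),
    JointAverage = mu_x,
    ClusterProminence = sum((i + j - 2 * mu_x)^4 * P),
    ClusterShade = sum((i + j - 2 * mu_x)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu_x)^2 * P),
    Contrast = contrast,
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlog2(p_dif)),
    DifferenceVariance = sum((kdif - da)^2 * p_dif),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ksum * p_sum),
    SumEntropy = -sum(xlog2(p_sum)),
    SumSquares = sum((i - mu_x)^2 * P)
  )
}

# shared form of the run-length / size-zone feature set: counts matrix M with
# rows = grey level g, cols = run length / zone size, plus Np pixels.
rl_sz_features <- function(M, np, prefix_small, prefix_large, axis) {
  nr_ <- sum(M)
  g <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  l <- t(matrix(seq_len(ncol(M)), ncol(M), nrow(M)))
  p <- M / nr_
  mu_g <- sum(p * g)
  mu_l <- sum(p * l)
  out <- c(
    sum(M / l^2) / nr_,                      # small emphasis
    sum(M * l^2) / nr_,                      # large emphasis
    sum(rowSums(M)^2) / nr_,                 # grey level non-uniformity
    sum(rowSums(M)^2) / nr_^2,               # normalised
    sum(colSums(M)^2) / nr_,                 # run/zone non-uniformity
    sum(colSums(M)^2) / nr_^2,               # normalised
    nr_ / np,                                # run/zone percentage
    sum(p * (g - mu_g)^2),                   # grey level variance
    sum(p * (l - mu_l)^2),                   # run/zone variance
    -sum(xlog2(p)),                          # entropy
    sum(M / g^2) / nr_,                      # low grey level emphasis
    sum(M * g^2) / nr_,                      # high grey level emphasis
    sum(M / (g^2 * l^2)) / nr_,              # small + low
    sum(M * g^2 / l^2) / nr_,                # small + high
    sum(M * l^2 / g^2) / nr_,                # large + low
    sum(M * g^2 * l^2) / nr_                 # large + high
  )
  names(out) <- c(
    paste0(prefix_small, "Emphasis"),
    paste0(prefix_large, "Emphasis"),
    "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized",
    paste0(axis, "NonUniformity"),
    paste0(axis, "NonUniformityNormalized"),
    paste0(axis, "Percentage"),
    "GrayLevelVariance",
    paste0(sub("Length", "", axis), "Variance"),
    paste0(sub("Length", "", axis), "Entropy"),
    "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis",
    paste0(prefix_small, "LowGrayLevelEmphasis"),
    paste0(prefix_small, "HighGrayLevelEmphasis"),
    paste0(prefix_large, "LowGrayLevelEmphasis"),
    paste0(prefix_large, "HighGrayLevelEmphasis")
  )
  out
}

#' GLRLM features (16)
#'
#' Direction-averaged short/long run emphases, non-uniformities, run
#' percentage, variances, entropy and grey-level-weighted emphases.
#'
#' @param m a `texture_matrix` from [glrlm()]
#' @return named numeric vector of 16 features
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLRLM")
  per_dir <- lapply(m$counts, rl_sz_features, np = m$n_pixels,
                    prefix_small = "ShortRun", prefix_large = "LongRun",
                    axis = "RunLength")
  out <- Reduce(`+`, per_dir) / length(per_dir)
  names(out) <- paste0("glrlm_", names(per_dir[[1]]))
  names(out)[names(out) == "glrlm_RunLengthPercentage"] <- "glrlm_RunPercentage"
  out
}

#' GLSZM features (16)
#'
#' @param m a `texture_matrix` from [glszm()]
#' @return named numeric vector of 16 features
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLSZM")
  out <- rl_sz_features(m$counts, np = m$n_pixels,
                        prefix_small = "SmallArea", prefix_large = "LargeArea",
                        axis = "SizeZone")
  names(out) <- paste0("glszm_", names(out))
  # align the two axis-derived names with the reference vocabulary
  names(out)[names(out) == "glszm_SizeZonePercentage"] <- "glszm_ZonePercentage"
  names(out)[names(out) == "glszm_SizeZoneVariance"] <- "glszm_ZoneVariance"
  names(out)[names(out) == "glszm_SizeZoneEntropy"] <- "glszm_ZoneEntropy"
  out
}

#' GLDM features (14)
#'
#' Columns of the dependence matrix are indexed by the neighbour count
#' `d = 0, 1, ...`; feature weights use the dependence size `j = d + 1`
#' (the centre pixel counts towards its own dependence), which keeps the
#' small-dependence emphasis finite for isolated pixels.
#'
#' @param m a `texture_matrix` from [gldm()]
#' @return named numeric vector of 14 features
#' @export
gldm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLDM")
  M <- m$counts
  nz <- sum(M)
  g <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  d <- t(matrix(seq_len(ncol(M)), ncol(M), nrow(M)))  # dependence size j = d + 1
  p <- M / nz
  mu_g <- sum(p * g)
  mu_d <- sum(p * d)
  out <- c(
    SmallDependenceEmphasis = sum(M / d^2) / nz,
    LargeDependenceEmphasis = sum(M * d^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(M)^2) / nz,
    DependenceNonUniformity = sum(colSums(M)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(M)^2) / nz^2,
    GrayLevelVariance = sum(p * (g - mu_g)^2),
    DependenceVariance = sum(p * (d - mu_d)^2),
    DependenceEntropy = -sum(xlog2(p)),
    LowGrayLevelEmphasis = sum(M / g^2) / nz,
    HighGrayLevelEmphasis = sum(M * g^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(M / (g^2 * d^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(M * g^2 / d^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(M * d^2 / g^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(M * g^2 * d^2) / nz
  )
  names(out) <- paste0("gldm_", names(out))
  out
}

#' NGTDM features (5)
#'
#' Coarseness, contrast, busyness, complexity and strength from the per-level
#' summed neighbourhood differences. Degenerate conventions: coarseness is
#' capped at 1e6 when the denominator vanishes (constant ROI); contrast and
#' busyness are 0 when only one level is present.
#'
#' @param m a `texture_matrix` from [ngtdm()]
#' @return named numeric vector of 5 features
#' @export
ngtdm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "NGTDM")
  nv <- m$n_valid
  pres <- which(m$n > 0)
  p <- m$n / nv
  s <- m$s
  ngp <- length(pres)
  lev <- seq_along(p)

  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6

  contrast <- if (ngp > 1) {
    pi_pj <- outer(p[pres], p[pres])
    dij2 <- outer(lev[pres], lev[pres], function(a, b) (a - b)^2)
    (sum(pi_pj * dij2) / (ngp * (ngp - 1))) * (sum(s) / nv)
  } else 0

  busy_den <- sum(abs(outer(lev[pres] * p[pres], lev[pres] * p[pres], `-`)))
  busyness <- if (ngp > 1 && busy_den > 0) sum(p * s) / busy_den else 0

  complexity <- if (ngp >= 1) {
    acc <- 0
    for (a in pres) for (b in pres)
      acc <- acc + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    acc / nv
  } else 0

  strength <- if (sum(s) > 0) {
    acc <- 0
    for (a in pres) for (b in pres)
      acc <- acc + (p[a] + p[b]) * (a - b)^2
    acc / sum(s)
  } else 0

  out <- c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
           Complexity = complexity, Strength = strength)
  names(out) <- paste0("ngtdm_", names(out))
  out
}

#' First-order statistics (18)
#'
#' Energy, total energy, entropy, minimum, 10th/90th percentiles, maximum,
#' mean, median, interquartile range, range, mean absolute deviation, robust
#' MAD (over the 10-90 percentile subset), root mean square, skewness,
#' kurtosis (non-excess), variance (population) and uniformity. Entropy and
#' uniformity are computed on the discretised intensity histogram
#' (`n_levels` equal-width bins); percentiles use linear interpolation.
#'
#' @param image pixel matrix (or `annotated_image`)
#' @param mask nonzero = ROI
#' @param n_levels bins for the entropy/uniformity histogram
#' @return named numeric vector of 18 features
#' @export
first_order_features <- function(image, mask, n_levels = 32L) {
  px <- get_pixels(image)
  roi <- mask != 0
  if (!any(roi)) ot_error("mask selects no pixels", "osteotex_empty_mask")
  x <- as.numeric(px[roi])
  n <- length(x)
  q <- quantise(px, mask, n_levels)
  p <- tabulate(q$levels[!is.na(q$levels)], nbins = q$n_levels) / n
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p10 <- unname(quantile(x, 0.10, type = 7))
  p90 <- unname(quantile(x, 0.90, type = 7))
  sub <- x[x >= p10 & x <= p90]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = sum(x^2),   # pixel area is 1 in the synthetic frame
    Entropy = -sum(xlog2(p)),
    Minimum = min(x),
    Percentile10 = p10,
    Percentile90 = p90,
    Maximum = max(x),
    Mean = mu,
    Median = unname(quantile(x, 0.5, type = 7)),
    InterquartileRange = unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(sub - mean(sub))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  names(out) <- paste0("fois_", names(out))
  out
}
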