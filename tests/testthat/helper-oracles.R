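# Independent brute-force oracles for the texture matrices and helpers for
# building small fixtures. These deliberately use naive per-pixel loops so
# they share no code path with the package implementation.

# random quantised ROI: level matrix with NA holes, levels 1..ng
random_roi <- function(nr, nc, ng, hole_frac = 0.15, seed = 1) {
  set.seed(seed)
  L <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  holes <- sample(length(L), round(hole_frac * length(L)))
  L[holes] <- NA_integer_
  if (all(is.na(L))) L[1] <- 1L
  L
}

# wrap a level matrix as a quantised_roi without going through quantise()
as_qroi <- function(L) {
  structure(list(levels = L, n_levels = max(L, na.rm = TRUE),
                 n_pixels = sum(!is.na(L))),
            class = "quantised_roi")
}

# image/mask pair whose quantisation at ng levels reproduces L exactly
# (identity-ish mapping: intensity = level)
roi_image <- function(L) {
  px <- L
  px[is.na(px)] <- 0L
  mask <- ifelse(is.na(L), 0L, 255L)
  list(pixels = px, mask = mask)
}

# brute-force symmetric GLCM counts for one offset
oracle_glcm <- function(L, dr, dc) {
  ng <- max(L, na.rm = TRUE)
  m <- matrix(0L, ng, ng)
  nr <- nrow(L); nc <- ncol(L)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- L[r, cc]; b <- L[r2, c2]
    if (is.na(a) || is.na(b)) next
    m[a, b] <- m[a, b] + 1L
    m[b, a] <- m[b, a] + 1L
  }
  m
}

# brute-force run-length counts for one direction (scans every maximal run)
oracle_glrlm <- function(L, dr, dc) {
  ng <- max(L, na.rm = TRUE)
  nr <- nrow(L); nc <- ncol(L)
  inb <- function(r, cc) r >= 1 && r <= nr && cc >= 1 && cc <= nc
  runs <- list()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    v <- L[r, cc]
    if (is.na(v)) next
    # only start a run if the previous cell along the direction doesn't continue it
    pr <- r - dr; pc <- cc - dc
    if (inb(pr, pc) && !is.na(L[pr, pc]) && L[pr, pc] == v) next
    len <- 0L
    r2 <- r; c2 <- cc
    while (inb(r2, c2) && !is.na(L[r2, c2]) && L[r2, c2] == v) {
      len <- len + 1L; r2 <- r2 + dr; c2 <- c2 + dc
    }
    runs[[length(runs) + 1L]] <- c(v, len)
  }
  lmax <- max(vapply(runs, `[`, 1L, 2))
  m <- matrix(0L, ng, lmax)
  for (rn in runs) m[rn[1], rn[2]] <- m[rn[1], rn[2]] + 1L
  m
}

# brute-force 8-connected zones via recursive-free flood fill
oracle_glszm <- function(L) {
  ng <- max(L, na.rm = TRUE)
  nr <- nrow(L); nc <- ncol(L)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (seen[r, cc] || is.na(L[r, cc])) next
    v <- L[r, cc]
    queue <- list(c(r, cc)); seen[r, cc] <- TRUE; size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (seen[r2, c2] || is.na(L[r2, c2]) || L[r2, c2] != v) next
        seen[r2, c2] <- TRUE
        queue[[length(queue) + 1L]] <- c(r2, c2)
      }
    }
    zones[[length(zones) + 1L]] <- c(v, size)
  }
  zmax <- max(vapply(zones, `[`, 1L, 2))
  m <- matrix(0L, ng, zmax)
  for (z in zones) m[z[1], z[2]] <- m[z[1], z[2]] + 1L
  m
}

# brute-force dependence counts: per pixel, neighbours within Chebyshev
# distance delta with |level difference| <= alpha
oracle_gldm <- function(L, alpha = 0L, delta = 1L) {
  ng <- max(L, na.rm = TRUE)
  nr <- nrow(L); nc <- ncol(L)
  dep <- c()
  lev <- c()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(L[r, cc])) next
    d <- 0L
    for (dr in -delta:delta) for (dc in -delta:delta) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(L[r2, c2]) && abs(L[r2, c2] - L[r, cc]) <= alpha) d <- d + 1L
    }
    dep <- c(dep, d); lev <- c(lev, L[r, cc])
  }
  dmax <- max(dep)
  m <- matrix(0L, ng, dmax + 1L)
  for (i in seq_along(dep)) m[lev[i], dep[i] + 1L] <- m[lev[i], dep[i] + 1L] + 1L
  m
}

# brute-force NGTDM per-level sums and counts
oracle_ngtdm <- function(L, delta = 1L) {
  ng <- max(L, na.rm = TRUE)
  nr <- nrow(L); nc <- ncol(L)
  s <- numeric(ng); n <- numeric(ng); nvalid <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(L[r, cc])) next
    nb <- c()
    for (dr in -delta:delta) for (dc in -delta:delta) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(L[r2, c2])) nb <- c(nb, L[r2, c2])
    }
    if (!length(nb)) next
    nvalid <- nvalid + 1L
    g <- L[r, cc]
    s[g] <- s[g] + abs(g - mean(nb))
    n[g] <- n[g] + 1
  }
  list(s = s, n = n, n_valid = nvalid)
}

# brute-force pairwise mutual-1NN Tomek links on z-scored features
oracle_tomek <- function(t) {
  x <- as.matrix(t[, setdiff(names(t), c("label", "origin"))])
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  n <- nrow(x)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  nn1 <- apply(d, 1, which.min)
  out <- list()
  for (i in seq_len(n)) {
    j <- nn1[i]
    if (i < j && nn1[j] == i && t$label[i] != t$label[j])
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0)))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

# brute-force confusion-matrix metric counter
oracle_metrics <- function(truth, pred) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "degraded" && pred[i] == "degraded") tp <- tp + 1
    else if (truth[i] == "degraded") fn <- fn + 1
    else if (pred[i] == "degraded") fp <- fp + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
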