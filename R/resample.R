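# Class-imbalance resampling: random undersampling, SMOTE, ADASYN, the
# Tomek-link and edited-nearest-neighbour cleaners, the hybrid SMOTETomek /
# SMOTEENN, and the post-synthesis range constraint.
#
# Neighbour searches use Euclidean distance on z-scored features (statistics
# of the table being resampled): radiomic features span orders of magnitude
# and unscaled distances would be dominated by the largest-valued columns.
# Interpolation itself happens on the raw feature values (the convex
# combination is affine, so scaling only influences neighbour choice).
# Nearest-neighbour ties are broken by the lowest row index, which keeps
# every technique fully deterministic under its seed.

TECHNIQUES <- c("UNDERSAMPLING", "SMOTE", "ADASYN", "SMOTETomek", "SMOTEENN")

zscale <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(x, 2, mu), 2, s, "/")
}

# k nearest neighbours (indices into `among`) of each query row; self-matches
# (same index) excluded; stable tie-break by lowest index
knn_among <- function(x, query_idx, among_idx, k) {
  d <- as.matrix(dist(x))
  nn <- vapply(query_idx, function(i) {
    dd <- d[i, among_idx]
    dd[among_idx == i] <- Inf
    among_idx[order(dd)[seq_len(k)]]
  }, integer(k))
  # always queries x k, also when k = 1 (vapply returns a bare vector then)
  matrix(nn, nrow = length(query_idx), ncol = k, byrow = TRUE)
}

class_counts <- function(y) {
  tab <- table(y)
  if (length(unique(as.vector(tab))) == 1 && "degraded" %in% names(tab)) {
    # balanced table: degraded is the clinical minority by convention
    min_lab <- "degraded"
  } else {
    min_lab <- names(tab)[which.min(tab)]
  }
  maj_lab <- setdiff(names(tab), min_lab)[1]
  if (is.na(maj_lab)) maj_lab <- min_lab
  list(minority = min_lab, majority = maj_lab,
       n_min = tab[[min_lab]], n_maj = max(tab))
}

new_resampling_result <- function(table, technique, origin, seed) {
  structure(list(table = table, technique = technique,
                 origin = origin, seed = seed),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("<resampling_result %s: %d rows (%d original, %d synthetic)>\n",
              x$technique, nrow(x$table), sum(x$origin == "original"),
              sum(x$origin == "synthetic")))
  invisible(x)
}

check_two_classes <- function(y) {
  if (length(unique(as.character(y))) < 2)
    ot_error("input contains a single class", "osteotex_single_class")
}

#' Random undersampling of the majority class
#'
#' Pseudo-randomly removes majority-class rows (without replacement) until
#' both classes have the minority count. All minority rows are retained.
#'
#' @param t feature table (data.frame with `label` column)
#' @param seed integer seed
#' @return a `resampling_result`
#' @export
random_undersample <- function(t, seed = 1L) {
  check_two_classes(t$label)
  cc <- class_counts(t$label)
  set.seed(seed)
  maj_idx <- which(t$label == cc$majority)
  keep_maj <- sort(sample(maj_idx, cc$n_min))
  keep <- sort(c(which(t$label == cc$minority), keep_maj))
  new_resampling_result(t[keep, , drop = FALSE], "UNDERSAMPLING",
                        rep("original", length(keep)), seed)
}

smote_synthesise <- function(x, min_idx, k, n_needed) {
  nn <- knn_among(zscale(x), min_idx, min_idx, k)
  base <- sample(seq_along(min_idx), n_needed, replace = TRUE)
  pick <- sample(k, n_needed, replace = TRUE)
  u <- runif(n_needed)
  xb <- x[min_idx[base], , drop = FALSE]
  xn <- x[nn[cbind(base, pick)], , drop = FALSE]
  xb + u * (xn - xb)
}

finish_oversample <- function(t, synth, minority, technique, seed) {
  feat_cols <- setdiff(names(t), "label")
  add <- as.data.frame(synth)
  names(add) <- feat_cols
  add$label <- as_label_factor(rep(minority, nrow(add)))
  add <- add[, names(t), drop = FALSE]
  out <- rbind(t, add)
  rownames(out) <- NULL
  new_resampling_result(out, technique,
                        c(rep("original", nrow(t)), rep("synthetic", nrow(add))),
                        seed)
}

#' SMOTE oversampling of the minority class
#'
#' Raises the minority count to the majority count: each synthetic row is a
#' convex combination `x + u (x_nn - x)` of a randomly chosen minority row
#' and one of its `k` nearest minority neighbours, `u ~ Uniform(0, 1)`.
#'
#' @param t feature table with `label` column
#' @param k number of minority nearest neighbours (default 5)
#' @param seed integer seed
#' @return a `resampling_result` (original rows first, synthetic appended)
#' @export
smote <- function(t, k = 5L, seed = 1L) {
  check_two_classes(t$label)
  cc <- class_counts(t$label)
  if (cc$n_min <= k)
    ot_error(sprintf("minority count %d must exceed k = %d", cc$n_min, k),
             "osteotex_too_few_minority")
  n_needed <- cc$n_maj - cc$n_min
  if (n_needed == 0)
    return(new_resampling_result(t, "SMOTE", rep("original", nrow(t)), seed))
  set.seed(seed)
  fx <- split_features(t)
  synth <- smote_synthesise(fx$x, which(fx$y == cc$minority), k, n_needed)
  finish_oversample(t, synth, cc$minority, "SMOTE", seed)
}

#' ADASYN adaptive oversampling of the minority class
#'
#' Like SMOTE, but each minority row's share of the synthetic samples is
#' proportional to the fraction of majority points among its `k` nearest
#' neighbours in the full table, concentrating synthesis near the decision
#' boundary. When no minority row has majority neighbours the density is
#' degenerate and quotas fall back to uniform (SMOTE-like behaviour, with a
#' warning).
#'
#' @inheritParams smote
#' @return a `resampling_result`
#' @export
adasyn <- function(t, k = 5L, seed = 1L) {
  check_two_classes(t$label)
  cc <- class_counts(t$label)
  if (cc$n_min <= k)
    ot_error(sprintf("minority count %d must exceed k = %d", cc$n_min, k),
             "osteotex_too_few_minority")
  n_needed <- cc$n_maj - cc$n_min
  if (n_needed == 0)
    return(new_resampling_result(t, "ADASYN", rep("original", nrow(t)), seed))
  set.seed(seed)
  fx <- split_features(t)
  min_idx <- which(fx$y == cc$minority)
  xs <- zscale(fx$x)
  nn_all <- knn_among(xs, min_idx, seq_len(nrow(fx$x)), k)
  r <- rowSums(matrix(fx$y[nn_all] == cc$majority, nrow = length(min_idx))) / k
  if (sum(r) == 0) {
    warning("degenerate density: no minority sample has majority neighbours; ",
            "falling back to uniform quotas", call. = FALSE)
    rhat <- rep(1 / length(min_idx), length(min_idx))
  } else {
    rhat <- r / sum(r)
  }
  # integer quotas by largest remainder, summing exactly to n_needed
  raw <- rhat * n_needed
  quota <- floor(raw)
  rem <- n_needed - sum(quota)
  if (rem > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  nn_min <- knn_among(xs, min_idx, min_idx, k)
  base <- rep(seq_along(min_idx), quota)
  pick <- sample(k, length(base), replace = TRUE)
  u <- runif(length(base))
  xb <- fx$x[min_idx[base], , drop = FALSE]
  xn <- fx$x[nn_min[cbind(base, pick)], , drop = FALSE]
  finish_oversample(t, xb + u * (xn - xb), cc$minority, "ADASYN", seed)
}

#' Tomek links of a feature table
#'
#' A pair of rows is a Tomek link iff they carry opposite labels and each is
#' the other's single nearest neighbour.
#'
#' @param t feature table with `label` column
#' @return data.frame with columns `i`, `j` (row indices, `i < j`)
#' @export
tomek_links <- function(t) {
  fx <- split_features(t)
  n <- nrow(fx$x)
  nn1 <- knn_among(zscale(fx$x), seq_len(n), seq_len(n), 1L)[, 1]
  is_link <- vapply(seq_len(n), function(i) {
    j <- nn1[i]
    nn1[j] == i && fx$y[i] != fx$y[j] && i < j
  }, logical(1))
  data.frame(i = which(is_link), j = nn1[which(is_link)])
}

#' Remove the majority-class members of all Tomek links
#' @param t feature table with `label` column
#' @return the table with the majority members of each link removed
#' @export
remove_majority_of_links <- function(t) {
  cc <- class_counts(t$label)
  links <- tomek_links(t)
  members <- c(links$i, links$j)
  drop <- members[t$label[members] == cc$majority]
  if (length(drop)) t[-drop, , drop = FALSE] else t
}

#' Edited nearest neighbour cleaning of the majority class
#'
#' Removes every majority-class row whose `k`-nearest-neighbour majority vote
#' (among all other rows) disagrees with its label; a tied vote keeps the
#' row. Minority rows are always retained.
#'
#' @param t feature table with `label` column
#' @param k neighbour count for the vote (default 3)
#' @return the cleaned table
#' @export
enn_clean <- function(t, k = 3L) {
  cc <- class_counts(t$label)
  fx <- split_features(t)
  n <- nrow(fx$x)
  maj_idx <- which(fx$y == cc$majority)
  nn <- knn_among(zscale(fx$x), maj_idx, seq_len(n), k)
  votes_against <- rowSums(matrix(fx$y[nn] != cc$majority, nrow = length(maj_idx)))
  drop <- maj_idx[votes_against > k / 2]
  if (length(drop)) t[-drop, , drop = FALSE] else t
}

subset_result <- function(r, keep_rows) {
  new_resampling_result(r$table[keep_rows, , drop = FALSE], r$technique,
                        r$origin[keep_rows], r$seed)
}

#' SMOTE followed by Tomek-link cleaning
#' @inheritParams smote
#' @return a `resampling_result`
#' @export
smote_tomek <- function(t, k = 5L, seed = 1L) {
  s <- smote(t, k, seed)
  s$technique <- "SMOTETomek"
  links <- tomek_links(s$table)
  cc <- class_counts(s$table$label)
  members <- c(links$i, links$j)
  drop <- members[s$table$label[members] == cc$majority]
  if (!length(drop)) return(s)
  subset_result(s, setdiff(seq_len(nrow(s$table)), drop))
}

#' SMOTE followed by edited-nearest-neighbour cleaning
#' @inheritParams smote
#' @param k_enn neighbour count for the ENN vote (default 3)
#' @return a `resampling_result`
#' @export
smote_enn <- function(t, k = 5L, seed = 1L, k_enn = 3L) {
  s <- smote(t, k, seed)
  s$technique <- "SMOTEENN"
  cc <- class_counts(s$table$label)
  fx <- split_features(s$table)
  maj_idx <- which(fx$y == cc$majority)
  nn <- knn_among(zscale(fx$x), maj_idx, seq_len(nrow(fx$x)), k_enn)
  votes_against <- rowSums(matrix(fx$y[nn] != cc$majority, nrow = length(maj_idx)))
  drop <- maj_idx[votes_against > k_enn / 2]
  if (!length(drop)) return(s)
  subset_result(s, setdiff(seq_len(nrow(s$table)), drop))
}

#' Constrain synthetic rows to the original feature ranges
#'
#' Clamps every synthetic row's feature values to the columnwise
#' `[min, max]` of the original table, so synthesised samples cannot leave
#' the range spanned by real ones. Original rows are untouched.
#'
#' @param r a `resampling_result`
#' @param original the feature table the resampler was applied to
#' @return the clipped `resampling_result`
#' @export
clip_to_original_range <- function(r, original) {
  stopifnot(inherits(r, "resampling_result"))
  feat_cols <- setdiff(names(original), c("label", "origin"))
  syn <- which(r$origin == "synthetic")
  if (!length(syn)) return(r)
  for (cl in feat_cols) {
    lo <- min(original[[cl]]); hi <- max(original[[cl]])
    r$table[[cl]][syn] <- pmin(pmax(r$table[[cl]][syn], lo), hi)
  }
  r
}

#' Apply one resampling technique by name
#' @param t feature table
#' @param technique one of UNDERSAMPLING, SMOTE, ADASYN, SMOTETomek, SMOTEENN
#' @param seed integer seed
#' @param k SMOTE/ADASYN neighbour count
#' @param clip clamp synthetic rows to the input table's feature ranges
#' @return a `resampling_result`
#' @export
apply_resampling <- function(t, technique, seed = 1L, k = 5L, clip = TRUE) {
  technique <- match.arg(technique, TECHNIQUES)
  r <- switch(technique,
    UNDERSAMPLING = random_undersample(t, seed),
    SMOTE = smote(t, k, seed),
    ADASYN = adasyn(t, k, seed),
    SMOTETomek = smote_tomek(t, k, seed),
    SMOTEENN = smote_enn(t, k, seed)
  )
  if (clip) clip_to_original_range(r, t) else r
}

#' Build the full dataset-by-technique resampling matrix
#'
#' Applies the five techniques to the training partition of each feature
#' dataset (one shared stratified split across all datasets), yielding
#' `length(datasets) * 5` resampled training sets. Test partitions are never
#' resampled.
#'
#' @param datasets named list of feature tables (e.g. [assemble_datasets()])
#' @param seed integer seed (expanded per dataset/technique)
#' @param train_fraction passed to [stratified_split()]
#' @param k SMOTE/ADASYN neighbour count
#' @return list with `resampled` (named list, `"<dataset>|<technique>"`),
#'   `train` and `test` (named lists of the shared partitions)
#' @export
build_resampled_matrix <- function(datasets, seed = 1L, train_fraction = 0.7,
                                   k = 5L) {
  labels <- datasets[[1]]$label
  idx <- stratified_split_index(labels, train_fraction, seed)
  train <- lapply(datasets, function(d) {
    d <- d[idx$train, , drop = FALSE]; rownames(d) <- NULL; d
  })
  test <- lapply(datasets, function(d) {
    d <- d[idx$test, , drop = FALSE]; rownames(d) <- NULL; d
  })
  resampled <- list()
  ctr <- 0L
  n_degenerate <- 0L
  for (dn in names(datasets)) {
    for (tech in TECHNIQUES) {
      ctr <- ctr + 1L
      resampled[[paste(dn, tech, sep = "|")]] <- withCallingHandlers(
        apply_resampling(train[[dn]], tech, seed = derive_seed(seed, ctr), k = k),
        warning = function(w) {
          if (grepl("degenerate density", conditionMessage(w))) {
            n_degenerate <<- n_degenerate + 1L
            invokeRestart("muffleWarning")
          }
        })
    }
  }
  if (n_degenerate > 0)
    warning(sprintf(paste("ADASYN density was degenerate (no majority",
                          "neighbours) for %d of %d datasets; uniform quotas",
                          "were used there"), n_degenerate, length(datasets)),
            call. = FALSE)
  list(resampled = resampled, train = train, test = test)
}
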