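# Rule-based L1-L4 ROI mask generation from scanner-style overlay annotations.
#
# The algorithm mirrors how clinical densitometry software marks the lumbar
# spine: the lateral contour is drawn in black (grey value 0) and white
# horizontal segments bound the vertebrae. Four steps: (1) trace the left
# contour, (2) trace the right contour, (3) locate the top-of-L1 and
# bottom-of-L4 divider rows, (4) draw the boundary on a black canvas and
# flood-fill its interior.
#
# Coordinates are (row, column), 1-based, row 1 at the top (the scan runs
# top to bottom).

get_pixels <- function(image) {
  if (inherits(image, "annotated_image")) image$pixels else image
}

#' Trace one lateral spine contour
#'
#' Scans each row from the image edge towards the middle (left edge for
#' `side = "left"`, right edge for `side = "right"`). A zero-valued pixel is
#' accepted as a contour point when (a) the mean intensity of up to
#' `neighbourhood` pixels on its inner side strictly exceeds the mean on its
#' outer side (the spine is brighter than the background; ties are rejected),
#' and (b) it is 8-connected to the contour point accepted on the previous
#' contour-bearing row. The connectivity check is waived for the first
#' accepted row.
#'
#' @param image an `annotated_image` or an integer pixel matrix
#' @param side `"left"` or `"right"`
#' @param neighbourhood window half-width (pixels each side on the same row)
#'   for the mean-intensity test; truncated at image borders
#' @return a data.frame with columns `row`, `col` (class `contour_trace`)
#' @export
find_contour <- function(image, side = c("left", "right"), neighbourhood = 5L) {
  side <- match.arg(side)
  px <- get_pixels(image)
  h <- nrow(px); w <- ncol(px)
  mid <- floor(w / 2)
  cols_scan <- if (side == "left") seq_len(mid) else seq(w, mid + 1L)

  rows_out <- integer(0)
  cols_out <- integer(0)
  prev_col <- NA_integer_
  prev_row <- NA_integer_

  for (r in seq_len(h)) {
    found <- NA_integer_
    for (cc in cols_scan) {
      if (px[r, cc] != 0L) next
      # neighbourhood mean test: inner side must be strictly brighter
      lo <- max(1L, cc - neighbourhood)
      hi <- min(w, cc + neighbourhood)
      left_cols <- if (cc > 1L) lo:(cc - 1L) else integer(0)
      right_cols <- if (cc < w) (cc + 1L):hi else integer(0)
      if (!length(left_cols) || !length(right_cols)) next
      m_left <- mean(px[r, left_cols])
      m_right <- mean(px[r, right_cols])
      ok <- if (side == "left") m_right > m_left else m_left > m_right
      if (!ok) next
      # 8-connectivity with the previously accepted row's point
      if (!is.na(prev_col)) {
        if (r - prev_row != 1L || abs(cc - prev_col) > 1L) next
      }
      found <- cc
      break
    }
    if (!is.na(found)) {
      rows_out <- c(rows_out, r)
      cols_out <- c(cols_out, found)
      prev_col <- found
      prev_row <- r
    }
  }
  if (!length(rows_out))
    ot_error(sprintf("no %s contour found: image appears unannotated", side),
             "osteotex_no_contour")
  structure(data.frame(row = rows_out, col = cols_out),
            class = c("contour_trace", "data.frame"), side = side)
}

#' Locate the top-of-L1 and bottom-of-L4 divider rows
#'
#' Scans rows from the top edge downward and from the bottom edge upward for
#' the first row carrying a horizontal segment of at least `min_segment`
#' pixels at the maximum representable grey value (white overlay).
#'
#' @param image an `annotated_image` or pixel matrix
#' @param min_segment minimum horizontal run length accepted as a divider
#'   segment (rejects speckle)
#' @param white_value the maximum representable grey value (255 for 8-bit)
#' @return a list with `top_row` and `bottom_row` (class `roi_vertices`)
#' @export
find_roi_vertices <- function(image, min_segment = 10L, white_value = 255L) {
  px <- get_pixels(image)
  has_segment <- vapply(seq_len(nrow(px)), function(r) {
    rl <- rle(px[r, ] == white_value)
    any(rl$values & rl$lengths >= min_segment)
  }, logical(1))
  seg_rows <- which(has_segment)
  if (length(seg_rows) < 2)
    ot_error("fewer than two white divider segments found",
             "osteotex_no_divider")
  structure(list(top_row = seg_rows[1], bottom_row = seg_rows[length(seg_rows)]),
            class = "roi_vertices")
}

# white run between the contours on a given row (used to draw the boundary)
white_run_between <- function(px, r, lc, rc, white_value = 255L) {
  cols <- which(px[r, ] == white_value)
  cols[cols >= lc & cols <= rc]
}

#' Build the binary L1-L4 ROI mask
#'
#' Step 4 of the mask algorithm: a black canvas of the image's dimensions is
#' created; the contour pixels (clipped to the divider rows), the top and
#' bottom divider segments and the flood-filled interior they enclose are set
#' white. The fill is 4-connected, seeded at the centroid of the enclosing
#' rectangle; if it reaches the image border the boundary is not closed and
#' an error is raised.
#'
#' @inheritParams find_contour
#' @param neighbourhood passed to [find_contour()]
#' @param min_segment passed to [find_roi_vertices()]
#' @return an integer matrix of the image's dimensions with values 0
#'   (background) and 255 (ROI)
#' @export
build_mask <- function(image, neighbourhood = 5L, min_segment = 10L) {
  px <- get_pixels(image)
  h <- nrow(px); w <- ncol(px)
  left <- find_contour(px, "left", neighbourhood)
  right <- find_contour(px, "right", neighbourhood)
  v <- find_roi_vertices(px, min_segment)
  top <- v$top_row; bottom <- v$bottom_row

  barrier <- matrix(FALSE, h, w)
  keep_l <- left$row >= top & left$row <= bottom
  keep_r <- right$row >= top & right$row <= bottom
  barrier[cbind(left$row[keep_l], left$col[keep_l])] <- TRUE
  barrier[cbind(right$row[keep_r], right$col[keep_r])] <- TRUE

  lc_of <- function(trace, r) trace$col[match(r, trace$row)]
  for (r in c(top, bottom)) {
    lcr <- lc_of(left, r); rcr <- lc_of(right, r)
    if (is.na(lcr) || is.na(rcr))
      ot_error("divider row not spanned by both contours", "osteotex_mask_not_closed")
    run <- white_run_between(px, r, lcr, rcr)
    barrier[r, run] <- TRUE
  }

  # 4-connected flood fill of the open region, seeded at the ROI centroid
  open <- matrix(1L, h, w)
  open[barrier] <- NA_integer_
  seed_row <- round((top + bottom) / 2)
  seed_col <- round((lc_of(left, seed_row) + lc_of(right, seed_row)) / 2)
  if (is.na(open[seed_row, seed_col]))
    ot_error("fill seed fell on the boundary", "osteotex_mask_not_closed")
  lab <- cc_label(open, 4L)
  region <- lab == lab[seed_row, seed_col]
  touches_border <- any(region[1, ]) || any(region[h, ]) ||
    any(region[, 1]) || any(region[, w])
  if (touches_border)
    ot_error("flood fill leaked to the image border: boundary not closed",
             "osteotex_mask_not_closed")

  mask <- matrix(0L, h, w)
  mask[barrier | region] <- 255L
  mask
}

#' Jaccard overlap between two binary masks
#'
#' @param a,b integer or logical matrices of equal dimensions; nonzero = ROI
#' @return intersection-over-union in \[0, 1\]
#' @export
mask_jaccard <- function(a, b) {
  a <- a != 0; b <- b != 0
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
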