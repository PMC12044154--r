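#' Number of sliding windows covering a sample
#'
#' For a bounding box of extents `m` x `n`, windows of side `s` sliding with
#' overlap fraction `o` have stride `s * (1 - o)`; the grid has
#' `a = ceiling(m / (s (1 - o)))` columns, `b = ceiling(n / (s (1 - o)))`
#' rows, and `z = a * b` windows in total.
#'
#' @param m,n Bounding-box extents along x and y.
#' @param s Window side length, > 0.
#' @param o Overlap fraction in `[0, 1)`.
#' @return Named integer vector `c(a, b, z)`.
#' @examples
#' window_count(100, 100, 50, 0.5)  # a = b = 4, z = 16
#' @export
window_count <- function(m, n, s, o) {
  stopifnot("s must be positive" = s > 0,
            "extents must be nonnegative" = m >= 0 && n >= 0)
  if (o < 0 || o >= 1) stop("parameter error: overlap o must be in [0, 1)")
  stride <- s * (1 - o)
  a <- max(1L, as.integer(ceiling(m / stride)))
  b <- max(1L, as.integer(ceiling(n / stride)))
  c(a = a, b = b, z = a * b)
}

#' Decompose a sample into a grid of overlapping square windows
#'
#' The grid is anchored at the sample's minimum x/y. The window at grid
#' position (row r, column c) covers
#' `[x_min + c * stride, x_min + c * stride + s)` x
#' `[y_min + r * stride, y_min + r * stride + s)` with `stride = s (1 - o)`;
#' intervals are half-open except that the last row/column is right-closed,
#' so at `o = 0` the windows exactly partition the bounding box (cells on
#' the maximum coordinate included). Windows with fewer member cells than
#' intraview features are flagged invalid and excluded from modelling.
#'
#' @param cells A [cell_table()].
#' @param views The sample's [build_views()] result (used for the feature
#'   count), or `NULL` if `n_features` is given directly.
#' @param s Window side length.
#' @param o Overlap fraction in `[0, 1)`.
#' @param n_features Intraview feature count for the validity rule; taken
#'   from `views` when omitted.
#' @return A `window_set`: list with a `windows` data.frame (index, row,
#'   col, bounds, n_cells, valid), `members` (list of cell index vectors),
#'   grid dims `a`, `b`, and the parameters.
#' @export
decompose_sample <- function(cells, views = NULL, s, o, n_features = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  n_features <- n_features %||% ncol(views$intraview)
  if (is.null(n_features)) stop("n_features (or views) required for validity")
  xmin <- min(cells$x); ymin <- min(cells$y)
  m <- max(cells$x) - xmin
  n_ext <- max(cells$y) - ymin
  dims <- window_count(m, n_ext, s, o)
  a <- dims[["a"]]; b <- dims[["b"]]
  stride <- s * (1 - o)
  z <- a * b
  idx <- 0L
  rows <- integer(z); cols <- integer(z)
  xlo <- numeric(z); ylo <- numeric(z)
  members <- vector("list", z)
  for (r in 0:(b - 1L)) {
    for (c in 0:(a - 1L)) {
      idx <- idx + 1L
      rows[idx] <- r; cols[idx] <- c
      xlo[idx] <- xmin + c * stride
      ylo[idx] <- ymin + r * stride
      in_x <- cells$x >= xlo[idx] &
        (cells$x < xlo[idx] + s | (c == a - 1L & cells$x <= xlo[idx] + s))
      in_y <- cells$y >= ylo[idx] &
        (cells$y < ylo[idx] + s | (r == b - 1L & cells$y <= ylo[idx] + s))
      members[[idx]] <- which(in_x & in_y)
    }
  }
  n_cells <- lengths(members)
  windows <- data.frame(
    index = seq_len(z) - 1L, row = rows, col = cols,
    x_lo = xlo, x_hi = xlo + s, y_lo = ylo, y_hi = ylo + s,
    n_cells = n_cells, valid = n_cells >= n_features
  )
  structure(list(sample_id = cells$sample_id, windows = windows,
                 members = members, s = s, o = o, a = a, b = b,
                 n_features = n_features),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> sample", x$sample_id, ":", x$a, "x", x$b, "grid,",
      nrow(x$windows), "windows (", sum(x$windows$valid), "valid )\n")
  cat("  s =", x$s, ", overlap =", x$o, ", validity >=", x$n_features,
      "cells\n")
  invisible(x)
}
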