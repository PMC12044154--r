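#' Build the two-view composition of a sample
#'
#' Dispatches on the configured mode: cell-type mode yields a one-hot
#' intraview and a k-nearest-neighbour paraview (sum of the one-hot vectors
#' of each cell's k nearest neighbours, self excluded); marker mode yields a
#' marker-abundance intraview and an RBF distance-weighted paraview.
#' Views are always computed on the full sample and subset to windows
#' afterwards, so neighbourhoods crossing window borders are captured.
#'
#' @param cells A [cell_table()].
#' @param config A [winsig_config()].
#' @param features Optional feature set (cohort-wide cell-type levels);
#'   defaults to the levels present in `cells`.
#' @return A `view_composition`.
#' @export
build_views <- function(cells, config, features = NULL) {
  if (config$mode == "celltype") {
    build_celltype_views(cells, k = config$paraview_k, levels = features)
  } else {
    build_marker_views(cells, l = config$paraview_l)
  }
}

#' Cell-type views: one-hot intraview and KNN paraview
#'
#' Row i of the paraview is the sum of the one-hot encoded types of the
#' `min(k, n - 1)` nearest neighbours of cell i by Euclidean distance, self
#' excluded; distance ties are broken by ascending cell index.
#'
#' @param cells A [cell_table()] with cell-type labels.
#' @param k Neighbour count (default 10); capped at `n - 1`.
#' @param levels Optional cohort-wide type levels (lexicographic union);
#'   defaults to the sample's own levels.
#' @return A `view_composition`: list with `intraview` and `paraview`
#'   matrices (cells x types), `mode`, `features`, and `params`.
#' @examples
#' ct <- cell_table("s", x = c(0, 1, 2), y = c(0, 0, 0),
#'                  celltype = c("A", "B", "B"))
#' v <- build_celltype_views(ct, k = 10)
#' v$paraview[1, ]  # A:0, B:2 (effective k = 2)
#' @export
build_celltype_views <- function(cells, k = 10, levels = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  if (is.null(cells$celltype)) stop("mode error: cells carry no cell-type labels")
  n <- cells$n
  if (n < 2) stop("insufficient cells: need at least 2, got ", n)
  levels <- levels %||% levels(cells$celltype)
  ctype <- factor(as.character(cells$celltype), levels = levels)
  if (anyNA(ctype)) stop("cell types outside the declared level set")
  intra <- matrix(0, n, length(levels), dimnames = list(cells$cell_id, levels))
  intra[cbind(seq_len(n), as.integer(ctype))] <- 1
  k_eff <- min(k, n - 1)
  xy <- cbind(cells$x, cells$y)
  para <- matrix(0, n, length(levels), dimnames = list(cells$cell_id, levels))
  block <- 1024L
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    d <- pairwise_dist(xy[lo:hi, , drop = FALSE], xy)
    for (i in lo:hi) {
      di <- d[i - lo + 1L, ]
      di[i] <- Inf
      nbr <- order(di, seq_len(n))[seq_len(k_eff)]
      para[i, ] <- colSums(intra[nbr, , drop = FALSE])
    }
  }
  structure(list(mode = "celltype", intraview = intra, paraview = para,
                 features = levels, params = list(k = k, k_eff = k_eff),
                 sample_id = cells$sample_id),
            class = "view_composition")
}

#' Marker views: abundance intraview and RBF-weighted paraview
#'
#' The paraview of cell i for marker g is
#' `sum_{j != i} exp(-d_ij^2 / l^2) * markers[j, g]`, the dense sum over all
#' other cells (no truncation radius).
#'
#' @param cells A [cell_table()] with a marker matrix.
#' @param l RBF length scale in coordinate units; must be positive.
#' @return A `view_composition`.
#' @export
build_marker_views <- function(cells, l = 100) {
  stopifnot(inherits(cells, "cell_table"))
  if (is.null(cells$markers)) stop("mode error: cells carry no marker columns")
  if (!is.numeric(l) || l <= 0) stop("parameter error: RBF length scale l must be positive")
  n <- cells$n
  intra <- cells$markers
  xy <- cbind(cells$x, cells$y)
  para <- matrix(0, n, ncol(intra), dimnames = dimnames(intra))
  block <- 1024L
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    w <- exp(-pairwise_dist(xy[lo:hi, , drop = FALSE], xy)^2 / l^2)
    w[cbind(seq_len(hi - lo + 1L), lo:hi)] <- 0  # exclude self
    para[lo:hi, ] <- w %*% intra
  }
  structure(list(mode = "marker", intraview = intra, paraview = para,
                 features = colnames(intra), params = list(l = l),
                 sample_id = cells$sample_id),
            class = "view_composition")
}

#' @export
print.view_composition <- function(x, ...) {
  cat("<view_composition> sample", x$sample_id, "- mode:", x$mode, "\n")
  cat("  ", nrow(x$intraview), "cells x", ncol(x$intraview), "features\n")
  cat("  params:", paste(names(x$params), unlist(x$params),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
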