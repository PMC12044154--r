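#' Global composition of one sample
#'
#' The non-spatial baseline: cell-type fractions (cell-type mode) or
#' per-marker total abundance relative to the sample's grand total (marker
#' mode). Entries sum to 1.
#'
#' @param cells A [cell_table()].
#' @param mode `"celltype"` or `"marker"`.
#' @param features Optional cohort-wide feature set (absent cell types get
#'   fraction 0).
#' @return Named numeric composition vector.
#' @export
global_composition <- function(cells, mode = c("celltype", "marker"),
                               features = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cells, "cell_table"))
  if (cells$n == 0) stop("empty sample")
  if (mode == "celltype") {
    if (is.null(cells$celltype)) stop("mode error: no cell-type labels")
    levels <- features %||% levels(cells$celltype)
    tab <- table(factor(as.character(cells$celltype), levels = levels))
    as.numeric(tab) / cells$n -> out
    stats::setNames(out, levels)
  } else {
    if (is.null(cells$markers)) stop("mode error: no marker columns")
    tot <- colSums(cells$markers)
    tot / sum(tot)
  }
}

#' Global relationship representation of one sample
#'
#' Runs the multi-view relationship model on a single window spanning the
#' whole sample; the unfiltered concatenation of weighted standardized
#' importances is the sample's representation. By construction this equals
#' the first-representation row of a windowed run whose window covers the
#' entire sample (same seed substream), which the test suite asserts
#' bitwise.
#'
#' @param cells A [cell_table()].
#' @param config A [winsig_config()].
#' @param features Optional cohort-wide feature set.
#' @return Named numeric importance vector over the signature feature
#'   space.
#' @export
global_relationship <- function(cells, config, features = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  v <- build_views(cells, config, features = features)
  if (cells$n < ncol(v$intraview)) {
    stop("sample has fewer cells (", cells$n, ") than intraview features (",
         ncol(v$intraview), ")")
  }
  sig_feats <- signature_features(v$features, v$mode)
  wm <- fit_window_model(
    v, seq_len(cells$n), config,
    seed = substream_seed(config$seed, "model", cells$sample_id, 0L)
  )
  raw_importance_vector(wm, sig_feats)
}

#' Window composition clustering (WCC) baseline
#'
#' The composition-based windowed baseline: each valid window (same grid
#' and cell-count validity rule as the relationship pipeline) is
#' represented by its normalized cell-type composition (or per-window
#' marker totals over the window's grand total), all windows of all samples
#' are clustered by seeded k-means, and each sample is represented by its
#' window-cluster frequencies. No persistence filter is applied.
#'
#' @param cohort A `winsig_cohort`.
#' @param config A [winsig_config()] (window size/overlap and mode).
#' @param n_clusters Number of k-means clusters (matched to the persistent
#'   cluster count of the relationship run when comparing).
#' @param seed Integer seed.
#' @return List with `representation` (samples x clusters frequency
#'   matrix), `windows` (window table with cluster labels), and `centers`.
#' @export
wcc_representation <- function(cohort, config, n_clusters, seed = 1L) {
  stopifnot(inherits(cohort, "winsig_cohort"))
  nf <- length(cohort$features)
  comp_rows <- list(); meta <- list()
  for (sid in names(cohort$samples)) {
    cells <- cohort$samples[[sid]]
    ws <- decompose_sample(cells, s = config$window_size, o = config$overlap,
                           n_features = nf)
    for (i in which(ws$windows$valid)) {
      mem <- ws$members[[i]]
      comp <- if (cohort$mode == "celltype") {
        tab <- table(factor(as.character(cells$celltype[mem]),
                            levels = cohort$features))
        as.numeric(tab) / length(mem)
      } else {
        tot <- colSums(cells$markers[mem, , drop = FALSE])
        as.numeric(tot / sum(tot))
      }
      node <- paste0(sid, ":", ws$windows$index[i])
      comp_rows[[node]] <- comp
      meta[[node]] <- data.frame(sample = sid,
                                 index = ws$windows$index[i],
                                 stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, comp_rows)
  colnames(X) <- cohort$features
  if (n_clusters > nrow(X)) {
    stop("n_clusters (", n_clusters, ") exceeds the number of valid windows (",
         nrow(X), ")")
  }
  set.seed(seed)
  km <- stats::kmeans(X, centers = n_clusters, nstart = 10)
  windows <- do.call(rbind, meta)
  windows$cluster <- km$cluster
  rownames(windows) <- NULL
  samples <- names(cohort$samples)
  R <- matrix(0, length(samples), n_clusters,
              dimnames = list(samples, paste0("wcc", seq_len(n_clusters))))
  for (sid in samples) {
    sub <- windows$cluster[windows$sample == sid]
    if (length(sub)) {
      R[sid, ] <- as.numeric(table(factor(sub, levels = seq_len(n_clusters)))) /
        length(sub)
    }
  }
  list(representation = R, windows = windows, centers = km$centers)
}
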