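#' Enumerate the signature feature space
#'
#' The per-window signature concatenates the weighted standardized
#' importances of every (view, predictor, target) triple the mode admits:
#' in cell-type mode the paraview triples (all predictor-target pairs), in
#' marker mode additionally the intraview triples (predictor != target).
#' Ordering is deterministic: view (intra before para), then target, then
#' predictor, features lexicographic as fixed by the cohort.
#'
#' @param features Cohort-wide feature names (cell types or markers).
#' @param mode `"celltype"` or `"marker"`.
#' @return A data.frame with columns `view`, `predictor`, `target`, `name`.
#' @export
signature_features <- function(features, mode = c("celltype", "marker")) {
  mode <- match.arg(mode)
  out <- list()
  if (mode == "marker") {
    out$intra <- do.call(rbind, lapply(features, function(t) {
      data.frame(view = "intra", predictor = setdiff(features, t), target = t,
                 stringsAsFactors = FALSE)
    }))
  }
  out$para <- do.call(rbind, lapply(features, function(t) {
    data.frame(view = "para", predictor = features, target = t,
               stringsAsFactors = FALSE)
  }))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df$name <- paste0(df$view, ":", df$predictor, "->", df$target)
  df
}

# Unfiltered concatenation of weighted standardized importances M over the
# full signature feature space (zeros for degenerate/skipped targets).
raw_importance_vector <- function(result, sig_feats) {
  v <- stats::setNames(numeric(nrow(sig_feats)), sig_feats$name)
  for (t in names(result$targets)) {
    res <- result$targets[[t]]
    if (isTRUE(res$degenerate)) next
    for (vw in names(res$M)) {
      v[paste0(vw, ":", names(res$M[[vw]]), "->", t)] <- res$M[[vw]]
    }
  }
  v
}

#' Build the filtered importance signature of one window
#'
#' Entries for targets whose gain in variance explained falls below
#' `gain_threshold` are set to 0, and negative entries are clamped to 0
#' (importances below the mean carry no signal for the signature), so all
#' windows share one nonnegative coordinate system for cosine comparison.
#'
#' @param result A [fit_window_model()] result.
#' @param sig_feats A [signature_features()] table (defaults to the one
#'   implied by `result`).
#' @param gain_threshold Minimum per-target gain (default 0.01).
#' @return Named nonnegative numeric vector over the signature features.
#' @export
build_signature <- function(result, sig_feats = NULL, gain_threshold = 0.01) {
  stopifnot(inherits(result, "window_model"))
  sig_feats <- sig_feats %||% signature_features(result$features, result$mode)
  v <- raw_importance_vector(result, sig_feats)
  gains <- vapply(result$targets, function(t)
    if (isTRUE(t$degenerate)) 0 else t$gain, 0)
  low <- names(gains)[gains < gain_threshold]
  v[sig_feats$target %in% low] <- 0
  v[v < 0] <- 0
  v
}

#' Cosine-similarity graph over window signatures
#'
#' Nodes are the windows with nonzero signatures; an edge is kept with
#' weight `cos(u, v)` iff the cosine similarity is at least `cutoff`.
#' Cosine of nonnegative vectors lies in `[0, 1]`.
#'
#' @param S Numeric matrix, windows x signature features, with row names.
#' @param cutoff Similarity threshold in `[0, 1]`.
#' @return An undirected `igraph` graph with edge attribute `weight`.
#' @export
similarity_graph <- function(S, cutoff = 0.8) {
  stopifnot(is.matrix(S), cutoff >= 0, cutoff <= 1)
  nz <- rowSums(S != 0) > 0
  if (!any(nz)) stop("empty-graph error: all signatures are zero")
  S <- S[nz, , drop = FALSE]
  sim <- cosine_rows(S)
  # small tolerance so exact-boundary similarities (e.g. cos = 1/2 computed
  # through irrational norms) are kept at cutoff = 0.5
  adj <- sim >= cutoff - 1e-12
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(S), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(S))
  if (nrow(idx)) {
    g <- igraph::add_edges(g, t(idx), weight = sim[idx])
  }
  g
}

#' Leiden community detection on the signature graph
#'
#' Deterministic under a fixed seed. Cluster labels are renumbered by
#' descending window count (ties by first occurrence) for stable reporting.
#'
#' @param graph An igraph graph from [similarity_graph()].
#' @param resolution Leiden resolution parameter.
#' @param seed Integer seed.
#' @return Named integer vector of cluster labels (names = window ids).
#' @export
leiden_clusters <- function(graph, resolution = 1, seed = 1L) {
  stopifnot(igraph::vcount(graph) > 0)
  set.seed(seed)
  w <- if (igraph::ecount(graph) > 0) igraph::E(graph)$weight else NULL
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution, weights = w,
                               n_iterations = 5)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(memb)])
  names(out) <- igraph::V(graph)$name
  out
}

#' Persistence filter over window clusters
#'
#' A cluster is retained iff it has windows in at least
#' `min(ceiling(fraction * n_samples), count)` distinct samples; windows of
#' dropped clusters are removed from the representation.
#'
#' @param labels Named integer cluster labels (from [leiden_clusters()]).
#' @param samples Character vector, same length/order as `labels`: the
#'   sample each window belongs to.
#' @param n_samples Total number of samples in the cohort.
#' @param fraction,count The two branches of the persistence criterion
#'   (defaults 0.10 and 5); either suffices, so the binding threshold is
#'   their minimum.
#' @return Sorted integer vector of persistent cluster ids, with the
#'   threshold in attribute `"threshold"`.
#' @export
persistence_filter <- function(labels, samples, n_samples,
                               fraction = 0.10, count = 5L) {
  stopifnot(length(labels) == length(samples))
  threshold <- min(ceiling(fraction * n_samples), count)
  tab <- tapply(samples, labels, function(s) length(unique(s)))
  keep <- sort(as.integer(names(tab)[tab >= threshold]))
  attr(keep, "threshold") <- threshold
  keep
}
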