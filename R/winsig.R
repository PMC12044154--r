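#' Fit the windowed relationship representation of a cohort
#'
#' The main fitting function. For every sample it builds the two-view
#' composition ([build_views()]), decomposes the sample into overlapping
#' square windows ([decompose_sample()]), and fits the per-window multi-view
#' relationship models ([fit_window_model()]). The filtered importance
#' signatures of all valid windows across all samples (first representation)
#' are compared by cosine similarity, the thresholded similarity graph is
#' clustered by Leiden community detection (second representation), and
#' clusters failing the persistence criterion are removed (third
#' representation). Samples are finally represented by their frequency
#' distribution over persistent clusters.
#'
#' @param cohort A `winsig_cohort` from [as_cohort()] or [load_cohort()].
#' @param config A [winsig_config()]; its `mode` must match the cohort.
#' @param verbose Print per-stage progress.
#' @return An object of class `winsig` with components `windows` (one row
#'   per window: grid position, bounds, cell count, validity, cluster label,
#'   persistence flag), `signatures` (windows x kept signature features),
#'   `M_raw` (unfiltered importance vectors), `target_stats` (per-window,
#'   per-target variance explained), `clusters`, `persistent`,
#'   `representation` (samples x persistent clusters), the per-sample
#'   `views` and `window_sets`, and the `config`.
#' @seealso [stratify()], [explain_cluster()], [moran_contiguity()],
#'   [frequency_null()]
#' @export
winsig <- function(cohort, config = winsig_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "winsig_cohort"),
            inherits(config, "winsig_config"))
  if (cohort$mode != config$mode) {
    stop("mode mismatch: cohort is '", cohort$mode, "', config is '",
         config$mode, "'")
  }
  t0 <- proc.time()[["elapsed"]]
  note <- function(...) if (verbose) message(sprintf(...))
  sig_feats <- signature_features(cohort$features, cohort$mode)

  views <- list(); wsets <- list()
  win_rows <- list(); sig_rows <- list(); raw_rows <- list(); stat_rows <- list()
  for (sid in names(cohort$samples)) {
    cells <- cohort$samples[[sid]]
    v <- build_views(cells, config, features = cohort$features)
    ws <- decompose_sample(cells, v, s = config$window_size,
                           o = config$overlap)
    views[[sid]] <- v
    views[[sid]]$xy <- cbind(x = cells$x, y = cells$y)
    wsets[[sid]] <- ws
    wdf <- ws$windows
    wdf <- cbind(sample = sid, wdf, node = paste0(sid, ":", wdf$index),
                 stringsAsFactors = FALSE)
    win_rows[[sid]] <- wdf
    for (i in which(wdf$valid)) {
      wm <- fit_window_model(
        v, ws$members[[i]], config,
        seed = substream_seed(config$seed, "model", sid, wdf$index[i])
      )
      node <- wdf$node[i]
      sig_rows[[node]] <- build_signature(wm, sig_feats,
                                          gain_threshold = config$gain_threshold)
      raw_rows[[node]] <- raw_importance_vector(wm, sig_feats)
      gains <- lapply(names(wm$targets), function(t) {
        res <- wm$targets[[t]]
        data.frame(sample = sid, window = wdf$index[i], target = t,
                   degenerate = isTRUE(res$degenerate),
                   r2_intra = res$r2_intra, r2_multi = res$r2_multi,
                   gain = res$gain,
                   p_intra = if ("intra" %in% names(res$p)) res$p[["intra"]] else NA_real_,
                   p_para = res$p[["para"]],
                   stringsAsFactors = FALSE)
      })
      stat_rows[[node]] <- do.call(rbind, gains)
    }
    note("sample %s: %d cells, %d/%d valid windows [%.1fs]", sid, cells$n,
         sum(wdf$valid), nrow(wdf), proc.time()[["elapsed"]] - t0)
  }
  windows <- do.call(rbind, win_rows)
  rownames(windows) <- NULL
  S_full <- do.call(rbind, sig_rows)
  M_raw <- do.call(rbind, raw_rows)
  target_stats <- do.call(rbind, stat_rows)
  rownames(target_stats) <- NULL

  # drop signature columns that are zero across every window
  kept <- colSums(S_full != 0) > 0
  S <- S_full[, kept, drop = FALSE]
  note("signatures: %d windows x %d nonzero features", nrow(S), ncol(S))

  windows$cluster <- NA_integer_
  persistent <- integer(0)
  graph_edges <- data.frame(from = character(), to = character(),
                            weight = numeric())
  nz <- rowSums(S != 0) > 0
  if (any(nz)) {
    g <- similarity_graph(S, cutoff = config$similarity_cutoff)
    if (igraph::ecount(g) > 0) {
      el <- igraph::as_data_frame(g, what = "edges")
      graph_edges <- data.frame(from = el$from, to = el$to,
                                weight = el$weight)
    }
    labels <- leiden_clusters(g, resolution = config$leiden_resolution,
                              seed = substream_seed(config$seed, "leiden"))
    windows$cluster[match(names(labels), windows$node)] <- labels
    lab_samples <- windows$sample[match(names(labels), windows$node)]
    persistent <- persistence_filter(labels, lab_samples,
                                     n_samples = length(cohort$samples),
                                     fraction = config$persistence_fraction,
                                     count = config$persistence_count)
    note("clusters: %d total, %d persistent (threshold %d samples)",
         length(unique(labels)), length(persistent),
         attr(persistent, "threshold"))
  }
  windows$persistent <- !is.na(windows$cluster) &
    windows$cluster %in% persistent

  fit <- structure(list(
    config = config, mode = cohort$mode, features = cohort$features,
    sig_feats = sig_feats, windows = windows,
    signatures = S, M_raw = M_raw, target_stats = target_stats,
    graph_edges = graph_edges, clusters = windows$cluster,
    persistent = persistent, condition = cohort$condition,
    views = views, window_sets = wsets,
    n_samples = length(cohort$samples),
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "winsig")
  fit$representation <- sample_representation(fit)
  fit
}

#' @export
print.winsig <- function(x, ...) {
  cat("<winsig> fit on", x$n_samples, "samples (mode:", x$mode, ")\n")
  cat("  windows:", nrow(x$windows), "total,", sum(x$windows$valid),
      "valid,", sum(!is.na(x$windows$cluster)), "assigned\n")
  cat("  clusters:", length(unique(stats::na.omit(x$windows$cluster))),
      "detected,", length(x$persistent), "persistent\n")
  cat("  window size", x$config$window_size, "with overlap",
      x$config$overlap, "; cosine cutoff", x$config$similarity_cutoff, "\n")
  invisible(x)
}

#' @export
summary.winsig <- function(object, ...) {
  w <- object$windows
  cl <- stats::na.omit(unique(w$cluster))
  tab <- do.call(rbind, lapply(sort(cl), function(k) {
    sub <- w[!is.na(w$cluster) & w$cluster == k, ]
    data.frame(cluster = k, n_windows = nrow(sub),
               n_samples = length(unique(sub$sample)),
               persistent = k %in% object$persistent)
  }))
  out <- list(clusters = tab, n_samples = object$n_samples,
              persistence_threshold = attr(object$persistent, "threshold"),
              representation = object$representation)
  class(out) <- "summary.winsig"
  out
}

#' @export
print.summary.winsig <- function(x, ...) {
  cat("Window clusters (", x$n_samples, "samples; persistence threshold",
      x$persistence_threshold %||% NA, "samples):\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Plot the window-cluster map of one sample
#'
#' Draws the sample's cells (grey points) and overlays its valid windows
#' coloured by persistent cluster label; unassigned or non-persistent
#' windows are left unfilled.
#'
#' @param x A `winsig` fit.
#' @param sample Sample id to plot (default: first).
#' @param cex Cell point size.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted window table.
#' @export
plot.winsig <- function(x, sample = names(x$views)[1], cex = 0.3, ...) {
  w <- x$windows[x$windows$sample == sample, ]
  v <- x$views[[sample]]
  cols <- grDevices::hcl.colors(max(1, length(x$persistent)), "Dark 3")
  graphics::plot(range(w$x_lo, w$x_hi), range(w$y_lo, w$y_hi), type = "n",
                 xlab = "x", ylab = "y",
                 main = paste("sample", sample), asp = 1, ...)
  if (!is.null(v$xy)) {
    graphics::points(v$xy[, "x"], v$xy[, "y"], pch = 16, cex = cex,
                     col = "grey55")
  }
  for (i in seq_len(nrow(w))) {
    fill <- NA
    if (w$persistent[i]) {
      fill <- grDevices::adjustcolor(
        cols[match(w$cluster[i], x$persistent)], alpha.f = 0.35)
    }
    graphics::rect(w$x_lo[i], w$y_lo[i], w$x_hi[i], w$y_hi[i],
                   col = fill, border = "grey70")
  }
  if (length(x$persistent)) {
    graphics::legend("topright", legend = paste("cluster", x$persistent),
                     fill = cols[seq_along(x$persistent)], cex = 0.8,
                     bg = "white")
  }
  invisible(w)
}

#' Re-cluster a fit at a different cutoff or resolution
#'
#' The window models and signatures are kept; only the similarity graph,
#' Leiden communities, persistence filter and sample representation are
#' recomputed. Used by [sweep_clustering()] for the per-task grid search
#' over the two clustering parameters.
#'
#' @param fit A [winsig()] fit.
#' @param similarity_cutoff,leiden_resolution New clustering parameters
#'   (defaults: keep the fit's values).
#' @return A `winsig` fit with updated clustering and representation.
#' @export
recluster <- function(fit, similarity_cutoff = fit$config$similarity_cutoff,
                      leiden_resolution = fit$config$leiden_resolution) {
  stopifnot(inherits(fit, "winsig"))
  cfg <- fit$config
  cfg$similarity_cutoff <- similarity_cutoff
  cfg$leiden_resolution <- leiden_resolution
  w <- fit$windows
  w$cluster <- NA_integer_
  persistent <- integer(0)
  graph_edges <- data.frame(from = character(), to = character(),
                            weight = numeric())
  if (any(rowSums(fit$signatures != 0) > 0)) {
    g <- similarity_graph(fit$signatures, cutoff = similarity_cutoff)
    if (igraph::ecount(g) > 0) {
      el <- igraph::as_data_frame(g, what = "edges")
      graph_edges <- data.frame(from = el$from, to = el$to,
                                weight = el$weight)
    }
    labels <- leiden_clusters(g, resolution = leiden_resolution,
                              seed = substream_seed(cfg$seed, "leiden"))
    w$cluster[match(names(labels), w$node)] <- labels
    persistent <- persistence_filter(
      labels, w$sample[match(names(labels), w$node)],
      n_samples = fit$n_samples,
      fraction = cfg$persistence_fraction, count = cfg$persistence_count)
  }
  w$persistent <- !is.na(w$cluster) & w$cluster %in% persistent
  fit$config <- cfg
  fit$windows <- w
  fit$clusters <- w$cluster
  fit$persistent <- persistent
  fit$graph_edges <- graph_edges
  fit$representation <- suppressWarnings(sample_representation(fit))
  fit
}

#' Grid search over similarity cutoff and Leiden resolution
#'
#' The two clustering parameters are selected per task by their downstream
#' stratification performance: for every grid point the fit is re-clustered
#' and the cross-validated macro-AUROC of the cluster-frequency logistic
#' model is recorded. Ties prefer the sparser representation (fewer
#' persistent clusters), then the higher cutoff.
#'
#' @param fit A [winsig()] fit.
#' @param labels Binary labels (default: the fit's stored condition).
#' @param cutoffs,resolutions Grid values.
#' @param folds,seed Passed to [stratify()].
#' @return List with `grid` (cutoff, resolution, persistent-cluster count,
#'   AUROC), `best` (selected parameters), and `fit` (the re-clustered fit
#'   at the selection).
#' @export
sweep_clustering <- function(fit, labels = NULL,
                             cutoffs = seq(0.3, 0.8, by = 0.1),
                             resolutions = c(0.5, 1, 2),
                             folds = 10L, seed = 1L) {
  stopifnot(inherits(fit, "winsig"))
  labels <- labels %||% fit$condition
  grid <- expand.grid(cutoff = cutoffs, resolution = resolutions,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n_persistent <- NA_integer_
  grid$auroc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    f2 <- recluster(fit, grid$cutoff[i], grid$resolution[i])
    grid$n_persistent[i] <- length(f2$persistent)
    if (length(f2$persistent) >= 1) {
      st <- suppressWarnings(stratify(f2$representation, labels,
                                      folds = folds, seed = seed))
      grid$auroc[i] <- st$auroc
    }
  }
  ord <- order(-grid$auroc, grid$n_persistent, -grid$cutoff)
  best <- grid[ord[1], , drop = FALSE]
  list(grid = grid, best = best,
       fit = recluster(fit, best$cutoff, best$resolution))
}
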