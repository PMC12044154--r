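#' Pipeline configuration
#'
#' Collects every tunable parameter of the windowed relationship pipeline in
#' one validated object. All randomness in the pipeline flows from `seed`;
#' each stochastic stage derives its own substream seed from it.
#'
#' @param mode Input representation: `"celltype"` (one-hot cell-type
#'   intraview, k-nearest-neighbour paraview) or `"marker"` (marker-abundance
#'   intraview, RBF distance-weighted paraview).
#' @param paraview_k Neighbour count for the cell-type paraview (default 10).
#' @param paraview_l RBF length scale for the marker paraview, in the
#'   coordinate units of the input (default 100).
#' @param window_size Side length `s` of the square sliding window, in
#'   coordinate units.
#' @param overlap Fractional window overlap `o` in `[0, 1)`; the grid stride
#'   is `s * (1 - o)` (default 0.5).
#' @param n_trees Trees per random forest (default 100).
#' @param mtry Features tried per split; `NULL` uses `floor(sqrt(p))`,
#'   the usual forest default.
#' @param similarity_cutoff Minimum cosine similarity for an edge in the
#'   window-signature graph (default 0.8).
#' @param leiden_resolution Resolution of the Leiden community detection
#'   (default 1).
#' @param persistence_fraction,persistence_count A window cluster is
#'   persistent when it occurs in at least
#'   `min(ceiling(persistence_fraction * n_samples), persistence_count)`
#'   distinct samples (defaults 0.10 and 5).
#' @param gain_threshold Minimum gain in variance explained for a target's
#'   importances to enter the signature (default 0.01, i.e. 1%).
#' @param ridge_lambda L2 penalty of the late-fusion linear meta-model,
#'   applied on standardized view predictions (default 1e-3).
#' @param seed Integer master seed.
#'
#' @return An object of class `winsig_config`.
#' @examples
#' cfg <- winsig_config(mode = "celltype", window_size = 200, seed = 7)
#' cfg$paraview_k
#' @export
winsig_config <- function(mode = c("celltype", "marker"),
                          paraview_k = 10L,
                          paraview_l = 100,
                          window_size = 200,
                          overlap = 0.5,
                          n_trees = 100L,
                          mtry = NULL,
                          similarity_cutoff = 0.8,
                          leiden_resolution = 1,
                          persistence_fraction = 0.10,
                          persistence_count = 5L,
                          gain_threshold = 0.01,
                          ridge_lambda = 1e-3,
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(
    "window_size must be positive" = is.numeric(window_size) && window_size > 0,
    "overlap must be in [0, 1)" = is.numeric(overlap) && overlap >= 0 && overlap < 1,
    "similarity_cutoff must be in [0, 1]" =
      similarity_cutoff >= 0 && similarity_cutoff <= 1,
    "n_trees must be >= 1" = n_trees >= 1,
    "paraview_k must be >= 1" = paraview_k >= 1,
    "paraview_l must be positive" = paraview_l > 0,
    "persistence_fraction must be in [0, 1]" =
      persistence_fraction >= 0 && persistence_fraction <= 1,
    "ridge_lambda must be nonnegative" = ridge_lambda >= 0
  )
  structure(list(
    mode = mode,
    paraview_k = as.integer(paraview_k),
    paraview_l = paraview_l,
    window_size = window_size,
    overlap = overlap,
    n_trees = as.integer(n_trees),
    mtry = mtry,
    similarity_cutoff = similarity_cutoff,
    leiden_resolution = leiden_resolution,
    persistence_fraction = persistence_fraction,
    persistence_count = as.integer(persistence_count),
    gain_threshold = gain_threshold,
    ridge_lambda = ridge_lambda,
    seed = as.integer(seed)
  ), class = "winsig_config")
}

#' @export
print.winsig_config <- function(x, ...) {
  cat("<winsig_config>\n")
  cat("  mode:", x$mode, "\n")
  cat("  window: s =", x$window_size, ", overlap =", x$overlap, "\n")
  if (x$mode == "celltype") {
    cat("  paraview: k =", x$paraview_k, "nearest neighbours\n")
  } else {
    cat("  paraview: RBF length scale l =", x$paraview_l, "\n")
  }
  cat("  forests:", x$n_trees, "trees\n")
  cat("  graph: cosine cutoff =", x$similarity_cutoff,
      ", Leiden resolution =", x$leiden_resolution, "\n")
  cat("  persistence: >= min(ceiling(", x$persistence_fraction,
      "* S),", x$persistence_count, ") samples\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields absent from the file keep their [winsig_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `winsig_config` object.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(winsig_config))
  vals <- vals[intersect(names(vals), known)]
  do.call(winsig_config, vals)
}
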