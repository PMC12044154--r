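#' Construct a segmented-cell table
#'
#' A cell table holds one sample's segmented cells: continuous x/y centroid
#' coordinates plus either a categorical cell-type label, a nonnegative
#' marker-abundance matrix over a shared panel, or both.
#'
#' @param sample_id Sample identifier (length-1 character).
#' @param x,y Numeric centroid coordinates, finite.
#' @param celltype Optional factor/character of per-cell type labels.
#' @param markers Optional nonnegative numeric matrix (cells x markers) with
#'   column names.
#' @param cell_id Optional character per-cell ids; defaults to `"c1"..."cn"`.
#'   Must be unique within the sample.
#' @return An object of class `cell_table`.
#' @examples
#' ct <- cell_table("s1", x = c(0, 1, 2), y = c(0, 0, 1),
#'                  celltype = c("A", "B", "B"))
#' ct$n
#' @export
cell_table <- function(sample_id, x, y, celltype = NULL, markers = NULL,
                       cell_id = NULL) {
  n <- length(x)
  stopifnot(
    "x and y must have equal length" = length(y) == n,
    "coordinates must be finite" = all(is.finite(x)) && all(is.finite(y)),
    "one of celltype or markers is required" =
      !is.null(celltype) || !is.null(markers)
  )
  cell_id <- cell_id %||% paste0("c", seq_len(n))
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) {
    stop("duplicated cell_id within sample '", sample_id, "'")
  }
  if (!is.null(celltype)) {
    stopifnot(length(celltype) == n)
    if (!is.factor(celltype)) {
      celltype <- factor(celltype, levels = sort(unique(as.character(celltype))))
    }
  }
  if (!is.null(markers)) {
    markers <- as.matrix(markers)
    stopifnot(
      "markers must have one row per cell" = nrow(markers) == n,
      "markers must be named" = !is.null(colnames(markers)),
      "markers must be nonnegative and finite" =
        all(is.finite(markers)) && all(markers >= 0)
    )
    rownames(markers) <- cell_id
  }
  structure(list(sample_id = as.character(sample_id), n = n,
                 cell_id = cell_id, x = as.numeric(x), y = as.numeric(y),
                 celltype = celltype, markers = markers),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> sample", x$sample_id, "with", x$n, "cells\n")
  cat("  extent: x [", round(min(x$x), 2), ",", round(max(x$x), 2),
      "], y [", round(min(x$y), 2), ",", round(max(x$y), 2), "]\n")
  if (!is.null(x$celltype)) {
    cat("  cell types:", paste(levels(x$celltype), collapse = ", "), "\n")
  }
  if (!is.null(x$markers)) {
    cat("  markers:", ncol(x$markers), "(", paste(utils::head(colnames(x$markers), 5),
        collapse = ", "), if (ncol(x$markers) > 5) ", ..." else "", ")\n")
  }
  invisible(x)
}

#' Read a cell table from delimited text
#'
#' @param path CSV (or TSV, by extension) file with one row per cell.
#' @param sample_id Sample identifier; defaults to the file name sans
#'   extension.
#' @param columns Column mapping: a list with entries `x`, `y` (required),
#'   and optionally `cell_id`, `celltype`, and `markers` (character vector of
#'   marker column names).
#' @param mode Optional mode check: `"celltype"` requires a cell-type column,
#'   `"marker"` requires marker columns; an informative error is raised when
#'   the requested mode's columns are absent.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path, sample_id = NULL,
                            columns = list(x = "x", y = "y",
                                           cell_id = "cell_id",
                                           celltype = "celltype",
                                           markers = NULL),
                            mode = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (fld in c("x", "y")) {
    col <- columns[[fld]] %||% fld
    if (!col %in% names(df)) {
      stop("schema error: required coordinate column '", col,
           "' not found in ", path)
    }
  }
  ct_col <- columns$celltype %||% "celltype"
  has_ct <- ct_col %in% names(df)
  mk_cols <- columns$markers
  has_mk <- !is.null(mk_cols) && all(mk_cols %in% names(df))
  if (!is.null(mode)) {
    if (mode == "celltype" && !has_ct) {
      stop("mode error: mode 'celltype' requested but column '", ct_col,
           "' is absent in ", path)
    }
    if (mode == "marker" && !has_mk) {
      stop("mode error: mode 'marker' requested but marker columns are ",
           "absent in ", path)
    }
  }
  if (!has_ct && !has_mk) {
    stop("schema error: neither cell-type nor marker columns found in ", path)
  }
  id_col <- columns$cell_id %||% "cell_id"
  cell_table(
    sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
    x = df[[columns$x %||% "x"]],
    y = df[[columns$y %||% "y"]],
    celltype = if (has_ct) df[[ct_col]] else NULL,
    markers = if (has_mk) as.matrix(df[, mk_cols, drop = FALSE]) else NULL,
    cell_id = if (id_col %in% names(df)) as.character(df[[id_col]]) else NULL
  )
}

#' Write a cell table as CSV
#'
#' Numeric columns are written with 17 significant digits so that reading
#' the file back reproduces the stored doubles bit-exactly.
#'
#' @param ct A [cell_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(ct, path) {
  stopifnot(inherits(ct, "cell_table"))
  fmt <- function(v) sub("^\\s+", "", sprintf("%.17g", v))
  df <- data.frame(cell_id = ct$cell_id, x = fmt(ct$x), y = fmt(ct$y),
                   stringsAsFactors = FALSE)
  if (!is.null(ct$celltype)) df$celltype <- as.character(ct$celltype)
  if (!is.null(ct$markers)) {
    for (m in colnames(ct$markers)) df[[m]] <- fmt(ct$markers[, m])
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest maps samples to their cell-table files and binary condition
#' labels. CSV manifests need columns `sample_id`, `path`, `condition` and
#' optionally `patient_id`; YAML manifests a list of records with the same
#' fields.
#'
#' @param path CSV or YAML manifest file.
#' @return A `data.frame` of class `winsig_manifest`.
#' @export
read_manifest <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(sample_id = r$sample_id, path = r$path,
                 condition = r$condition,
                 patient_id = r$patient_id %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "path", "condition") %in% names(df)))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in manifest")
  class(df) <- c("winsig_manifest", "data.frame")
  df
}

#' Assemble a cohort from in-memory cell tables
#'
#' Harmonizes the feature space across samples: cell-type levels become the
#' lexicographically ordered union over the cohort (absent levels count 0 in
#' any one sample), while marker panels must match exactly.
#'
#' @param samples List of [cell_table()] objects.
#' @param condition Binary condition label per sample (factor or character).
#' @param mode `"celltype"` or `"marker"`.
#' @return An object of class `winsig_cohort`: a list with `samples`
#'   (named list), `condition` (named factor), `features`, and `mode`.
#' @export
as_cohort <- function(samples, condition, mode = c("celltype", "marker")) {
  mode <- match.arg(mode)
  stopifnot(length(samples) == length(condition),
            all(vapply(samples, inherits, TRUE, "cell_table")))
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicated sample ids in cohort")
  names(samples) <- ids
  if (mode == "celltype") {
    if (any(vapply(samples, function(s) is.null(s$celltype), TRUE))) {
      stop("mode error: mode 'celltype' but a sample lacks cell-type labels")
    }
    features <- sort(unique(unlist(lapply(samples, function(s)
      levels(s$celltype)))))
    samples <- lapply(samples, function(s) {
      s$celltype <- factor(as.character(s$celltype), levels = features)
      s
    })
  } else {
    if (any(vapply(samples, function(s) is.null(s$markers), TRUE))) {
      stop("mode error: mode 'marker' but a sample lacks marker columns")
    }
    panels <- lapply(samples, function(s) sort(colnames(s$markers)))
    if (length(unique(panels)) != 1) {
      stop("panel-mismatch error: marker panels differ across samples")
    }
    features <- panels[[1]]
    samples <- lapply(samples, function(s) {
      s$markers <- s$markers[, features, drop = FALSE]
      s
    })
  }
  condition <- factor(condition)
  if (nlevels(condition) != 2) {
    warning("cohort condition is not binary (", nlevels(condition),
            " levels); downstream stratification requires two classes")
  }
  names(condition) <- ids
  structure(list(samples = samples, condition = condition,
                 features = features, mode = mode),
            class = "winsig_cohort")
}

#' Load a cohort from a manifest
#'
#' @param manifest A [read_manifest()] result (or path to one).
#' @param columns Column mapping passed to [read_cell_table()].
#' @param mode `"celltype"` or `"marker"`.
#' @param base_dir Directory that relative manifest paths are resolved
#'   against; defaults to the manifest's own directory when `manifest` is a
#'   path, else the working directory.
#' @return A `winsig_cohort`.
#' @export
load_cohort <- function(manifest, columns = list(x = "x", y = "y"),
                        mode = c("celltype", "marker"), base_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  base_dir <- base_dir %||% "."
  samples <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$path[i])
    samples[[i]] <- tryCatch(
      read_cell_table(p, sample_id = manifest$sample_id[i],
                      columns = columns, mode = mode),
      error = function(e) stop("failed to load sample '",
                               manifest$sample_id[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  as_cohort(samples, manifest$condition, mode)
}

#' @export
print.winsig_cohort <- function(x, ...) {
  cat("<winsig_cohort>", length(x$samples), "samples, mode:", x$mode, "\n")
  print(table(condition = x$condition))
  cat("features (", length(x$features), "): ",
      paste(utils::head(x$features, 8), collapse = ", "),
      if (length(x$features) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
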