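# Shared fixtures and independent brute-force oracles. Expensive objects
# are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

# --- small deterministic cell tables -------------------------------------

tiny_cells <- function(n = 60, n_types = 4, extent = 200, seed = 7) {
  set.seed(seed)
  cell_table(sprintf("tiny%d", seed),
             x = runif(n, 0, extent), y = runif(n, 0, extent),
             celltype = sample(paste0("T", seq_len(n_types)), n,
                               replace = TRUE))
}

tiny_marker_cells <- function(n = 50, n_markers = 5, extent = 200,
                              seed = 7) {
  set.seed(seed)
  M <- matrix(rgamma(n * n_markers, 2, 1), n, n_markers,
              dimnames = list(NULL, paste0("M", seq_len(n_markers))))
  cell_table(sprintf("tinymk%d", seed),
             x = runif(n, 0, extent), y = runif(n, 0, extent), markers = M)
}

small_cohort <- function(seed = 5) {
  sim <- simulate_cohort(cohort_spec(
    samples_per_condition = 3, extent = 400, cells_per_sample = 350,
    n_types = 5, seed = seed))
  sim
}

# Default desk-scale positive-control cohort and its fit; seed fixed at 42.
default_sim <- function() {
  fixture("default_sim", function() simulate_cohort(cohort_spec(seed = 42)))
}

default_fit <- function() {
  fixture("default_fit", function() {
    winsig(default_sim()$cohort,
           winsig_config(mode = "celltype", seed = 42))
  })
}

# Window with a planted exact relationship: type B wherever >= 2 of the 10
# nearest neighbours are type A.
planted_cells <- function(n = 120, seed = 31) {
  set.seed(seed)
  x <- runif(n, 0, 200); y <- runif(n, 0, 200)
  types <- rep("C", n)
  types[sample(n, round(n / 4.5))] <- "A"
  ct0 <- cell_table("s", x, y,
                    celltype = factor(types, levels = c("A", "B", "C")))
  v0 <- build_celltype_views(ct0, k = 10)
  types[types != "A" & v0$paraview[, "A"] >= 2] <- "B"
  cell_table("s", x, y, celltype = types)
}

# --- brute-force oracles --------------------------------------------------

# KNN paraview by all-pairs distance sort (self excluded, index ties).
bf_knn_paraview <- function(cells, k, levels) {
  n <- cells$n
  onehot <- outer(as.character(cells$celltype), levels, "==") * 1
  out <- matrix(0, n, length(levels))
  for (i in seq_len(n)) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    nbr <- ord[seq_len(min(k, n - 1))]
    out[i, ] <- colSums(onehot[nbr, , drop = FALSE])
  }
  out
}

# RBF paraview by dense double loop.
bf_rbf_paraview <- function(cells, l) {
  n <- cells$n
  out <- matrix(0, n, ncol(cells$markers))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d2 <- (cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2
      out[i, ] <- out[i, ] + exp(-d2 / l^2) * cells$markers[j, ]
    }
  }
  out
}

# Textbook Moran's I double sum.
bf_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * z[i] * z[j]
  }
  n / sum(W) * num / sum(z^2)
}

# Minimal stand-in winsig object for functions that only need the window
# table / persistent set (representation, Moran wrappers).
fake_fit <- function(windows, persistent, samples = unique(windows$sample)) {
  structure(list(
    windows = windows, persistent = persistent,
    views = setNames(vector("list", length(samples)), samples),
    n_samples = length(samples),
    config = winsig_config(seed = 1)
  ), class = "winsig")
}
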