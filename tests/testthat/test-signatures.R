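# A handmade window_model for filter tests: two targets, one view.
mock_model <- function(gains, M) {
  feats <- names(gains)
  targets <- lapply(feats, function(t) {
    list(degenerate = FALSE, r2_intra = 0, r2_multi = gains[[t]],
         gain = gains[[t]], p = c(para = 0.1),
         I = list(para = abs(M[[t]])), M = list(para = M[[t]]))
  })
  names(targets) <- feats
  structure(list(targets = targets, features = feats, mode = "celltype",
                 views_used = "para", n_cells = 50, seed = 1),
            class = "window_model")
}

test_that("signature filtering zeroes low-gain targets and negatives", {
  feats <- c("A", "B")
  m <- mock_model(
    gains = c(A = 0.005, B = 0.05),
    M = list(A = c(A = 1.2, B = -0.3), B = c(A = 1.5, B = -0.8))
  )
  sig <- build_signature(m, gain_threshold = 0.01)
  # target A at 0.5% gain contributes nothing
  expect_equal(unname(sig[c("para:A->A", "para:B->A")]), c(0, 0))
  # negatives clamp to zero, positives survive
  expect_equal(unname(sig[c("para:A->B", "para:B->B")]), c(1.5, 0))
})

test_that("cosine similarity graph keeps edges at or above the cutoff", {
  S <- rbind(u = c(1, 0, 1), v = c(1, 1, 0), w = c(1, 0, 1), z = c(0, 0, 0))
  colnames(S) <- paste0("f", 1:3)
  g <- similarity_graph(S, cutoff = 0.5)
  # zero row excluded; identical rows u,w at cos 1; u-v and w-v at cos 0.5
  expect_setequal(igraph::V(g)$name, c("u", "v", "w"))
  el <- igraph::as_data_frame(g)
  key <- paste(pmin(el$from, el$to), pmax(el$from, el$to))
  expect_setequal(key, c("u w", "u v", "v w"))
  expect_equal(sort(el$weight), c(0.5, 0.5, 1))
  # above 0.5 the mixed edges drop
  g2 <- similarity_graph(S, cutoff = 0.6)
  expect_equal(igraph::ecount(g2), 1)
  # disjoint support = cosine 0: dropped for any positive cutoff
  S2 <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(igraph::ecount(similarity_graph(S2, cutoff = 1e-9)), 0)
  expect_error(similarity_graph(matrix(0, 2, 2), 0.5), "empty-graph")
})

test_that("raising the cutoff never adds edges", {
  set.seed(12)
  S <- matrix(rexp(40 * 6), 40, 6)
  S[sample(length(S), 120)] <- 0
  rownames(S) <- paste0("w", 1:40); colnames(S) <- paste0("f", 1:6)
  edges <- function(cut) {
    g <- similarity_graph(S, cut)
    el <- igraph::as_data_frame(g)
    paste(pmin(el$from, el$to), pmax(el$from, el$to))
  }
  prev <- edges(0.1)
  for (cut in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- edges(cut)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("Leiden clustering is deterministic and recovers cliques", {
  # two groups with identical signatures within group, orthogonal across
  S <- rbind(matrix(rep(c(2, 1, 0, 0), 5), 5, byrow = TRUE),
             matrix(rep(c(0, 0, 3, 1), 5), 5, byrow = TRUE))
  rownames(S) <- paste0("w", 1:10); colnames(S) <- paste0("f", 1:4)
  g <- similarity_graph(S, cutoff = 0.5)
  lab1 <- leiden_clusters(g, resolution = 1, seed = 11)
  lab2 <- leiden_clusters(g, resolution = 1, seed = 11)
  expect_identical(lab1, lab2)
  expect_equal(length(unique(lab1)), 2)
  # communities match the connected components (independent reference)
  comp <- igraph::components(g)$membership
  expect_equal(mclust::adjustedRandIndex(lab1, comp[names(lab1)]), 1)
  # single node graph: one cluster
  g1 <- similarity_graph(S[1, , drop = FALSE], cutoff = 0.9)
  expect_equal(unname(leiden_clusters(g1, 1, 1)), 1L)
})

test_that("persistence criterion keeps clusters spanning enough samples", {
  # 60-sample cohort: threshold min(ceiling(6), 5) = 5
  lab <- c(rep(1, 6), rep(2, 4))
  smp <- c(paste0("s", 1:5), "s1", paste0("t", 1:4))
  names(lab) <- paste0("w", 1:10)
  keep <- persistence_filter(lab, smp, n_samples = 60)
  expect_equal(as.integer(keep), 1L)  # cluster 1 in 5 samples, 2 in 4
  expect_equal(attr(keep, "threshold"), 5)
  # 20-sample cohort: threshold min(2, 5) = 2
  keep20 <- persistence_filter(lab, smp, n_samples = 20)
  expect_setequal(as.integer(keep20), c(1L, 2L))
  expect_equal(attr(keep20, "threshold"), 2)
})

test_that("raising the persistence threshold never adds clusters", {
  set.seed(3)
  lab <- sample(1:6, 80, TRUE)
  smp <- sample(paste0("s", 1:12), 80, TRUE)
  names(lab) <- paste0("w", 1:80)
  prev <- persistence_filter(lab, smp, 12, fraction = 0, count = 1L)
  for (k in 2:8) {
    cur <- persistence_filter(lab, smp, 12, fraction = 1, count = k)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("signatures are invariant to the ordering of cells in a window", {
  ct <- planted_cells(n = 120, seed = 31)
  v <- build_celltype_views(ct, k = 10)
  cfg <- winsig_config(seed = 2)
  set.seed(10)
  perm <- sample(ct$n)
  ctp <- cell_table(ct$sample_id, ct$x[perm], ct$y[perm], ct$celltype[perm])
  vp <- build_celltype_views(ctp, k = 10)
  s1 <- build_signature(fit_window_model(v, 1:ct$n, cfg, seed = 5))
  s2 <- build_signature(fit_window_model(vp, 1:ct$n, cfg, seed = 5))
  # same cells in a different order: the planted relationship dominates
  # both signatures (bit-identity is not expected because the bootstrap
  # draws differ with row order)
  expect_equal(names(which.max(s1)), names(which.max(s2)))
  expect_gt(cor(s1, s2), 0.8)
})
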