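test_that("global compositions are normalized fractions", {
  ct <- cell_table("s", 1:4, 1:4, celltype = c("A", "A", "B", "B"))
  expect_equal(unname(global_composition(ct)), c(0.5, 0.5))
  one <- cell_table("s", 1:3, 1:3, celltype = rep("A", 3))
  expect_equal(unname(global_composition(one, features = c("A", "B"))),
               c(1, 0))
  mk <- cell_table("s", 1:2, 1:2,
                   markers = matrix(c(1, 1, 3, 3), 2,
                                    dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(global_composition(mk, mode = "marker")),
               c(0.25, 0.75))
})

test_that("global relationship equals a single-window windowed run bitwise", {
  ct <- planted_cells(n = 80, seed = 19)
  cfg <- winsig_config(mode = "celltype", window_size = 1000, overlap = 0,
                       seed = 77)
  # single-sample cohort: the binary-label warning is expected
  coh <- suppressWarnings(as_cohort(list(ct), "g1"))
  fit <- suppressWarnings(winsig(coh, cfg))
  expect_equal(sum(fit$windows$valid), 1)
  gr <- global_relationship(ct, cfg)
  expect_identical(unname(gr), unname(fit$M_raw[1, ]))
})

test_that("a planted global relationship tops the representation", {
  ct <- planted_cells(n = 120, seed = 3)
  cfg <- winsig_config(mode = "celltype", seed = 5)
  gr <- global_relationship(ct, cfg)
  expect_equal(names(which.max(gr)), "para:A->B")
})

test_that("shuffled labels give a near-empty filtered representation", {
  set.seed(41)
  ct <- cell_table("s", runif(100, 0, 300), runif(100, 0, 300),
                   celltype = sample(c("A", "B", "C"), 100, TRUE))
  cfg <- winsig_config(mode = "celltype", seed = 6)
  v <- build_views(ct, cfg)
  wm <- fit_window_model(v, 1:100, cfg, seed = 8)
  gains <- vapply(wm$targets, `[[`, 0, "gain")
  expect_lt(mean(gains), 0.05)
  sig <- build_signature(wm)
  expect_lt(mean(sig != 0), 0.5)
})

test_that("window composition clustering separates planted compositions", {
  # two samples, each a 2x1 grid of windows with opposite pure
  # compositions; k = 2 recovers the regions exactly
  mk <- function(sid) {
    x <- c(runif(60, 0, 99), runif(60, 101, 200))
    types <- rep(c("A", "B"), each = 60)
    cell_table(sid, x, runif(120, 0, 50), celltype = types)
  }
  coh <- as_cohort(list(mk("s1"), mk("s2")), c("g1", "g2"))
  cfg <- winsig_config(window_size = 100, overlap = 0, seed = 1)
  wcc <- wcc_representation(coh, cfg, n_clusters = 2, seed = 4)
  truth <- rep(rep(1:2, 2))
  expect_equal(mclust::adjustedRandIndex(wcc$windows$cluster, truth), 1)
  expect_equal(unname(rowSums(wcc$representation)), c(1, 1))
  # window composition example: counts (2,2,0) over three types
  ct <- cell_table("s", c(1, 2, 3, 4), rep(1, 4),
                   celltype = factor(c("A", "A", "B", "B"),
                                     levels = c("A", "B", "C")))
  coh2 <- suppressWarnings(as_cohort(list(ct), "g1"))
  cfg2 <- winsig_config(window_size = 10, overlap = 0, seed = 1)
  wcc2 <- wcc_representation(coh2, cfg2, n_clusters = 1, seed = 1)
  expect_equal(unname(wcc2$centers[1, ]), c(0.5, 0.5, 0))
})

test_that("WCC is deterministic and invariant to cell order", {
  sim <- small_cohort(seed = 6)
  cfg <- winsig_config(window_size = 200, seed = 2)
  w1 <- wcc_representation(sim$cohort, cfg, n_clusters = 3, seed = 9)
  w2 <- wcc_representation(sim$cohort, cfg, n_clusters = 3, seed = 9)
  expect_identical(w1$representation, w2$representation)

  coh <- sim$cohort
  ct <- coh$samples[[1]]
  set.seed(1)
  perm <- sample(ct$n)
  coh$samples[[1]] <- cell_table(ct$sample_id, ct$x[perm], ct$y[perm],
                                 ct$celltype[perm])
  w3 <- wcc_representation(coh, cfg, n_clusters = 3, seed = 9)
  expect_equal(w3$representation, w1$representation)

  expect_error(wcc_representation(sim$cohort, cfg, n_clusters = 1e4,
                                  seed = 1), "exceeds")
})
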