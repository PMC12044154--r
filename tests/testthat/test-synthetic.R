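test_that("the generator is deterministic and satisfies cell-table invariants", {
  spec <- cohort_spec(samples_per_condition = 2, extent = 300,
                      cells_per_sample = 200, n_types = 4, seed = 15)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  for (sid in names(s1$cohort$samples)) {
    expect_identical(s1$cohort$samples[[sid]]$x, s2$cohort$samples[[sid]]$x)
    expect_identical(as.character(s1$cohort$samples[[sid]]$celltype),
                     as.character(s2$cohort$samples[[sid]]$celltype))
  }
  expect_identical(s1$truth$presence, s2$truth$presence)
  # cohort-level invariants come from the cell_table constructor
  expect_true(all(vapply(s1$cohort$samples, inherits, TRUE, "cell_table")))
  expect_equal(s1$cohort$features, paste0("T", 1:4))
})

test_that("marker-mode cohorts carry nonnegative panels on a shared panel", {
  spec <- cohort_spec(samples_per_condition = 2, extent = 300,
                      cells_per_sample = 150, n_types = 4,
                      mode = "marker", n_markers = 6, seed = 3)
  sim <- simulate_cohort(spec)
  expect_equal(sim$cohort$mode, "marker")
  for (s in sim$cohort$samples) {
    expect_true(all(s$markers >= 0))
    expect_equal(colnames(s$markers), sim$cohort$features)
  }
})

test_that("niche enrichment increases monotonically with effect strength", {
  enrich <- vapply(c(0, 1, 3), function(str) {
    spec <- cohort_spec(samples_per_condition = 2, extent = 400,
                        cells_per_sample = 600, n_types = 4,
                        niches = list(niche_def(types = c("T1", "T2"),
                                                strength = str,
                                                radius = 130,
                                                interaction_radius = 40)),
                        prevalence = c(1, 1), seed = 9)
    sim <- simulate_cohort(spec)
    # fraction of T2 among region cells with at least one T1 neighbour,
    # relative to the T2 background frequency
    rates <- vapply(names(sim$cohort$samples), function(sid) {
      ct <- sim$cohort$samples[[sid]]
      reg <- sim$truth$cells[[sid]]$region != "background"
      tt <- as.character(ct$celltype)
      d <- winsig:::pairwise_dist(cbind(ct$x, ct$y)[reg, , drop = FALSE],
                                  cbind(ct$x, ct$y))
      hasA <- vapply(seq_len(sum(reg)), function(i) {
        any(d[i, ] <= 40 & tt == "T1" & d[i, ] > 0)
      }, TRUE)
      mean(tt[reg][hasA] == "T2")
    }, numeric(1))
    mean(rates) / 0.25
  }, numeric(1))
  expect_true(all(diff(enrich) > 0))
  # zero strength is indistinguishable from background
  expect_lt(abs(enrich[1] - 1), 0.35)
})

test_that("recovery scoring recognizes relabeled truth and random labels", {
  sim <- small_cohort(seed = 5)
  fit <- fixture("small_fit", function() {
    winsig(sim$cohort, winsig_config(window_size = 200, seed = 5))
  })
  # overwrite clusters with the ground-truth window labels, relabeled
  wt <- winsig:::window_truth_labels(fit, sim$truth)
  fit2 <- fit
  idx <- match(names(wt), fit2$windows$node)
  fit2$windows$cluster <- NA_integer_
  fit2$windows$cluster[idx] <- as.integer(factor(wt)) + 5L
  fit2$persistent <- sort(unique(na.omit(fit2$windows$cluster)))
  rec <- score_recovery(fit2, sim$truth)
  expect_equal(rec$mean_ari, 1)
  expect_equal(rec$recall, 1)
  expect_gte(rec$niche_jaccard$best_jaccard[1], 0.5)

  # random labels: ARI concentrates at zero
  set.seed(33)
  aris <- replicate(20, {
    fit3 <- fit2
    fit3$windows$cluster[idx] <- sample(fit2$windows$cluster[idx])
    score_recovery(fit3, sim$truth)$mean_ari
  })
  expect_lt(abs(mean(aris)), 0.05)
})
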