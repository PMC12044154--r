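make_windows <- function(sample, clusters) {
  n <- length(clusters)
  data.frame(sample = sample, index = seq_len(n) - 1L,
             row = 0L, col = seq_len(n) - 1L,
             x_lo = 0, x_hi = 1, y_lo = 0, y_hi = 1, n_cells = 10,
             valid = TRUE, node = paste0(sample, ":", seq_len(n) - 1L),
             cluster = clusters,
             persistent = FALSE)
}

test_that("sample representation is the persistent-cluster frequency", {
  w <- rbind(make_windows("s1", c(1L, 1L, 2L)),
             make_windows("s2", c(3L, 3L, NA)))
  fit <- fake_fit(w, persistent = c(1L, 2L))
  fit$windows$persistent <- !is.na(fit$windows$cluster) &
    fit$windows$cluster %in% fit$persistent
  expect_warning(R <- sample_representation(fit), "s2")
  expect_equal(unname(R["s1", ]), c(2 / 3, 1 / 3))
  # all windows of s2 fall in dropped clusters: zero vector
  expect_equal(unname(R["s2", ]), c(0, 0))
  expect_equal(unname(rowSums(R)), c(1, 0))
})

test_that("logistic CV separates separable representations", {
  set.seed(2)
  R <- rbind(matrix(c(0.8, 0.2), 6, 2, byrow = TRUE),
             matrix(c(0.1, 0.9), 6, 2, byrow = TRUE)) +
    matrix(runif(24, 0, 0.05), 12, 2)
  rownames(R) <- paste0("s", 1:12)
  colnames(R) <- c("cl1", "cl2")
  lab <- rep(c("a", "b"), each = 6)
  expect_warning(st <- stratify(R, lab, folds = 10, seed = 1),
                 "fold count reduced")
  expect_equal(st$auroc, 1)
  expect_equal(st$loss, 0)
})

test_that("constant representations score at chance", {
  R <- matrix(0.5, 12, 2, dimnames = list(paste0("s", 1:12), c("cl1", "cl2")))
  st <- suppressWarnings(stratify(R, rep(c("a", "b"), 6), seed = 1))
  expect_equal(st$auroc, 0.5)
})

test_that("permuted labels give chance-level AUROC on average", {
  set.seed(77)
  aur <- replicate(25, {
    R <- matrix(runif(24 * 3), 24, 3,
                dimnames = list(paste0("s", 1:24), paste0("cl", 1:3)))
    lab <- sample(rep(c("a", "b"), 12))
    suppressWarnings(stratify(R, lab, seed = 1))$auroc
  })
  expect_lt(abs(mean(aur) - 0.5), 0.1)
})

test_that("binary macro-AUROC equals the plain one-vs-rest AUROC", {
  set.seed(5)
  lab <- factor(rep(c("a", "b"), each = 10))
  sc <- runif(20)
  plain <- as.numeric(pROC::auc(pROC::roc(
    response = lab == "b", predictor = sc,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  expect_equal(winsig:::macro_auroc(lab, sc), plain)
})

test_that("signed model reliance identities hold", {
  expect_equal(smr_value(2, 0.2, 0.2), 1)
  expect_equal(smr_value(-0.5, 0.1, 0.3), -3)
  # a constant feature: permuting it cannot change the scores, so the
  # reliance ratio is exactly sign(beta)
  set.seed(12)
  n <- 30
  lab <- rep(c("a", "b"), each = n / 2)
  R <- cbind(cl1 = ifelse(lab == "a", 0.65, 0.35) + rnorm(n, 0, 0.2),
             cl2 = rep(0.5, n))
  rownames(R) <- paste0("s", 1:n)
  st <- suppressWarnings(stratify(R, lab, seed = 1))
  expect_gt(st$loss, 0)
  st$beta["cl2"] <- 0.7  # constant columns are dropped by glm; force a sign
  smr <- signed_model_reliance(st, features = "cl2", n_perm = 10, seed = 1)
  expect_equal(unname(smr), 1)
})

test_that("zero CV loss is floored with a warning", {
  set.seed(4)
  R <- cbind(cl1 = c(rep(0.9, 6), rep(0.1, 6)))
  rownames(R) <- paste0("s", 1:12)
  st <- suppressWarnings(stratify(R, rep(c("a", "b"), each = 6), seed = 1))
  expect_equal(st$loss, 0)
  expect_warning(signed_model_reliance(st, n_perm = 5, seed = 1),
                 "floored")
})

test_that("an uninformative feature has reliance near one", {
  set.seed(12)
  n <- 30
  lab <- rep(c("a", "b"), each = n / 2)
  # informative but overlapping feature (so the logistic fit converges)
  # plus a pure-noise feature
  R <- cbind(cl1 = ifelse(lab == "a", 0.65, 0.35) + rnorm(n, 0, 0.2),
             cl2 = runif(n))
  rownames(R) <- paste0("s", 1:n)
  st <- suppressWarnings(stratify(R, lab, seed = 1))
  smr <- signed_model_reliance(st, n_perm = 100, seed = 2)
  expect_lt(abs(abs(smr[["cl2"]]) - 1), 0.25)
  expect_gt(abs(smr[["cl1"]]), 1)
  # sign matches the logistic coefficient
  expect_equal(sign(smr), sign(coef(st))[names(smr)], ignore_attr = TRUE)
})

test_that("AUROC is invariant to monotone transforms of the scores", {
  set.seed(6)
  lab <- factor(rep(c("a", "b"), each = 8))
  sc <- runif(16)
  a1 <- winsig:::macro_auroc(lab, sc)
  expect_equal(winsig:::macro_auroc(lab, plogis(5 * sc - 1)), a1)
  expect_equal(winsig:::macro_auroc(lab, rank(sc) / 20), a1)
})
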