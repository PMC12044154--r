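#' Per-sample frequency representation over persistent clusters
#'
#' Each sample is represented by the fraction of its persistent windows in
#' every persistent cluster (denominator: the sample's persistent windows;
#' windows of dropped clusters are removed). Rows sum to 1, or to 0 for
#' samples without persistent windows (flagged with a warning).
#'
#' @param fit A [winsig()] fit.
#' @return Numeric matrix, samples x persistent clusters (columns
#'   `cl<label>`).
#' @export
sample_representation <- function(fit) {
  stopifnot(inherits(fit, "winsig"))
  samples <- names(fit$views)
  clusters <- fit$persistent
  R <- matrix(0, length(samples), length(clusters),
              dimnames = list(samples,
                              if (length(clusters)) paste0("cl", clusters)))
  w <- fit$windows[fit$windows$persistent, , drop = FALSE]
  for (sid in samples) {
    sub <- w[w$sample == sid, , drop = FALSE]
    if (!nrow(sub)) next
    tab <- table(factor(sub$cluster, levels = clusters))
    R[sid, ] <- as.numeric(tab) / nrow(sub)
  }
  empty <- rowSums(R) == 0
  if (any(empty)) {
    warning(sum(empty), " sample(s) without persistent windows have ",
            "all-zero representations: ",
            paste(samples[empty], collapse = ", "))
  }
  R
}

# Macro-averaged AUROC over the two classes from concatenated scores
# (score = predicted probability of the second factor level). For binary
# labels the two one-vs-rest terms coincide with the plain AUROC.
macro_auroc <- function(labels, scores) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2)
  auc1 <- function(resp, sc) {
    as.numeric(pROC::auc(pROC::roc(response = resp, predictor = sc,
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  }
  pos <- levels(labels)[2]
  mean(c(auc1(labels == pos, scores),
         auc1(labels != pos, 1 - scores)))
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratify samples from their cluster-frequency representation
#'
#' Fits an unregularized logistic model to the binary condition labels and
#' evaluates it by stratified 10-fold cross-validation, reporting the
#' macro-averaged AUROC computed on the concatenated out-of-fold scores.
#' Final coefficients come from a fit on all samples.
#'
#' @param x A [winsig()] fit (uses its representation and stored condition)
#'   or a numeric representation matrix (samples x features).
#' @param labels Binary labels per sample; defaults to the fit's condition.
#' @param folds Number of CV folds (default 10); reduced with a warning
#'   when a class has fewer samples than folds.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `winsig_strat`: out-of-fold `scores`,
#'   `auroc`, `loss` (`1 - auroc`), full-data coefficients `beta`, per-fold
#'   coefficient matrix and fold assignment (used by
#'   [signed_model_reliance()]).
#' @export
stratify <- function(x, labels = NULL, folds = 10L, seed = 1L) {
  if (inherits(x, "winsig")) {
    labels <- labels %||% x$condition
    x <- x$representation
  }
  stopifnot(is.matrix(x), !is.null(labels), nrow(x) == length(labels))
  labels <- droplevels(factor(labels))
  stopifnot("need exactly 2 classes" = nlevels(labels) == 2,
            "need >= 2 samples per class" = all(table(labels) >= 2))
  n <- nrow(x)
  if (folds > min(table(labels))) {
    folds <- max(2L, min(table(labels)))
    warning("fold count reduced to ", folds,
            " (fewer samples per class than folds)")
  }
  colnames(x) <- make.names(colnames(x) %||% paste0("f", seq_len(ncol(x))))
  df <- data.frame(.y = labels, x, check.names = FALSE)
  fold <- stratified_folds(labels, folds, seed)
  scores <- numeric(n)
  fold_coefs <- matrix(0, folds, ncol(x) + 1,
                       dimnames = list(NULL, c("(Intercept)", colnames(x))))
  for (f in seq_len(folds)) {
    train <- df[fold != f, , drop = FALSE]
    fitf <- suppressWarnings(
      stats::glm(.y ~ ., data = train, family = stats::binomial())
    )
    cf <- stats::coef(fitf)
    cf[!is.finite(cf)] <- 0
    fold_coefs[f, names(cf)] <- cf
    scores[fold == f] <- stats::plogis(
      fold_coefs[f, 1] +
        as.matrix(x[fold == f, , drop = FALSE]) %*% fold_coefs[f, -1]
    )
  }
  full <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial())
  )
  beta <- stats::coef(full)[-1]
  beta[!is.finite(beta)] <- 0
  names(beta) <- colnames(x)
  auroc <- macro_auroc(labels, scores)
  structure(list(scores = scores, auroc = auroc, loss = 1 - auroc,
                 beta = beta, intercept = unname(stats::coef(full)[1]),
                 fold = fold, fold_coefs = fold_coefs, folds = folds,
                 X = x, labels = labels, seed = seed),
            class = "winsig_strat")
}

#' @export
print.winsig_strat <- function(x, ...) {
  cat("<winsig_strat> logistic stratification,", length(x$labels),
      "samples,", x$folds, "-fold CV\n")
  cat("  macro-AUROC:", round(x$auroc, 3), "\n")
  cat("  features:", ncol(x$X), "\n")
  invisible(x)
}

#' @export
coef.winsig_strat <- function(object, ...) object$beta

#' @export
predict.winsig_strat <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  as.numeric(stats::plogis(object$intercept + X %*% object$beta))
}

#' Signed model-reliance ratio
#'
#' The closed form behind [signed_model_reliance()]:
#' `sgn(beta) * mean(loss_perm) / loss`. A feature whose permutation leaves
#' the loss unchanged has `|sMR| = 1`; values above 1 mark features the
#' model relies on, with the sign of the logistic coefficient giving the
#' class the feature votes for.
#'
#' @param beta Coefficient (only its sign is used).
#' @param loss Loss `1 - AUROC` on the unpermuted data (must be > 0).
#' @param loss_perm Loss(es) under permutation of the feature.
#' @return The signed reliance value.
#' @examples
#' smr_value(2, 0.2, 0.2)    #  1
#' smr_value(-0.5, 0.1, 0.3) # -3
#' @export
smr_value <- function(beta, loss, loss_perm) {
  stopifnot(loss > 0)
  sign(beta) * mean(loss_perm) / loss
}

#' Signed model reliance of representation features
#'
#' Permutation-based relevance of each cluster-frequency feature:
#' `sMR_i = sgn(beta_i) * L(f, D_perm(i)) / L(f, D)` with loss
#' `L = 1 - AUROC`, averaged over `n_perm` independent permutations of
#' feature i. The out-of-fold scores are recomputed from the stored fold
#' models on the permuted data, so the model itself is never refitted.
#' `|sMR| > 1` means the model relies on the feature; the sign gives the
#' class the feature votes for.
#'
#' @param strat A [stratify()] result.
#' @param features Character or integer subset of features (default all).
#' @param n_perm Number of permutations per feature (default 100).
#' @param seed Integer seed.
#' @return Named numeric vector of sMR values.
#' @export
signed_model_reliance <- function(strat, features = NULL, n_perm = 100L,
                                  seed = 1L) {
  stopifnot(inherits(strat, "winsig_strat"))
  X <- strat$X
  feats <- features %||% colnames(X)
  if (is.numeric(feats)) feats <- colnames(X)[feats]
  L <- strat$loss
  if (L <= 0) {
    L <- 1 / (2 * nrow(X))
    warning("zero CV loss; floored at 1/(2 n) = ", signif(L, 3),
            " for the reliance ratio")
  }
  oof_scores <- function(Xp) {
    sc <- numeric(nrow(Xp))
    for (f in seq_len(strat$folds)) {
      idx <- strat$fold == f
      sc[idx] <- stats::plogis(
        strat$fold_coefs[f, 1] +
          Xp[idx, , drop = FALSE] %*% strat$fold_coefs[f, -1]
      )
    }
    sc
  }
  out <- stats::setNames(numeric(length(feats)), feats)
  set.seed(seed)
  for (ft in feats) {
    lp <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      Xp <- X
      Xp[, ft] <- Xp[sample(nrow(X)), ft]
      lp[r] <- 1 - macro_auroc(strat$labels, oof_scores(Xp))
    }
    out[ft] <- smr_value(strat$beta[ft], L, lp)
  }
  out
}

#' Explain a persistent cluster
#'
#' Summarizes what a window cluster captures: per-target mean and sd of
#' variance explained (and gain) across member windows; mean weighted
#' standardized importances, filtered to targets with mean gain at or above
#' the signature threshold and importances at least `1` sd above the mean
#' (cell-type mode paraview; marker mode intraview) or `0.5` sd (marker
#' mode paraview); and the Pearson correlation between each retained
#' predictor's view value and the target's intraview value, pooled over the
#' member windows' cells, which approximates the sign of the relationship.
#'
#' @param fit A [winsig()] fit.
#' @param cluster Cluster label to explain.
#' @param min_importance Importance threshold(s) in sd units; default
#'   `c(intra = 1, para = 1)` in cell-type mode and
#'   `c(intra = 1, para = 0.5)` in marker mode.
#' @return An object of class `cluster_explanation` with `target_stats`,
#'   `importances` (all mean importances), and `filtered` (retained
#'   relationships with their sign correlations).
#' @export
explain_cluster <- function(fit, cluster, min_importance = NULL) {
  stopifnot(inherits(fit, "winsig"))
  w <- fit$windows[!is.na(fit$windows$cluster) &
                     fit$windows$cluster == cluster, , drop = FALSE]
  if (!nrow(w)) stop("cluster ", cluster, " has no member windows")
  few <- nrow(w) < 2
  min_importance <- min_importance %||%
    if (fit$mode == "marker") c(intra = 1, para = 0.5) else c(intra = 1, para = 1)

  key <- paste(fit$target_stats$sample, fit$target_stats$window)
  member_key <- paste(w$sample, w$index)
  ts <- fit$target_stats[key %in% member_key, , drop = FALSE]
  agg <- function(v, f) tapply(v, ts$target, f)
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  target_stats <- data.frame(
    target = names(agg(ts$r2_multi, mean)),
    mean_r2 = as.numeric(agg(ts$r2_multi, mean)),
    sd_r2 = as.numeric(agg(ts$r2_multi, sd0)),
    mean_gain = as.numeric(agg(ts$gain, mean)),
    sd_gain = as.numeric(agg(ts$gain, sd0)),
    stringsAsFactors = FALSE
  )
  M <- fit$M_raw[w$node, , drop = FALSE]
  imp <- fit$sig_feats
  imp$mean_M <- colMeans(M)
  imp$mean_gain <- target_stats$mean_gain[match(imp$target,
                                                target_stats$target)]
  thr <- min_importance[imp$view]
  sel <- imp$mean_M >= thr & imp$mean_gain >= fit$config$gain_threshold
  filtered <- imp[sel, , drop = FALSE]

  # sign of each retained relationship: correlation of predictor view value
  # with target intraview value, pooled over member-window cells
  if (nrow(filtered)) {
    filtered$correlation <- NA_real_
    pooled <- list()
    for (sid in unique(w$sample)) {
      ws <- fit$window_sets[[sid]]
      cells <- sort(unique(unlist(
        ws$members[w$index[w$sample == sid] + 1L])))
      pooled[[sid]] <- cells
    }
    for (r in seq_len(nrow(filtered))) {
      px <- numeric(0); ty <- numeric(0)
      for (sid in names(pooled)) {
        v <- fit$views[[sid]]
        cells <- pooled[[sid]]
        src <- if (filtered$view[r] == "para") v$paraview else v$intraview
        px <- c(px, src[cells, filtered$predictor[r]])
        ty <- c(ty, v$intraview[cells, filtered$target[r]])
      }
      if (stats::sd(px) > 0 && stats::sd(ty) > 0) {
        filtered$correlation[r] <- stats::cor(px, ty)
      }
    }
  }
  structure(list(cluster = cluster, n_windows = nrow(w),
                 n_samples = length(unique(w$sample)),
                 few_windows = few, target_stats = target_stats,
                 importances = imp, filtered = filtered),
            class = "cluster_explanation")
}

#' @export
print.cluster_explanation <- function(x, ...) {
  cat("<cluster_explanation> cluster", x$cluster, ":", x$n_windows,
      "windows in", x$n_samples, "samples\n")
  if (x$few_windows) cat("  (fewer than 2 windows; sds reported as 0)\n")
  informative <- x$target_stats[
    x$target_stats$mean_gain >= 0.01, , drop = FALSE]
  cat("  targets with gain >= 1%:", nrow(informative), "\n")
  if (nrow(x$filtered)) {
    cat("  retained relationships:\n")
    print(x$filtered[, c("view", "predictor", "target", "mean_M",
                         "correlation")], row.names = FALSE, digits = 3)
  } else {
    cat("  no relationships above the importance threshold\n")
  }
  invisible(x)
}
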