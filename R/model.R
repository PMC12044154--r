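#' View-contribution-weighted standardized importance
#'
#' Standardizes a vector of raw forest importances for one (target, view)
#' pair and weights it by the view's contribution:
#' `M_j = ((I_j - mean(I)) / sd(I)) * (1 - p)`. When `sd(I) = 0` the result
#' is the zero vector; `p` is clamped to `[0, 1]`.
#'
#' @param I Numeric vector of raw importances (one per predictor).
#' @param p The view-contribution p-value for this target.
#' @return Numeric vector of the same length (and names) as `I`.
#' @examples
#' weighted_importance(c(1, 2, 3), 0.5)  # -0.5, 0, 0.5
#' @export
weighted_importance <- function(I, p) {
  p <- min(max(p, 0), 1)
  s <- stats::sd(I)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(I))
  } else {
    out <- (I - mean(I)) / s * (1 - p)
  }
  names(out) <- names(I)
  out
}

# L2-regularized linear fusion of view predictions: intercept unpenalized,
# predictors standardized, penalty lambda on the standardized scale.
# Returns variance explained of the fitted meta-model on the window.
ridge_fusion <- function(y, P, lambda) {
  n <- length(y)
  yc <- y - mean(y)
  sst <- sum(yc^2)
  mu <- colMeans(P)
  sdv <- apply(P, 2, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  if (!any(keep)) {
    return(list(r2 = 0, alpha0 = mean(y),
                alpha = stats::setNames(rep(0, ncol(P)), colnames(P))))
  }
  Xs <- sweep(sweep(P[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  p <- ncol(Xs)
  beta <- solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, yc))
  fitted <- mean(y) + Xs %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sst
  alpha <- stats::setNames(rep(0, ncol(P)), colnames(P))
  alpha[keep] <- beta / sdv[keep]
  list(r2 = r2, alpha0 = mean(y) - sum(alpha * mu), alpha = alpha)
}

# Cross-validated variance explained of the fusion meta-model: ridge
# coefficients are refit without each fold and the held-out predictions
# concatenated, so window-level R2 is honest (can be negative for noise)
# rather than optimistic in-sample fit.
cv_fusion_r2 <- function(y, P, lambda, fold) {
  oof <- numeric(length(y))
  for (f in unique(fold)) {
    tr <- fold != f
    if (stats::var(y[tr]) == 0) {
      oof[!tr] <- mean(y[tr])
      next
    }
    fit <- ridge_fusion(y[tr], P[tr, , drop = FALSE], lambda)
    oof[!tr] <- fit$alpha0 + P[!tr, , drop = FALSE] %*% fit$alpha
  }
  1 - sum((y - oof)^2) / sum((y - mean(y))^2)
}

# Two-sided t-test p-value of each view's coefficient in an unregularized
# linear refit of the fusion on the view predictions; degenerate views get 1.
view_pvalues <- function(y, P) {
  out <- stats::setNames(rep(1, ncol(P)), colnames(P))
  df <- data.frame(y = y, P, check.names = FALSE)
  fit <- try(suppressWarnings(stats::lm(y ~ ., data = df)), silent = TRUE)
  if (inherits(fit, "try-error")) return(out)
  cf <- stats::coef(summary(fit))
  for (v in colnames(P)) {
    if (v %in% rownames(cf) && is.finite(cf[v, 4])) {
      out[v] <- min(max(cf[v, 4], 0), 1)
    }
  }
  out
}

#' Fit the multi-view relationship model of one window
#'
#' For every intraview feature (target) in a valid window, fits one random
#' forest per view on the window's cells and fuses the views' out-of-bag
#' predictions with an L2-regularized linear meta-model. In cell-type mode
#' only the paraview is modelled (predicting a cell's one-hot type from its
#' own type is trivial), so the gain in variance explained equals the total
#' variance explained. In marker mode the intraview forest uses all other
#' markers of the same cell as predictors and the paraview forest all
#' neighbourhood-aggregated markers; the gain is
#' `R2_multi - R2_intra`. Raw impurity importances (total reduction of
#' target variance) are standardized and weighted by the view contribution
#' `1 - p` ([weighted_importance()]).
#'
#' Targets with zero variance in the window are skipped and recorded with
#' zero variance explained and all-zero importances.
#'
#' @param views The sample's [build_views()] result.
#' @param members Integer indices of the window's member cells.
#' @param config A [winsig_config()].
#' @param seed Integer seed for this window's forests (derive one per
#'   window for cohort runs).
#' @return A `window_model`: per-target list with `r2_intra`, `r2_multi`,
#'   `gain`, per-view p-values `p`, raw importances `I`, and weighted
#'   standardized importances `M`.
#' @export
fit_window_model <- function(views, members, config, seed = config$seed) {
  stopifnot(inherits(views, "view_composition"))
  feats <- views$features
  intra <- views$intraview[members, , drop = FALSE]
  para <- views$paraview[members, , drop = FALSE]
  n <- length(members)
  views_used <- if (views$mode == "celltype") "para" else c("intra", "para")
  targets <- vector("list", length(feats))
  names(targets) <- feats
  # one fold assignment per window, shared by all targets
  set.seed(substream_seed(seed, "cvfold"))
  cv_fold <- sample(rep_len(seq_len(min(10L, n)), n))
  for (t in feats) {
    y <- intra[, t]
    if (stats::var(y) == 0) {
      targets[[t]] <- list(degenerate = TRUE, r2_intra = 0, r2_multi = 0,
                           gain = 0,
                           p = stats::setNames(rep(1, length(views_used)),
                                               views_used),
                           I = NULL, M = NULL)
      next
    }
    preds <- list()
    if (views$mode == "marker") preds$intra <- intra[, setdiff(feats, t), drop = FALSE]
    preds$para <- para
    oob <- matrix(0, n, length(preds), dimnames = list(NULL, names(preds)))
    imp <- list()
    for (v in names(preds)) {
      X <- preds[[v]]
      mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(X))))
      rf <- ranger::ranger(
        x = X, y = y,
        num.trees = config$n_trees, mtry = min(mtry, ncol(X)),
        importance = "impurity", replace = TRUE,
        seed = substream_seed(seed, "rf", t, v), num.threads = 1
      )
      pv <- rf$predictions
      pv[!is.finite(pv)] <- mean(y)
      oob[, v] <- pv
      imp[[v]] <- rf$variable.importance
    }
    p <- view_pvalues(y, oob)
    fus_multi <- ridge_fusion(y, oob, config$ridge_lambda)
    r2_multi <- cv_fusion_r2(y, oob, config$ridge_lambda, cv_fold)
    if (views$mode == "marker") {
      r2_intra <- cv_fusion_r2(y, oob[, "intra", drop = FALSE],
                               config$ridge_lambda, cv_fold)
    } else {
      r2_intra <- 0
    }
    M <- lapply(views_used, function(v) weighted_importance(imp[[v]], p[[v]]))
    names(M) <- views_used
    targets[[t]] <- list(degenerate = FALSE, r2_intra = r2_intra,
                         r2_multi = r2_multi, gain = r2_multi - r2_intra,
                         p = p, I = imp, M = M, alpha = fus_multi$alpha,
                         alpha0 = fus_multi$alpha0)
  }
  structure(list(targets = targets, features = feats, mode = views$mode,
                 views_used = views_used, n_cells = n, seed = seed),
            class = "window_model")
}

#' Extract the importance table of a fitted window model
#'
#' @param result A [fit_window_model()] result.
#' @return Long-format data.frame with columns view, predictor, target,
#'   raw importance `I`, weighted standardized importance `M`, the view
#'   p-value, and the target's variance-explained summaries.
#' @export
extract_importances <- function(result) {
  stopifnot(inherits(result, "window_model"))
  rows <- list()
  for (t in names(result$targets)) {
    res <- result$targets[[t]]
    if (isTRUE(res$degenerate)) next
    for (v in names(res$M)) {
      rows[[paste(t, v)]] <- data.frame(
        view = v, predictor = names(res$M[[v]]), target = t,
        I = unname(res$I[[v]]), M = unname(res$M[[v]]),
        p_view = unname(res$p[[v]]),
        r2_intra = res$r2_intra, r2_multi = res$r2_multi, gain = res$gain,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(view = character(), predictor = character(),
                      target = character(), I = numeric(), M = numeric(),
                      p_view = numeric(), r2_intra = numeric(),
                      r2_multi = numeric(), gain = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.window_model <- function(x, ...) {
  ok <- !vapply(x$targets, function(t) isTRUE(t$degenerate), TRUE)
  r2 <- vapply(x$targets[ok], `[[`, 0, "r2_multi")
  cat("<window_model>", x$n_cells, "cells, mode:", x$mode, "\n")
  cat("  targets modelled:", sum(ok), "of", length(x$targets),
      "; mean R2 =", round(mean(r2), 3), "\n")
  invisible(x)
}
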