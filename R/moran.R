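#' Moran's I with analytic randomization test
#'
#' Textbook double-sum Moran's I of a numeric vector over a binary (or
#' general) weight matrix, with mean, variance and one-sided upper-tail
#' p-value under the randomization assumption.
#'
#' @param x Numeric vector of observations (one per spatial unit).
#' @param W Square weight matrix (no self-weights); need not be symmetric
#'   or row-standardized.
#' @return List with `I`, `expected`, `sd`, `z`, `p` (one-sided, upper
#'   tail). When `x` is constant the statistic is undefined and all fields
#'   are `NA`; with fewer than 4 units the variance (hence z and p) is `NA`.
#' @examples
#' # 2x2 checkerboard with rook adjacency: I = -1
#' W <- matrix(0, 4, 4)
#' W[cbind(c(1, 1, 2, 3, 2, 4, 3, 4), c(2, 3, 1, 1, 4, 2, 4, 3))] <- 1
#' moran_stat(c(1, 0, 0, 1), W)$I
#' @export
moran_stat <- function(x, W) {
  n <- length(x)
  stopifnot(is.matrix(W), nrow(W) == n, ncol(W) == n)
  na <- list(I = NA_real_, expected = NA_real_, sd = NA_real_,
             z = NA_real_, p = NA_real_)
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 == 0) return(na)
  S0 <- sum(W)
  if (S0 == 0) return(na)
  I <- n / S0 * as.numeric(t(z) %*% W %*% z) / m2
  EI <- -1 / (n - 1)
  if (n < 4) {
    return(list(I = I, expected = EI, sd = NA_real_, z = NA_real_,
                p = NA_real_))
  }
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / m2^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  sdI <- sqrt(max(varI, 0))
  zval <- (I - EI) / sdI
  list(I = I, expected = EI, sd = sdI, z = zval,
       p = stats::pnorm(zval, lower.tail = FALSE))
}

# Queen (8-neighbour) adjacency between windows from their grid positions.
grid_adjacency <- function(row, col) {
  dr <- abs(outer(row, row, "-"))
  dc <- abs(outer(col, col, "-"))
  W <- (pmax(dr, dc) == 1) * 1
  diag(W) <- 0
  W
}

#' Spatial contiguity of a cluster within one sample
#'
#' Moran's I of the binary cluster-membership indicator over the sample's
#' valid windows, with binary 8-neighbour adjacency on the window grid
#' (overlapping windows make grid neighbours spatially contiguous).
#'
#' @param fit A [winsig()] fit.
#' @param sample Sample id.
#' @param cluster Cluster label.
#' @return List as from [moran_stat()], plus `n_windows` and `n_members`.
#'   Requires at least two windows assigned to the cluster and two valid
#'   windows overall; a constant indicator yields `NA` (not applicable).
#' @export
morans_i <- function(fit, sample, cluster) {
  stopifnot(inherits(fit, "winsig"))
  w <- fit$windows[fit$windows$sample == sample & fit$windows$valid, ,
                   drop = FALSE]
  ind <- as.numeric(!is.na(w$cluster) & w$cluster == cluster)
  if (nrow(w) < 2 || sum(ind) < 2) {
    stop("need >= 2 valid windows and >= 2 cluster members in sample '",
         sample, "'")
  }
  W <- grid_adjacency(w$row, w$col)
  out <- moran_stat(ind, W)
  out$n_windows <- nrow(w)
  out$n_members <- sum(ind)
  out
}

#' Cohort-wide spatial-contiguity test for persistent clusters
#'
#' Runs [morans_i()] for every (persistent cluster, sample) pair with at
#' least two matched windows, Bonferroni-corrects the one-sided p-values
#' per cluster across its samples, then Benjamini-Hochberg-corrects the
#' whole table across clusters.
#'
#' @param fit A [winsig()] fit.
#' @param clusters Cluster labels to test (default: the persistent set).
#' @return Data.frame with cluster, sample, member/window counts, I, z,
#'   `p`, `p_bonferroni` (within cluster), `p_adj` (BH across clusters).
#' @export
moran_contiguity <- function(fit, clusters = fit$persistent) {
  rows <- list()
  for (k in clusters) {
    w <- fit$windows[!is.na(fit$windows$cluster) &
                       fit$windows$cluster == k, , drop = FALSE]
    for (sid in unique(w$sample)) {
      if (sum(w$sample == sid) < 2) next
      nv <- sum(fit$windows$sample == sid & fit$windows$valid)
      if (nv < 2) next
      m <- morans_i(fit, sid, k)
      rows[[paste(k, sid)]] <- data.frame(
        cluster = k, sample = sid, n_members = m$n_members,
        n_windows = m$n_windows, I = m$I, z = m$z, p = m$p,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster = integer(), sample = character(),
                      n_members = integer(), n_windows = integer(),
                      I = numeric(), z = numeric(), p = numeric(),
                      p_bonferroni = numeric(), p_adj = numeric()))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_bonferroni <- NA_real_
  for (k in unique(tab$cluster)) {
    idx <- tab$cluster == k
    tab$p_bonferroni[idx] <- stats::p.adjust(tab$p[idx],
                                             method = "bonferroni")
  }
  tab$p_adj <- stats::p.adjust(tab$p_bonferroni, method = "BH")
  tab
}
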