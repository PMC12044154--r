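#' Multivariate hypergeometric null for cluster sample-spread
#'
#' How many distinct samples would a cluster of `W` windows span if its
#' windows were drawn uniformly without replacement from the pooled cohort
#' windows? Simulates draws with per-sample capacities equal to the
#' per-sample valid-window counts and summarizes the distribution of the
#' number of distinct samples hit.
#'
#' @param capacities Integer vector of per-sample window counts.
#' @param W Number of windows in the cluster (`0 <= W <= sum(capacities)`).
#' @param n_sim Number of simulated draws (default 10000).
#' @param seed Integer seed.
#' @return List with `median`, `q10`, `q90` (discrete, inverse-ECDF
#'   quantiles of the simulated counts) and the raw `draws`.
#' @export
hypergeometric_null <- function(capacities, W, n_sim = 10000L, seed = 1L) {
  stopifnot(all(capacities >= 0), W >= 0, W <= sum(capacities))
  if (W == 0) {
    return(list(median = 0, q10 = 0, q90 = 0, draws = rep(0L, n_sim)))
  }
  pool <- rep(seq_along(capacities), capacities)
  set.seed(seed)
  draws <- vapply(seq_len(n_sim), function(i) {
    length(unique(pool[sample.int(length(pool), W)]))
  }, integer(1))
  q <- stats::quantile(draws, c(0.1, 0.5, 0.9), type = 1, names = FALSE)
  list(median = q[2], q10 = q[1], q90 = q[3], draws = draws)
}

#' Observed versus expected sample-spread of persistent clusters
#'
#' For every persistent cluster, compares the observed number of distinct
#' samples containing it with the hypergeometric null at its window count;
#' clusters falling below the null's 10% quantile are spread over fewer
#' samples than chance predicts, the mark of a condition- or
#' sample-restricted local pattern.
#'
#' @param fit A [winsig()] fit.
#' @param n_sim Simulated draws per cluster.
#' @param seed Integer seed.
#' @return Data.frame with cluster, `n_windows`, `n_samples` (observed),
#'   `null_median`, `null_q10`, `null_q90`, and `below_q10`.
#' @export
frequency_null <- function(fit, n_sim = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "winsig"))
  valid <- fit$windows[fit$windows$valid, , drop = FALSE]
  capacities <- as.integer(table(factor(valid$sample,
                                        levels = names(fit$views))))
  rows <- lapply(fit$persistent, function(k) {
    w <- valid[!is.na(valid$cluster) & valid$cluster == k, , drop = FALSE]
    nullq <- hypergeometric_null(capacities, nrow(w), n_sim = n_sim,
                                 seed = substream_seed(seed, "hnull", k))
    data.frame(cluster = k, n_windows = nrow(w),
               n_samples = length(unique(w$sample)),
               null_median = nullq$median, null_q10 = nullq$q10,
               null_q90 = nullq$q90,
               below_q10 = length(unique(w$sample)) < nullq$q10)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
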