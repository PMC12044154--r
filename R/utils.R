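#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: every stochastic stage draws its own seed
# from the single user-facing seed plus a stage key, so stages are
# reproducible independently of evaluation order. Kept below 2^31 - 1.
substream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1987654321
  as.integer((as.numeric(seed) %% 65537 * 32003 + h) %% 2147483647)
}

# Cosine similarity between rows of a nonnegative matrix; rows with zero
# norm must be removed by the caller (cosine undefined there).
cosine_rows <- function(S) {
  nrm <- sqrt(rowSums(S^2))
  Sn <- S / nrm
  sim <- tcrossprod(Sn)
  sim[sim > 1] <- 1
  sim[sim < 0] <- 0
  sim
}

# Euclidean distances between rows of a (subset of) coordinate matrix,
# computed blockwise to bound memory on large samples.
pairwise_dist <- function(xy, xy2 = xy) {
  s1 <- rowSums(xy^2)
  s2 <- rowSums(xy2^2)
  d2 <- outer(s1, s2, "+") - 2 * tcrossprod(xy, xy2)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
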