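#' Define a planted niche for the synthetic generator
#'
#' A niche is a disc-shaped tissue region in which the involved cell types
#' follow a neighbour-conditional placement rule: `attraction` boosts the
#' probability of each involved type near the other, `avoidance` suppresses
#' it, and `motif` chains the boost (A attracts B, B attracts C). Effect
#' strength 0 makes the niche indistinguishable from background.
#'
#' @param id Niche identifier.
#' @param types Involved cell types (2 for attraction/avoidance, 3 for a
#'   motif).
#' @param rule `"attraction"`, `"avoidance"`, or `"motif"`.
#' @param strength Nonnegative effect strength (log-scale tilt).
#' @param radius Disc radius of the region, coordinate units.
#' @param interaction_radius Radius within which neighbours condition the
#'   type assignment.
#' @return A `niche_def` list.
#' @export
niche_def <- function(id = "niche1", types = c("T1", "T2"),
                      rule = c("attraction", "avoidance", "motif"),
                      strength = 3, radius = 150, interaction_radius = 40) {
  rule <- match.arg(rule)
  stopifnot(strength >= 0, radius > 0, interaction_radius > 0,
            length(types) >= 2)
  if (rule == "motif") stopifnot(length(types) == 3)
  structure(list(id = id, types = types, rule = rule, strength = strength,
                 radius = radius, interaction_radius = interaction_radius),
            class = "niche_def")
}

#' Specify a synthetic two-condition cohort
#'
#' The generator emulates multi-sample spatial omics cohorts: homogeneous
#' Poisson cell placement on a square tissue, background cell types drawn
#' iid, and planted disc-shaped niches realized by sequential
#' neighbour-conditional (Gibbs-like) type assignment. The two conditions
#' differ only through niche prevalence. In marker mode each cell's marker
#' vector is its type archetype plus linear intra-cell dependencies, an
#' RBF-coupled neighbour dependency, and Gaussian noise.
#'
#' @param samples_per_condition Samples per condition (default 10).
#' @param extent Tissue side length in coordinate units (default 800).
#' @param cells_per_sample Expected cells per sample, Poisson (default
#'   1500).
#' @param n_types Number of cell types (default 8, named `T1`...).
#' @param mode `"celltype"` or `"marker"`.
#' @param n_markers Markers in marker mode (default 12).
#' @param niches List of [niche_def()]s (default: one strong attraction
#'   niche between `T1` and `T2`).
#' @param prevalence Length-2 probability that a sample of each condition
#'   contains each niche (default `c(0.9, 0.1)`).
#' @param background_freq Background type frequencies (default uniform).
#' @param noise_sd Marker noise sd (default 0.1).
#' @param gibbs_sweeps Neighbour-conditional assignment passes (default 3).
#' @param seed Integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(samples_per_condition = 10L, extent = 800,
                        cells_per_sample = 1500, n_types = 8L,
                        mode = c("celltype", "marker"), n_markers = 12L,
                        niches = list(niche_def()),
                        prevalence = c(0.9, 0.1),
                        background_freq = NULL, noise_sd = 0.1,
                        gibbs_sweeps = 3L, seed = 1L) {
  mode <- match.arg(mode)
  types <- paste0("T", seq_len(n_types))
  background_freq <- background_freq %||%
    stats::setNames(rep(1 / n_types, n_types), types)
  stopifnot(all(prevalence >= 0 & prevalence <= 1),
            length(prevalence) == 2,
            abs(sum(background_freq) - 1) < 1e-8,
            all(names(background_freq) == types))
  for (nd in niches) stopifnot(all(nd$types %in% types))
  structure(list(samples_per_condition = as.integer(samples_per_condition),
                 extent = extent, cells_per_sample = cells_per_sample,
                 n_types = as.integer(n_types), types = types, mode = mode,
                 n_markers = as.integer(n_markers), niches = niches,
                 prevalence = prevalence, background_freq = background_freq,
                 noise_sd = noise_sd, gibbs_sweeps = as.integer(gibbs_sweeps),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Sequential neighbour-conditional type assignment inside a niche region.
# Works on the current type vector; only region cells are re-typed.
gibbs_niche_pass <- function(types, region_idx, xy, nd, bg_freq, sweeps) {
  if (nd$strength == 0 || !length(region_idx)) return(types)
  lev <- names(bg_freq)
  d <- pairwise_dist(xy[region_idx, , drop = FALSE], xy)
  nbrs <- lapply(seq_along(region_idx), function(i) {
    hit <- which(d[i, ] <= nd$interaction_radius)
    setdiff(hit, region_idx[i])
  })
  tilt <- function(cnt) exp(nd$strength * min(cnt, 3))
  inv <- nd$types
  for (sw in seq_len(sweeps)) {
    for (i in sample(seq_along(region_idx))) {
      # asymmetric neighbour-conditional rule: only the downstream type(s)
      # of the chain are tilted, so the upstream type keeps its background
      # frequency and neighbourhoods remain informative about identity
      w <- bg_freq
      cnt <- table(factor(types[nbrs[[i]]], levels = lev))
      if (nd$rule == "attraction") {
        w[inv[2]] <- w[inv[2]] * tilt(cnt[[inv[1]]])
      } else if (nd$rule == "avoidance") {
        w[inv[2]] <- w[inv[2]] / tilt(cnt[[inv[1]]])
      } else { # motif: A attracts B, B attracts C
        w[inv[2]] <- w[inv[2]] * tilt(cnt[[inv[1]]])
        w[inv[3]] <- w[inv[3]] * tilt(cnt[[inv[2]]])
      }
      types[region_idx[i]] <- sample(lev, 1, prob = w / sum(w))
    }
  }
  types
}

# Marker panel archetypes: each type expresses two signature markers on a
# low common baseline; drawn once per cohort.
make_archetypes <- function(n_types, n_markers, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n_types * n_markers, 0.1, 0.5), n_types,
              n_markers,
              dimnames = list(paste0("T", seq_len(n_types)),
                              paste0("M", sprintf("%02d", seq_len(n_markers)))))
  for (t in seq_len(n_types)) {
    hi <- ((t - 1) * 2) %% n_markers + c(1, 2)
    hi <- (hi - 1) %% n_markers + 1
    A[t, hi] <- A[t, hi] + 2
  }
  A
}

#' Generate a synthetic cohort with planted niches and full ground truth
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (a `winsig_cohort`), `truth` (per-sample
#'   per-cell region labels, niche definitions, per-sample niche presence),
#'   and `spec`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(samples_per_condition = 2,
#'                                    extent = 300, cells_per_sample = 150,
#'                                    n_types = 4, seed = 7))
#' length(sim$cohort$samples)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  exp_feats <- if (spec$mode == "celltype") spec$n_types else spec$n_markers
  if (spec$cells_per_sample < exp_feats) {
    warning("infeasible density: expected cells per sample (",
            spec$cells_per_sample, ") below feature count (", exp_feats, ")")
  }
  arche <- if (spec$mode == "marker") {
    make_archetypes(spec$n_types, spec$n_markers,
                    substream_seed(spec$seed, "archetypes"))
  }
  samples <- list(); condition <- character(0)
  truth_cells <- list(); presence <- list()
  for (cond in 1:2) {
    for (rep in seq_len(spec$samples_per_condition)) {
      sid <- sprintf("c%d_s%02d", cond, rep)
      set.seed(substream_seed(spec$seed, "sample", cond, rep))
      n <- max(stats::rpois(1, spec$cells_per_sample), 2)
      xy <- cbind(x = stats::runif(n, 0, spec$extent),
                  y = stats::runif(n, 0, spec$extent))
      region <- rep("background", n)
      types <- sample(spec$types, n, replace = TRUE,
                      prob = spec$background_freq)
      pres <- stats::setNames(integer(length(spec$niches)),
                              vapply(spec$niches, `[[`, "", "id"))
      # three fixed candidate sites per sample (jittered lattice), each
      # occupied independently with the condition's prevalence: samples
      # carry a graded niche load, not a single presence bit
      site_base <- matrix(c(0.25, 0.25, 0.75, 0.25, 0.5, 0.75),
                          ncol = 2, byrow = TRUE) * spec$extent
      for (nd in spec$niches) {
        occupied <- stats::rbinom(nrow(site_base), 1,
                                  spec$prevalence[cond]) == 1
        jit <- matrix(stats::runif(length(site_base), -40, 40),
                      ncol = 2)
        pres[nd$id] <- sum(occupied)
        for (sidx in which(occupied)) {
          ctr <- pmin(pmax(site_base[sidx, ] + jit[sidx, ], nd$radius),
                      spec$extent - nd$radius)
          inside <- which(sqrt((xy[, 1] - ctr[1])^2 +
                                 (xy[, 2] - ctr[2])^2) <= nd$radius &
                            region == "background")
          region[inside] <- nd$id
          types <- gibbs_niche_pass(types, inside, xy, nd,
                                    spec$background_freq, spec$gibbs_sweeps)
        }
      }
      if (spec$mode == "celltype") {
        ct <- cell_table(sid, xy[, 1], xy[, 2],
                         celltype = factor(types, levels = spec$types))
      } else {
        M <- arche[types, , drop = FALSE]
        if (ncol(M) >= 5) {
          # linear intra-cell dependencies between fixed marker pairs
          M[, 3] <- M[, 3] + 0.4 * M[, 1]
          M[, 4] <- M[, 4] + 0.3 * M[, 2]
          # RBF-coupled neighbour dependency: marker 5 picks up marker 1 of
          # nearby cells (length scale 50 units)
          w <- exp(-pairwise_dist(xy)^2 / 50^2)
          diag(w) <- 0
          M[, 5] <- M[, 5] + 0.3 * (w %*% M[, 1]) / pmax(rowSums(w), 1)
        }
        M <- M + matrix(stats::rnorm(length(M), 0, spec$noise_sd),
                        nrow(M), ncol(M))
        M[M < 0] <- 0
        rownames(M) <- NULL
        ct <- cell_table(sid, xy[, 1], xy[, 2], markers = M)
      }
      samples[[sid]] <- ct
      condition <- c(condition, paste0("cond", cond))
      truth_cells[[sid]] <- data.frame(cell_id = ct$cell_id,
                                       region = region,
                                       celltype = types,
                                       stringsAsFactors = FALSE)
      presence[[sid]] <- pres
    }
  }
  cohort <- as_cohort(samples, condition, mode = spec$mode)
  truth <- list(cells = truth_cells, niches = spec$niches,
                presence = do.call(rbind, presence),
                condition = stats::setNames(condition, names(samples)))
  list(cohort = cohort, truth = truth, spec = spec)
}

# Majority ground-truth region label of each valid window.
window_truth_labels <- function(fit, truth) {
  out <- list()
  for (sid in names(fit$window_sets)) {
    ws <- fit$window_sets[[sid]]
    reg <- truth$cells[[sid]]$region
    for (i in which(ws$windows$valid)) {
      tab <- sort(table(reg[ws$members[[i]]]), decreasing = TRUE)
      out[[paste0(sid, ":", ws$windows$index[i])]] <- names(tab)[1]
    }
  }
  unlist(out)
}

#' Score niche recovery of a fitted representation against ground truth
#'
#' Compares window cluster labels with the majority ground-truth region
#' label per window: per-sample adjusted Rand index (unassigned windows
#' count as their own label) and its cohort mean, plus niche-detection
#' recall — the fraction of planted niches matched by at least one
#' persistent cluster with window-set Jaccard >= `jaccard_min`.
#'
#' @param fit A [winsig()] fit on the simulated cohort.
#' @param truth The `truth` component of [simulate_cohort()].
#' @param jaccard_min Match threshold (default 0.5).
#' @param min_fraction Fraction of a window's cells that must lie in a
#'   niche region for the window to count as part of that niche's footprint
#'   (default 0.25). With 50% window overlap each niche cell is seen by
#'   about four windows, so the relationship planted in a niche is carried
#'   by substantially more windows than those where niche cells are the
#'   outright majority; the ARI comparison still uses the majority label.
#' @return List with `per_sample_ari`, `mean_ari`, `niche_jaccard` (best
#'   Jaccard and matching cluster per niche), and `recall`.
#' @export
score_recovery <- function(fit, truth, jaccard_min = 0.5,
                           min_fraction = 0.25) {
  stopifnot(inherits(fit, "winsig"))
  wt <- window_truth_labels(fit, truth)
  w <- fit$windows[fit$windows$valid, , drop = FALSE]
  lab <- ifelse(is.na(w$cluster), 0L, w$cluster)
  names(lab) <- w$node
  ari <- vapply(names(fit$views), function(sid) {
    idx <- w$sample == sid
    if (sum(idx) < 2) return(NA_real_)
    mclust::adjustedRandIndex(lab[w$node[idx]], wt[w$node[idx]])
  }, numeric(1))
  niche_ids <- vapply(truth$niches, `[[`, "", "id")
  # niche footprint: windows with at least min_fraction of cells in region
  frac <- list()
  for (sid in names(fit$window_sets)) {
    ws <- fit$window_sets[[sid]]
    reg <- truth$cells[[sid]]$region
    for (i in which(ws$windows$valid)) {
      node <- paste0(sid, ":", ws$windows$index[i])
      frac[[node]] <- table(factor(reg[ws$members[[i]]],
                                   levels = c("background", niche_ids))) /
        length(ws$members[[i]])
    }
  }
  fr <- do.call(rbind, frac)
  jac <- do.call(rbind, lapply(niche_ids, function(nid) {
    truth_nodes <- rownames(fr)[fr[, nid] >= min_fraction]
    best <- 0; best_cl <- NA_integer_
    for (k in fit$persistent) {
      cl_nodes <- w$node[!is.na(w$cluster) & w$cluster == k]
      u <- length(union(truth_nodes, cl_nodes))
      j <- if (u == 0) 0 else length(intersect(truth_nodes, cl_nodes)) / u
      if (j > best) { best <- j; best_cl <- k }
    }
    data.frame(niche = nid, n_windows = length(truth_nodes),
               best_jaccard = best, cluster = best_cl)
  }))
  list(per_sample_ari = ari, mean_ari = mean(ari, na.rm = TRUE),
       niche_jaccard = jac,
       recall = mean(jac$best_jaccard >= jaccard_min))
}
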