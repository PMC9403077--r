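#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test with Welch-Satterthwaite fractional degrees of
#' freedom, computed directly from group means, SDs and sizes, plus a
#' pooled-SD Cohen's d. The d is returned signed as `(m1 - m2) / s_pooled`;
#' report its magnitude where an unsigned effect size is wanted.
#'
#' @param m1,s1,n1 group-1 mean, SD, size.
#' @param m2,s2,n2 group-2 mean, SD, size.
#' @return a `welch_result`: `t`, `df`, `p` (two-tailed), `d`,
#'   `m1`, `s1`, `n1`, `m2`, `s2`, `n2`.
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0 && m1 == m2)
    stop("degenerate input: zero variance in both groups with equal means")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 d = (m1 - m2) / sp,
                 m1 = m1, s1 = s1, n1 = n1, m2 = m2, s2 = s2, n2 = n2),
            class = "welch_result")
}

#' Welch two-sample t-test from raw samples
#'
#' Identical to [welch_t_from_summary()] applied to the samples' own
#' means and SDs (the two agree exactly on the sufficient statistics).
#'
#' @param x1,x2 numeric sample vectors (each of length >= 2).
#' @return a `welch_result`.
#' @export
welch_t_from_samples <- function(x1, x2) {
  if (length(x1) < 2L || length(x2) < 2L)
    stop("each group needs at least 2 observations")
  welch_t_from_summary(mean(x1), stats::sd(x1), length(x1),
                       mean(x2), stats::sd(x2), length(x2))
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.2f, p = %.4g, d = %.3f\n",
              x$t, x$df, x$p, x$d))
  invisible(x)
}

# Vectorized Welch t over the columns of X for a 2-level grouping.
welch_t_cols <- function(X, grp) {
  st <- group_col_stats(X, grp)
  v1 <- st[[1L]]$v / st[[1L]]$n
  v2 <- st[[2L]]$v / st[[2L]]$n
  se <- sqrt(v1 + v2)
  t <- (st[[1L]]$m - st[[2L]]$m) / se
  df <- (v1 + v2)^2 /
    (v1^2 / (st[[1L]]$n - 1) + v2^2 / (st[[2L]]$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Connected components of a cell subset under a precomputed adjacency
# list; returns a list of integer vectors (components of size >= 1).
components_of <- function(cells, adj_list) {
  if (length(cells) == 0L) return(list())
  in_set <- logical(length(adj_list))
  in_set[cells] <- TRUE
  seen <- logical(length(adj_list))
  comps <- list()
  for (c0 in cells) {
    if (seen[c0]) next
    comp <- integer(0)
    queue <- c0
    seen[c0] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- adj_list[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

adjacency_to_list <- function(A) {
  lapply(seq_len(nrow(A)), function(i) which(A[i, ] != 0))
}

cluster_masses <- function(t, p, adj_list, cell_alpha) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(!is.na(p) & p < cell_alpha & sign(t) == sgn)
    for (comp in components_of(supra, adj_list)) {
      if (length(comp) >= 2L)   # a cluster needs two or more adjacent cells
        out[[length(out) + 1L]] <- list(cells = comp, sign = sgn,
                                        mass = sum(t[comp]))
    }
  }
  out
}

#' Cluster-based permutation test on a multidimensional grid
#'
#' Family-wise-error-controlling two-group comparison: a Welch t-test is
#' run at every grid cell; cells with `p < cell_alpha` are grouped into
#' connected components (of two or more adjacent cells) separately for
#' positive and negative t; each cluster's mass is the sum of its t
#' values; the null distribution of the maximum absolute cluster mass is
#' built from random relabelings of the subjects; cluster p-values use
#' the plus-one convention and are tested at the two-tailed
#' `cluster_alpha`.
#'
#' @param X subjects x cells data matrix.
#' @param groups two-level grouping vector (length `nrow(X)`).
#' @param adjacency symmetric cell adjacency matrix (or adjacency list).
#' @param n_perm number of random permutations.
#' @param cell_alpha cell-level threshold (default 0.05).
#' @param cluster_alpha cluster-level threshold (default 0.025,
#'   two-tailed).
#' @param seed integer seed for the permutations.
#' @return a `cluster_test_result`: `clusters` (data.frame: id, sign,
#'   n_cells, mass, p, significant), `members` (list of cell indices),
#'   `t` (cell-level t), `null_max` (permutation distribution),
#'   `n_perm`.
#' @export
cluster_permutation_test <- function(X, groups, adjacency,
                                     n_perm = 1000, cell_alpha = 0.05,
                                     cluster_alpha = 0.025, seed = 1) {
  stopifnot(is.matrix(X), nrow(X) == length(groups))
  if (length(unique(groups)) != 2L) stop("need exactly two groups")
  if (min(table(groups)) < 2L) stop("need >= 2 subjects per group")
  adj_list <- if (is.list(adjacency)) adjacency
              else adjacency_to_list(adjacency)
  stopifnot(length(adj_list) == ncol(X))
  if (all(lengths(adj_list) == 0L))
    warning("adjacency has no edges: no cluster can have 2 cells")
  obs <- welch_t_cols(X, groups)
  clusters <- cluster_masses(obs$t, obs$p, adj_list, cell_alpha)
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    gp <- sample(groups)
    pt <- welch_t_cols(X, gp)
    cm <- cluster_masses(pt$t, pt$p, adj_list, cell_alpha)
    null_max[b] <- if (length(cm))
      max(abs(vapply(cm, `[[`, numeric(1), "mass"))) else 0
  }
  if (length(clusters)) {
    mass <- vapply(clusters, `[[`, numeric(1), "mass")
    pvals <- vapply(mass, function(m)
      (1 + sum(null_max >= abs(m))) / (n_perm + 1), numeric(1))
    tab <- data.frame(
      id = seq_along(clusters),
      sign = vapply(clusters, `[[`, numeric(1), "sign"),
      n_cells = vapply(clusters, function(cl) length(cl$cells), integer(1)),
      mass = mass, p = pvals, significant = pvals < cluster_alpha)
    members <- lapply(clusters, `[[`, "cells")
  } else {
    tab <- data.frame(id = integer(0), sign = numeric(0),
                      n_cells = integer(0), mass = numeric(0),
                      p = numeric(0), significant = logical(0))
    members <- list()
  }
  structure(list(clusters = tab, members = members, t = obs$t,
                 null_max = null_max, n_perm = n_perm),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %d cluster(s), %d permutation(s)\n",
              nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Permutation Pearson correlation
#'
#' Sample Pearson correlation with a two-tailed permutation p-value:
#' `y` is randomly permuted `n_perm` times and
#' `p = (1 + #{|r_perm| >= |r|}) / (n_perm + 1)`.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer seed.
#' @return a `perm_corr_result`: `r`, `p`, `n`, `n_perm`.
#' @export
perm_pearson <- function(x, y, n_perm = 10000, seed = 1) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  r <- sum(xs * ys) / (n - 1)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    rp <- sum(xs * ys[sample.int(n)]) / (n - 1)
    if (abs(rp) >= abs(r) - 1e-15) exceed <- exceed + 1L
  }
  structure(list(r = r, p = (1 + exceed) / (n_perm + 1), n = n,
                 n_perm = n_perm), class = "perm_corr_result")
}

#' @export
print.perm_corr_result <- function(x, ...) {
  cat(sprintf("r = %.3f, permutation p = %.4g (n = %d, %d permutations)\n",
              x$r, x$p, x$n, x$n_perm))
  invisible(x)
}

#' Welch tests of global network indices per band, metric and polarity
#'
#' One Welch test per (band, metric, polarity) combination of the
#' global-level index table, flagged at the multiple-comparison-
#' corrected alpha (0.01 for four bands).
#'
#' @param indices tidy data.frame with columns `subject`, `group`,
#'   `band`, `polarity`, `metric`, `value` (global level only).
#' @param alpha significance level for the flag.
#' @return data.frame: band, polarity, metric, n1, n2, mean1, sd1,
#'   mean2, sd2, t, df, p, d, significant.
#' @export
global_index_tests <- function(indices, alpha = 0.01) {
  need <- c("subject", "group", "band", "polarity", "metric", "value")
  stopifnot(all(need %in% names(indices)))
  groups <- sort(unique(indices$group))
  stopifnot(length(groups) == 2L)
  combos <- unique(indices[, c("band", "polarity", "metric")])
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    sel <- indices$band == combos$band[k] &
      indices$polarity == combos$polarity[k] &
      indices$metric == combos$metric[k]
    sub <- indices[sel & is.finite(indices$value), , drop = FALSE]
    if (nrow(sub) < nrow(indices[sel, ]))
      message(sprintf("global_index_tests: %d missing value(s) dropped for %s/%s/%s",
                      sum(sel) - nrow(sub), combos$band[k],
                      combos$polarity[k], combos$metric[k]))
    x1 <- sub$value[sub$group == groups[1L]]
    x2 <- sub$value[sub$group == groups[2L]]
    w <- welch_t_from_samples(x1, x2)
    data.frame(band = combos$band[k], polarity = combos$polarity[k],
               metric = combos$metric[k], n1 = w$n1, n2 = w$n2,
               mean1 = w$m1, sd1 = w$s1, mean2 = w$m2, sd2 = w$s2,
               t = w$t, df = w$df, p = w$p, d = w$d,
               significant = w$p < alpha)
  })
  do.call(rbind, rows)
}

#' Cell adjacency for a regions-by-bands grid
#'
#' Cells are (region, band) pairs, regions varying fastest. Within a
#' band, cells follow the atlas spatial adjacency; the same region in
#' consecutive bands is also connected (band chain).
#'
#' @param atlas_adjacency region adjacency matrix (e.g. `atlas$adjacency`).
#' @param n_bands number of frequency bands.
#' @param band_chain connect the same region across consecutive bands.
#' @return adjacency matrix over `n_regions * n_bands` cells.
#' @export
band_chain_adjacency <- function(atlas_adjacency, n_bands,
                                 band_chain = TRUE) {
  n <- nrow(atlas_adjacency)
  N <- n * n_bands
  A <- matrix(0, N, N)
  for (b in seq_len(n_bands)) {
    idx <- (b - 1L) * n + seq_len(n)
    A[idx, idx] <- atlas_adjacency
    if (band_chain && b < n_bands) {
      idx2 <- b * n + seq_len(n)
      A[cbind(idx, idx2)] <- 1
      A[cbind(idx2, idx)] <- 1
    }
  }
  A
}

#' Cell adjacency for a series-by-time-by-frequency grid
#'
#' Cells are (series, time, frequency) with series varying fastest, then
#' time, then frequency. Neighbors are the adjacent time point and the
#' adjacent frequency bin within a series; optionally all series are
#' mutually adjacent at the same (time, frequency) cell (used for the
#' four lobe-averaged power series).
#'
#' @param n_series,n_time,n_freq grid dimensions.
#' @param series_complete treat the series as fully mutually adjacent.
#' @return adjacency list over `n_series * n_time * n_freq` cells.
#' @export
tf_grid_adjacency <- function(n_series, n_time, n_freq,
                              series_complete = TRUE) {
  idx <- function(s, t, f) s + (t - 1L) * n_series +
    (f - 1L) * n_series * n_time
  N <- n_series * n_time * n_freq
  out <- vector("list", N)
  for (f in seq_len(n_freq)) for (t in seq_len(n_time)) {
    for (s in seq_len(n_series)) {
      me <- idx(s, t, f)
      nb <- integer(0)
      if (t > 1L) nb <- c(nb, idx(s, t - 1L, f))
      if (t < n_time) nb <- c(nb, idx(s, t + 1L, f))
      if (f > 1L) nb <- c(nb, idx(s, t, f - 1L))
      if (f < n_freq) nb <- c(nb, idx(s, t, f + 1L))
      if (series_complete && n_series > 1L)
        nb <- c(nb, idx(setdiff(seq_len(n_series), s), t, f))
      out[[me]] <- nb
    }
  }
  out
}
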