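test_that("Welch test from summaries reproduces published-style rows", {
  # 53 vs 39 cohort, strength row: printed -2.56 / 77.35 / 0.55
  w <- welch_t_from_summary(15.98, 7.57, 53, 20.30, 8.33, 39)
  expect_lt(abs(w$t - (-2.56)), 0.02)
  expect_lt(abs(w$df - 77.35), 0.15)
  expect_lt(abs(abs(w$d) - 0.55), 0.01)
  # path-length row: printed 3.15 / 89.30 / 0.64
  w2 <- welch_t_from_summary(2.75, 0.81, 53, 2.27, 0.65, 39)
  expect_lt(abs(w2$t - 3.15), 0.02)
  expect_lt(abs(w2$df - 89.30), 0.15)
  expect_lt(abs(abs(w2$d) - 0.64), 0.01)

  ident <- welch_t_from_summary(5, 1, 20, 5, 1, 20)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_equal(ident$d, 0)
  expect_error(welch_t_from_summary(5, 0, 20, 5, 0, 20), "degenerate")
})

test_that("sample and summary forms agree exactly; matches stats::t.test", {
  set.seed(11)
  x1 <- rnorm(20, 1, 2)
  x2 <- rnorm(15, 0, 1)
  ws <- welch_t_from_samples(x1, x2)
  wm <- welch_t_from_summary(mean(x1), sd(x1), 20, mean(x2), sd(x2), 15)
  expect_equal(ws$t, wm$t, tolerance = 1e-12)
  expect_equal(ws$df, wm$df, tolerance = 1e-12)
  # independent reference: base R's Welch test
  tt <- t.test(x1, x2)
  expect_equal(ws$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ws$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(ws$p, tt$p.value, tolerance = 1e-10)

  expect_equal(welch_t_from_samples(x1, x1)$t, 0)
  expect_error(welch_t_from_samples(x1, 1), "at least 2")
})

test_that("Welch test holds its nominal type-I rate under the null", {
  set.seed(22)
  n_rep <- 2000
  X <- rbind(matrix(rnorm(53 * n_rep), 53), matrix(rnorm(39 * n_rep), 39))
  r <- icohnet:::welch_t_cols(X, rep(1:2, c(53, 39)))
  rate <- mean(r$p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("clusters need two or more adjacent supra-threshold cells", {
  set.seed(3)
  n <- 40
  grp <- rep(1:2, each = 20)
  X <- matrix(rnorm(n * 5, 0, 0.5), n, 5)
  X[grp == 1, 3] <- X[grp == 1, 3] + 5   # one isolated strong cell
  chain <- matrix(0, 5, 5)
  chain[cbind(1:4, 2:5)] <- 1
  chain <- chain + t(chain)
  chain[3, ] <- 0
  chain[, 3] <- 0                        # cell 3 has no neighbors
  r <- cluster_permutation_test(X, grp, chain, n_perm = 99, seed = 1)
  expect_equal(nrow(r$clusters), 0)

  # the same effect on two adjacent cells forms one significant cluster
  X2 <- matrix(rnorm(n * 5, 0, 0.5), n, 5)
  X2[grp == 1, 2:3] <- X2[grp == 1, 2:3] + 5
  chain2 <- matrix(0, 5, 5)
  chain2[cbind(1:4, 2:5)] <- 1
  chain2 <- chain2 + t(chain2)
  r2 <- cluster_permutation_test(X2, grp, chain2, n_perm = 199, seed = 1)
  expect_gte(nrow(r2$clusters), 1)
  top <- which.max(abs(r2$clusters$mass))
  expect_true(all(c(2, 3) %in% r2$members[[top]]))
  expect_lt(r2$clusters$p[top], 0.025)
  # permutation p-values can never be zero
  expect_gte(min(r2$clusters$p), 1 / (r2$n_perm + 1))
})

test_that("complete adjacency collapses supra cells into one omnibus cluster", {
  set.seed(4)
  grp <- rep(1:2, each = 15)
  X <- matrix(rnorm(30 * 6, 0, 0.4), 30, 6)
  X[grp == 1, c(1, 4)] <- X[grp == 1, c(1, 4)] + 4  # non-neighboring cells
  full <- matrix(1, 6, 6) - diag(6)
  r <- cluster_permutation_test(X, grp, full, n_perm = 99, seed = 2)
  pos <- r$clusters[r$clusters$sign > 0, ]
  expect_equal(nrow(pos), 1)
  expect_true(all(c(1, 4) %in% r$members[[pos$id]]))

  empty <- matrix(0, 6, 6)
  expect_warning(cluster_permutation_test(X, grp, empty, n_perm = 9,
                                          seed = 1),
                 "no edges")
})

test_that("permutation correlation handles exact and null cases", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  r1 <- perm_pearson(x, 2 * x + 1, n_perm = 999, seed = 1)
  expect_equal(r1$r, 1)
  expect_lte(r1$p, 2 / 1000)
  expect_equal(perm_pearson(x, -x, n_perm = 99, seed = 1)$r, -1)
  expect_error(perm_pearson(x, rep(1, 8)), "zero variance")

  # null calibration: rejection rate at alpha = 0.05
  set.seed(5)
  ps <- replicate(500, {
    a <- rnorm(53)
    b <- rnorm(53)
    perm_pearson(a, b, n_perm = 500, seed = sample.int(1e6, 1))$p
  })
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("global index tests flag only real group differences", {
  set.seed(6)
  mk_tab <- function(delta_theta_strength = 0) {
    grid <- expand.grid(band = c("theta", "alpha", "low_beta", "high_beta"),
                        polarity = c("positive", "negative"),
                        metric = c("strength", "clustering", "path_length"),
                        stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
      v <- rnorm(40)
      if (grid$band[k] == "theta" && grid$metric[k] == "strength" &&
          grid$polarity[k] == "positive")
        v[1:20] <- v[1:20] + delta_theta_strength
      data.frame(subject = sprintf("S%02d", 1:40),
                 group = rep(1:2, each = 20), band = grid$band[k],
                 polarity = grid$polarity[k], metric = grid$metric[k],
                 level = "global", value = v)
    }))
  }
  strong <- global_index_tests(mk_tab(3), alpha = 0.01)  # d = 3 effect
  hit <- strong[strong$band == "theta" & strong$metric == "strength" &
                  strong$polarity == "positive", ]
  expect_true(hit$significant)

  # null calibration: flag rate over repeated null tables stays near the
  # nominal 1% per test
  set.seed(7)
  flags <- replicate(60, sum(global_index_tests(mk_tab(0),
                                                alpha = 0.01)$significant))
  n_tests <- 60 * 24
  expect_gt(binom.test(sum(flags), n_tests, 0.01)$p.value, 0.001)
})

test_that("grid adjacency builders wire neighborhoods as specified", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 1
  A <- band_chain_adjacency(a, 2)
  expect_equal(dim(A), c(6, 6))
  expect_equal(A[1, 2], 1)           # spatial within band
  expect_equal(A[1, 4], 1)           # same region, next band
  expect_equal(A[1, 5], 0)           # no diagonal coupling
  expect_true(all(A == t(A)))

  adj <- tf_grid_adjacency(2, 3, 2, series_complete = TRUE)
  expect_length(adj, 12)
  # cell (s=1, t=1, f=1): neighbors are t+1, f+1 and the other series
  expect_setequal(adj[[1]], c(3, 7, 2))
})
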