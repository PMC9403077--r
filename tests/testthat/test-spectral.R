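test_that("frequency grid has 27 bins and the four analysis bands", {
  g <- frequency_grid()
  expect_length(g$frequencies, 27)
  expect_equal(g$frequencies[band_bins(g, "theta")], 4:8)
  expect_equal(g$frequencies[band_bins(g, "alpha")], 8:12)
  expect_equal(g$frequencies[band_bins(g, "low_beta")], 12:22)
  expect_equal(g$frequencies[band_bins(g, "high_beta")], 22:30)
  expect_error(band_bins(g, "delta"), "excluded")
  expect_error(band_bins(g, "gamma"), "unknown")
})

test_that("a stationary tone gives a flat ridge scaling with amplitude^2", {
  fs <- 1000
  t <- seq(-1, 1, by = 1 / fs)
  x <- 2 * sin(2 * pi * 10 * t)
  tf <- tf_transform(x, fs, t0 = -1, step = 20L)
  expect_equal(dim(tf$power), c(61, 27))
  ridge <- tf$power[, which(tf$frequencies == 10)]
  interior <- !is.na(ridge)
  expect_gt(sum(interior), 30)
  expect_lt(sd(ridge[interior]) / mean(ridge[interior]), 0.01)
  # frequency resolution: a well-separated lower bin (600 ms window at
  # 5 Hz resolves a 5 Hz offset) carries far less power than the ridge
  expect_gt(mean(ridge, na.rm = TRUE),
            10 * mean(tf$power[, tf$frequencies == 5], na.rm = TRUE))

  # doubling the amplitude quadruples power, to numerical precision
  tf2 <- tf_transform(2 * x, fs, t0 = -1, step = 20L)
  expect_lt(max(abs(tf2$power / tf$power - 4), na.rm = TRUE), 1e-9)

  # zero signal: all zeros
  tf0 <- tf_transform(numeric(length(t)), fs, t0 = -1, step = 100L)
  expect_true(all(tf0$power[!is.na(tf0$power)] == 0))
})

test_that("unit-energy taper makes white-noise power flat in time and frequency", {
  fs <- 1000
  set.seed(5)
  n_tr <- 150
  X <- matrix(rnorm(n_tr * 2001), n_tr, 2001)
  tf <- tf_transform(X, fs, t0 = -1, step = 50L)
  # mean over trials at 10 Hz: no time trend (slope t-test)
  pw <- colMeans(tf$power[, , tf$frequencies == 10])
  keep <- !is.na(pw)
  fit <- summary(lm(pw[keep] ~ tf$times[keep]))
  expect_gt(fit$coefficients[2, 4], 0.01)
  # mean power ~ noise variance at every frequency (unit-energy taper)
  mp <- apply(tf$power, 3, mean, na.rm = TRUE)
  expect_true(all(abs(mp - 1) < 0.2))
})

test_that("baseline normalization maps power to relative change", {
  times <- seq(-0.2, 1, by = 0.05)
  nf <- 27
  P <- matrix(1, length(times), nf)
  tf <- structure(list(power = P, times = times,
                       frequencies = 4:30, normalized = FALSE),
                  class = "tf_power")
  z <- baseline_normalize(tf)
  expect_true(all(z$power == 0))

  P2 <- P
  P2[times > 0, ] <- 2       # task power doubles the baseline
  tf2 <- structure(list(power = P2, times = times, frequencies = 4:30,
                        normalized = FALSE), class = "tf_power")
  z2 <- baseline_normalize(tf2)
  expect_true(all(z2$power[times > 0, ] == 1))

  P3 <- P
  P3[times > 0, ] <- 0.5
  tf3 <- structure(list(power = P3, times = times, frequencies = 4:30,
                        normalized = FALSE), class = "tf_power")
  expect_true(all(baseline_normalize(tf3)$power[times > 0, ] == -0.5))

  tf0 <- structure(list(power = P * 0, times = times, frequencies = 4:30,
                        normalized = FALSE), class = "tf_power")
  expect_error(baseline_normalize(tf0), "degenerate")
})

test_that("total power averages trials pointwise and keeps induced bursts", {
  mk <- function(vals) structure(
    list(power = matrix(vals, 2, 2), times = c(0, 1), frequencies = c(5, 6),
         normalized = TRUE), class = "tf_power")
  expect_equal(total_power(list(mk(1), mk(1)))$power, mk(1)$power)
  expect_true(all(total_power(list(mk(1), mk(-1)))$power == 0))
  expect_error(total_power(list()), "no trials")

  # induced (random-phase) 6 Hz bursts survive trial averaging of
  # per-trial normalized power
  fs <- 1000
  t <- seq(-1, 1, by = 1 / fs)
  set.seed(12)
  n_tr <- 40
  trials <- lapply(seq_len(n_tr), function(e) {
    phi <- runif(1, 0, 2 * pi)
    env <- exp(-(t - 0.3)^2 / (2 * 0.15^2))
    x <- rnorm(length(t)) + 1.5 * env * cos(2 * pi * 6 * t + phi)
    baseline_normalize(tf_transform(x, fs, t0 = -1, step = 50L))
  })
  tot <- total_power(trials)
  g <- frequency_grid()
  burst <- tot$times > 0.15 & tot$times < 0.45
  vals <- sapply(trials, function(tr)
    mean(tr$power[burst, band_bins(g, "theta")]))
  expect_gt(mean(vals), 3 * sd(vals) / sqrt(n_tr))
})

test_that("lobe aggregation averages band bins over each lobe's regions", {
  a <- load_atlas()
  nt <- 5
  pw <- array(0, dim = c(68, nt, 27))
  base <- matrix(seq_len(nt * 27), nt, 27)
  for (r in 1:68) pw[r, , ] <- base   # identical regions
  tf <- structure(list(power = pw, times = seq_len(nt),
                       frequencies = 4:30, normalized = TRUE),
                  class = "tf_power")
  g <- frequency_grid()
  agg <- aggregate_power(tf, a, "theta", g)
  expect_equal(nrow(agg), 4)
  for (l in rownames(agg))
    expect_equal(unname(agg[l, ]),
                 unname(rowMeans(base[, band_bins(g, "theta")])))
  expect_error(aggregate_power(tf, a, "delta", g), "excluded")
})

test_that("the subject-level power sweep matches the per-trial path exactly", {
  ep <- make_epochs(n_epochs = 3, n_sig = 2, n_samp = 2001, seed = 31)
  sweep_tp <- subject_total_power(ep, step = 100L)
  trials <- lapply(1:3, function(e) {
    tf <- tf_transform(matrix(ep$data[e, , ], 2), 1000, t0 = -1,
                       step = 100L)
    baseline_normalize(tf)
  })
  ref <- total_power(trials)
  expect_equal(sweep_tp$power, ref$power, tolerance = 1e-12)
})
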