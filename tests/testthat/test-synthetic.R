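test_that("event sequence has the exact target count and fixed spacing", {
  ev <- generate_event_sequence(paradigm_spec(), seed = 3)
  expect_equal(sum(ev$type == "target"), 60)
  expect_equal(sum(ev$type == "standard"), 340)
  expect_equal(diff(ev$onset_ms), rep(1500, 399))

  ev2 <- generate_event_sequence(paradigm_spec(), seed = 3)
  expect_identical(ev, ev2)

  tiny <- generate_event_sequence(
    paradigm_spec(n_stimuli = 2, target_fraction = 0.5), seed = 1)
  expect_equal(sum(tiny$type == "target"), 1)
  expect_equal(sum(tiny$type == "standard"), 1)
})

test_that("cohort simulation is a pure function of spec and seed", {
  spec <- tiny_cohort(seed = 5)
  a <- icohnet:::simulate_subject(spec, 1, 8, 99)
  b <- icohnet:::simulate_subject(spec, 1, 8, 99)
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data), c(8, 68, 2001))

  c1 <- simulate_cohort(cohort_spec(n_group1 = 1, n_group2 = 1, seed = 5),
                        tiny_paradigm(5))
  c2 <- simulate_cohort(cohort_spec(n_group1 = 1, n_group2 = 1, seed = 5),
                        tiny_paradigm(5))
  expect_identical(c1$subjects[[1]]$data, c2$subjects[[1]]$data)
  expect_equal(dim(c1$subjects[[1]]$data)[1], 5)  # target epochs only
})

test_that("coupling-pair validation and group asymmetry hold", {
  expect_error(cohort_spec(n_rois = 4,
    coupling_pairs = data.frame(i = 1, j = 9, freq = 6, lag = pi / 2,
                                s1 = 0.3, s2 = 0.5)),
    "outside")
  cp <- default_coupling_pairs()
  expect_true(all(cp$s1 <= cp$s2))         # group-1 deficit or equality
  expect_true(any(cp$s1 < cp$s2))          # the deficit edges exist
  expect_true(max(cp$s1) == max(cp$s2))    # common edges pin max weight
  expect_true(all(cp$lag > 0 & cp$lag < pi))
})

test_that("uncoupled regions carry no task-vs-baseline iCoh difference", {
  spec <- cohort_spec(n_group1 = 1, n_group2 = 1, n_rois = 8,
                      coupling_pairs = data.frame(i = integer(0),
                                                  j = integer(0),
                                                  freq = numeric(0),
                                                  lag = numeric(0),
                                                  s1 = numeric(0),
                                                  s2 = numeric(0)),
                      seed = 21)
  ep <- icohnet:::simulate_subject(spec, 1, 40, 77)
  d <- icoh(cross_spectra(ep, c(0, 1)), "theta")$values -
    icoh(cross_spectra(ep, c(-1, 0)), "theta")$values
  dv <- d[upper.tri(d)]
  expect_lt(abs(mean(dv)), 3 * sd(dv) / sqrt(length(dv)))
})

test_that("theta-only coupling puts more band energy in theta than high-beta", {
  spec <- cohort_spec(n_group1 = 1, n_group2 = 1, n_rois = 4,
                      coupling_pairs = data.frame(i = 1, j = 2, freq = 6,
                                                  lag = pi / 2, s1 = 0.8,
                                                  s2 = 0.8),
                      seed = 8)
  ep <- icohnet:::simulate_subject(spec, 1, 20, 44)
  grid <- frequency_grid()
  tp <- subject_total_power(ep, grid, step = 50L)
  task <- tp$times > 0.1 & tp$times < 0.5
  theta <- mean(tp$power[1, task, band_bins(grid, "theta")], na.rm = TRUE)
  hbeta <- mean(tp$power[1, task, band_bins(grid, "high_beta")],
                na.rm = TRUE)
  expect_gt(theta / hbeta, 1)
})

test_that("sensor projection mixes instantaneously and injects artifacts", {
  spec <- cohort_spec(n_group1 = 1, n_group2 = 1, n_rois = 3,
                      coupling_pairs = data.frame(i = integer(0),
                                                  j = integer(0),
                                                  freq = numeric(0),
                                                  lag = numeric(0),
                                                  s1 = numeric(0),
                                                  s2 = numeric(0)),
                      noise_sd = 10, seed = 31)
  ep <- icohnet:::simulate_subject(spec, 1, 12, 5)
  M <- matrix(rnorm(12), 4, 3)

  clean <- simulate_sensor_projection(ep, M, artifact_rate = 0, seed = 2)
  expect_equal(nrow(reject_epochs(clean, 1e6)$report), 12)
  expect_true(all(reject_epochs(clean, 1e6)$report$kept))

  dirty <- simulate_sensor_projection(ep, M, artifact_rate = 1, seed = 2)
  expect_true(all(!reject_epochs(dirty, 100)$report$kept |
                    reject_epochs(dirty, 100)$report$max_abs <= 100))
  expect_equal(dim(reject_epochs(dirty, 100)$epochs$data)[1], 0)

  expect_warning(
    simulate_sensor_projection(ep, matrix(c(1, 1, 2, 2, 3, 3), 2, 3),
                               seed = 1),
    "rank deficient")
})

test_that("zero-lag mixing of independent sources yields null-level iCoh", {
  # sensors are instantaneous mixtures z1 = x + y, z2 = x - y: the
  # imaginary part of coherency must stay at the trial-matched null level
  set.seed(60)
  n_tr <- 40
  mk <- function(mix) {
    dat <- array(0, dim = c(n_tr, 2, 1501))
    for (e in seq_len(n_tr)) {
      x <- rnorm(1501)
      y <- rnorm(1501)
      if (mix) {
        dat[e, 1, ] <- x + y
        dat[e, 2, ] <- x - y
      } else {
        dat[e, 1, ] <- x
        dat[e, 2, ] <- y
      }
    }
    epoch_array(dat, fs = 1000, t0 = 0)
  }
  v_mix <- icoh(cross_spectra(mk(TRUE), c(0, 1.5)), "theta")$values[1, 2]
  null_v <- replicate(15,
    icoh(cross_spectra(mk(FALSE), c(0, 1.5)), "theta")$values[1, 2])
  expect_lt(abs(v_mix - mean(null_v)), 3 * sd(null_v))
})

test_that("symptom scores follow the configured linear model", {
  idx <- seq(0.1, 0.6, length.out = 20)
  spec1 <- symptom_spec(score_names = "S", intercept = 50, slope = -10,
                        noise_sd = 0, range = list(c(0, 100)))
  s <- generate_symptom_scores(idx, spec1, seed = 1)$S
  expect_equal(cor(s, idx), -1)

  # clipping respects the instrument floor
  spec2 <- symptom_spec(score_names = "BDI", intercept = 1, slope = -50,
                        noise_sd = 0, range = list(c(0, 63)))
  s2 <- generate_symptom_scores(idx, spec2, seed = 1)$BDI
  expect_true(all(s2 >= 0))

  # zero slope: permutation p-values are uniform (KS test at 200 reps)
  spec0 <- symptom_spec(score_names = "S", intercept = 50, slope = 0,
                        noise_sd = 5, range = list(c(-1e6, 1e6)))
  set.seed(33)
  ps <- replicate(200, {
    ix <- rnorm(20)
    sc <- generate_symptom_scores(ix, spec0,
                                  seed = sample.int(1e6, 1))$S
    perm_pearson(ix, sc, n_perm = 199, seed = sample.int(1e6, 1))$p
  })
  # jitter breaks the ties of the discrete permutation p grid
  expect_gt(suppressWarnings(
    stats::ks.test(ps + runif(200, 0, 1 / 200), "punif")$p.value), 0.01)
})
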