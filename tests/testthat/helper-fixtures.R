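# Shared fixtures: all generated in code, sized for fast tests.

# Small epoch array of sinusoids plus noise.
make_epochs <- function(n_epochs = 5, n_sig = 3, n_samp = 2001,
                        fs = 1000, t0 = -1, noise = 0.1, seed = 1) {
  set.seed(seed)
  t <- t0 + (seq_len(n_samp) - 1) / fs
  dat <- array(rnorm(n_epochs * n_sig * n_samp, 0, noise),
               dim = c(n_epochs, n_sig, n_samp))
  for (e in seq_len(n_epochs))
    for (s in seq_len(n_sig))
      dat[e, s, ] <- dat[e, s, ] + sin(2 * pi * (4 + s) * t)
  epoch_array(dat, fs = fs, t0 = t0)
}

# Epoch array of a quadrature pair: y lags x by a quarter cycle at f.
make_quadrature_epochs <- function(n_trials = 30, f = 6, fs = 1000,
                                   n_samp = 2001, t0 = -1, noise = 0,
                                   seed = 1) {
  set.seed(seed)
  t <- t0 + (seq_len(n_samp) - 1) / fs
  dat <- array(0, dim = c(n_trials, 2, n_samp))
  for (e in seq_len(n_trials)) {
    phi <- runif(1, 0, 2 * pi)
    dat[e, 1, ] <- cos(2 * pi * f * t + phi) + rnorm(n_samp, 0, noise)
    dat[e, 2, ] <- cos(2 * pi * f * t + phi - pi / 2) +
      rnorm(n_samp, 0, noise)
  }
  epoch_array(dat, fs = fs, t0 = t0)
}

# Random nonnegative symmetric weight matrix with zero diagonal.
random_weight_matrix <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  w <- runif(sum(up))
  w[runif(sum(up)) > density] <- 0
  W[up] <- w
  W + t(W)
}

# Brute-force oracles -------------------------------------------------

# Onnela clustering by explicit enumeration over all (j, k) pairs.
clustering_bruteforce <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(rep(0, n))
  Wh <- W / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (l in seq_len(n)) {
      if (j == i || l == i || j == l) next
      acc <- acc + (Wh[i, j] * Wh[j, l] * Wh[l, i])^(1 / 3)
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# All-pairs shortest paths on 1/W lengths by Floyd-Warshall.
distances_floyd <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# A tiny cohort spec for pipeline-level tests (68 regions to match the
# packaged atlas, few subjects/epochs).
tiny_cohort <- function(n1 = 2, n2 = 2, seed = 11)
  cohort_spec(n_group1 = n1, n_group2 = n2, seed = seed)

tiny_paradigm <- function(n_targets = 10)
  paradigm_spec(n_stimuli = round(n_targets / 0.15), target_fraction = 0.15)
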