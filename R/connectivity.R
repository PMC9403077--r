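#' Trial- and time-averaged cross-spectra of an epoch array
#'
#' For every frequency bin, tapered Fourier coefficients (single Hanning
#' taper, 3 cycles per frequency) are computed at window centers stepped
#' every `step` seconds; only centers whose full taper lies inside the
#' analysis window contribute. The cross-spectrum `S[x, y](f)` is the
#' average over trials and valid centers of `X_x * Conj(X_y)`.
#'
#' @param epochs an `epoch_array`.
#' @param window analysis window (s), e.g. `c(-1, 0)` baseline or
#'   `c(0, 1)` task.
#' @param grid a [frequency_grid()].
#' @param step spacing of window centers (s).
#' @return a `cross_spectra` object: `S` (complex regions x regions x
#'   frequency array, Hermitian slices), `frequencies`, `n_trials`,
#'   `n_centers` per frequency, `window`.
#' @export
cross_spectra <- function(epochs, window, grid = frequency_grid(),
                          step = 0.05) {
  stopifnot(inherits(epochs, "epoch_array"), length(window) == 2L,
            window[1] < window[2])
  d <- dim(epochs$data)
  if (d[1L] < 2L) stop("coherence needs at least 2 trials")
  t_axis <- epoch_times(epochs)
  if (window[1] < t_axis[1L] - 1e-9 || window[2] > t_axis[d[3L]] + 1e-9)
    stop("analysis window extends beyond the epoch")
  M <- matrix(epochs$data, d[1L] * d[2L], d[3L])
  nf <- length(grid$frequencies)
  S <- array(0 + 0i, dim = c(d[2L], d[2L], nf))
  n_centers <- integer(nf)
  for (fi in seq_len(nf)) {
    f <- grid$frequencies[fi]
    half <- (tf_kernel(f, epochs$fs)$L - 1L) / 2 / epochs$fs
    ct <- seq(window[1] + half, window[2] - half + 1e-12, by = step)
    if (length(ct) == 0L || ct[1L] > window[2] - half + 1e-12)
      stop(sprintf("window too short for 3 cycles at %g Hz", f))
    centers <- as.integer(round((ct - epochs$t0) * epochs$fs)) + 1L
    co <- tf_coef_matrix(M, epochs$fs, f, centers)[[1L]]
    acc <- matrix(0 + 0i, d[2L], d[2L])
    for (ci in seq_along(centers)) {
      V <- matrix(co[, ci], d[1L], d[2L])    # trials x regions
      acc <- acc + t(V) %*% Conj(V)
    }
    S[, , fi] <- acc / (d[1L] * length(centers))
    n_centers[fi] <- length(centers)
  }
  dimnames(S) <- list(epochs$labels, epochs$labels, NULL)
  structure(list(S = S, frequencies = grid$frequencies,
                 n_trials = d[1L], n_centers = n_centers, window = window),
            class = "cross_spectra")
}

#' Imaginary-coherency connectivity matrix for one band
#'
#' Per frequency bin the coherency is
#' `C[x, y](f) = S[x, y](f) / sqrt(S[x, x](f) S[y, y](f))`; the edge
#' weight is the mean over the band's bins of `|Im C|`, which is bounded
#' by 1, vanishes for strictly zero-lag (volume-conduction-like)
#' coupling, and is maximal for quarter-cycle-lagged signals. The
#' magnitude is taken per bin so the network weights are nonnegative.
#'
#' @param cs a [cross_spectra()] result.
#' @param band band name.
#' @param grid a [frequency_grid()] (must match the cross-spectra).
#' @return a `connectivity_matrix`: `values` (symmetric, zero diagonal,
#'   in [0, 1]), `band`, `window`, `n_trials`.
#' @export
icoh <- function(cs, band, grid = frequency_grid()) {
  stopifnot(inherits(cs, "cross_spectra"))
  bins <- band_bins(grid, band)
  n <- dim(cs$S)[1L]
  acc <- matrix(0, n, n)
  for (fi in bins) {
    Sxx <- Re(diag(cs$S[, , fi]))
    if (any(Sxx <= 0))
      stop(sprintf("zero auto-spectrum at %g Hz", cs$frequencies[fi]))
    denom <- sqrt(outer(Sxx, Sxx))
    acc <- acc + abs(Im(cs$S[, , fi] / denom))
  }
  W <- acc / length(bins)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(cs$S)[1:2]
  structure(list(values = W, band = band, window = cs$window,
                 n_trials = cs$n_trials),
            class = "connectivity_matrix")
}

#' Task-specific enhanced and diminished connectomes
#'
#' Subtracts the baseline-window connectivity from the task-window
#' connectivity and splits the difference by sign into two nonnegative
#' weighted networks: the positive (enhanced) connectome holds edges
#' whose task connectivity exceeds baseline, the negative (diminished)
#' connectome the reverse. An edge is in exactly one of the two.
#'
#' @param task,baseline `connectivity_matrix` objects for the same band
#'   and region order.
#' @return a `task_connectome`: `positive`, `negative` (both symmetric,
#'   nonnegative, zero diagonal, elementwise-disjoint supports), `band`.
#' @export
task_normalize <- function(task, baseline) {
  stopifnot(inherits(task, "connectivity_matrix"),
            inherits(baseline, "connectivity_matrix"))
  if (!identical(dim(task$values), dim(baseline$values)))
    stop("matrix shape mismatch between task and baseline")
  if (!identical(task$band, baseline$band))
    stop("band mismatch between task and baseline")
  delta <- task$values - baseline$values
  structure(list(positive = pmax(delta, 0), negative = pmax(-delta, 0),
                 band = task$band),
            class = "task_connectome")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix> %dx%d, band %s, window [%g, %g] s, %d trials\n",
    nrow(x$values), ncol(x$values), x$band, x$window[1], x$window[2],
    x$n_trials))
  invisible(x)
}

#' @export
print.task_connectome <- function(x, ...) {
  cat(sprintf(
    "<task_connectome> band %s: %d enhanced / %d diminished edges\n",
    x$band, sum(x$positive[upper.tri(x$positive)] > 0),
    sum(x$negative[upper.tri(x$negative)] > 0)))
  invisible(x)
}
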