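#' Analysis frequency grid and band definitions
#'
#' 27 frequency bins from 4 to 30 Hz in 1 Hz steps, grouped into four
#' bands: theta (4-8 Hz), alpha (8-12 Hz), low-beta (12-22 Hz) and
#' high-beta (22-30 Hz). Band edges shared by two bands belong to both
#' (inclusive membership). Delta is excluded: a 1 s task window is too
#' short to cover delta oscillatory cycles reliably.
#'
#' @param fmin,fmax grid limits (Hz).
#' @param fstep bin spacing (Hz).
#' @return a `frequency_grid` with `frequencies` and `bands`.
#' @export
frequency_grid <- function(fmin = 4, fmax = 30, fstep = 1) {
  structure(list(
    frequencies = seq(fmin, fmax, by = fstep),
    bands = list(theta = c(4, 8), alpha = c(8, 12),
                 low_beta = c(12, 22), high_beta = c(22, 30))),
    class = "frequency_grid")
}

#' Frequency-bin indices of a band
#'
#' @param grid a [frequency_grid()].
#' @param band band name; `"delta"` raises an error (excluded band).
#' @return integer indices into `grid$frequencies` (inclusive band edges).
#' @export
band_bins <- function(grid, band) {
  if (identical(band, "delta"))
    stop("delta band is excluded from the analysis")
  if (!band %in% names(grid$bands))
    stop("unknown band: ", band)
  e <- grid$bands[[band]]
  which(grid$frequencies >= e[1] & grid$frequencies <= e[2])
}

# Complex Hanning-taper kernel for one frequency: 3 cycles long, unit
# energy (so white-noise power is flat across frequency).
tf_kernel <- function(f, fs) {
  L <- 2L * floor(3 * fs / f / 2) + 1L       # odd, ~3 cycles
  tau <- (seq_len(L) - (L + 1L) / 2) / fs
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1L) / (L - 1L)))
  w <- w / sqrt(sum(w^2))
  list(L = L, half = (L - 1L) %/% 2L,
       re = w * cos(2 * pi * f * tau), im = -w * sin(2 * pi * f * tau))
}

# Tapered Fourier coefficients of the rows of M (signals x samples) at
# the given frequencies and center sample indices. One BLAS call per
# frequency: kernels for all centers are stacked into a sparse-in-effect
# dense matrix. Returns a list (one per frequency) of complex matrices
# signals x length(centers); centers whose window crosses the data edge
# yield NA columns.
tf_coef_matrix <- function(M, fs, freqs, centers) {
  n_samp <- ncol(M)
  lapply(freqs, function(f) {
    k <- tf_kernel(f, fs)
    ok <- centers - k$half >= 1L & centers + k$half <= n_samp
    out <- matrix(NA_complex_, nrow(M), length(centers))
    if (any(ok)) {
      cc <- centers[ok]
      K <- matrix(0, n_samp, 2L * length(cc))
      for (ci in seq_along(cc)) {
        rows <- (cc[ci] - k$half):(cc[ci] + k$half)
        K[rows, 2L * ci - 1L] <- k$re
        K[rows, 2L * ci] <- k$im
      }
      P <- M %*% K
      out[, ok] <- P[, seq(1L, ncol(K), 2L), drop = FALSE] +
        1i * P[, seq(2L, ncol(K), 2L), drop = FALSE]
    }
    out
  })
}

#' Single-taper time-frequency power of epoch signals
#'
#' For each frequency f the signal is windowed with a Hanning taper three
#' cycles long (3/f s) centered at each output time point; power is the
#' squared magnitude of the tapered Fourier coefficient. Time points
#' whose window crosses the epoch edge are missing (NA), not zero-padded.
#'
#' @param x numeric vector (one signal) or matrix signals x samples.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (s, relative to stimulus onset).
#' @param grid a [frequency_grid()].
#' @param tmin,tmax output time-axis limits (s); defaults cover the
#'   -200 to 1,000 ms analysis axis.
#' @param step output time step in samples (1 = every sample, giving
#'   1,201 points at 1 kHz).
#' @return a `tf_power` object: `power` (time x frequency matrix for a
#'   vector input, signals x time x frequency array otherwise), `times`,
#'   `frequencies`, `normalized = FALSE`.
#' @export
tf_transform <- function(x, fs, t0 = -1, grid = frequency_grid(),
                         tmin = -0.2, tmax = 1.0, step = 1L) {
  single <- !is.matrix(x)
  M <- if (single) matrix(x, 1L) else x
  times <- seq(tmin, tmax, by = step / fs)
  centers <- as.integer(round((times - t0) * fs)) + 1L
  if (any(centers < 1L | centers > ncol(M)))
    stop("requested time axis extends beyond the epoch")
  if (3 / min(grid$frequencies) > (ncol(M) - 1) / fs)
    stop("epoch too short to fit 3 cycles of the lowest frequency")
  co <- tf_coef_matrix(M, fs, grid$frequencies, centers)
  pw <- array(NA_real_, dim = c(nrow(M), length(times),
                                length(grid$frequencies)))
  for (fi in seq_along(co)) pw[, , fi] <- Mod(co[[fi]])^2
  structure(list(
    power = if (single) pw[1L, , ] else pw,
    times = times, frequencies = grid$frequencies,
    normalized = FALSE), class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  d <- if (is.matrix(x$power)) c(1L, dim(x$power)) else dim(x$power)
  cat(sprintf(
    "<tf_power> %d signal(s) x %d time points x %d frequency bins%s\n",
    d[1L], d[2L], d[3L],
    if (isTRUE(x$normalized)) " (baseline-normalized)" else ""))
  invisible(x)
}

#' Baseline-normalize time-frequency power
#'
#' Expresses power as relative change from the pre-stimulus baseline:
#' `(P(t, f) - B(f)) / B(f)` with `B(f)` the mean power over baseline
#' time points at each frequency (and each signal). A task cell with
#' twice the baseline power maps to +1.
#'
#' @param tf a `tf_power` (one trial).
#' @param baseline baseline window (s), default -200 to 0 ms.
#' @return normalized `tf_power`.
#' @export
baseline_normalize <- function(tf, baseline = c(-0.2, 0)) {
  stopifnot(inherits(tf, "tf_power"))
  if (isTRUE(tf$normalized)) stop("power is already baseline-normalized")
  bl <- tf$times >= baseline[1] & tf$times <= baseline[2]
  if (!any(bl)) stop("baseline window contains no time points")
  if (is.matrix(tf$power)) {
    B <- colMeans(tf$power[bl, , drop = FALSE], na.rm = TRUE)
    if (any(!is.finite(B)) || any(B == 0))
      stop("degenerate baseline power (zero or all-missing)")
    tf$power <- sweep(sweep(tf$power, 2L, B), 2L, B, "/")
  } else {
    for (s in seq_len(dim(tf$power)[1L])) {
      P <- tf$power[s, , ]
      B <- colMeans(P[bl, , drop = FALSE], na.rm = TRUE)
      if (any(!is.finite(B)) || any(B == 0))
        stop("degenerate baseline power (zero or all-missing)")
      tf$power[s, , ] <- sweep(sweep(P, 2L, B), 2L, B, "/")
    }
  }
  tf$normalized <- TRUE
  tf
}

#' Total power: trial average of baseline-normalized power
#'
#' Pointwise mean across trials of per-trial (baseline-normalized) power.
#' Averaging after the per-trial transform retains induced
#' (non-phase-locked) activity, unlike evoked power. Missing cells
#' propagate as missing.
#'
#' @param trials list of `tf_power` objects on identical axes.
#' @return a `tf_power` of the same shape.
#' @export
total_power <- function(trials) {
  if (length(trials) == 0L) stop("no trials to average")
  stopifnot(all(vapply(trials, inherits, logical(1), "tf_power")))
  out <- trials[[1L]]
  acc <- trials[[1L]]$power
  for (k in seq_along(trials)[-1L]) acc <- acc + trials[[k]]$power
  out$power <- acc / length(trials)
  out
}

#' Band-averaged lobe power traces
#'
#' Averages a per-region `tf_power` over the frequency bins of one band
#' and over the regions of each lobe, yielding one time series per lobe
#' (the four-lobe power-map summary).
#'
#' @param tf a `tf_power` with regions as signals (3D power array).
#' @param atlas an `roi_atlas` matching the region axis.
#' @param band band name (`"delta"` is rejected).
#' @param grid the [frequency_grid()] the power was computed on.
#' @return matrix lobes x time; empty lobes are omitted with a warning.
#' @export
aggregate_power <- function(tf, atlas, band, grid = frequency_grid()) {
  stopifnot(inherits(tf, "tf_power"), !is.matrix(tf$power))
  bins <- band_bins(grid, band)
  part <- lobe_partition(atlas)
  empty <- names(part)[vapply(part, length, integer(1)) == 0L]
  if (length(empty)) {
    warning("empty lobe(s) omitted: ", paste(empty, collapse = ", "))
    part <- part[vapply(part, length, integer(1)) > 0L]
  }
  out <- t(vapply(part, function(idx) {
    apply(tf$power[idx, , bins, drop = FALSE], 2L, mean)
  }, numeric(length(tf$times))))
  rownames(out) <- names(part)
  out
}

#' Subject-level baseline-normalized total power
#'
#' Computes per-trial time-frequency power for every region of an epoch
#' array, baseline-normalizes each trial, and averages over trials, in a
#' memory-bounded frequency-by-frequency sweep.
#'
#' @param epochs an `epoch_array` (regions as signals).
#' @param grid a [frequency_grid()].
#' @param tmin,tmax,step output time axis (see [tf_transform()]).
#' @param baseline baseline window (s).
#' @return a `tf_power`, regions x time x frequency, normalized.
#' @export
subject_total_power <- function(epochs, grid = frequency_grid(),
                                tmin = -0.2, tmax = 1.0, step = 1L,
                                baseline = c(-0.2, 0)) {
  stopifnot(inherits(epochs, "epoch_array"))
  d <- dim(epochs$data)
  if (d[1L] < 1L) stop("no trials to average")
  M <- matrix(epochs$data, d[1L] * d[2L], d[3L])
  times <- seq(tmin, tmax, by = step / epochs$fs)
  centers <- as.integer(round((times - epochs$t0) * epochs$fs)) + 1L
  bl <- times >= baseline[1] & times <= baseline[2]
  grp <- rep(seq_len(d[2L]), each = d[1L])
  pw <- array(NA_real_, dim = c(d[2L], length(times),
                                length(grid$frequencies)))
  for (fi in seq_along(grid$frequencies)) {
    co <- tf_coef_matrix(M, epochs$fs, grid$frequencies[fi], centers)[[1L]]
    P <- Mod(co)^2                                # (epochs*regions) x time
    B <- rowMeans(P[, bl, drop = FALSE], na.rm = TRUE)
    if (any(!is.finite(B)) || any(B == 0))
      stop("degenerate baseline power (zero or all-missing)")
    P <- (P - B) / B
    pw[, , fi] <- rowsum(P, grp, reorder = TRUE) / d[1L]
  }
  structure(list(power = pw, times = times,
                 frequencies = grid$frequencies, normalized = TRUE),
            class = "tf_power")
}
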