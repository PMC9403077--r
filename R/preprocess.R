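#' Epoched multi-channel time-series container
#'
#' @param data numeric array epochs x signals x samples.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample relative to stimulus onset (s).
#' @param labels signal (channel/region) labels.
#' @param event_type character vector, one entry per epoch.
#' @return an `epoch_array`.
#' @export
epoch_array <- function(data, fs, t0 = -1, labels = NULL,
                        event_type = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  d <- dim(data)
  labels <- labels %||% sprintf("sig%02d", seq_len(d[2L]))
  event_type <- event_type %||% rep("target", d[1L])
  stopifnot(length(labels) == d[2L], length(event_type) == d[1L])
  structure(list(data = data, fs = fs, t0 = t0, labels = labels,
                 event_type = event_type),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_array> %d epochs x %d signals x %d samples @ %g Hz, t0 = %g s\n",
    d[1L], d[2L], d[3L], x$fs, x$t0))
  invisible(x)
}

#' Time axis of an epoch array (seconds)
#' @param x an `epoch_array`.
#' @export
epoch_times <- function(x) x$t0 + (seq_len(dim(x$data)[3L]) - 1L) / x$fs

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' the channel mean is zero everywhere. Accepts a channels x samples
#' matrix or an `epoch_array`. Idempotent.
#'
#' @param x matrix (channels x samples) or `epoch_array`.
#' @return same shape as the input.
#' @export
rereference_car <- function(x) {
  if (inherits(x, "epoch_array")) {
    if (dim(x$data)[2L] < 2L) stop("need at least 2 channels for CAR")
    for (e in seq_len(dim(x$data)[1L])) {
      m <- matrix(x$data[e, , ], dim(x$data)[2L], dim(x$data)[3L])
      x$data[e, , ] <- sweep(m, 2L, colMeans(m))
    }
    return(x)
  }
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("need at least 2 channels for CAR")
  sweep(x, 2L, colMeans(x))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero net phase and an effective
#' sixth-order magnitude response. Defaults to the 1-55 Hz analysis band.
#'
#' @param x numeric vector, channels x samples matrix, or `epoch_array`.
#' @param fs sampling rate (Hz); taken from the object for epoch arrays.
#' @param low,high band edges (Hz), `high` must be below Nyquist.
#' @param order filter order per pass.
#' @return filtered data, same shape.
#' @export
bandpass_zero_phase <- function(x, fs = NULL, low = 1, high = 55,
                                order = 3) {
  if (inherits(x, "epoch_array")) {
    fs <- x$fs
    check_band(low, high, fs)
    flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
    for (e in seq_len(dim(x$data)[1L]))
      for (ch in seq_len(dim(x$data)[2L]))
        x$data[e, ch, ] <- signal::filtfilt(flt, x$data[e, ch, ])
    return(x)
  }
  stopifnot(!is.null(fs))
  check_band(low, high, fs)
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    t(apply(x, 1L, function(ch) signal::filtfilt(flt, ch)))
  } else {
    signal::filtfilt(flt, x)
  }
}

check_band <- function(low, high, fs) {
  if (high >= fs / 2)
    stop(sprintf("upper edge %g Hz is at or above Nyquist (%g Hz)",
                 high, fs / 2))
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  invisible(TRUE)
}

#' Cut continuous data into stimulus-locked epochs
#'
#' @param x channels x samples matrix of continuous data.
#' @param fs sampling rate (Hz).
#' @param events data.frame with `onset_ms` and `type`
#'   (see [generate_event_sequence()]).
#' @param window epoch limits in seconds relative to onset.
#' @param keep_type event type to keep (default `"target"`; the analysis
#'   uses target trials only).
#' @return an `epoch_array`; events whose window would cross the
#'   recording edge are skipped with a warning.
#' @export
epoch_continuous <- function(x, fs, events, window = c(-1, 1),
                             keep_type = "target") {
  stopifnot(is.matrix(x), window[1] < window[2])
  ev <- events[events$type == keep_type, , drop = FALSE]
  n_pre <- round(-window[1] * fs)
  n_len <- round((window[2] - window[1]) * fs) + 1L
  onset_idx <- round(ev$onset_ms / 1000 * fs) + 1L
  start <- onset_idx - n_pre
  ok <- start >= 1L & (start + n_len - 1L) <= ncol(x)
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the recording edge; skipped",
                    sum(!ok)))
  keep <- which(ok)
  dat <- array(0, dim = c(length(keep), nrow(x), n_len))
  for (k in seq_along(keep))
    dat[k, , ] <- x[, start[keep[k]]:(start[keep[k]] + n_len - 1L)]
  epoch_array(dat, fs = fs, t0 = window[1],
              labels = rownames(x) %||% sprintf("ch%02d", seq_len(nrow(x))),
              event_type = rep(keep_type, length(keep)))
}

#' Reject epochs with large amplitude excursions
#'
#' An epoch is removed when any sample of any channel exceeds the
#' threshold in absolute value (physiological-artifact criterion,
#' +/- 100 uV by default).
#'
#' @param epochs an `epoch_array` with data in uV.
#' @param threshold rejection threshold (uV).
#' @return list with `epochs` (kept epochs) and `report` (data.frame:
#'   epoch index, max absolute amplitude, kept flag).
#' @export
reject_epochs <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epoch_array"))
  n <- dim(epochs$data)[1L]
  mx <- vapply(seq_len(n), function(e) max(abs(epochs$data[e, , ])),
               numeric(1))
  keep <- mx <= threshold
  report <- data.frame(epoch = seq_len(n), max_abs = mx, kept = keep)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$event_type <- epochs$event_type[keep]
  list(epochs = epochs, report = report)
}

#' First-principal-component summary of a region's vertex signals
#'
#' Reduces several vertex-level time series within one cortical region to
#' one representative signal: the first principal-component score of the
#' vertex covariance, fitted per subject on all epochs concatenated and
#' applied per epoch. The component sign is aligned so its correlation
#' with the vertex-mean signal is nonnegative.
#'
#' @param vertex_epochs array epochs x vertices x samples.
#' @return matrix epochs x samples of the representative signal.
#' @export
roi_representative_signal <- function(vertex_epochs) {
  stopifnot(is.array(vertex_epochs), length(dim(vertex_epochs)) == 3L)
  d <- dim(vertex_epochs)
  # concatenate epochs: samples*epochs rows x vertices columns
  X <- matrix(aperm(vertex_epochs, c(3L, 1L, 2L)), d[1L] * d[3L], d[2L])
  if (all(apply(X, 2L, stats::sd) < .Machine$double.eps^0.5)) {
    warning("zero-variance vertex signals; returning zeros")
    return(matrix(0, d[1L], d[3L]))
  }
  X <- sweep(X, 2L, colMeans(X))
  v <- eigen(crossprod(X) / (nrow(X) - 1L), symmetric = TRUE)$vectors[, 1L]
  score <- X %*% v
  vm <- rowMeans(X)
  if (stats::sd(vm) > 0 && stats::cor(score, vm) < 0) score <- -score
  matrix(score, d[3L], d[1L]) |> t()
}
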