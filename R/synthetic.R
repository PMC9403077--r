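#' Auditory oddball paradigm specification
#'
#' Describes the stimulus stream of the auditory oddball task: 400 pure
#' tones, 15% rare targets among frequent standards, inter-stimulus
#' interval 1,500 ms, 100 ms tones with 10 ms rise/fall ramps.
#'
#' @param n_stimuli total number of tones.
#' @param target_fraction proportion of target tones, in (0, 1).
#' @param isi inter-stimulus onset interval (ms).
#' @param tone_duration tone duration (ms).
#' @param rise_fall rise/fall ramp (ms).
#' @return a `paradigm_spec` list.
#' @export
paradigm_spec <- function(n_stimuli = 400, target_fraction = 0.15,
                          isi = 1500, tone_duration = 100, rise_fall = 10) {
  stopifnot(n_stimuli >= 1, target_fraction > 0, target_fraction < 1,
            isi > 0, tone_duration > 0, rise_fall >= 0)
  structure(list(n_stimuli = as.integer(n_stimuli),
                 target_fraction = target_fraction, isi = isi,
                 tone_duration = tone_duration, rise_fall = rise_fall),
            class = "paradigm_spec")
}

#' Generate a randomized oddball event sequence
#'
#' Onsets are regularly spaced by the inter-stimulus interval; exactly
#' `round(n_stimuli * target_fraction)` events are targets, placed in
#' random order under the seed.
#'
#' @param spec a [paradigm_spec()].
#' @param seed integer seed; the sequence is a pure function of
#'   `(spec, seed)`.
#' @return data.frame with columns `onset_ms` and `type`
#'   (`"target"`/`"standard"`).
#' @export
generate_event_sequence <- function(spec = paradigm_spec(), seed = 1) {
  n <- spec$n_stimuli
  n_target <- round(n * spec$target_fraction)
  type <- rep("standard", n)
  set.seed(seed)
  type[sample.int(n, n_target)] <- "target"
  data.frame(onset_ms = (seq_len(n) - 1) * spec$isi, type = type)
}

#' Two-group cohort simulation specification
#'
#' Describes a synthetic two-group oddball cohort at the cortical-region
#' level: group sizes default to the 53-patient / 39-control design, 68
#' regions sampled at 1,000 Hz over a [-1, 1] s epoch, with phase-lagged
#' theta-band oscillatory bursts around 300 ms post-stimulus shared by
#' coupled region pairs. Coupling is weaker in group 1 ("patients") under
#' the default pairs, and a between-subject trait standard deviation
#' spreads the realized coupling so theta-band group effect sizes land
#' in a moderate-to-large range (d around 1-1.7 on the global indices)
#' while the uncoupled beta bands stay at the null.
#'
#' @param n_group1,n_group2 subject counts (patients, controls).
#' @param n_rois number of cortical regions.
#' @param fs sampling rate (Hz).
#' @param epoch_window epoch limits in seconds relative to stimulus onset.
#' @param coupling_pairs data.frame with columns `i`, `j` (region indices),
#'   `freq` (Hz), `lag` (radians, in (0, pi) so the imaginary part of
#'   coherency is nonzero), `s1`, `s2` (coupling strengths per group,
#'   in [0, 1]).
#' @param burst_center burst envelope center (s).
#' @param burst_width burst envelope Gaussian SD (s).
#' @param burst_amplitude per-pair oscillator amplitude, in units of the
#'   background-noise SD; the coupling strength sets the shared
#'   (coherent) fraction of each member's oscillator, not its power.
#' @param noise_sd background 1/f noise SD (signal units).
#' @param subject_sd between-subject SD of the coupling-strength trait.
#' @param seed master seed; the cohort is a pure function of the spec.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_group1 = 53, n_group2 = 39, n_rois = 68,
                        fs = 1000, epoch_window = c(-1, 1),
                        coupling_pairs = default_coupling_pairs(n_rois),
                        burst_center = 0.3, burst_width = 0.15,
                        burst_amplitude = 2.2, noise_sd = 1,
                        subject_sd = 0.18, seed = 1) {
  stopifnot(n_group1 >= 1, n_group2 >= 1, n_rois >= 2, fs > 0,
            length(epoch_window) == 2L, epoch_window[1] < epoch_window[2])
  cp <- coupling_pairs
  if (nrow(cp)) {
    stopifnot(all(c("i", "j", "freq", "lag", "s1", "s2") %in% names(cp)),
              all(cp$s1 >= 0 & cp$s1 <= 1), all(cp$s2 >= 0 & cp$s2 <= 1),
              all(cp$lag > 0 & cp$lag < pi))
    if (any(cp$i > n_rois | cp$j > n_rois | cp$i < 1 | cp$j < 1))
      stop("coupling pair references a region index outside 1..n_rois")
  }
  structure(list(n_group1 = as.integer(n_group1),
                 n_group2 = as.integer(n_group2),
                 n_rois = as.integer(n_rois), fs = fs,
                 epoch_window = epoch_window, coupling_pairs = cp,
                 burst_center = burst_center, burst_width = burst_width,
                 burst_amplitude = burst_amplitude, noise_sd = noise_sd,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default theta coupling set (distributed posterior deficit)
#'
#' Region pairs share a 6 Hz oscillator with a quarter-cycle phase lag.
#' Two kinds of coupling are configured:
#'
#' * a distributed deficit field: every within-hemisphere pair of
#'   parieto-temporo-occipital (plus posterior-cingulate) regions whose
#'   centroids lie within 50 mm is coupled, with group-1 strength (0.28)
#'   weaker than group-2 strength (0.50). In the dense unthresholded
#'   networks the analysis uses, nodal degree is always 67, so a
#'   handful of strong edges cannot move the clustering coefficient;
#'   only a broad weight field shifted between groups reproduces the
#'   joint strength/clustering/path-length contrast;
#' * common edges with equal coupling (0.55) in both groups, placed in
#'   sensorimotor/frontal cortex. These pin the network-wide maximum
#'   weight — which the Onnela clustering coefficient normalizes by —
#'   at a group-independent value; without them each group's own
#'   strongest edge would normalize itself away and the clustering
#'   contrast would invert.
#'
#' @param n_rois number of regions (pairs are defined on the packaged
#'   68-region atlas ordering; for smaller test grids the pairs that fit
#'   are kept).
#' @export
default_coupling_pairs <- function(n_rois = 68) {
  atl <- utils::read.delim(
    system.file("extdata", "dk68_atlas.tsv", package = "icohnet"))
  atl <- atl[order(atl$hemi, atl$label), ]
  post <- which(atl$lobe %in% c("parietal", "temporal", "occipital") |
                  grepl("isthmuscingulate|posteriorcingulate", atl$label))
  pairs <- NULL
  for (a in post) for (b in post) {
    if (a >= b || atl$hemi[a] != atl$hemi[b]) next
    d <- sqrt(sum((atl[a, c("x", "y", "z")] - atl[b, c("x", "y", "z")])^2))
    if (d < 50) pairs <- rbind(pairs, c(a, b))
  }
  common <- rbind(
    c("lh.precentral", "lh.postcentral"),
    c("rh.precentral", "rh.postcentral"),
    c("lh.superiorfrontal", "rh.superiorfrontal"))
  cp <- rbind(
    data.frame(i = pairs[, 1], j = pairs[, 2],
               freq = 6, lag = pi / 2, s1 = 0.28, s2 = 0.50),
    data.frame(i = match(common[, 1], atl$label),
               j = match(common[, 2], atl$label),
               freq = 6, lag = pi / 2, s1 = 0.55, s2 = 0.55))
  cp[cp$i <= n_rois & cp$j <= n_rois, , drop = FALSE]
}

# 1/f-shaped background noise (flat below 1 Hz) with a high-frequency
# noise floor — real EEG spectra flatten toward the beta/gamma range
# where sensor and muscle noise dominate. White noise is spectrally
# reweighted and rescaled to the requested SD.
# Returns an n_samples x n_signals matrix.
pink_noise <- function(n_samples, n_signals, fs, sd = 1) {
  n2 <- 2L^ceiling(log2(n_samples))        # radix-2 length, then truncate
  W <- matrix(stats::rnorm(n2 * n_signals), n2, n_signals)
  f <- seq(0, fs, length.out = n2 + 1L)[seq_len(n2)]
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  g <- sqrt(1 / pmax(f, 1) + 0.2)
  X <- stats::mvfft(W) * g
  P <- Re(stats::mvfft(X, inverse = TRUE))[seq_len(n_samples), ,
                                           drop = FALSE] / n2
  sds <- sqrt(colMeans(P^2) - colMeans(P)^2)
  sweep(P, 2L, sds / sd, "/")
}

# Connected components of the coupling graph, as lists of region
# indices (sorted; deterministic).
components_from_pairs <- function(cp, n_rois) {
  g <- igraph::graph_from_edgelist(cbind(cp$i, cp$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_rois - igraph::vcount(g)))
  co <- igraph::components(g)
  keep <- which(co$csize >= 2L)
  lapply(keep, function(k) sort(which(co$membership == k)))
}

simulate_subject <- function(spec, group, n_epochs, subj_seed) {
  set.seed(subj_seed)
  t <- seq(spec$epoch_window[1], spec$epoch_window[2], by = 1 / spec$fs)
  n_s <- length(t)
  n_r <- spec$n_rois
  dat <- array(0, dim = c(n_epochs, n_r, n_s))
  noise <- pink_noise(n_s, n_epochs * n_r, spec$fs, spec$noise_sd)
  dat[] <- aperm(array(noise, dim = c(n_s, n_epochs, n_r)), c(2, 3, 1))
  cp <- spec$coupling_pairs
  if (nrow(cp)) {
    trait <- stats::rnorm(1, 0, spec$subject_sd)
    trait <- max(-2.5 * spec$subject_sd, min(2.5 * spec$subject_sd, trait))
    s_grp <- if (group == 1) cp$s1 else cp$s2
    s_subj <- pmin(1, pmax(0, s_grp + trait))
    add_burst <- function(roi, amp, f, del, phase) {
      ts <- t - del
      env <- exp(-(ts - spec$burst_center)^2 / (2 * spec$burst_width^2))
      # cos(2*pi*f*ts + phi) = cos(phi) carrier_c - sin(phi) carrier_s
      cc <- env * cos(2 * pi * f * ts)
      ss <- env * sin(2 * pi * f * ts)
      dat[, roi, ] <<- dat[, roi, ] +
        amp * (outer(cos(phase), cc) - outer(sin(phase), ss))
    }
    # Community-oscillator construction. Each connected component of
    # the coupling graph shares one theta driver; member region r
    # receives sqrt(c_r) of the driver (delayed by a region-specific
    # phase offset, so no pair is at zero lag) plus sqrt(1 - c_r) of a
    # private oscillator, with c_r the region's coupling (its largest
    # incident pair strength, shifted by the subject trait). All
    # phases are drawn per epoch: activity is induced, not
    # phase-locked. Consequences: (a) burst power per region is
    # amplitude^2/2 for every subject and group — contrasts are
    # carried by coherence, never power, whose estimator-floor
    # elevation and beta-band taper leakage would otherwise differ
    # between groups; (b) pairwise coherence is ~sqrt(c_i c_j)
    # independent of component size, where independent per-pair
    # oscillators would dilute it by the region's pair count; (c) an
    # isolated pair reduces to two regions sharing one lagged
    # oscillator.
    memb <- components_from_pairs(cp, n_r)
    phases <- lapply(memb, function(rois) {
      f_c <- stats::median(cp$freq[cp$i %in% rois & cp$j %in% rois])
      lag_c <- max(cp$lag[cp$i %in% rois & cp$j %in% rois])
      m <- length(rois)
      delta <- if (m == 2L) c(0, lag_c)
               else (seq_len(m) - 1L) / (m - 1L) * lag_c
      list(rois = rois, f = f_c, delta = delta)
    })
    for (co in phases) {
      phi <- stats::runif(n_epochs, 0, 2 * pi)   # shared driver phase
      for (k in seq_along(co$rois)) {
        r <- co$rois[k]
        s_r <- max(s_subj[cp$i == r | cp$j == r])
        del <- co$delta[k] / (2 * pi * co$f)     # offset in seconds
        add_burst(r, spec$burst_amplitude * sqrt(s_r), co$f, del, phi)
        if (s_r < 1)
          add_burst(r, spec$burst_amplitude * sqrt(1 - s_r), co$f, del,
                    stats::runif(n_epochs, 0, 2 * pi))
      }
    }
  }
  labels <- sprintf("roi%02d", seq_len(n_r))
  epoch_array(dat, fs = spec$fs, t0 = spec$epoch_window[1],
              labels = labels, event_type = rep("target", n_epochs))
}

#' Simulate a two-group epoched cohort at the region level
#'
#' Generates per-subject target epochs (regions x samples) containing
#' band-limited oscillatory bursts in coupled region pairs, on top of a
#' 1/f background. Only target epochs are synthesized: the analysis uses
#' target trials exclusively, and the number of epochs equals the number
#' of targets implied by the paradigm (60 under the defaults).
#'
#' @param spec a [cohort_spec()].
#' @param paradigm a [paradigm_spec()]; sets the target-epoch count.
#' @param out_dir optional directory; when given, each subject is written
#'   as an RDS epoch container and only file paths are kept in memory
#'   (recommended beyond ~10 subjects).
#' @return list with `manifest` (data.frame: `subject`, `group`, `seed`,
#'   `file`) and `subjects` (list of `epoch_array` objects, or `NULL`
#'   entries when `out_dir` is used).
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            paradigm = paradigm_spec(), out_dir = NULL) {
  n_epochs <- round(paradigm$n_stimuli * paradigm$target_fraction)
  groups <- rep(1:2, c(spec$n_group1, spec$n_group2))
  ids <- sprintf("S%03d", seq_along(groups))
  seeds <- vapply(ids, function(id) derive_seed(spec$seed, id), integer(1))
  files <- rep(NA_character_, length(ids))
  subjects <- vector("list", length(ids))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  for (k in seq_along(ids)) {
    ep <- simulate_subject(spec, groups[k], n_epochs, seeds[k])
    if (is.null(out_dir)) {
      subjects[[k]] <- ep
    } else {
      files[k] <- file.path(out_dir, paste0(ids[k], ".rds"))
      write_epochs(ep, files[k])
    }
  }
  manifest <- data.frame(subject = ids, group = groups, seed = seeds,
                         file = files)
  if (!is.null(out_dir))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(manifest = manifest, subjects = subjects)
}

#' Project region-level epochs to synthetic sensors
#'
#' Applies an instantaneous linear mixture (volume-conduction surrogate)
#' plus sensor noise, and optionally injects large-amplitude excursions
#' into a random subset of epochs to exercise amplitude-based rejection.
#'
#' @param epochs an `epoch_array` (regions as signals).
#' @param mixing channels x regions mixing matrix (full column rank
#'   expected; rank deficiency is only warned about).
#' @param artifact_rate probability that an epoch receives a > 100 uV
#'   excursion.
#' @param sensor_noise_sd additive sensor white-noise SD (uV).
#' @param seed integer seed.
#' @return sensor-level `epoch_array`.
#' @export
simulate_sensor_projection <- function(epochs, mixing, artifact_rate = 0,
                                       sensor_noise_sd = 1, seed = 1) {
  stopifnot(inherits(epochs, "epoch_array"),
            ncol(mixing) == dim(epochs$data)[2L])
  if (qr(mixing)$rank < ncol(mixing))
    warning("mixing matrix is rank deficient; sources are not separable")
  set.seed(seed)
  d <- dim(epochs$data)
  out <- array(0, dim = c(d[1L], nrow(mixing), d[3L]))
  for (e in seq_len(d[1L])) {
    out[e, , ] <- mixing %*% matrix(epochs$data[e, , ], d[2L], d[3L]) +
      matrix(stats::rnorm(nrow(mixing) * d[3L], 0, sensor_noise_sd),
             nrow(mixing), d[3L])
  }
  hit <- stats::runif(d[1L]) < artifact_rate
  for (e in which(hit)) {
    ch <- sample.int(nrow(mixing), 1L)
    at <- sample.int(d[3L] - 50L, 1L)
    out[e, ch, at:(at + 49L)] <- out[e, ch, at:(at + 49L)] + 150
  }
  epoch_array(out, fs = epochs$fs, t0 = epochs$t0,
              labels = sprintf("ch%02d", seq_len(nrow(mixing))),
              event_type = epochs$event_type)
}

#' Symptom-score generator specification
#'
#' Scores on three self-report instruments are generated as a linear
#' function of a chosen nodal network index plus Gaussian noise, clipped
#' to instrument ranges; with a negative slope this emulates symptom
#' severity rising as posterior theta clustering falls. The default
#' intercepts and slopes are scaled to the default cohort's theta nodal
#' clustering (around 0.075 with a between-subject SD of 0.009), giving
#' patient-group score means in the clinically reported range and a
#' recoverable negative correlation (r around -0.7).
#'
#' @param score_names instrument names.
#' @param intercept,slope,noise_sd per-instrument linear-model parameters.
#' @param range list of per-instrument `(min, max)` score ranges.
#' @export
symptom_spec <- function(score_names = c("IESR", "BDI", "BAI"),
                         intercept = c(128, 86, 90),
                         slope = c(-1000, -800, -800),
                         noise_sd = c(5, 5, 6),
                         range = list(c(0, 88), c(0, 63), c(0, 63))) {
  stopifnot(length(score_names) == length(intercept),
            length(intercept) == length(slope),
            length(slope) == length(noise_sd),
            length(noise_sd) == length(range))
  structure(list(score_names = score_names, intercept = intercept,
                 slope = slope, noise_sd = noise_sd, range = range),
            class = "symptom_spec")
}

#' Generate symptom scores from a per-subject nodal index
#'
#' @param index numeric vector, one network-index value per subject.
#' @param spec a [symptom_spec()].
#' @param seed integer seed.
#' @return data.frame with one column per instrument (clipped to range).
#' @export
generate_symptom_scores <- function(index, spec = symptom_spec(), seed = 1) {
  stopifnot(is.numeric(index), length(index) >= 1L)
  set.seed(seed)
  out <- lapply(seq_along(spec$score_names), function(k) {
    s <- spec$intercept[k] + spec$slope[k] * index +
      stats::rnorm(length(index), 0, spec$noise_sd[k])
    pmin(pmax(s, spec$range[[k]][1L]), spec$range[[k]][2L])
  })
  names(out) <- spec$score_names
  as.data.frame(out)
}
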