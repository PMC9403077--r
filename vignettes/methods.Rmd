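---
title: "Task-based cortical network analysis with imaginary coherency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based cortical network analysis with imaginary coherency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icohnet)
```

`icohnet` implements a complete task-based EEG cortical network
analysis for a 68-region cortical parcellation: epoched multi-region
time series are turned into baseline-normalized spectral power maps,
imaginary-coherency connectomes, task-specific enhanced and diminished
weighted networks, graph-theoretic indices, and permutation statistics.
This vignette explains the models behind each stage, the tunable
parameters and their defaults, the synthetic cohort generator used to
exercise the pipeline, and the numerical and design choices a user
should know about.

## The analysis chain

The scientific question the pipeline addresses is whether a clinical
group differs from controls in the *cortical functional networks
recruited by a cognitive task* — here an auditory oddball paradigm, in
which rare target tones among frequent standards elicit attention-
related activity (the P300 complex and its associated theta-band
oscillations) around 300 ms after the stimulus.

The chain is:

1. **Preprocessing** (`rereference_car`, `bandpass_zero_phase`,
   `epoch_continuous`, `reject_epochs`): common average reference,
   third-order Butterworth band-pass (1–55 Hz) applied forward and
   backward for zero net phase, epoching into [−1, 1] s windows around
   target onsets, and rejection of epochs with any sample exceeding
   ±100 µV. Filtering is applied to continuous data before epoching so
   filter transients do not contaminate epoch edges. Rejection is
   applied after filtering. `roi_representative_signal` reduces
   vertex-level source signals within a region to its first principal
   component, fitted per subject over all epochs concatenated (a
   per-epoch fit would make the component, and its sign, unstable
   across trials) and sign-aligned with the vertex mean.
2. **Spectral analysis** (`tf_transform`, `baseline_normalize`,
   `total_power`, `aggregate_power`): single Hanning-taper Fourier
   coefficients with a frequency-dependent window of three cycles
   (3/f s), on a 4–30 Hz grid of 27 one-hertz bins grouped into theta
   (4–8), alpha (8–12), low-beta (12–22) and high-beta (22–30 Hz).
   Delta is excluded: a 1 s task window holds too few delta cycles for
   a stable estimate. Power is baseline-normalized per trial as
   relative change from the −200 to 0 ms mean, then averaged over
   trials — *total* power, which retains induced (non-phase-locked)
   activity that trial-averaging before the transform would cancel.
3. **Connectivity** (`cross_spectra`, `icoh`, `task_normalize`):
   cross-spectra are averaged over trials and over window centers
   stepped every 50 ms inside the baseline (−1 to 0 s) and task (0 to
   1 s) windows; only centers whose full taper fits inside the window
   contribute. Coherency is normalized per frequency bin and the edge
   weight is the band mean of `|Im C|`. The imaginary part is immune to
   instantaneous (zero-lag) mixing, the signature of volume conduction,
   which is why it is preferred for EEG source connectivity. The task
   matrix minus the baseline matrix is split by sign into a
   *positive* (enhanced) and a *negative* (diminished) connectome, kept
   as two nonnegative weighted networks with disjoint edge supports. No
   edge thresholding is applied anywhere.
4. **Graph indices** (`nodal_strength`, `nodal_clustering`,
   `char_path_length`, `global_indices`): weighted strength (row sums),
   Onnela weighted clustering (geometric-mean triangle intensity on
   weights normalized by the network-wide maximum), and characteristic
   path length (mean finite Dijkstra distance on inverse-weight edge
   lengths; disconnected pairs are excluded and their fraction
   reported). Global strength and clustering aggregate nodal values by
   their mean; a sum aggregation is exposed for strength
   (`strength_agg`) since either convention appears in practice.
5. **Statistics** (`welch_t_from_summary`, `welch_t_from_samples`,
   `cluster_permutation_test`, `perm_pearson`, `global_index_tests`):
   Welch's unequal-variance t-test with Welch–Satterthwaite fractional
   degrees of freedom (the fractional df values in the reference
   summaries identify this form) and pooled-SD Cohen's d; a
   cluster-based permutation test over multidimensional grids; and
   permutation Pearson correlation (default 10,000 permutations)
   between network indices and symptom scores. Global indices are
   tested per band, metric and polarity at α = 0.01, a correction for
   the four frequency bands slightly stricter than Bonferroni
   (0.05/4 = 0.0125).

## The cluster-based permutation test

For grids such as 68 regions × 4 bands (nodal indices) or
lobes × time × frequency (power maps), a Welch t-test is computed per
cell; cells with p < 0.05 form clusters as connected components of two
or more adjacent cells, separately for positive and negative t; a
cluster's mass is its summed t; significance is assessed against the
permutation distribution of the maximum absolute cluster mass over
random relabelings of the subjects (default 1,000), two-tailed at
α = 0.025. The plus-one convention `(1 + #{perm ≥ obs})/(n_perm + 1)`
keeps p-values strictly positive. Using Welch cells inside the cluster
routine keeps the cell statistic consistent with the global tests; this
is a documented choice (an equal-variance Student cell test is the
historical default in some toolboxes).

Adjacency over cells must be supplied. For nodal grids,
`band_chain_adjacency` combines the atlas spatial adjacency within each
band with links between the same region in consecutive bands. For
power grids, `tf_grid_adjacency` links adjacent time points and
frequency bins within a series, with the (four) lobe series treated as
mutually adjacent. The parcellation itself does not define spatial
adjacency, so the packaged atlas derives it from region centroid
distances with a 40 mm radius — chosen once so the graph is connected
within each hemisphere — and ships the resulting neighbor lists
explicitly, making all cluster tests reproducible byte-for-byte.

## The published-summary surface

The packaged file `global_indices_summary.tsv` transcribes the
global-index group summaries (mean ± SD per band, metric and network
polarity for 53 patients vs 39 controls) together with their printed
t, df and effect sizes. `reproduce_tables()` recomputes the inferential
columns from the printed summaries and classifies each row:

* `ok` — recomputed t/df/d match the printed values within
  0.02/0.15/0.01;
* `rounding_limited` — they do not, but the printed value lies inside
  the interval achievable when the two-decimal inputs are perturbed
  within their ±0.005 rounding boxes (means enter monotonically, so
  box corners suffice; Welch df peaks *inside* the SD box, so the SDs
  are searched on a grid);
* `failed` — the printed value is unreachable under any rounding. One
  row (negative network, alpha strength) is in this class: its printed
  t/df/d are mutually consistent with a group-2 SD near 10.0 but not
  with the printed 3.02, indicating a transcription slip in the
  source. The packaged table keeps the printed values verbatim.

Clustering-coefficient rows, whose means are ~0.1–0.3 printed at two
decimals, are typically `rounding_limited`: the printed precision is
simply too coarse to pin a t-value to ±0.02.

## The synthetic cohort generator

No recordings accompany the reference analysis, so the package ships a
generator (`cohort_spec`, `simulate_cohort`) that emulates its study
conditions: two groups (defaults 53 and 39 subjects), 68 regions at
1,000 Hz, [−1, 1] s target epochs (60 per subject under the default
400-stimulus, 15%-target paradigm), theta-band oscillatory bursts
centered 300 ms post-stimulus, and symptom scores driven by a nodal
index. Group 1 plays the "patient" role with weaker task-related theta
coupling.

The coupling model is a *community oscillator*: each connected
component of the coupling-pair graph has one 6 Hz driver per epoch;
member region *r* receives a `sqrt(c_r)` share of the driver, delayed
by a region-specific phase offset spread over (0, π/2] so that no pair
sits at zero lag (imaginary coherency is blind to zero-lag coupling),
plus a `sqrt(1 − c_r)` private oscillator. Phases are drawn fresh every
epoch: the activity is induced, not phase-locked, which is exactly what
total power retains and evoked averaging would destroy. Three design
features deserve explanation because each guards against a specific
artifact discovered during calibration:

* **Power matching.** Burst power per region is `amplitude²/2`
  regardless of coupling, subject or group; the coupling strength sets
  only the coherent fraction. If burst power itself differed between
  groups, two confounds would appear: coherence estimated from finitely
  many windows has a floor that rises when a strong burst correlates
  neighboring window centers, and a 6 Hz burst seen through the short
  (100–136 ms) three-cycle tapers of the high-beta bins leaks
  coherently into them. Both would produce spurious "broadband" group
  effects from a purely theta-band manipulation.
* **Distributed deficit.** The deficit field couples every
  within-hemisphere pair of parieto-temporo-occipital (plus posterior
  cingulate) regions with centroids within 50 mm (~170 pairs), with
  group strengths 0.28 vs 0.50. In unthresholded dense networks every
  node has 67 weighted neighbors, so the Onnela clustering denominator
  `k(k−1)` is saturated and a handful of strong edges cannot move the
  coefficient: only a broad weight-field shift reproduces the joint
  strength/clustering/path-length contrast seen in the reference
  summaries.
* **Max-weight pinning.** Three group-equal "common" edges (bilateral
  sensorimotor pairs and an interhemispheric frontal pair, strength
  0.55) pin the network-wide maximum weight, by which Onnela clustering
  normalizes. Without them each group's own strongest edge normalizes
  itself away and the clustering contrast inverts — weaker-coupled
  subjects would paradoxically show *higher* clustering.

The background is 1/f noise with a flat high-frequency floor
(power ∝ 1/f + 0.2), mimicking the beta/gamma-range plateau of real
EEG; the flat floor also minimizes the theta-to-beta noise ratio,
keeping residual taper leakage below the beta noise floor. A
between-subject coupling trait (SD 0.18, truncated at ±2.5 SD) spreads
the realized coupling so that group effect sizes land in a moderate
range rather than being limited only by estimation noise: measured
once with 20 paired simulations per group, theta-band global effects
are d ≈ 1.4 (strength), 1.7 (clustering) and 1.1 (path length), with
high-beta |d| ≤ 0.1.
Symptom scores (IES-R, BDI, BAI scales) are linear in a chosen nodal
index plus noise, clipped to instrument ranges; the default intercepts
and slopes are scaled to the default cohort's posterior theta
clustering, giving patient-group score means in the clinically
reported range and a recoverable negative correlation.

What the generator does *not* emulate: volume conduction and inverse-
modeling leakage between regions (no forward model; an instantaneous
mixing surrogate exists only in `simulate_sensor_projection` for
preprocessing tests), ocular and muscle artifacts beyond an amplitude-
excursion injector, inter-regional 1/f coupling, and any empirical
spatial covariance of real source-localized EEG. Passing tests on this
cohort therefore demonstrate that the *pipeline* recovers known ground
truth under its own model assumptions — not that the original clinical
findings are reproduced, which would require the undeposited patient
recordings.

## Numerical choices

* **Taper normalization.** Each Hanning taper is normalized to unit
  energy, so white-noise power is flat across frequency and time.
* **Window edges.** Time–frequency cells whose three-cycle window
  crosses the epoch edge are missing (`NA`), not zero-padded; cluster
  tests drop missing cells. The time axis steps every sample by
  default (1,201 points over −200…1,000 ms at 1 kHz); the pipeline's
  demo configuration decimates to 20 ms steps to keep the run short.
* **Band edges.** Bins shared by two bands (8, 12, 22 Hz) belong to
  both, matching the printed band definitions.
* **Band averaging and baseline order.** Edge weights average
  `|Im C|` over band bins. Because this is linear, subtracting
  baseline from task per bin and then band-averaging is identical to
  subtracting band-level matrices; the order is therefore not a free
  parameter in this implementation.
* **Welch inside summaries.** `welch_t_from_samples` is defined as
  `welch_t_from_summary` of the sample moments, so the two agree to
  machine precision by construction.
* **Degenerate inputs.** Zero baseline power, zero-variance
  correlation inputs, empty networks (no edges → path length
  undefined) and single-channel referencing all raise errors rather
  than returning silent zeros; all-zero weight matrices return zero
  clustering without error (a well-defined limit).
* **Seeds.** Every stage of `run_pipeline` derives its own seed from
  the master seed and a stage tag through an integer-hash chain
  (`derive_seed`), so stages can be re-run in isolation and a full run
  is bit-reproducible; all derived seeds stay below 2³¹.

## Problem sizes

The shipped configurations are sized for a laptop: the demo cohort is
15 vs 15 subjects × 60 epochs × 68 regions × 2,001 samples;
permutation counts default to 1,000 (cluster) and 10,000 (correlation)
but the demo and test configurations use 40–500; the calibration suite
uses 200 null datasets at 200 permutations. These are package choices
documented here so that users scaling up to full cohorts and
permutation counts know which knobs to turn (`run_config`'s `stats`
block, and `power$step` for the power-map time grid).

## Known limitations

* Source estimation (head models, minimum-norm inversion) is out of
  scope: the pipeline starts from region-level signals, real or
  simulated. EDF import of raw sensor recordings is not provided; the
  epoch container round-trips through RDS files and delimited tables.
* The atlas adjacency radius (40 mm) is a documented stand-in for the
  unspecified neighborhood definition used by source-level cluster
  corrections in common toolboxes.
* Effect sizes of the synthetic cohort are calibrated to the reference
  summaries' ballpark, not to patient data; magnitudes of the raw
  indices (e.g. global strength ~1.7 on synthetic Δ-iCoh weights vs
  ~16–20 in the reference tables) differ because the reference values
  reflect estimator details of the original recordings that the
  synthetic noise model does not reproduce.
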