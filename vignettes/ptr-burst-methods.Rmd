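---
title: "Methods: burst analysis of post-task responses with per-region TDE-HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst analysis of post-task responses with per-region TDE-HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## 1. The model

### Bursts, not sustained oscillations

Trial-averaged time-frequency maps of M/EEG data show post-task responses
(PTRs): induced power increases after a task or stimulus period ends, of
which the post-movement beta rebound is the best-known example. In single
trials these responses are carried by transient bursts — short
high-amplitude narrowband events — so the trial average measures the
*probability* of a burst occurring at each latency, not the amplitude of
a sustained oscillation. The package's job is to find those bursts
without committing to a frequency band in advance, and to characterise
the ones that drive PTRs.

### Per-region time-delay embedded HMM

Each region's (preprocessed, z-scored) timecourse $x_t$ is lag-embedded:
the observation at time $t$ is the vector
$y_t = (x_{t-L}, \dots, x_t, \dots, x_{t+L})$ of $2L + 1$ lags spanning a
230 ms window. A $K$-state hidden Markov model with zero-mean Gaussian
emissions $y_t \mid z_t = k \sim \mathcal N(0, \Sigma_k)$ is fitted per
region; each $\Sigma_k$ is a lag-space covariance, i.e. an
autocovariance window, so each state carries a spectral fingerprint
without any band-pass filtering. $K = 3$: one state for bursts, one for
other task-locked activity (e.g. evoked responses), one to satisfy
continuity — active when neither of the others is.

Assumptions worth stating: states are mutually exclusive and Markovian;
emissions are stationary zero-mean Gaussians within state (amplitude
information enters through the covariance scale); and one model per
region suffices, i.e. no cross-region coupling is modelled at the
inference stage — cross-region structure is recovered afterwards by
clustering.

### Inference: maximum-likelihood EM

Inference is Baum–Welch EM with a scaled forward–backward E-step
(implemented in C++) and closed-form M-step. This is a deliberate,
documented substitution for the variational Bayesian inference used in
the HMM-MAR software lineage: EM is fully specifiable from first
principles, every quantity consumed downstream (posteriors, binary
timecourses, lifetimes) is a point estimate that is insensitive to the
prior at these data sizes, and an exact brute-force likelihood oracle can
certify the implementation (section 5).

Numerical choices:

* **Initialisation** — per-state covariances from a random partition of
  the valid timepoints, with a uniform scale jitter in $[0.8, 1.25]$ so
  the partition covariances are not numerically identical; transition
  matrix diagonally dominant (0.9 self-transition).
* **Restarts** — `nRestarts = 5` by default. Restarts are compared after
  a 10-iteration burn-in and only the best burn-in is run to
  convergence; this short-run selection is the standard economy over
  running every restart to convergence and selects the same basin in
  practice.
* **Convergence** — relative log-likelihood increase below `tol = 1e-6`,
  cap `maxIter = 100`. EM guarantees a non-decreasing log-likelihood; if
  floating-point effects ever produce a decrease beyond `1e-8` the run
  stops and keeps the previous parameters.
* **Regularisation** — every M-step covariance gets a ridge of
  `1e-6 × mean(diag)` to prevent degeneracy on short runs.
* **Embedding edges** — edge columns (and columns whose lag window
  straddles a participant boundary) are zero-padded but flagged invalid:
  they contribute no emission term to the likelihood, so transition
  estimates are not biased by padding or participant changeovers.

### Binarisation and lifetimes

Posteriors are thresholded at $2/3$ with a strict inequality: a state is
"on" only where its posterior *exceeds* the threshold, so ties at
exactly $2/3$ are off and any threshold above $1/2$ preserves mutual
exclusivity by the pigeonhole principle. Maximal runs of on-samples
become state lifetimes — burst durations for the burst state. Runs that
touch a concatenation boundary are split there and each half attributed
to its own participant, so no burst spans two participants.

## 2. Grouping states across regions

Because each region is fitted independently, state 1 in one region has
nothing to do with state 1 in another. The stacked binary timecourses
(regions × K rows; 234 for 78 regions and K = 3) are clustered by
k-means with k = 3 — the minimum able to separate three states; no
automatic model-order selection is attempted, since only the PTR cluster
is consumed downstream. The engine is `stats::kmeans` (Lloyd) wrapped in
seeded restarts (`nInit = 10`, best inertia kept); a start that yields an
empty cluster is re-seeded and logged. Per-row Euclidean distance to the
assigned centroid is retained as a cluster-quality measure.

The **PTR cluster** is identified from trial-averaged probability
evolutions: each (region, state) posterior is epoched by block and
averaged, evolutions are averaged within clusters, and the cluster
maximising *mean probability in the PTR window minus mean probability in
a baseline window* is selected. In practice this cluster is usually
identified by eye from the evolutions; the contrast is a reproducible
operationalisation of that judgement, with the baseline defaulting to the final 10 s
of rest (clear of both task and PTR windows) and a manual override
available by passing an explicit cluster index downstream. A tie within
`1e-9` raises an error demanding manual selection rather than guessing.

The **noise-sweep simulation** validates that k-means on binary
timecourses recovers planted structure: three mutually exclusive binary
templates are replicated to 78 rows each (234 rows), a fraction of each
row's samples is replaced by fair coin flips, and median
Hungarian-matched agreement with the planted grouping is tracked as the
fraction sweeps 0–90%. The template length and corruption scheme are
package choices, stated here once: templates of 18 samples built from a 6-sample
cycle (each template "on" in its third of the cycle, mimicking mutually
exclusive state timecourses), and corruption by *replacement with a fair
coin* (so at 100% noise a row carries no signal, and expected agreement
is the chance level 1/3 after Hungarian matching). With these choices
agreement stays ≥ 0.95 up to 40% noise and first falls below 0.55
(near-chance) at 80% — recovery is reliable until the corruption level
overwhelms the shared temporal structure.

## 3. Burst metrics

* **State spectra** — the PSD of each state is estimated from the data
  samples where the state is on: on-segments (≥ 3 samples) are
  concatenated, cut into 2 s multitaper segments (DPSS tapers,
  time-bandwidth 4, i.e. a 4 Hz half-bandwidth), and averaged with
  segment-length weights. Splice points contribute broadband leakage
  that is negligible next to narrowband burst power. State spectra can
  equally be derived from the fitted model itself; the data route
  estimates the same quantity while being inference-engine-agnostic, and
  `modelPsd()` — the Fourier transform of the state's autocovariance
  read off its lag-covariance matrix, with a cosine lag taper —
  provides the model route as a cross-check. States with under 2 s of
  total on-time are flagged missing and excluded from summaries rather
  than estimated badly.
* **Band power** — trapezoidal area under the PSD in theta (4–8 Hz),
  alpha (8–13 Hz) and beta (13–30 Hz). The printed band edges at 8 and
  13 Hz are shared between bands; edges are assigned half-open
  `[low, high)` so nothing is double-counted — an arbitrary but stated
  convention.
* **Oscillations per burst** — mean burst duration × peak spectral
  frequency. The product, not the ratio (which would carry units of
  s²), is the dimensionally consistent cycle count, and is what is
  implemented.
* **Burst rate and coincidence** — bursts are assigned to task / PTR /
  remaining-rest windows by their midpoint; rates are counts per second
  of window time. Coincidence between two regions is the Jaccard index
  of on-samples in a window — a frequency-agnostic connectivity measure.
* **TFR reconstruction** — per state,
  $\mathrm{TFR}(f, t) = \mathrm{PSD}(f) \times p(t)$, summed over
  states; the reconstruction's agreement with a direct sliding-window
  multitaper spectrogram (0.5 s windows, 0.1 s hop — short enough to
  resolve ~300 ms bursts) is measured by Pearson correlation over block
  time and the burst band.

## 4. The synthetic-data generator

`generateDataset()` emulates the statistical structure the analysis
assumes, with exact ground truth:

* **Background** — $1/f^a$-coloured Gaussian noise (default $a = 1$, the
  standard electrophysiological noise model; no source specifies the
  real background), scaled to unit sample SD.
* **Bursts** — an inhomogeneous Poisson process with window-specific
  rates (task / PTR window / remaining rest; defaults 0.1, 0.4, 0.1
  bursts/s, placing a clear post-task elevation). Each burst is a
  carrier sinusoid with uniform random phase, duration drawn from a
  truncated normal (mean 0.3 s, SD 0.05 s, truncated at two carrier
  cycles and one sample — the canonical ~300 ms burst timescale),
  Hann-enveloped, at amplitude 3× the background SD by default (no
  source reports real amplitudes; 3× makes bursts visible in
  single-trial TFRs, and the default is exercised by the recovery
  tests). Overlapping same-region bursts are merged into one truth
  interval so truth is unambiguous.
* **Durations are truncated-normal, not geometric** — so the ground-truth
  mean duration is directly controlled for recovery tests, at the cost
  of not matching the geometric dwell-time implied by a Markov chain.
* **Block design** — defaults follow the n-back layout: 2 s instruction,
  30 s task, 30 s rest (62 s blocks), PTR window 0–7 s after task
  cessation; the grip-force layout (2/5/10 s grips, 30 s rest, PTR 2–6 s)
  is expressible through the same fields.
* **Sampling** — default 600 Hz acquisition so preprocessing exercises
  the 600 → 100 Hz path.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: cross-region burst co-occurrence (bursts are
independent across regions; real PTR bursts co-activate networks, which
makes the real clustering problem easier than the synthetic one in that
respect), evoked (phase-locked) responses, artefacts (eye blinks,
cardiac, SQUID resets), non-Gaussian or non-stationary backgrounds,
inter-participant variability beyond what independent seeds produce, and
any forward-model/leakage structure between parcels.

## 5. Validation strategy and problem sizes

The package certifies itself in layers (all in `tests/testthat/`):

* the forward-algorithm log-likelihood is checked against brute-force
  enumeration over all $K^T$ state paths on 50 random small instances
  ($K \le 3$, $T \le 8$), to $10^{-8}$;
* EM log-likelihood trajectories are checked non-decreasing (tolerance
  $10^{-8}$) on every fitted fixture;
* burst recovery runs the full pipeline on 20 regions (10/20 Hz
  carriers, 3× amplitude, 0.3 s bursts; four 62 s blocks at 600 Hz,
  analysed at 100 Hz) and scores the identified PTR state per region
  against ground truth (sample-wise Jaccard, lifetime error);
* the PTR-identification check uses ten regions (six with post-task
  modulation, four without) over five seeds, three blocks each;
* the wiring check runs 78 regions × K = 3 over three blocks and
  verifies exactly 234 timecourses enter clustering;
* statistics are validated against closed forms (null and
  signal-plus-noise R², Bonferroni arithmetic) and a planted-correlation
  power simulation (r = 0.8, n = 20, 500 replicates);
* the cross-task analogue pairs synthetic "tasks" sharing region specs
  (12 regions, 10 pairs) and regresses regional alpha power across
  tasks, with region-shuffled pairs as the collapse control.

Fixture sizes (blocks, regions, restart counts) are the package's chosen
desk-scale defaults for self-validation; they are stated in each test
and chosen so the full suite runs in minutes while leaving comfortable
margins on every threshold.

## 6. Known limitations

* EM point estimates carry no posterior uncertainty over state
  parameters; model-evidence-based choices of $K$ are out of scope.
* The 2/3 threshold discards low-confidence burst samples, shortening
  lifetimes slightly relative to truth (the recovery tests bound this
  below 20% under the default conditions).
* Whole-brain multivariate HMMs, autoregressive observation models, and
  harmonic analysis of beta bursts are out of scope.
* Z-scoring is per region on the concatenation (each region's HMM is
  univariate, so only per-region scale matters); a global scaling across
  regions would change nothing downstream except the covariance scale.
* The pipeline starts at region timecourses: beamforming,
  co-registration, artefact rejection and other sensor-level steps are
  upstream of this package.
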