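#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose top eigenvectors are the DPSS; tapers are normalised to unit
#' energy. Cached per (n, nw, k).
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product (default 4; reduced automatically for
#'   very short segments).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return n x k matrix of tapers.
#' @export
dpssTapers <- local({
  cache <- new.env(parent = emptyenv())
  function(n, nw = 4, k = NULL) {
    nw <- min(nw, max((n - 1) / 2, 0.5))
    if (is.null(k)) k <- max(1L, floor(2 * nw - 1))
    k <- min(k, n)
    key <- sprintf("%d-%g-%d", n, nw, k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    w <- nw / n
    t0 <- seq_len(n) - 1
    diag0 <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
    offd <- (seq_len(n - 1)) * (n - seq_len(n - 1)) / 2
    A <- matrix(0, n, n)
    diag(A) <- diag0
    A[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- offd
    A[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- offd
    ev <- eigen(A, symmetric = TRUE)
    tap <- ev$vectors[, seq_len(k), drop = FALSE]
    # conventional polarity: even tapers positive mean, odd positive slope
    for (j in seq_len(k)) {
      s <- if (j %% 2L == 1L) sum(tap[, j]) else sum(diff(tap[, j]))
      if (s < 0) tap[, j] <- -tap[, j]
    }
    tap <- sweep(tap, 2L, sqrt(colSums(tap^2)), "/")
    cache[[key]] <- tap
    tap
  }
})

# one-sided multitaper PSD of one segment on an nfft grid
mtSegmentPsd <- function(x, fs, nfft, nw = 4) {
  n <- length(x)
  tap <- dpssTapers(n, nw)
  Xt <- matrix(0, nfft, ncol(tap))
  for (j in seq_len(ncol(tap))) {
    padded <- c(x * tap[, j], rep(0, nfft - n))
    Xt[, j] <- Mod(stats::fft(padded))^2
  }
  half <- seq_len(nfft %/% 2 + 1L)
  S <- rowMeans(Xt)[half] / fs
  S[-c(1L, length(half))] <- 2 * S[-c(1L, length(half))]
  S
}

#' Multitaper PSD of a state's on-segments
#'
#' Estimates the spectral fingerprint of one HMM state directly from the
#' data samples where the state is on. On-segments of at least 3 samples
#' are concatenated (bursts are far shorter than a stable spectral
#' window), the concatenation is cut into `segLen`-second multitaper
#' segments, and segment PSDs are averaged with segment-length weights.
#' The splice points contribute broadband leakage that is negligible next
#' to the narrowband burst power. Returns `NULL` with a warning when
#' total on-time is below `minOnTime` (the estimate would be too unstable
#' to summarise).
#'
#' @param x numeric signal vector.
#' @param onoff 0/1 vector, same length: the state's binary timecourse.
#' @param fs sampling rate, Hz.
#' @param nw time-bandwidth product (default 4: a 4 Hz half-bandwidth on
#'   2 s segments, separating the canonical bands).
#' @param segLen multitaper segment length, seconds (default 2).
#' @param nfft FFT length (default 512, a <= 0.2 Hz grid at 100 Hz).
#' @param minOnTime minimum total on-time in seconds (default 2).
#' @param peakRange range in Hz over which the peak frequency is located
#'   (default `c(3, 45)`).
#' @return a [StateSpectrum-class], or `NULL` if on-time is insufficient.
#' @export
statePsd <- function(x, onoff, fs, nw = 4, segLen = 2, nfft = 512L,
                     minOnTime = 2, peakRange = c(3, 45)) {
  stopifnot(length(x) == length(onoff))
  runs <- runsOfOnes(onoff)
  keep <- runs[, 2L] - runs[, 1L] + 1L >= 3L
  runs <- runs[keep, , drop = FALSE]
  onTime <- if (nrow(runs)) sum(runs[, 2L] - runs[, 1L] + 1L) / fs else 0
  if (onTime < minOnTime) {
    warning(sprintf("state on-time %.2f s below %g s; spectrum flagged missing",
                    onTime, minOnTime))
    return(NULL)
  }
  concat <- unlist(lapply(seq_len(nrow(runs)),
                          function(i) x[runs[i, 1L]:runs[i, 2L]]))
  n <- round(segLen * fs)
  starts <- seq(1L, length(concat), by = n)
  segs <- lapply(starts, function(s) concat[s:min(s + n - 1L, length(concat))])
  segs <- segs[lengths(segs) >= max(3L, n %/% 4L)]  # drop tiny tail remnant
  if (!length(segs)) segs <- list(concat)
  lens <- lengths(segs)
  psds <- vapply(segs, mtSegmentPsd, numeric(nfft %/% 2 + 1L),
                 fs = fs, nfft = nfft, nw = nw)
  psd <- as.vector(psds %*% lens) / sum(lens)
  freqs <- (seq_len(nfft %/% 2 + 1L) - 1L) * fs / nfft
  inPeak <- freqs >= peakRange[1L] & freqs <= peakRange[2L]
  peak <- freqs[inPeak][which.max(psd[inPeak])]
  new("StateSpectrum", freqs = freqs, psd = psd, peakFreq = peak,
      onTime = onTime)
}

#' Model-derived state PSD (cross-check)
#'
#' The Fourier transform of the state's autocovariance sequence, read off
#' the fitted lag-space covariance matrix (averaging the matrix
#' diagonals). Independent of the data-segment route of [statePsd()] and
#' used to cross-check it; negative ripple from the finite lag window is
#' clipped at zero.
#'
#' @param fit a [TdeHmmFit-class].
#' @param state state index.
#' @param freqs frequency grid, Hz (default 0.5-49.5 Hz by 0.5).
#' @return a [StateSpectrum-class].
#' @export
modelPsd <- function(fit, state, freqs = seq(0.5, 49.5, by = 0.5)) {
  S <- fit@covariances[[state]]
  d <- nrow(S)
  acv <- vapply(0:(d - 1L), function(tau) {
    mean(S[cbind(seq_len(d - tau), seq_len(d - tau) + tau)])
  }, 0)
  lagS <- (0:(d - 1L)) / fit@fs
  # Tukey-style taper on the lag window softens truncation ripple
  wgt <- 0.5 + 0.5 * cos(pi * (0:(d - 1L)) / d)
  psd <- vapply(freqs, function(f) {
    (acv[1L] + 2 * sum(wgt[-1L] * acv[-1L] * cos(2 * pi * f * lagS[-1L]))) / fit@fs
  }, 0)
  psd <- pmax(psd, 0)
  inPeak <- freqs >= 3 & freqs <= 45
  new("StateSpectrum", freqs = freqs, psd = psd,
      peakFreq = freqs[inPeak][which.max(psd[inPeak])],
      onTime = NA_real_)
}

trapezoidArea <- function(freqs, psd, low, high) {
  if (low < min(freqs) || high > max(freqs)) {
    stop("spectrum grid does not cover the requested band")
  }
  inside <- freqs > low & freqs < high
  f <- c(low, freqs[inside], high)
  p <- c(stats::approx(freqs, psd, low)$y, psd[inside],
         stats::approx(freqs, psd, high)$y)
  sum(diff(f) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}

#' Band power: area under the PSD in canonical bands
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, as trapezoidal area under
#' the PSD curve. Bands are treated half-open `[low, high)` so the shared
#' edges at 8 and 13 Hz are not double-counted.
#'
#' @param spec a [StateSpectrum-class].
#' @param bands named list of `(low, high)` pairs.
#' @return named numeric vector of band powers.
#' @export
bandPower <- function(spec,
                      bands = list(theta = c(4, 8), alpha = c(8, 13),
                                   beta = c(13, 30))) {
  vapply(bands, function(b) trapezoidArea(spec@freqs, spec@psd, b[1L], b[2L]), 0)
}

#' Per-region burst summary for the PTR state
#'
#' Mean and standard error of burst durations (state lifetimes) across
#' participants, oscillations per burst (mean duration times the state's
#' peak spectral frequency), and burst rate per window type (bursts per
#' second of task / PTR-window / remaining-rest time).
#'
#' @param bursts lifetime table (see [stateLifetimes()]) already filtered
#'   to one region's PTR state.
#' @param spec the state's [StateSpectrum-class] (may be `NULL`).
#' @param design the [BlockDesign-class] of the recording.
#' @param nParticipants number of concatenated participants (scales window
#'   time for rates).
#' @return one-row data.frame (`region`, `n_bursts`, `mean_duration_s`,
#'   `se_duration_s`, `peak_hz`, `cycles_per_burst`, `rate_task_hz`,
#'   `rate_ptr_hz`, `rate_rest_hz`), or `NULL` when `bursts` is empty
#'   (summary flagged missing with a warning).
#' @export
summarizeRegion <- function(bursts, spec, design, nParticipants = 1L) {
  if (is.null(bursts) || !nrow(bursts)) {
    warning("no bursts for this region; summary flagged missing")
    return(NULL)
  }
  region <- bursts$region[1L]
  perPart <- tapply(bursts$duration_s, bursts$participant, mean)
  meanDur <- mean(perPart)
  seDur <- if (length(perPart) > 1L) {
    stats::sd(perPart) / sqrt(length(perPart))
  } else if (nrow(bursts) > 1L) {
    stats::sd(bursts$duration_s) / sqrt(nrow(bursts))
  } else 0
  peak <- if (is.null(spec)) NA_real_ else spec@peakFreq
  # classify bursts by the window type their midpoint falls in
  bl <- blockLength(design)
  mid <- ((bursts$onset_s + bursts$offset_s) / 2) %% bl
  taskStart <- design@instructionDur
  taskEnd <- design@instructionDur + design@taskDur
  ptr <- taskEnd + design@ptrWindow
  type <- ifelse(mid >= taskStart & mid < taskEnd, "task",
                 ifelse(mid >= ptr[1L] & mid < ptr[2L], "ptr", "rest"))
  winTime <- c(
    task = design@taskDur,
    ptr = diff(design@ptrWindow),
    rest = bl - design@taskDur - diff(design@ptrWindow)
  ) * design@nBlocks * nParticipants
  rate <- vapply(c("task", "ptr", "rest"),
                 function(w) sum(type == w) / winTime[[w]], 0)
  data.frame(region = region, n_bursts = nrow(bursts),
             mean_duration_s = meanDur, se_duration_s = seDur,
             peak_hz = peak, cycles_per_burst = meanDur * peak,
             rate_task_hz = rate[["task"]], rate_ptr_hz = rate[["ptr"]],
             rate_rest_hz = rate[["rest"]])
}

#' Reconstruct a time-frequency representation from state outputs
#'
#' The TFR of a region is reconstructed as the matrix product of the state
#' probability timecourses with the state power spectra: per state,
#' `TFR(f, t) = psd(f) * probability(t)`; the total reconstruction is the
#' sum over states. Time axis equals the probability-evolution axis.
#'
#' @param probs K x T matrix of state probability timecourses (e.g. one
#'   region's rows of a [ProbabilityEvolution-class]).
#' @param specs list of K [StateSpectrum-class] (entries may be `NULL`;
#'   those states contribute nothing).
#' @return list with `freqs`, `perState` (list of freq x time matrices)
#'   and `total`.
#' @export
reconstructTfr <- function(probs, specs) {
  probs <- as.matrix(probs)
  if (length(specs) != nrow(probs)) {
    stop("need one spectrum per state probability row")
  }
  grids <- lapply(Filter(Negate(is.null), specs), function(s) s@freqs)
  if (!length(grids)) stop("all state spectra are missing")
  freqs <- grids[[1L]]
  if (!all(vapply(grids, function(g) identical(g, freqs), TRUE))) {
    stop("state spectra are on different frequency grids")
  }
  perState <- vector("list", nrow(probs))
  total <- matrix(0, length(freqs), ncol(probs))
  for (k in seq_len(nrow(probs))) {
    if (is.null(specs[[k]])) next
    perState[[k]] <- outer(specs[[k]]@psd, probs[k, ])
    total <- total + perState[[k]]
  }
  list(freqs = freqs, perState = perState, total = total)
}

#' Direct multitaper spectrogram
#'
#' Sliding-window multitaper PSD, the conventional TFR estimate that the
#' state-based reconstruction ([reconstructTfr()]) is compared against.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param window window length, seconds (default 0.5 — short enough to
#'   resolve ~300 ms bursts).
#' @param step hop between window centres, seconds (default 0.1).
#' @param nw time-bandwidth product (default 2 for the short window).
#' @param nfft FFT length (default 512).
#' @return list with `freqs`, `times` (window centres, s) and `power`
#'   (freq x time matrix).
#' @export
mtSpectrogram <- function(x, fs, window = 0.5, step = 0.1, nw = 2,
                          nfft = 512L) {
  n <- round(window * fs)
  hop <- max(1L, round(step * fs))
  starts <- seq(1L, length(x) - n + 1L, by = hop)
  power <- vapply(starts, function(s) {
    mtSegmentPsd(x[s:(s + n - 1L)], fs, nfft, nw)
  }, numeric(nfft %/% 2 + 1L))
  list(freqs = (seq_len(nfft %/% 2 + 1L) - 1L) * fs / nfft,
       times = (starts - 1L + n / 2) / fs,
       power = power)
}

#' Fidelity of a state-based TFR reconstruction
#'
#' Correlates a reconstructed TFR (see [reconstructTfr()]) against the
#' trial-averaged direct multitaper spectrogram of the same region, over
#' block time and a frequency band. Both estimate the same induced power
#' modulation, so agreement is reported as a Pearson correlation.
#'
#' @param x the region's signal (concatenated blocks).
#' @param design the [BlockDesign-class].
#' @param fs sampling rate, Hz.
#' @param recon reconstruction list from [reconstructTfr()] whose time
#'   axis is block time at `fs`.
#' @param band `(low, high)` Hz over which to compare.
#' @param window,step spectrogram parameters, seconds.
#' @return list with `r` (Pearson correlation), `times`, `band`.
#' @export
tfrFidelity <- function(x, design, fs, recon, band, window = 0.5,
                        step = 0.1) {
  ep <- epochBlocks(x, design, fs)
  sg <- NULL
  for (b in seq_len(nrow(ep))) {
    s <- mtSpectrogram(ep[b, ], fs, window = window, step = step)
    sg <- if (is.null(sg)) s$power else sg + s$power
  }
  sg <- sg / nrow(ep)
  s1 <- mtSpectrogram(ep[1L, ], fs, window = window, step = step)
  fsel <- s1$freqs >= band[1L] & s1$freqs <= band[2L]
  if (!identical(length(recon$freqs), length(s1$freqs)) ||
      max(abs(recon$freqs - s1$freqs)) > 1e-9) {
    stop("reconstruction and spectrogram are on different frequency grids")
  }
  half <- round(window * fs / 2)
  reconAtTimes <- vapply(s1$times, function(tc) {
    c0 <- round(tc * fs)
    idx <- max(1L, c0 - half):min(ncol(recon$total), c0 + half)
    rowMeans(recon$total[, idx, drop = FALSE])
  }, numeric(length(recon$freqs)))
  r <- stats::cor(as.vector(sg[fsel, ]), as.vector(reconAtTimes[fsel, ]))
  list(r = r, times = s1$times, band = band)
}

#' Burst coincidence between two regions
#'
#' Jaccard index of the on-samples of two binary state timecourses within
#' a window: the fraction of time either region bursts during which both
#' do. A frequency-agnostic burst-connectivity measure.
#'
#' @param a,b 0/1 vectors of equal length.
#' @param window integer sample indices to evaluate over (default all).
#' @return Jaccard index in `[0, 1]` (`NA` if neither bursts).
#' @export
burstCoincidence <- function(a, b, window = seq_along(a)) {
  stopifnot(length(a) == length(b))
  if (!length(window)) stop("window must be non-empty")
  jaccardIndex(a[window], b[window])
}
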