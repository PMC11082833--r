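#' @import methods
NULL

#' BurstSpec: statistical description of one region's bursts
#'
#' A burst is a short (~100-500 ms) high-amplitude narrowband event riding
#' on 1/f background noise. Trial-averaged power changes in this framework
#' reflect changes in burst probability, not sustained oscillations.
#'
#' @slot carrierFreq carrier frequency in Hz (theta/alpha/beta range).
#' @slot amplitude peak carrier amplitude relative to the background SD.
#' @slot meanDuration mean burst duration in seconds.
#' @slot durationDispersion SD of the burst-duration distribution (seconds);
#'   durations are drawn from a truncated normal.
#' @slot envelope `"hanning"` (default) or `"rectangular"` amplitude envelope.
#' @export
setClass("BurstSpec",
  representation(carrierFreq = "numeric", amplitude = "numeric",
                 meanDuration = "numeric", durationDispersion = "numeric",
                 envelope = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@carrierFreq <= 0) msg <- c(msg, "carrierFreq must be > 0")
    if (object@meanDuration <= 0) msg <- c(msg, "meanDuration must be > 0")
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
    if (object@durationDispersion < 0) msg <- c(msg, "durationDispersion must be >= 0")
    if (!object@envelope %in% c("hanning", "rectangular")) {
      msg <- c(msg, "envelope must be 'hanning' or 'rectangular'")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a BurstSpec
#'
#' @param carrierFreq carrier frequency, Hz.
#' @param amplitude carrier amplitude relative to background SD; default 3
#'   makes single bursts visible in single-trial time-frequency maps.
#' @param meanDuration mean duration, s (default 0.3, the canonical burst
#'   timescale).
#' @param durationDispersion SD of durations, s.
#' @param envelope `"hanning"` or `"rectangular"`.
#' @return a [BurstSpec-class] object.
#' @export
burstSpec <- function(carrierFreq, amplitude = 3, meanDuration = 0.3,
                      durationDispersion = 0.05, envelope = "hanning") {
  new("BurstSpec", carrierFreq = carrierFreq, amplitude = amplitude,
      meanDuration = meanDuration, durationDispersion = durationDispersion,
      envelope = envelope)
}

#' RegionSpec: generative description of one parcellated region
#'
#' Encodes the task/PTR modulation of burst probability: a homogeneous
#' Poisson rate within each window type (task, post-task-response window,
#' remaining rest).
#'
#' @slot regionName unique region label (AAL-style string).
#' @slot burst a [BurstSpec-class].
#' @slot backgroundExponent 1/f background noise exponent (power ~ 1/f^a).
#' @slot rateTask,ratePtr,rateRest burst rates (bursts/s) in the task
#'   period, the PTR window, and remaining rest respectively.
#' @export
setClass("RegionSpec",
  representation(regionName = "character", burst = "BurstSpec",
                 backgroundExponent = "numeric", rateTask = "numeric",
                 ratePtr = "numeric", rateRest = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@rateTask, object@ratePtr, object@rateRest) < 0)) {
      msg <- c(msg, "rates must be >= 0")
    }
    if (!nzchar(object@regionName)) msg <- c(msg, "regionName must be non-empty")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RegionSpec
#' @param regionName unique region label.
#' @param burst a [BurstSpec-class] (see [burstSpec()]).
#' @param backgroundExponent 1/f exponent of the background (default 1,
#'   the standard electrophysiological noise model).
#' @param rateTask,ratePtr,rateRest window-specific burst rates, bursts/s.
#'   Defaults place a clear post-task elevation (0.4/s in the PTR window vs
#'   0.1/s elsewhere), mirroring a burst-probability-driven PTR.
#' @return a [RegionSpec-class] object.
#' @export
regionSpec <- function(regionName, burst = burstSpec(20),
                       backgroundExponent = 1,
                       rateTask = 0.1, ratePtr = 0.4, rateRest = 0.1) {
  new("RegionSpec", regionName = regionName, burst = burst,
      backgroundExponent = backgroundExponent, rateTask = rateTask,
      ratePtr = ratePtr, rateRest = rateRest)
}

#' BlockDesign: timing template of one experimental block
#'
#' A block is instruction + task + rest; the PTR window is expressed
#' relative to task cessation (start of rest).
#'
#' @slot instructionDur,taskDur,restDur durations in seconds.
#' @slot nBlocks number of blocks in the recording.
#' @slot ptrWindow `(start, end)` seconds after task cessation.
#' @slot conditionLabels one label per block (e.g. "1-back", "2-back").
#' @export
setClass("BlockDesign",
  representation(instructionDur = "numeric", taskDur = "numeric",
                 restDur = "numeric", nBlocks = "integer",
                 ptrWindow = "numeric", conditionLabels = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@ptrWindow) != 2L || diff(object@ptrWindow) <= 0) {
      msg <- c(msg, "ptrWindow must be (start, end) with end > start")
    }
    if (object@ptrWindow[1] < 0 || object@ptrWindow[2] > object@restDur) {
      msg <- c(msg, "ptrWindow must lie within [0, restDur]")
    }
    if (object@nBlocks < 1L) msg <- c(msg, "nBlocks must be >= 1")
    if (length(object@conditionLabels) != object@nBlocks) {
      msg <- c(msg, "need one condition label per block")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a BlockDesign
#'
#' Defaults describe the n-back working-memory design: a 2 s instruction
#' screen, a 30 s task period (1 s letters separated by 1 s pauses) and a
#' 30 s rest period, i.e. 62 s blocks, with the PTR window 0-7 s after
#' task cessation.
#'
#' @param instructionDur,taskDur,restDur seconds.
#' @param nBlocks number of blocks (default 16).
#' @param ptrWindow `(start, end)` s after task cessation.
#' @param conditionLabels labels, recycled to `nBlocks` if length 1.
#' @return a [BlockDesign-class] object.
#' @export
blockDesign <- function(instructionDur = 2, taskDur = 30, restDur = 30,
                        nBlocks = 16L, ptrWindow = c(0, 7),
                        conditionLabels = "task") {
  nBlocks <- as.integer(nBlocks)
  if (length(conditionLabels) == 1L) {
    conditionLabels <- rep(conditionLabels, nBlocks)
  }
  new("BlockDesign", instructionDur = instructionDur, taskDur = taskDur,
      restDur = restDur, nBlocks = nBlocks, ptrWindow = ptrWindow,
      conditionLabels = conditionLabels)
}

#' @describeIn BlockDesign-class block length in seconds.
#' @param design a [BlockDesign-class].
#' @export
blockLength <- function(design) {
  design@instructionDur + design@taskDur + design@restDur
}

#' SyntheticDataset: one participant's simulated region timecourses
#'
#' @slot data regions x time signal matrix (unit-SD background).
#' @slot fs sampling rate, Hz.
#' @slot design the [BlockDesign-class] used.
#' @slot regions list of [RegionSpec-class], one per row of `data`.
#' @slot truth data.frame of ground-truth bursts
#'   (`region`, `onset_s`, `offset_s`, `carrier_hz`).
#' @slot participantId label.
#' @slot seed integer seed the dataset was generated from.
#' @export
setClass("SyntheticDataset",
  representation(data = "matrix", fs = "numeric", design = "BlockDesign",
                 regions = "list", truth = "data.frame",
                 participantId = "character", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@data) != length(object@regions)) {
      msg <- c(msg, "row count must equal number of RegionSpec entries")
    }
    cf <- vapply(object@regions, function(r) r@burst@carrierFreq, 0)
    if (length(cf) && object@fs <= 2 * max(cf)) {
      msg <- c(msg, "fs must exceed twice the largest carrier frequency")
    }
    nm <- vapply(object@regions, function(r) r@regionName, "")
    if (anyDuplicated(nm)) msg <- c(msg, "region names must be unique")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn SyntheticDataset-class region names, in row order.
#' @param object,x a `SyntheticDataset`.
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname SyntheticDataset-class
#' @export
setMethod("regionNames", "SyntheticDataset", function(x) {
  vapply(x@regions, function(r) r@regionName, "")
})

#' @describeIn SyntheticDataset-class ground-truth burst table.
#' @export
groundTruth <- function(x) x@truth

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d regions x %d samples at %g Hz (%s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              object@participantId))
  cat(sprintf("  %d blocks of %g s; %d ground-truth bursts; seed %d\n",
              object@design@nBlocks, blockLength(object@design),
              nrow(object@truth), object@seed))
})

#' ConcatenatedSeries: per-region z-scored concatenation across participants
#'
#' @slot values regions x time matrix, z-scored per region over the full
#'   concatenation.
#' @slot fs sampling rate, Hz.
#' @slot boundaries sample indices at which participant segments abut
#'   (i.e. the last sample index of each non-final segment).
#' @slot segmentLabels participant/condition label per segment.
#' @slot regionNames one per row.
#' @export
setClass("ConcatenatedSeries",
  representation(values = "matrix", fs = "numeric", boundaries = "integer",
                 segmentLabels = "character", regionNames = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@regionNames) != nrow(object@values)) {
      msg <- c(msg, "one regionName per row required")
    }
    if (length(object@boundaries) &&
        any(object@boundaries <= 0 | object@boundaries >= ncol(object@values))) {
      msg <- c(msg, "boundaries must be interior sample indices")
    }
    if (length(object@segmentLabels) != length(object@boundaries) + 1L) {
      msg <- c(msg, "need one segment label per segment")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ConcatenatedSeries", function(object) {
  cat(sprintf("ConcatenatedSeries: %d regions x %d samples at %g Hz, %d segment(s)\n",
              nrow(object@values), ncol(object@values), object@fs,
              length(object@segmentLabels)))
})

#' @rdname ConcatenatedSeries-class
#' @param x a `ConcatenatedSeries`.
#' @export
setMethod("regionNames", "ConcatenatedSeries", function(x) x@regionNames)

#' TdeHmmFit: fitted time-delay embedded HMM for one region
#'
#' States are zero-mean Gaussians over lag-embedded vectors, so each state
#' is characterised by a lag-space covariance (an autocovariance window)
#' and hence carries a spectral fingerprint.
#'
#' @slot K number of states.
#' @slot transition K x K row-stochastic transition matrix.
#' @slot initial initial state distribution.
#' @slot covariances list of K lag-space covariance matrices.
#' @slot loglikTrajectory per-EM-iteration log-likelihood of the returned
#'   (best-restart) fit.
#' @slot gamma K x T posterior state probabilities.
#' @slot valid logical length-T mask; FALSE where the embedding was
#'   zero-padded (series edges, concatenation boundaries) and the
#'   likelihood was not evaluated.
#' @slot window embedding window, seconds.
#' @slot fs sampling rate, Hz.
#' @slot seed seed used for initialisation.
#' @export
setClass("TdeHmmFit",
  representation(K = "integer", transition = "matrix", initial = "numeric",
                 covariances = "list", loglikTrajectory = "numeric",
                 gamma = "matrix", valid = "logical", window = "numeric",
                 fs = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(abs(rowSums(object@transition) - 1) > 1e-9)) {
      msg <- c(msg, "transition rows must sum to 1")
    }
    if (abs(sum(object@initial) - 1) > 1e-9) {
      msg <- c(msg, "initial distribution must sum to 1")
    }
    if (nrow(object@gamma) != object@K) msg <- c(msg, "gamma must be K x T")
    cs <- colSums(object@gamma)
    if (any(abs(cs - 1) > 1e-6)) msg <- c(msg, "gamma columns must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn TdeHmmFit-class transition matrix accessor.
#' @param object,x a `TdeHmmFit`.
#' @export
transitionMatrix <- function(x) x@transition

#' @describeIn TdeHmmFit-class K x T posterior probability matrix (gamma).
#' @export
posterior <- function(x) x@gamma

#' @describeIn TdeHmmFit-class number of states.
#' @export
nStates <- function(x) x@K

setMethod("show", "TdeHmmFit", function(object) {
  cat(sprintf("TdeHmmFit: K = %d states, %d lags (%g ms window at %g Hz)\n",
              object@K, nrow(object@covariances[[1]]),
              1000 * object@window, object@fs))
  cat(sprintf("  T = %d, final log-likelihood %.2f after %d EM iterations\n",
              ncol(object@gamma), tail(object@loglikTrajectory, 1L),
              length(object@loglikTrajectory)))
})

#' BinaryStateMatrix: thresholded on/off state timecourses
#'
#' @slot onoff K x T matrix in \{0, 1\}.
#' @slot threshold the posterior probability threshold applied (default 2/3;
#'   any threshold > 1/2 guarantees mutual exclusivity).
#' @slot fs sampling rate, Hz.
#' @export
setClass("BinaryStateMatrix",
  representation(onoff = "matrix", threshold = "numeric", fs = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(object@onoff %in% c(0, 1))) msg <- c(msg, "entries must be 0/1")
    if (object@threshold > 0.5 && any(colSums(object@onoff) > 1)) {
      msg <- c(msg, "states must be mutually exclusive for threshold > 1/2")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn BinaryStateMatrix-class the on/off matrix.
#' @param x a `BinaryStateMatrix`.
#' @export
onOff <- function(x) x@onoff

setMethod("show", "BinaryStateMatrix", function(object) {
  fo <- rowMeans(object@onoff)
  cat(sprintf("BinaryStateMatrix: %d states x %d samples (threshold %.4g)\n",
              nrow(object@onoff), ncol(object@onoff), object@threshold))
  cat("  fractional occupancy:", paste(sprintf("%.3f", fo), collapse = " "), "\n")
})

#' StateTimecourseMatrix: stacked binary state timecourses across regions
#'
#' The clustering substrate: one row per (region, state) pair. For 78
#' regions and K = 3 this is 234 rows.
#'
#' @slot matrix n_rows x T binary matrix.
#' @slot regions region name per row.
#' @slot states state index (1-based) per row.
#' @export
setClass("StateTimecourseMatrix",
  representation(matrix = "matrix", regions = "character", states = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@regions) != nrow(object@matrix) ||
        length(object@states) != nrow(object@matrix)) {
      msg <- c(msg, "need region and state annotation per row")
    }
    if (!all(object@matrix %in% c(0, 1))) msg <- c(msg, "entries must be 0/1")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "StateTimecourseMatrix", function(object) {
  cat(sprintf("StateTimecourseMatrix: %d state timecourses (%d regions x %d states) x %d samples\n",
              nrow(object@matrix), length(unique(object@regions)),
              length(unique(object@states)), ncol(object@matrix)))
})

#' ClusterResult: k-means grouping of state timecourses across regions
#'
#' @slot k number of clusters.
#' @slot labels cluster index (1-based) per row of the clustered matrix.
#' @slot centroids k x T centroid matrix.
#' @slot distances per-row Euclidean distance to the row's own centroid
#'   (cluster quality: smaller means the centroid represents that state's
#'   dynamics better).
#' @slot inertia total within-cluster sum of squared distances.
#' @slot regions,states row annotations carried from the input.
#' @export
setClass("ClusterResult",
  representation(k = "integer", labels = "integer", centroids = "matrix",
                 distances = "numeric", inertia = "numeric",
                 regions = "character", states = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(object@labels < 1L | object@labels > object@k)) {
      msg <- c(msg, "labels must lie in 1..k")
    }
    if (length(unique(object@labels)) < object@k) {
      msg <- c(msg, "every cluster must be non-empty")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn ClusterResult-class cluster labels, one per row.
#' @param x a `ClusterResult`.
#' @export
clusterLabels <- function(x) x@labels

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k = %d, inertia %.3f\n", object@k, object@inertia))
  print(table(cluster = object@labels))
})

#' ProbabilityEvolution: trial-averaged state probability over one block
#'
#' @slot evolution n_rows x block-samples matrix of trial-averaged
#'   probabilities, one row per (region, state).
#' @slot regions,states row annotations.
#' @slot fs sampling rate, Hz.
#' @slot design the [BlockDesign-class] used for epoching.
#' @export
setClass("ProbabilityEvolution",
  representation(evolution = "matrix", regions = "character",
                 states = "integer", fs = "numeric", design = "BlockDesign"),
  validity = function(object) {
    msg <- NULL
    if (any(object@evolution < -1e-9 | object@evolution > 1 + 1e-9)) {
      msg <- c(msg, "probabilities must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ProbabilityEvolution", function(object) {
  cat(sprintf("ProbabilityEvolution: %d (region, state) rows x %d block samples at %g Hz\n",
              nrow(object@evolution), ncol(object@evolution), object@fs))
})

#' StateSpectrum: multitaper power spectral density of one state
#'
#' @slot freqs frequency grid, Hz.
#' @slot psd power at each frequency.
#' @slot peakFreq argmax of the PSD over 3-45 Hz.
#' @slot onTime total state-on time used, seconds.
#' @export
setClass("StateSpectrum",
  representation(freqs = "numeric", psd = "numeric", peakFreq = "numeric",
                 onTime = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@freqs) != length(object@psd)) {
      msg <- c(msg, "freqs and psd must align")
    }
    if (any(object@psd < 0)) msg <- c(msg, "psd must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "StateSpectrum", function(object) {
  cat(sprintf("StateSpectrum: %d frequencies in [%.2f, %.2f] Hz; peak %.2f Hz; %.1f s on-time\n",
              length(object@freqs), min(object@freqs), max(object@freqs),
              object@peakFreq, object@onTime))
})
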