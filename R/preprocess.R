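#' Zero-phase bandpass filter
#'
#' Butterworth bandpass applied forward-backward (zero phase), so burst
#' onset/offset timing — which downstream lifetime estimates depend on —
#' is not skewed by filter delay. DC is removed by the passband itself
#' (mean is subtracted first for numerical safety).
#'
#' @param x numeric vector, or a regions x time matrix filtered row-wise.
#' @param fs sampling rate, Hz.
#' @param band `(low, high)` passband edges in Hz; default `c(1, 150)`.
#' @param order filter order (default 4, applied twice by filtfilt).
#' @return filtered series, same shape as `x`.
#' @export
bandpassFilter <- function(x, fs, band = c(1, 150), order = 4L) {
  if (band[1L] <= 0 || band[2L] <= band[1L] || band[2L] >= fs / 2) {
    stop("band must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt1 <- function(v) {
    if (length(v) < 3 * (2 * order + 1)) {
      stop("series too short for the filter's impulse response")
    }
    signal::filtfilt(bf, v - mean(v))
  }
  if (is.matrix(x)) t(apply(x, 1L, filt1)) else filt1(x)
}

#' Downsample with anti-alias filtering
#'
#' For integer decimation factors an 8th-order Butterworth low-pass at 80%
#' of the new Nyquist is applied forward-backward before subsampling; for
#' non-integer ratios polyphase resampling (`signal::resample`) is used.
#' The canonical path is 600 to 100 Hz, a factor-6 decimation.
#'
#' @param x numeric vector or regions x time matrix.
#' @param fs current sampling rate, Hz.
#' @param targetFs new sampling rate, Hz (must be <= `fs`).
#' @return downsampled series; length `ceiling(T * targetFs / fs)` for
#'   integer factors.
#' @export
downsampleSeries <- function(x, fs, targetFs) {
  if (targetFs > fs) stop("targetFs must not exceed fs")
  if (targetFs == fs) return(x)
  down1 <- function(v) {
    ratio <- fs / targetFs
    if (abs(ratio - round(ratio)) < 1e-9) {
      lp <- signal::butter(8L, 0.8 * targetFs / fs, type = "low")
      v <- signal::filtfilt(lp, v)
      v[seq(1L, length(v), by = round(ratio))]
    } else {
      signal::resample(v, p = round(targetFs), q = round(fs))
    }
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, down1))
    rownames(out) <- rownames(x)
    out
  } else down1(x)
}

#' Concatenate per-participant series and z-score the concatenation
#'
#' Data are concatenated across participants (and conditions) so that a
#' single HMM describes each region; z-scoring is applied once to the
#' concatenated series (per region) to reduce between-participant variance.
#' Segment boundaries are recorded so downstream state lifetimes can be
#' split rather than spanning two participants.
#'
#' @param segments list of regions x time matrices (or vectors) sharing the
#'   same sampling rate and region order.
#' @param fs sampling rate, Hz.
#' @param labels one label per segment (participant/condition); defaults to
#'   `"seg1"`, `"seg2"`, ...
#' @param regionNames one name per region; defaults to rownames of the
#'   first segment.
#' @return a [ConcatenatedSeries-class]; per region, mean 0 and SD 1 to
#'   within 1e-9.
#' @export
concatZscore <- function(segments, fs, labels = NULL, regionNames = NULL) {
  if (!length(segments)) stop("empty segment list")
  segments <- lapply(segments, function(s) if (is.matrix(s)) s else matrix(s, 1L))
  nr <- nrow(segments[[1L]])
  if (any(vapply(segments, nrow, 0L) != nr)) {
    stop("all segments must have the same number of regions")
  }
  if (is.null(labels)) labels <- paste0("seg", seq_along(segments))
  if (is.null(regionNames)) {
    regionNames <- rownames(segments[[1L]])
    if (is.null(regionNames)) regionNames <- paste0("region", seq_len(nr))
  }
  lens <- vapply(segments, ncol, 0L)
  values <- do.call(cbind, segments)
  values <- t(apply(values, 1L, function(v) (v - mean(v)) / stats::sd(v)))
  boundaries <- as.integer(cumsum(lens)[-length(lens)])
  new("ConcatenatedSeries", values = values, fs = fs,
      boundaries = boundaries, segmentLabels = labels,
      regionNames = regionNames)
}

#' Epoch a series into blocks
#'
#' Cuts a time series (signal, posterior probability, or binary state row)
#' into one row per experimental block. Trailing partial blocks are
#' dropped with a warning, never zero-padded.
#'
#' @param x numeric vector covering whole blocks back-to-back.
#' @param design a [BlockDesign-class].
#' @param fs sampling rate, Hz.
#' @return `n_blocks x block-samples` matrix.
#' @export
epochBlocks <- function(x, design, fs) {
  bl <- round(blockLength(design) * fs)
  if (bl > length(x)) stop("block length exceeds series length")
  nb <- length(x) %/% bl
  if (nb * bl < length(x)) {
    warning(sprintf("dropping %d trailing samples (partial block)",
                    length(x) - nb * bl))
  }
  nb <- min(nb, design@nBlocks)
  matrix(x[seq_len(nb * bl)], nrow = nb, byrow = TRUE)
}

#' End-to-end preprocessing for a list of participants
#'
#' Bandpass filter, downsample and z-scored concatenation, in that order,
#' for a list of [SyntheticDataset-class] objects (or raw matrices sharing
#' `fs`).
#'
#' @param datasets list of [SyntheticDataset-class].
#' @param band bandpass edges, Hz.
#' @param targetFs output sampling rate, Hz.
#' @param filterOrder Butterworth order for the bandpass.
#' @return a [ConcatenatedSeries-class] at `targetFs`.
#' @export
preprocessDatasets <- function(datasets, band = c(1, 150), targetFs = 100,
                               filterOrder = 4L) {
  stopifnot(length(datasets) >= 1L)
  fs <- datasets[[1L]]@fs
  segs <- lapply(datasets, function(ds) {
    stopifnot(ds@fs == fs)
    x <- ds@data
    if (band[2L] < fs / 2) x <- bandpassFilter(x, fs, band, filterOrder)
    downsampleSeries(x, fs, targetFs)
  })
  concatZscore(segs, fs = targetFs,
               labels = vapply(datasets, function(d) d@participantId, ""),
               regionNames = regionNames(datasets[[1L]]))
}
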