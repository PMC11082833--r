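#' Generate a synthetic bursty multi-region dataset
#'
#' Simulates parcellated source-space timecourses in which short narrowband
#' bursts ride on 1/f background noise, with burst probability modulated by
#' the block design (task period, post-task-response window, remaining
#' rest). Every placed burst is recorded in a ground-truth table, so burst
#' recovery by the analysis pipeline can be scored exactly.
#'
#' Background is 1/f^exponent-coloured Gaussian noise scaled to unit sample
#' SD. Bursts are placed by an inhomogeneous Poisson process with
#' window-specific rates; each burst is a carrier sinusoid with uniform
#' random phase, duration drawn from a truncated normal (truncated below at
#' two carrier cycles and at one sample), enveloped and added to the
#' background. Overlapping bursts within a region are merged into a single
#' ground-truth interval so the truth is unambiguous.
#'
#' @param regions list of [RegionSpec-class] objects.
#' @param design a [BlockDesign-class].
#' @param fs sampling rate, Hz (default 600, the acquisition rate the
#'   preprocessing path downsamples from).
#' @param participantId label stored with the dataset.
#' @param seed integer seed; identical `(regions, design, fs, seed)`
#'   reproduce the dataset bit-for-bit.
#' @return a [SyntheticDataset-class].
#' @examples
#' ds <- generateDataset(list(regionSpec("M1", burstSpec(20))),
#'                       blockDesign(nBlocks = 2L), fs = 200, seed = 1)
#' ds
#' @export
generateDataset <- function(regions, design, fs = 600,
                            participantId = "sim-01", seed) {
  if (missing(seed)) stop("a seed must be supplied")
  if (!length(regions)) stop("region list must be non-empty")
  for (r in regions) validObject(r)
  validObject(design)
  cf <- vapply(regions, function(r) r@burst@carrierFreq, 0)
  if (fs <= 2 * max(cf)) {
    stop("sampling rate violates the Nyquist limit for a carrier frequency")
  }
  nT <- round(blockLength(design) * design@nBlocks * fs)
  withLocalSeed(substreamSeed(seed, "simulate"), {
    dat <- matrix(0, length(regions), nT)
    truth <- vector("list", length(regions))
    for (i in seq_along(regions)) {
      rs <- regions[[i]]
      bg <- onefNoise(nT, rs@backgroundExponent)
      bursts <- placeBursts(rs, design, fs, nT)
      sig <- bg
      if (nrow(bursts)) {
        for (b in seq_len(nrow(bursts))) {
          idx <- bursts$start[b]:bursts$end[b]
          tt <- (idx - bursts$start[b]) / fs
          env <- burstEnvelope(rs@burst@envelope, length(idx))
          sig[idx] <- sig[idx] + rs@burst@amplitude * env *
            sin(2 * pi * rs@burst@carrierFreq * tt + bursts$phase[b])
        }
        merged <- mergeIntervals(bursts$start, bursts$end)
        truth[[i]] <- data.frame(
          region = rs@regionName,
          onset_s = (merged[, 1L] - 1L) / fs,
          offset_s = merged[, 2L] / fs,
          carrier_hz = rs@burst@carrierFreq)
      } else {
        truth[[i]] <- data.frame(region = character(), onset_s = numeric(),
                                 offset_s = numeric(), carrier_hz = numeric())
      }
      dat[i, ] <- sig
    }
    truthDf <- do.call(rbind, truth)
    rownames(truthDf) <- NULL
    rownames(dat) <- vapply(regions, function(r) r@regionName, "")
    new("SyntheticDataset", data = dat, fs = fs, design = design,
        regions = regions, truth = truthDf, participantId = participantId,
        seed = as.integer(seed))
  })
}

# 1/f^a coloured Gaussian noise with exact unit sample SD
onefNoise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(as.vector(scale(w)))
  W <- stats::fft(w)
  freq <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L)))
  shape <- c(0, freq[-1L]^(-exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  as.vector(scale(x))
}

burstEnvelope <- function(type, n) {
  if (type == "rectangular") return(rep(1, n))
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))  # hanning
}

# windows of one block type across the recording: matrix (start_s, end_s)
designWindows <- function(design, type) {
  bl <- blockLength(design)
  t0 <- (seq_len(design@nBlocks) - 1L) * bl
  taskEnd <- t0 + design@instructionDur + design@taskDur
  switch(type,
    task = cbind(t0 + design@instructionDur, taskEnd),
    ptr  = cbind(taskEnd + design@ptrWindow[1L], taskEnd + design@ptrWindow[2L]),
    rest = {
      pre <- cbind(t0, t0 + design@instructionDur)          # instruction screen
      gap1 <- cbind(taskEnd, taskEnd + design@ptrWindow[1L])
      gap2 <- cbind(taskEnd + design@ptrWindow[2L], t0 + bl)
      w <- rbind(pre, gap1, gap2)
      w[w[, 2L] - w[, 1L] > 1e-12, , drop = FALSE]
    },
    stop("unknown window type"))
}

# Poisson burst placement for one region -> data.frame(start, end, phase) in samples
placeBursts <- function(rs, design, fs, nT) {
  rates <- c(task = rs@rateTask, ptr = rs@ratePtr, rest = rs@rateRest)
  minDur <- max(2 / rs@burst@carrierFreq, 1 / fs)
  out <- list()
  for (type in names(rates)) {
    if (rates[[type]] <= 0) next
    win <- designWindows(design, type)
    for (w in seq_len(nrow(win))) {
      len <- win[w, 2L] - win[w, 1L]
      nb <- stats::rpois(1L, rates[[type]] * len)
      if (nb == 0L) next
      onset <- sort(stats::runif(nb, win[w, 1L], win[w, 2L]))
      dur <- truncNorm(nb, rs@burst@meanDuration, rs@burst@durationDispersion,
                       minDur)
      phase <- stats::runif(nb, 0, 2 * pi)
      out[[length(out) + 1L]] <- data.frame(onset = onset, dur = dur,
                                            phase = phase)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), phase = numeric()))
  }
  b <- do.call(rbind, out)
  start <- pmax(1L, pmin(nT, as.integer(floor(b$onset * fs)) + 1L))
  end <- pmax(start, pmin(nT, as.integer(ceiling((b$onset + b$dur) * fs))))
  data.frame(start = start, end = end, phase = b$phase)
}

# truncated normal via rejection; lower truncation only
truncNorm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(pmax(mean, lower), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("duration distribution incompatible with its lower truncation")
    }
  }
  x
}

# merge overlapping/adjacent [start, end] sample intervals
mergeIntervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  outS <- integer(); outE <- integer()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      outS <- c(outS, ms); outE <- c(outE, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(c(outS, ms), c(outE, me))
}

#' Write a SyntheticDataset to a directory
#'
#' The container is plain text: `data.csv` (regions x time, no header),
#' `attrs.json` (sampling rate, participant, seed, dimensions),
#' `meta.json` (block design and region specs sidecar) and `truth.csv`
#' (ground-truth bursts, header `region,onset_s,offset_s,carrier_hz`).
#' The sampling rate is stored in both `attrs.json` and `meta.json`;
#' [readDataset()] cross-checks them.
#'
#' @param ds a [SyntheticDataset-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(ds, path) {
  validObject(ds)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(ds@data), file.path(path, "data.csv"),
                     col.names = FALSE)
  attrs <- list(fs = ds@fs, participant_id = ds@participantId,
                seed = ds@seed, n_regions = nrow(ds@data),
                n_samples = ncol(ds@data))
  jsonlite::write_json(attrs, file.path(path, "attrs.json"), auto_unbox = TRUE,
                       digits = NA)
  d <- ds@design
  meta <- list(
    fs = ds@fs, participant_id = ds@participantId,
    design = list(instruction_dur = d@instructionDur, task_dur = d@taskDur,
                  rest_dur = d@restDur, n_blocks = d@nBlocks,
                  ptr_window = d@ptrWindow,
                  condition_labels = d@conditionLabels),
    regions = lapply(ds@regions, function(r) list(
      region_name = r@regionName,
      carrier_freq = r@burst@carrierFreq, amplitude = r@burst@amplitude,
      mean_duration = r@burst@meanDuration,
      duration_dispersion = r@burst@durationDispersion,
      envelope = r@burst@envelope,
      background_exponent = r@backgroundExponent,
      rate_task = r@rateTask, rate_ptr = r@ratePtr, rate_rest = r@rateRest)))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  data.table::fwrite(ds@truth, file.path(path, "truth.csv"))
  invisible(path)
}

#' Read a SyntheticDataset written by [writeDataset()]
#'
#' @param path directory containing `data.csv`, `attrs.json`, `meta.json`
#'   and `truth.csv`.
#' @return a [SyntheticDataset-class].
#' @export
readDataset <- function(path) {
  need <- c("data.csv", "attrs.json", "meta.json", "truth.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("missing dataset file(s): ", paste(missing, collapse = ", "))
  }
  attrs <- jsonlite::read_json(file.path(path, "attrs.json"), simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = FALSE)
  if (!isTRUE(all.equal(as.numeric(attrs$fs), as.numeric(meta$fs)))) {
    stop("metadata mismatch: sampling rate differs between container attrs and sidecar")
  }
  dat <- as.matrix(data.table::fread(file.path(path, "data.csv"), header = FALSE))
  dimnames(dat) <- NULL
  md <- meta$design
  design <- new("BlockDesign", instructionDur = md$instruction_dur,
                taskDur = md$task_dur, restDur = md$rest_dur,
                nBlocks = as.integer(md$n_blocks),
                ptrWindow = as.numeric(unlist(md$ptr_window)),
                conditionLabels = as.character(unlist(md$condition_labels)))
  regions <- lapply(meta$regions, function(r) {
    new("RegionSpec", regionName = r$region_name,
        burst = new("BurstSpec", carrierFreq = r$carrier_freq,
                    amplitude = r$amplitude, meanDuration = r$mean_duration,
                    durationDispersion = r$duration_dispersion,
                    envelope = r$envelope),
        backgroundExponent = r$background_exponent,
        rateTask = r$rate_task, ratePtr = r$rate_ptr, rateRest = r$rate_rest)
  })
  truth <- as.data.frame(data.table::fread(file.path(path, "truth.csv")))
  if (!nrow(truth)) {
    truth <- data.frame(region = character(), onset_s = numeric(),
                        offset_s = numeric(), carrier_hz = numeric())
  }
  rownames(dat) <- vapply(regions, function(r) r@regionName, "")
  new("SyntheticDataset", data = dat, fs = as.numeric(attrs$fs),
      design = design, regions = regions, truth = truth,
      participantId = as.character(attrs$participant_id),
      seed = as.integer(attrs$seed))
}
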