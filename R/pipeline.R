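#' Pipeline configuration
#'
#' Collects every stage parameter with the pipeline's canonical
#' defaults: 1-150 Hz bandpass, 100 Hz analysis rate,
#' 230 ms embedding window, K = 3 states, 2/3 posterior threshold, k = 3
#' clusters, theta/alpha/beta bands, Bonferroni family of 4. Unknown keys
#' are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return a named list with class `ptrburstConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    band = c(1, 150), targetFs = 100, filterOrder = 4L,
    window = 0.230, K = 3L, threshold = 2 / 3,
    kClusters = 3L, ptrWindow = NULL, baselineWindow = NULL,
    bands = list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30)),
    nRestarts = 5L, tol = 1e-6, maxIter = 100L, nInit = 10L,
    mComparisons = 4L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  structure(cfg, class = "ptrburstConfig")
}

#' Write / read a pipeline configuration as JSON
#' @param cfg a `ptrburstConfig`.
#' @param path JSON file path.
#' @return `readConfig` returns a `ptrburstConfig`.
#' @export
writeConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$bands <- lapply(raw$bands, as.numeric)
  do.call(pipelineConfig, raw)
}

#' Run the full burst-analysis pipeline
#'
#' Executes the stages in order: preprocess (bandpass, downsample,
#' z-scored concatenation across participants), per-region TDE-HMM fits,
#' 2/3 posterior thresholding, k-means grouping of the stacked binary
#' state timecourses, PTR cluster identification from trial-averaged
#' probability evolutions, and per-region burst metrics for the PTR
#' state. All randomness derives from `seed` through named substreams, so
#' reruns are bit-reproducible.
#'
#' @param datasets list of [SyntheticDataset-class] (one per participant).
#' @param config a [pipelineConfig()].
#' @param seed integer root seed.
#' @param outDir optional directory for CSV outputs plus a run manifest.
#' @param verbose emit per-stage progress messages (default TRUE).
#' @return list with elements `series` ([ConcatenatedSeries-class]),
#'   `fits`, `binaries`, `stm`, `nClusterRows`, `clusters`
#'   ([ClusterResult-class]), `evolution`, `ptrCluster`, `ptrStates`
#'   (named per-region PTR state index), `lifetimes`, `spectra`,
#'   `bandPowers`, `summaries` and `config`.
#' @export
runPipeline <- function(datasets, config = pipelineConfig(), seed,
                        outDir = NULL, verbose = TRUE) {
  if (missing(seed)) stop("a seed must be supplied")
  say <- function(...) if (verbose) message(sprintf(...))
  design <- datasets[[1L]]@design
  say("preprocess: %d participant(s)", length(datasets))
  series <- preprocessDatasets(datasets, band = config$band,
                               targetFs = config$targetFs,
                               filterOrder = config$filterOrder)
  fs <- series@fs
  rn <- regionNames(series)
  fits <- vector("list", length(rn)); names(fits) <- rn
  binaries <- vector("list", length(rn)); names(binaries) <- rn
  for (i in seq_along(rn)) {
    say("tde-hmm: region %s (%d/%d)", rn[i], i, length(rn))
    fits[[i]] <- fitTdeHmm(series@values[i, ], fs = fs,
                           window = config$window, K = config$K,
                           seed = substreamSeed(seed, "hmm", i),
                           nRestarts = config$nRestarts, tol = config$tol,
                           maxIter = config$maxIter,
                           boundaries = series@boundaries)
    binaries[[i]] <- thresholdPosterior(fits[[i]], config$threshold)
  }
  stm <- stateTimecourseMatrix(binaries)
  say("clustering: %d state timecourses entering k-means", nrow(stm@matrix))
  clusters <- kmeansBinary(stm, k = config$kClusters,
                           seed = substreamSeed(seed, "kmeans-cluster"),
                           nInit = config$nInit)
  gammaRows <- do.call(rbind, lapply(fits, posterior))
  evolution <- probabilityEvolution(gammaRows, design, fs,
                                    regions = stm@regions, states = stm@states)
  ptrCluster <- identifyPtrCluster(evolution, clusterLabels(clusters),
                                   ptrWindow = config$ptrWindow,
                                   baselineWindow = config$baselineWindow)
  say("PTR cluster: %d", ptrCluster)
  # per region: its state assigned to the PTR cluster (best-quality on ties)
  ptrStates <- vapply(rn, function(r) {
    rows <- which(stm@regions == r & clusterLabels(clusters) == ptrCluster)
    if (!length(rows)) return(NA_integer_)
    stm@states[rows[which.min(clusters@distances[rows])]]
  }, 0L)
  segLabels <- series@segmentLabels
  lifetimes <- list(); spectra <- list(); powers <- list(); summaries <- list()
  for (i in seq_along(rn)) {
    lt <- stateLifetimes(binaries[[i]], boundaries = series@boundaries,
                         segmentLabels = segLabels, region = rn[i])
    lifetimes[[rn[i]]] <- lt
    k <- ptrStates[[rn[i]]]
    if (is.na(k)) next
    sp <- withCallingHandlers(
      statePsd(series@values[i, ], onOff(binaries[[i]])[k, ], fs),
      warning = function(w) invokeRestart("muffleWarning"))
    spectra[[rn[i]]] <- sp
    if (!is.null(sp)) powers[[rn[i]]] <- bandPower(sp, config$bands)
    sm <- withCallingHandlers(
      summarizeRegion(lt[lt$state == k, , drop = FALSE], sp, design,
                      nParticipants = length(segLabels)),
      warning = function(w) invokeRestart("muffleWarning"))
    summaries[[rn[i]]] <- sm
  }
  res <- list(series = series, fits = fits, binaries = binaries, stm = stm,
              nClusterRows = nrow(stm@matrix), clusters = clusters,
              evolution = evolution, ptrCluster = ptrCluster,
              ptrStates = ptrStates, lifetimes = lifetimes,
              spectra = spectra, bandPowers = powers,
              summaries = Filter(Negate(is.null), summaries),
              config = config)
  if (!is.null(outDir)) writeRunOutputs(res, outDir, seed)
  res
}

# CSV outputs plus a manifest tying config, seed and files together
writeRunOutputs <- function(res, outDir, seed) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cl <- res$clusters
  clusterCsv <- file.path(outDir, "clusters.csv")
  data.table::fwrite(data.frame(region = cl@regions, state = cl@states,
                                cluster = clusterLabels(cl),
                                distance = cl@distances), clusterCsv)
  ltCsv <- file.path(outDir, "lifetimes.csv")
  data.table::fwrite(do.call(rbind, res$lifetimes), ltCsv)
  smCsv <- file.path(outDir, "summaries.csv")
  if (length(res$summaries)) {
    data.table::fwrite(do.call(rbind, res$summaries), smCsv)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ptrburst")),
    seed = seed,
    config = unclass(res$config),
    ptr_cluster = res$ptrCluster,
    n_cluster_rows = res$nClusterRows,
    outputs = basename(c(clusterCsv, ltCsv,
                         if (length(res$summaries)) smCsv)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}
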