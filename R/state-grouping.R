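#' Stack binary state timecourses across regions
#'
#' Builds the clustering substrate: one row per (region, state) pair. With
#' 78 regions and K = 3 states this is the 234-row matrix that k-means
#' partitions.
#'
#' @param binaries named list of [BinaryStateMatrix-class], one per region.
#' @return a [StateTimecourseMatrix-class].
#' @export
stateTimecourseMatrix <- function(binaries) {
  stopifnot(length(binaries) >= 1L)
  nm <- names(binaries)
  if (is.null(nm)) nm <- paste0("region", seq_along(binaries))
  rows <- list(); regions <- character(); states <- integer()
  for (i in seq_along(binaries)) {
    m <- onOff(binaries[[i]])
    for (k in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <- m[k, ]
      regions <- c(regions, nm[i])
      states <- c(states, k)
    }
  }
  new("StateTimecourseMatrix", matrix = do.call(rbind, rows),
      regions = regions, states = states)
}

#' K-means clustering of binary state timecourses
#'
#' Groups univariate HMM states across regions by temporal similarity over
#' the entire scan: Lloyd iterations on the rows as points in
#' T-dimensional space, minimising the sum of squared Euclidean distances
#' to cluster centroids. States with high functional connectivity across
#' the brain (co-occurring on/off patterns) cluster together. The best of
#' `nInit` seeded starts by inertia is returned; a start that produces an
#' empty cluster is re-seeded (with a message).
#'
#' @param stm a [StateTimecourseMatrix-class] or a numeric matrix of row
#'   timecourses.
#' @param k number of clusters (default 3, the minimum able to separate
#'   three HMM states; no automatic model-order selection is attempted).
#' @param seed integer seed.
#' @param nInit number of restarts (default 10).
#' @param maxIter Lloyd iteration cap per start.
#' @return a [ClusterResult-class].
#' @export
kmeansBinary <- function(stm, k = 3L, seed, nInit = 10L, maxIter = 100L) {
  if (missing(seed)) stop("a seed must be supplied")
  if (is(stm, "StateTimecourseMatrix")) {
    m <- stm@matrix; regions <- stm@regions; states <- stm@states
  } else {
    m <- as.matrix(stm)
    regions <- rep(NA_character_, nrow(m)); states <- rep(NA_integer_, nrow(m))
  }
  k <- as.integer(k)
  if (k > nrow(m)) stop("k exceeds the number of state timecourses")
  best <- NULL
  for (r in seq_len(as.integer(nInit))) {
    km <- withLocalSeed(substreamSeed(seed, "kmeans", r), {
      attempt <- 1L
      repeat {
        centers <- m[sample.int(nrow(m), k), , drop = FALSE]
        res <- tryCatch(
          stats::kmeans(m, centers = centers, iter.max = maxIter,
                        algorithm = "Lloyd"),
          error = function(e) e)
        if (!inherits(res, "error")) break
        if (attempt >= 50L) stop("k-means failed: ", conditionMessage(res))
        if (grepl("empty cluster", conditionMessage(res))) {
          message("k-means start produced an empty cluster; re-seeding centroid")
        }  # duplicate initial centres are re-drawn silently
        attempt <- attempt + 1L
      }
      res
    })
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- as.integer(best$cluster)
  centroids <- best$centers
  dist <- sqrt(rowSums((m - centroids[labels, , drop = FALSE])^2))
  new("ClusterResult", k = k, labels = labels, centroids = unname(centroids),
      distances = dist, inertia = best$tot.withinss,
      regions = regions, states = states)
}

#' Trial-averaged state probability evolution over one block
#'
#' Epochs each (region, state) probability (or binary) timecourse by block
#' and averages across blocks, giving the probability evolution over a
#' single block — K timecourses per region.
#'
#' @param stm a [StateTimecourseMatrix-class], or a numeric matrix with one
#'   row per (region, state) timecourse (probabilities in `[0, 1]`).
#' @param design a [BlockDesign-class].
#' @param fs sampling rate, Hz.
#' @param regions,states optional row annotations when `stm` is a bare
#'   matrix.
#' @param conditions optional subset of condition labels: only blocks with
#'   these labels enter the average.
#' @return a [ProbabilityEvolution-class].
#' @export
probabilityEvolution <- function(stm, design, fs, regions = NULL,
                                 states = NULL, conditions = NULL) {
  if (is(stm, "StateTimecourseMatrix")) {
    m <- stm@matrix; regions <- stm@regions; states <- stm@states
  } else {
    m <- as.matrix(stm)
    if (is.null(regions)) regions <- rep(NA_character_, nrow(m))
    if (is.null(states)) states <- rep(NA_integer_, nrow(m))
  }
  bl <- round(blockLength(design) * fs)
  if (ncol(m) < bl) stop("series shorter than one block")
  keep <- NULL
  if (!is.null(conditions)) {
    keep <- which(design@conditionLabels %in% conditions)
    if (!length(keep)) stop("no blocks with the requested condition labels")
  }
  evo <- t(apply(m, 1L, function(v) {
    ep <- epochBlocks(v, design, fs)
    if (!is.null(keep)) ep <- ep[keep[keep <= nrow(ep)], , drop = FALSE]
    colMeans(ep)
  }))
  new("ProbabilityEvolution", evolution = evo, regions = regions,
      states = as.integer(states), fs = fs, design = design)
}

#' Average probability evolutions within clusters
#'
#' @param evo a [ProbabilityEvolution-class].
#' @param labels cluster label per row (e.g. from [clusterLabels()]).
#' @return k x block-samples matrix of cluster-centroid evolutions.
#' @export
clusterEvolutions <- function(evo, labels) {
  stopifnot(length(labels) == nrow(evo@evolution))
  k <- max(labels)
  t(vapply(seq_len(k), function(c) colMeans(evo@evolution[labels == c, , drop = FALSE]),
           numeric(ncol(evo@evolution))))
}

#' Identify the PTR state cluster
#'
#' Operationalises the visual criterion — the cluster whose average
#' evolution contains a post-task response — as the cluster maximising the
#' contrast (mean probability inside the PTR window) minus (mean
#' probability in a baseline window). The baseline defaults to the final
#' 10 s of the rest period, well clear of both the task and the PTR
#' window.
#'
#' @param evo a [ProbabilityEvolution-class].
#' @param labels cluster label per row.
#' @param ptrWindow `(start, end)` seconds after task cessation; defaults
#'   to the design's window.
#' @param baselineWindow `(start, end)` seconds after task cessation for
#'   the baseline; default last 10 s of rest.
#' @return the selected cluster index, with the per-cluster contrasts as
#'   attribute `"contrast"`.
#' @export
identifyPtrCluster <- function(evo, labels, ptrWindow = NULL,
                               baselineWindow = NULL) {
  design <- evo@design
  fs <- evo@fs
  if (is.null(ptrWindow)) ptrWindow <- design@ptrWindow
  if (is.null(baselineWindow)) {
    baselineWindow <- c(max(design@restDur - 10, ptrWindow[2L]), design@restDur)
  }
  taskEnd <- design@instructionDur + design@taskDur
  idx <- function(w) {
    a <- floor((taskEnd + w[1L]) * fs) + 1L
    b <- min(ceiling((taskEnd + w[2L]) * fs), ncol(evo@evolution))
    a:b
  }
  cent <- clusterEvolutions(evo, labels)
  contrast <- apply(cent, 1L, function(v) mean(v[idx(ptrWindow)]) -
                                          mean(v[idx(baselineWindow)]))
  ord <- order(contrast, decreasing = TRUE)
  if (abs(contrast[ord[1L]] - contrast[ord[2L]]) < 1e-9) {
    stop("PTR cluster contrast is tied; select the cluster manually")
  }
  structure(ord[1L], contrast = contrast)
}

#' Noise sweep of the binary-timecourse clustering
#'
#' Reconstruction of the clustering simulation: three distinct binary
#' template timecourses are each replicated into `rowsPerGroup` rows, a
#' fraction of every row's samples is replaced by fair coin flips, k-means
#' (k = 3) is run at each noise level, and Hungarian-matched agreement
#' with the ground-truth grouping is recorded. Clustering recovers the
#' templates until the noise level gets too high, at which point agreement
#' falls to near chance (1/3 for three balanced groups).
#'
#' @param noiseLevels fractions in `[0, 1]` to sweep (default 0 to 0.9 by
#'   0.1).
#' @param nSeeds clustering repetitions per level (default 20).
#' @param rowsPerGroup rows per template (default 78, one per region).
#' @param nTime template length in samples (default 18).
#' @param seed integer root seed.
#' @return data.frame with columns `noise`, `seed`, `agreement`, plus the
#'   per-level medians as attribute `"median"`.
#' @export
clusterNoiseSweep <- function(noiseLevels = seq(0, 0.9, by = 0.1),
                              nSeeds = 20L, rowsPerGroup = 78L,
                              nTime = 18L, seed = 1L) {
  templates <- stateTemplates(nTime)
  truthLab <- rep(1:3, each = rowsPerGroup)
  out <- list()
  for (nl in noiseLevels) {
    for (s in seq_len(nSeeds)) {
      rows <- withLocalSeed(substreamSeed(seed, sprintf("noise-%g", nl), s), {
        m <- templates[truthLab, , drop = FALSE]
        flip <- matrix(stats::runif(length(m)) < nl, nrow(m))
        coin <- matrix(stats::rbinom(length(m), 1L, 0.5), nrow(m))
        m[flip] <- coin[flip]
        m
      })
      cl <- kmeansBinary(rows, k = 3L,
                         seed = substreamSeed(seed, sprintf("noise-km-%g", nl), s),
                         nInit = 5L)
      out[[length(out) + 1L]] <- data.frame(
        noise = nl, seed = s,
        agreement = matchLabels(truthLab, clusterLabels(cl))$agreement)
    }
  }
  res <- do.call(rbind, out)
  med <- vapply(noiseLevels,
                function(nl) stats::median(res$agreement[res$noise == nl]), 0)
  structure(res, median = data.frame(noise = noiseLevels, agreement = med))
}

# three mutually exclusive binary templates: each "on" during its third of
# a repeating cycle, mimicking mutually exclusive HMM state timecourses
stateTemplates <- function(nTime, cycle = 6L) {
  stopifnot(cycle %% 3L == 0L)
  phase <- ((seq_len(nTime) - 1L) %% cycle) %/% (cycle %/% 3L)
  t(vapply(0:2, function(p) as.numeric(phase == p), numeric(nTime)))
}

#' Lowest noise level at which clustering breaks down
#'
#' Runs [clusterNoiseSweep()] and reports the smallest noise fraction whose
#' median Hungarian-matched agreement falls below `breakdown`.
#'
#' @inheritParams clusterNoiseSweep
#' @param breakdown agreement threshold for "near chance" (default 0.55).
#' @return the noise fraction (or `NA` if agreement never drops).
#' @export
noiseBreakdownLevel <- function(noiseLevels = seq(0, 0.9, by = 0.1),
                                nSeeds = 20L, rowsPerGroup = 78L,
                                nTime = 18L, seed = 1L, breakdown = 0.55) {
  sweep <- clusterNoiseSweep(noiseLevels, nSeeds, rowsPerGroup, nTime, seed)
  med <- attr(sweep, "median")
  hit <- med$noise[med$agreement < breakdown]
  if (!length(hit)) NA_real_ else min(hit)
}
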