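# Shared fixtures, built in code and memoised so expensive pipeline runs
# happen once per test session.
.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# six regions spanning theta/alpha/beta carriers, four 62 s blocks,
# acquisition-rate simulation and the full pipeline at analysis rate
sixRegionRun <- function() {
  memoFixture("sixRegionRun", function() {
    design <- blockDesign(nBlocks = 4L)
    regions <- list(
      regionSpec("F1", burstSpec(6)), regionSpec("P1", burstSpec(10)),
      regionSpec("M1", burstSpec(20)), regionSpec("V1", burstSpec(10)),
      regionSpec("T1", burstSpec(20)), regionSpec("C1", burstSpec(6)))
    ds <- generateDataset(regions, design, fs = 600, seed = 5)
    cfg <- pipelineConfig(nRestarts = 3L, maxIter = 50L)
    res <- suppressMessages(
      runPipeline(list(ds), cfg, seed = 1, verbose = FALSE))
    list(dataset = ds, result = res, design = design)
  })
}

# ground-truth binary timecourse at the analysis rate
truthOnOff <- function(ds, targetFs, region = NULL) {
  tr <- groundTruth(ds)
  if (!is.null(region)) tr <- tr[tr$region == region, , drop = FALSE]
  T <- round(ncol(ds@data) * targetFs / ds@fs)
  on <- rep(0, T)
  for (i in seq_len(nrow(tr))) {
    a <- floor(tr$onset_s[i] * targetFs) + 1L
    b <- min(ceiling(tr$offset_s[i] * targetFs), T)
    on[a:b] <- 1
  }
  on
}

# random valid HMM parameters for oracle tests
randomHmm <- function(K, d) {
  A <- matrix(stats::runif(K * K) + 0.1, K)
  A <- A / rowSums(A)
  p <- stats::runif(K) + 0.1
  p <- p / sum(p)
  covs <- lapply(seq_len(K), function(k) {
    M <- matrix(stats::rnorm(d * d), d)
    crossprod(M) / d + diag(d)
  })
  list(transition = A, initial = p, covariances = covs)
}
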