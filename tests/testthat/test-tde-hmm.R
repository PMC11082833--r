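test_that("embedding produces symmetric lags with zero-padded edges", {
  expect_equal(embeddingLags(0.230, 100), 23L)
  expect_equal(embeddingLags(0.230, 600), 139L)  # 138 rounded up to odd
  # constant series: every valid embedded column is identical
  emb <- embedSeries(rep(2, 50), 5L)
  vals <- emb$X[, emb$valid, drop = FALSE]
  expect_true(all(vals == 2))
  expect_false(any(emb$valid[c(1, 2, 49, 50)]))
  # unit impulse: exactly one 1 per row, at column t0 - lag
  t0 <- 20L
  x <- rep(0, 40); x[t0] <- 1
  emb <- embedSeries(x, 7L)
  for (l in 1:7) {
    lag <- l - 4L
    expect_equal(which(emb$X[l, ] == 1), t0 - lag)
    expect_equal(sum(emb$X[l, ]), 1)
  }
  # boundary columns are flagged invalid
  emb <- embedSeries(rnorm(60), 5L, boundaries = 30L)
  expect_false(any(emb$valid[29:32]))
  expect_true(emb$valid[25] && emb$valid[35])
  expect_error(embedSeries(rnorm(4), 5L), "shorter")
})

test_that("forward log-likelihood matches exact path enumeration", {
  withr::local_seed(42)
  for (i in 1:10) {
    K <- sample(2:3, 1)
    T <- sample(5:8, 1)
    par <- randomHmm(K, d = 2L)
    X <- matrix(rnorm(2 * T), 2)
    expect_equal(
      hmmLogLik(X, par$transition, par$initial, par$covariances),
      logLikBruteForce(X, par$transition, par$initial, par$covariances),
      tolerance = 1e-10)
  }
  # with an invalid-column mask
  par <- randomHmm(2L, 2L)
  X <- matrix(rnorm(2 * 6), 2)
  valid <- c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(
    hmmLogLik(X, par$transition, par$initial, par$covariances, valid),
    logLikBruteForce(X, par$transition, par$initial, par$covariances, valid),
    tolerance = 1e-10)
})

test_that("degenerate instances match their closed forms", {
  withr::local_seed(7)
  # K = 1: sum of per-sample Gaussian log-densities
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  X <- matrix(rnorm(2 * 5), 2)
  ll <- hmmLogLik(X, matrix(1, 1, 1), 1, list(S))
  direct <- sum(apply(X, 2, function(v) {
    -0.5 * (2 * log(2 * pi) + determinant(S)$modulus +
              drop(v %*% solve(S, v)))
  }))
  expect_equal(ll, direct, tolerance = 1e-10)
  # T = 1: log of the initial-weighted Gaussian mixture density
  par <- randomHmm(3L, 2L)
  x1 <- matrix(rnorm(2), 2)
  dens <- vapply(1:3, function(k) {
    Sk <- par$covariances[[k]]
    exp(-0.5 * (2 * log(2 * pi) + as.numeric(determinant(Sk)$modulus) +
                  drop(t(x1) %*% solve(Sk, x1))))
  }, 0)
  expect_equal(hmmLogLik(x1, par$transition, par$initial, par$covariances),
               log(sum(par$initial * dens)), tolerance = 1e-10)
})

test_that("EM recovers a known two-state generator", {
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  sim <- simulateHmm(5000, A, c(0.5, 0.5), list(diag(3), 9 * diag(3)),
                     seed = 42)
  fit <- ptrburst:::emFit(sim$X, rep(TRUE, 5000), K = 2L, seed = 1,
                          nRestarts = 3L, tol = 1e-6, maxIter = 100L)
  decoded <- apply(fit$gamma, 2, which.max)
  expect_gte(matchLabels(sim$states, decoded)$agreement, 0.95)
  expect_true(all(diff(fit$trajectory) > -1e-8))
  # transition persistence recovered
  perm <- matchLabels(sim$states, decoded)$permutation
  expect_gt(min(diag(fit$transition)), 0.9)
})

test_that("a single-state model yields unit posteriors", {
  x <- rnorm(500)
  fit <- fitTdeHmm(x, fs = 100, window = 0.05, K = 1L, seed = 1,
                   nRestarts = 1L)
  expect_equal(fit@transition, matrix(1, 1, 1))
  expect_true(all(posterior(fit) == 1))
})

test_that("state-label permutation leaves the likelihood unchanged", {
  withr::local_seed(3)
  par <- randomHmm(3L, 3L)
  X <- matrix(rnorm(3 * 200), 3)
  ll <- hmmLogLik(X, par$transition, par$initial, par$covariances)
  p <- c(3L, 1L, 2L)
  llPerm <- hmmLogLik(X, par$transition[p, p], par$initial[p],
                      par$covariances[p])
  expect_equal(ll, llPerm, tolerance = 1e-8)
})

test_that("posterior thresholding is strict and mutually exclusive", {
  gamma <- cbind(c(0.70, 0.20, 0.10), c(0.50, 0.30, 0.20),
                 c(1 / 3, 1 / 3, 1 / 3), c(0.05, 0.90, 0.05))
  bsm <- thresholdPosterior(gamma, fs = 100)
  expect_equal(onOff(bsm)[, 1], c(1, 0, 0))
  expect_equal(onOff(bsm)[, 2], c(0, 0, 0))
  expect_equal(onOff(bsm)[, 3], c(0, 0, 0))
  expect_equal(onOff(bsm)[, 4], c(0, 1, 0))
  expect_true(all(colSums(onOff(bsm)) <= 1))
  # exactly 2/3 is off under the strict rule
  g <- matrix(c(2 / 3, 1 / 3), 2, 1)
  expect_equal(sum(onOff(thresholdPosterior(g, fs = 1))), 0)
  expect_error(thresholdPosterior(gamma, threshold = 1.2), "threshold")
})

test_that("lifetimes convert runs to intervals and split at boundaries", {
  m <- matrix(c(0, 1, 1, 1, 0), 1)
  lt <- stateLifetimes(m, fs = 100)
  expect_equal(nrow(lt), 1L)
  expect_equal(lt$duration_s, 0.03)
  expect_equal(lt$onset_s, 0.01)
  expect_equal(lt$offset_s, 0.04)
  expect_equal(nrow(stateLifetimes(matrix(0, 1, 10), fs = 100)), 0L)
  # run crossing a concatenation boundary is split and re-attributed
  m2 <- matrix(c(0, 0, 1, 1, 1, 1, 0, 0), 1)
  lt2 <- stateLifetimes(m2, fs = 100, boundaries = 4L,
                        segmentLabels = c("p1", "p2"))
  expect_equal(nrow(lt2), 2L)
  expect_equal(lt2$duration_s, c(0.02, 0.02))
  expect_equal(lt2$participant, c("p1", "p2"))
  expect_equal(lt2$offset_s[1], 0.04)
  expect_error(stateLifetimes(m, fs = -1), "fs")
})

test_that("the burst state is recoverable from synthetic TDE data", {
  # alpha bursts at 3x background, 300 ms; two seeds at desk scale
  design <- blockDesign(nBlocks = 3L)
  for (s in 1:2) {
    rs <- regionSpec("A", burstSpec(10, amplitude = 3, meanDuration = 0.3))
    ds <- generateDataset(list(rs), design, fs = 600, seed = s)
    cs <- preprocessDatasets(list(ds), targetFs = 100)
    fit <- fitTdeHmm(cs@values[1, ], fs = 100, K = 3L, seed = 100 + s,
                     nRestarts = 3L, maxIter = 60L)
    on <- onOff(thresholdPosterior(fit))
    gt <- truthOnOff(ds, 100)
    jac <- vapply(1:3, function(k) jaccardIndex(on[k, ], gt), 0)
    expect_gte(max(jac), 0.6)
    k <- which.max(jac)
    lt <- stateLifetimes(on[k, , drop = FALSE], fs = 100)
    truthDur <- mean(groundTruth(ds)$offset_s - groundTruth(ds)$onset_s)
    expect_lt(abs(mean(lt$duration_s) - truthDur) / truthDur, 0.2)
  }
})
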