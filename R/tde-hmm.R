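#' @useDynLib ptrburst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Number of lags for a time-delay embedding window
#'
#' `round(window * fs)`, forced odd so the lags are symmetric about zero;
#' the default 230 ms window at 100 Hz gives 23 lags, wide enough to
#' resolve autocovariance structure across the canonical frequency bands.
#'
#' @param window embedding window, seconds (default 0.230).
#' @param fs sampling rate, Hz.
#' @return odd integer >= 3.
#' @export
embeddingLags <- function(window = 0.230, fs) {
  n <- as.integer(round(window * fs))
  if (n %% 2L == 0L) n <- n + 1L
  if (n < 3L) stop("embedding window shorter than 3 samples")
  n
}

#' Time-delay embed a series
#'
#' Builds the lag-embedded matrix whose row l holds the series shifted by
#' lag `l - (nLags + 1) / 2`, zero-padded at the edges. Edge columns (and
#' columns whose window straddles a concatenation boundary) are flagged
#' invalid: they are excluded from the HMM likelihood so transition
#' estimates are not biased by padding or by participant changeovers.
#'
#' @param x numeric vector.
#' @param nLags odd lag count (see [embeddingLags()]).
#' @param boundaries optional concatenation boundary sample indices.
#' @return list with `X` (nLags x T matrix) and `valid` (logical length T).
#' @export
embedSeries <- function(x, nLags, boundaries = integer()) {
  T <- length(x)
  if (nLags %% 2L != 1L) stop("nLags must be odd")
  if (T <= nLags) stop("series shorter than the embedding window")
  L <- (nLags - 1L) %/% 2L
  X <- matrix(0, nLags, T)
  for (l in seq_len(nLags)) {
    lag <- l - 1L - L
    src <- seq_len(T) + lag
    ok <- src >= 1L & src <= T
    X[l, ok] <- x[src[ok]]
  }
  valid <- rep(TRUE, T)
  valid[seq_len(L)] <- FALSE
  valid[(T - L + 1L):T] <- FALSE
  for (b in boundaries) {
    lo <- max(1L, b - L + 1L)
    hi <- min(T, b + L)
    valid[lo:hi] <- FALSE
  }
  list(X = X, valid = valid)
}

# emission log-densities of zero-mean Gaussian states; invalid columns get 0
emissionLogLik <- function(X, covariances, valid = NULL) {
  d <- nrow(X)
  K <- length(covariances)
  logB <- matrix(0, K, ncol(X))
  cols <- if (is.null(valid)) seq_len(ncol(X)) else which(valid)
  Xv <- X[, cols, drop = FALSE]
  for (k in seq_len(K)) {
    R <- chol(covariances[[k]])
    logdet <- 2 * sum(log(diag(R)))
    Y <- backsolve(R, Xv, transpose = TRUE)
    q <- colSums(Y * Y)
    logB[k, cols] <- -0.5 * (d * log(2 * pi) + logdet + q)
  }
  logB
}

#' Forward-algorithm log-likelihood of an HMM
#'
#' Scaled forward pass over zero-mean Gaussian emissions; the quantity the
#' brute-force path enumeration ([logLikBruteForce()]) must reproduce.
#'
#' @param X d x T observation matrix.
#' @param transition K x K row-stochastic matrix.
#' @param initial length-K initial distribution.
#' @param covariances list of K d x d covariance matrices.
#' @param valid optional logical mask; invalid columns contribute no
#'   emission term.
#' @return log-likelihood scalar.
#' @export
hmmLogLik <- function(X, transition, initial, covariances, valid = NULL) {
  logB <- emissionLogLik(X, covariances, valid)
  forwardBackwardC(logB, transition, initial)$loglik
}

#' Brute-force HMM log-likelihood by path enumeration
#'
#' Sums the joint density over all K^T hidden state paths; exact but
#' exponential, usable only for tiny instances. Serves as the independent
#' oracle for the forward algorithm.
#'
#' @inheritParams hmmLogLik
#' @return log-likelihood scalar.
#' @export
logLikBruteForce <- function(X, transition, initial, covariances,
                             valid = NULL) {
  T <- ncol(X)
  K <- length(initial)
  if (T > 10L || K > 3L) stop("instance too large for path enumeration")
  logB <- emissionLogLik(X, covariances, valid)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1L, function(z) {
    v <- log(initial[z[1L]]) + logB[z[1L], 1L]
    if (T > 1L) for (t in 2:T) {
      v <- v + log(transition[z[t - 1L], z[t]]) + logB[z[t], t]
    }
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

#' Fit a time-delay embedded HMM to one region's series
#'
#' Maximum-likelihood EM (Baum-Welch) for a K-state HMM whose states are
#' zero-mean Gaussians over lag-embedded vectors — each state is an
#' autocovariance pattern with a spectral fingerprint. The E-step is the
#' scaled forward-backward algorithm; the M-step re-estimates the
#' transition matrix, initial distribution and per-state lag-space
#' covariances (with a small ridge, `1e-6 x mean diagonal`, to prevent
#' degeneracy on short runs). The best of `nRestarts` random-partition
#' initialisations by final log-likelihood is returned.
#'
#' @param x numeric vector (one region, concatenated and z-scored), or a
#'   [ConcatenatedSeries-class] with a single row.
#' @param fs sampling rate, Hz.
#' @param window embedding window, seconds (default 0.230).
#' @param K number of states (default 3: one burst state, one state for
#'   other task-locked activity, one background state).
#' @param seed integer seed for initialisation.
#' @param nRestarts number of EM restarts (default 5).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter maximum EM iterations per restart (default 100).
#' @param boundaries concatenation boundary indices (taken from the
#'   `ConcatenatedSeries` if one is supplied).
#' @return a [TdeHmmFit-class].
#' @export
fitTdeHmm <- function(x, fs, window = 0.230, K = 3L, seed, nRestarts = 5L,
                      tol = 1e-6, maxIter = 100L, boundaries = integer()) {
  if (missing(seed)) stop("a seed must be supplied")
  if (is(x, "ConcatenatedSeries")) {
    stopifnot(nrow(x@values) == 1L)
    boundaries <- x@boundaries
    fs <- x@fs
    x <- as.vector(x@values[1L, ])
  }
  nLags <- embeddingLags(window, fs)
  emb <- embedSeries(x, nLags, boundaries)
  fit <- emFit(emb$X, emb$valid, K = as.integer(K), seed = seed,
               nRestarts = as.integer(nRestarts), tol = tol,
               maxIter = as.integer(maxIter))
  new("TdeHmmFit", K = as.integer(K), transition = fit$transition,
      initial = fit$initial, covariances = fit$covariances,
      loglikTrajectory = fit$trajectory, gamma = fit$gamma,
      valid = emb$valid, window = window, fs = fs, seed = as.integer(seed))
}

# EM core on an embedded matrix. Restarts are compared after a short burn-in
# (`initIter` iterations); the best burn-in by log-likelihood is then run to
# convergence. This short-run selection is the standard economy over running
# every restart to convergence and selects the same basin in practice.
emFit <- function(X, valid, K, seed, nRestarts, tol, maxIter, initIter = 10L) {
  stopifnot(K >= 1L)
  d <- nrow(X)
  if (sum(valid) < 10L * K * d) {
    stop("too few valid embedded columns for a stable fit")
  }
  cols <- which(valid)
  Xv <- X[, cols, drop = FALSE]
  best <- NULL
  for (r in seq_len(nRestarts)) {
    init <- withLocalSeed(substreamSeed(seed, "hmm-init", r), initEm(Xv, K))
    run <- emRun(Xv, cols, ncol(X), K, init, tol,
                 min(initIter, maxIter))
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (maxIter > initIter && length(best$trajectory) >= initIter) {
    head <- best$trajectory
    best <- emRun(Xv, cols, ncol(X), K, best, tol, maxIter - initIter)
    best$trajectory <- c(head, best$trajectory[-1L])
  }
  best
}

initEm <- function(Xv, K) {
  part <- sample(rep_len(seq_len(K), ncol(Xv)))
  covariances <- vector("list", K)
  mdiag <- mean(Xv^2)
  for (k in seq_len(K)) {
    Xk <- Xv[, part == k, drop = FALSE]
    S <- tcrossprod(Xk) / ncol(Xk) + diag(1e-4 * mdiag + 1e-8, nrow(Xv))
    # random scale jitter separates otherwise near-identical partition covariances
    covariances[[k]] <- S * stats::runif(1L, 0.8, 1.25)
  }
  A <- matrix(0.1 / max(K - 1L, 1L), K, K)
  diag(A) <- if (K > 1L) 0.9 else 1
  list(transition = A, initial = rep(1 / K, K), covariances = covariances)
}

# one EM run. Xv holds only the valid columns; `cols` maps them back into
# the full 1..T timeline (invalid columns carry no emission term but remain
# in the chain).
emRun <- function(Xv, cols, T, K, par, tol, maxIter) {
  d <- nrow(Xv)
  trajectory <- numeric(0)
  prev <- -Inf
  state <- par
  gamma <- NULL
  for (it in seq_len(maxIter)) {
    logB <- matrix(0, K, T)
    for (k in seq_len(K)) {
      R <- chol(state$covariances[[k]])
      Y <- backsolve(R, Xv, transpose = TRUE)
      logB[k, cols] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) +
                                 colSums(Y * Y))
    }
    fb <- forwardBackwardC(logB, state$transition, state$initial)
    ll <- fb$loglik
    if (!is.finite(ll)) stop("non-finite likelihood: degenerate covariance")
    if (it > 1L && ll < prev - 1e-8) {
      # numerical regression beyond tolerance: keep the previous parameters
      break
    }
    trajectory <- c(trajectory, ll)
    gamma <- fb$gamma
    converged <- it > 1L && (ll - prev) < tol * (1 + abs(ll))
    prev <- ll
    if (converged) break
    # M-step
    xi <- fb$xi
    A <- xi / pmax(rowSums(xi), .Machine$double.xmin)
    initial <- gamma[, 1L]
    initial <- initial / sum(initial)
    covariances <- vector("list", K)
    for (k in seq_len(K)) {
      w <- gamma[k, cols]
      sw <- sum(w)
      Xw <- Xv * rep(w, each = d)
      S <- tcrossprod(Xw, Xv) / sw
      S <- (S + t(S)) / 2
      covariances[[k]] <- S + diag(1e-6 * mean(diag(S)), d)
    }
    state <- list(transition = A, initial = initial, covariances = covariances)
  }
  list(transition = state$transition, initial = state$initial,
       covariances = state$covariances, gamma = gamma,
       trajectory = trajectory, loglik = prev)
}

#' Threshold posterior probabilities into binary state timecourses
#'
#' A state is "on" where its posterior probability strictly exceeds the
#' threshold. With any threshold above 1/2 at most one state can be on per
#' sample, so the binary timecourses inherit the HMM's mutual exclusivity;
#' ties at exactly the threshold are off.
#'
#' @param x a [TdeHmmFit-class] or a K x T posterior matrix.
#' @param threshold probability in (0, 1); default 2/3.
#' @param fs sampling rate (taken from the fit if supplied).
#' @return a [BinaryStateMatrix-class].
#' @export
thresholdPosterior <- function(x, threshold = 2 / 3, fs = NA_real_) {
  if (is(x, "TdeHmmFit")) {
    fs <- x@fs
    x <- x@gamma
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (any(x < -1e-9) || any(x > 1 + 1e-9)) stop("posterior entries must lie in [0, 1]")
  onoff <- (x > threshold) + 0
  new("BinaryStateMatrix", onoff = onoff, threshold = threshold, fs = fs)
}

#' Extract state lifetimes (burst intervals) from binary timecourses
#'
#' Maximal runs of "on" samples become (onset, offset, duration) records —
#' state lifetimes, equivalently burst durations for the burst state. Runs
#' that touch a concatenation boundary are split there and each half is
#' attributed to its own segment/participant, so no burst spans two
#' participants.
#'
#' @param x a [BinaryStateMatrix-class] or K x T 0/1 matrix.
#' @param fs sampling rate, Hz (taken from the object if supplied).
#' @param boundaries concatenation boundary sample indices (last sample of
#'   each non-final segment).
#' @param segmentLabels participant label per segment.
#' @param region region name stamped on the rows.
#' @return data.frame with columns `region`, `state`, `onset_s`,
#'   `offset_s`, `duration_s`, `participant`.
#' @export
stateLifetimes <- function(x, fs = NA_real_, boundaries = integer(),
                           segmentLabels = NULL, region = "region1") {
  if (is(x, "BinaryStateMatrix")) {
    fs <- x@fs
    x <- x@onoff
  }
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  T <- ncol(x)
  segEnds <- c(sort(as.integer(boundaries)), T)
  if (is.null(segmentLabels)) segmentLabels <- paste0("seg", seq_along(segEnds))
  out <- list()
  for (k in seq_len(nrow(x))) {
    runs <- runsOfOnes(x[k, ])
    if (!nrow(runs)) next
    for (i in seq_len(nrow(runs))) {
      s <- runs[i, 1L]; e <- runs[i, 2L]
      cuts <- segEnds[segEnds >= s & segEnds < e]
      starts <- c(s, cuts + 1L)
      ends <- c(cuts, e)
      seg <- findInterval(starts - 1L, segEnds) + 1L
      out[[length(out) + 1L]] <- data.frame(
        region = region, state = k,
        onset_s = (starts - 1L) / fs, offset_s = ends / fs,
        duration_s = (ends - starts + 1L) / fs,
        participant = segmentLabels[seg])
    }
  }
  if (!length(out)) {
    return(data.frame(region = character(), state = integer(),
                      onset_s = numeric(), offset_s = numeric(),
                      duration_s = numeric(), participant = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$state, res$onset_s), , drop = FALSE]
}

#' Simulate observations from a Gaussian HMM
#'
#' Draws a hidden state path from the chain and zero-mean Gaussian
#' observations from each state's covariance. Used to validate inference
#' against a known generator.
#'
#' @param T number of samples.
#' @param transition,initial,covariances model parameters.
#' @param seed integer seed.
#' @return list with `X` (d x T) and `states` (length T).
#' @export
simulateHmm <- function(T, transition, initial, covariances, seed) {
  K <- length(initial)
  d <- nrow(covariances[[1L]])
  withLocalSeed(substreamSeed(seed, "hmm-sim"), {
    chols <- lapply(covariances, chol)
    z <- integer(T)
    z[1L] <- sample.int(K, 1L, prob = initial)
    for (t in seq_len(T)[-1L]) {
      z[t] <- sample.int(K, 1L, prob = transition[z[t - 1L], ])
    }
    X <- matrix(0, d, T)
    for (t in seq_len(T)) {
      X[, t] <- drop(crossprod(chols[[z[t]]], stats::rnorm(d)))
    }
    list(X = X, states = z)
  })
}
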